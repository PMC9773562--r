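---
title: "Phenomic proportions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenomic proportions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When an interspecific hybrid is produced — for example a common-bean line
derived from congruity backcrossing between *Phaseolus* species — breeders
and genebank curators want to know how much of each parent's phenotype the
hybrid still expresses. Molecular markers answer the ancestry question at
the genome level, but not at the level of what is actually *measurable* on
the plant: seed and pod shape, photosynthetic performance, yield
components. `phenoprop` quantifies that expressed contribution as a
**phenomic proportion**: the percentage of the hybrid's held-out
observations that a classifier, trained to distinguish the parents and
the hybrid, assigns to each parental class.

The pipeline has four stages, each usable on its own:

1. **Morphometry** — ImageJ-compatible shape descriptors from seed/pod
   images (thresholding, ROI extraction, calibrated measurement).
2. **Preprocessing** — multivariate outlier screening and 0–1
   standardization of descriptor panels.
3. **Classification and proportions** — PCA on the parents,
   PC-contribution weighting of descriptors, random-forest classification,
   and the confusion-matrix proportion estimate.
4. **Group comparison** — the heteroscedastic multivariate MATS statistic
   with parametric-bootstrap inference and pairwise post-hoc contrasts.

A synthetic-data module generates phenotype panels and images with known
ground truth, so every stage is testable end to end without field data.

## Image morphometry

Images are binarized with either the maximum-entropy (Kapur) criterion —
the level maximizing the summed Shannon entropies of the background and
foreground histogram classes — or Huang's fuzzy criterion, the level
minimizing the mean Shannon entropy of class-membership values
$u = 1 / (1 + |g - \mu_{class}| / C)$. Both are exhaustive searches over
the 256 candidate levels of an 8-bit histogram; the tests verify them
against an independent brute-force evaluation of each criterion. By
default seeds are binarized with maximum entropy and pods with Huang;
both are available per call. Foreground components use 8-connectivity,
the particle-analysis default in ImageJ-family software.

Twelve descriptors are measured per region of interest, in units fixed by
the pixels-per-cm scale: Area, Perimeter, Width, Height, Major, Minor,
Feret, MinFeret, Aspect Ratio ($= Major/Minor$), Circularity
($4\pi A / P^2$), Roundness ($4A / \pi \cdot Major^2$) and Solidity
($A / A_{hull}$). Conventions that matter:

* **Moment ellipse.** Major/Minor are the full axes of the ellipse with
  the region's normalized second central moments, $4\sqrt{\lambda}$, with
  $+1/12$ added to the axial moments so that each pixel counts as a unit
  square. A filled $100 \times 40$ rectangle then has an axis ratio of
  exactly 2.5 and a digitized disk is exact.
* **Perimeter.** Moore boundary tracing with the Vossepoel–Smeulders
  chain-code weights (0.980 per axial step, 1.406 per diagonal step,
  −0.091 per corner). This corner-corrected estimator gives digitized
  circles circularity ≈ 1; the raw crack length would give ≈ 0.79.
* **Feret diameters.** Computed on the convex hull of foreground *pixel
  centers*: Feret as the maximum vertex distance, MinFeret by a caliper
  sweep in 0.1° steps. On this convention a filled $200 \times 50$
  rectangle has Feret $\sqrt{199^2 + 49^2} \approx 204.9$ and MinFeret
  49 px.
* **Solidity.** Pixel-count area over the pixel-center hull area,
  clipped at 1: for convex regions the pixel-count area can exceed the
  center-hull area by up to half a boundary pixel, which is below the
  measurement resolution. Clipping keeps the $0 < S \le 1$ invariant
  while leaving concave (curved-pod) values untouched.
* Degenerate (collinear) regions get the minor axis floored at the
  one-pixel equivalent and are flagged in the output rather than
  silently measured.

## The synthetic study

`default_study_models()` and `generate_study_panel()` emulate a
four-accession study — three parents and one hybrid — across four
characterization components with the standard descriptor sets: seed and
pod morphometry (12 descriptors each), MultispeQ-style physiology (14
descriptors: Phi2, PhiNPQ, PhiNO, Chl, LEF, LTD, Fm', Fo', Fs', Fv'/Fm',
qL, qP, RFd, leaf thickness) and yield (PSW, PW, VW, SN, PHI, with
PHI $= 100 \cdot PSW / PW$).

Each parent is a multivariate normal; the hybrid is a **finite mixture**
over the parent distributions plus a hybrid-unique ("self") component.
The mixture weights are the ground-truth phenomic proportions, which is
what makes parameter-recovery testing possible: a perfect estimator
applied to a panel generated with weights (0.20, 0.10, 0.00, 0.70)
should report proportions near (20, 10, 0, 70).

Default conditions, chosen once: unit within-class standard deviation per
descriptor; class means mutually 6 sd apart (displacements along
orthonormal directions, or a regular simplex over PSW/VW/SN for yield,
whose PW and PHI columns are derived, not free); 150 units per class at
the workflow scale, 1000 at the recovery-test scale; hybrid mixture
weights (0.20, 0.10, 0.00, 0.70). Yield panels satisfy the accounting
constraints $PW = VW + PSW$ and $PHI = 100 \cdot PSW / PW$ by
construction. Synthetic images are dark objects on a light background
(intensities 40/220) with additive Gaussian noise; pods are capsules
around a quadratic arc whose sagitta-to-chord ratio is the `curvature`
parameter, so solidity decreases monotonically in it.

What the generator does **not** emulate: correlated descriptor blocks
within a class (covariances are diagonal by default, though any PSD
matrix is accepted), non-normal or skewed trait distributions,
repeated-measures structure across technical repetitions, G×E, or any
mechanistic photosynthesis model. Passing recovery tests therefore shows
the estimator is consistent under the stated mixture model — not that
field data meet that model.

## Classification and the proportion estimate

PCA is fitted on the *parents only*, centered and unit-scaled. Variable
contributions are $100 \cdot \ell_{jk}^2 / \sum_j \ell_{jk}^2$ per PC.
The retained set is the smallest number of leading PCs reaching 80%
cumulative explained variance (configurable). One weight per descriptor
is $w_j \propto \sum_{k \le r} contrib_{jk} \cdot evr_k$, normalized to
sum to 1, and the weighted panel is $w_j \times$ the 0–1 standardized
value. Standardization is fitted on parents and hybrid jointly by
default; values outside a fitted range (possible when fitting on a
subset) are clipped to [0, 1] and counted. Note that random forests
split each feature independently, so positive per-descriptor weights do
not change the forest's predictions; the weights matter for
interpretation and for any distance- or margin-based learner swapped in
downstream.

Forests use 100 trees on a stratified 70/30 split with `randomForest`
defaults otherwise (mtry $= \lfloor\sqrt{p}\rfloor$, sampling with
replacement). Both error views are reported rather than conflated: the
OOB error from bagging on the training partition, and the confusion
matrix on the held-out 30%. Importances are the unscaled permutation
mean decrease in accuracy and the Gini decrease; feature selection
applies both thresholds jointly (negative MDA values are treated as
zero) with a top-5-by-MDA fallback. Vote ties are broken toward the
alphabetically first class so that reruns under one seed are identical.

The phenomic proportions of a component are read from the hybrid row of
the 4-class validation confusion matrix: the percentage of held-out
hybrid units predicted as each class. Because a single 70/30 split of a
few hundred units leaves only ~45 hybrid validation units (±several
percentage points of pure split noise), the estimate is averaged over 25
replicated splits with derived per-replicate seeds; `replicates = 1`
reproduces the single-split protocol. A parent whose distribution
coincides with the hybrid-self component is not identifiable from the
hybrid's observations — only the *sum* of the two attributions is — and
the tests assert exactly that honesty property.

## Outlier screening

Units are scored by the mean Euclidean distance to their $k$ nearest
neighbours ($k = \min(10, n-1)$) on per-descriptor z-scaled data, which
makes scores invariant to affine rescaling of any descriptor; the
flagging rule is the Tukey upper fence (Q3 + 1.5 IQR) on the scores.
Flagged units are excluded downstream but always written to a flag
table, never silently dropped. This kNN score is this package's own
screening choice: it is simple, parameter-light and pluggable, which
suits a filter whose exact settings are rarely reported in studies.

## MATS group comparison

For $a$ groups with $n_i$ observations of $d$ descriptors, the modified
ANOVA-type statistic is

$$Q_N = N\,(T\bar{y})^\top (T \hat{D}_N T^\top)^+ (T\bar{y}),$$

where $\bar{y}$ stacks the group mean vectors, $\hat{D}_N$ is the
diagonal of the stacked empirical covariances scaled by $N/n_i$,
$T = P_a \otimes I_d$ with $P_a$ the one-way centering projection, and
$^+$ the Moore–Penrose inverse. The diagonal standardization makes
$Q_N$ invariant to positive per-descriptor rescaling and well-defined
under heteroscedastic and even singular covariances. Inference uses the
parametric bootstrap (paramBS): each group is redrawn from a mean-zero
normal with its empirical covariance and original $n_i$, and
$p = \#\{Q^* \ge Q_{obs}\}/B$ with $B = 10{,}000$ by default.

Numerical choices: the quadratic form is computed after dividing each
descriptor by its root-mean scaled variance — mathematically a no-op by
the invariance property (the rescaling commutes with $H \otimes I_d$
contrasts), but it keeps the pseudo-inverse well-conditioned when
descriptors live on wildly different scales, where a relative singular
value cutoff would otherwise truncate genuine directions. Bootstrap
draws are generated in memory-bounded blocks; empirical covariances
that fail PSD numerically are eigenvalue-clipped with a warning.

The post-hoc step runs the two-group MATS bootstrap for every unordered
pair and reports unadjusted p-values alongside Holm-adjusted ones; the
multivariate post-hoc machinery behind a "Tukey multivariate test" label
is not uniquely defined in this setting, so both columns are given and
the choice is left explicit. The global null bootstrap uses mean-zero
draws, i.e. the null construction, not mean-recentering of alternatives.

## Problem sizes and test design

The verification suite checks, among others: Feret/MinFeret agreement
with an exhaustive 0.1° caliper sweep within 0.5% on 1000 random blobs;
threshold equality with brute-force criterion search; recovery of the
(20, 10, 0, 70) mixture within ±7 points at 1000 hybrid units and 25
replicated splits (observed error ≈ 2 points); OOB error ≤ 5% for
well-separated parents and chance-level OOB for permuted labels; MATS
type-I error within [0.03, 0.07] at $\alpha = 0.05$ over a 500 × 500
null simulation with $d = 4$, $n_i = 15$; and bootstrap/Welch-t
agreement within 0.02 for two groups of 200 on one descriptor. These
sizes were chosen as the smallest at which the binomial/bootstrap noise
bounds in the assertions are meaningful.

## Limitations

* Proportions are *expressed-phenotype* shares, not genetic ancestry
  fractions; a trait silenced by environment or dominance contributes
  nothing regardless of its genomic presence.
* With overlapping class distributions the confusion-matrix estimate is
  biased toward the majority class in the overlap region; replication
  averages split noise but cannot remove that bias.
* Touching seeds/pods are not split (no watershed); color and
  colorimetric descriptors are out of scope.
* The paramBS p-value is a Monte-Carlo estimate with resolution $1/B$;
  seed-to-seed variation at $B = 10{,}000$ is ≤ 0.01 on the fixtures
  tested.
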