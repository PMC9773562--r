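# phenoprop

Phenomic proportions of interspecific hybrids from image-based and sensor
phenotypes.

## What it does

When an interspecific hybrid (for example a *Phaseolus* line produced by
congruity backcrossing) is characterized next to its parental accessions,
the practical question is: **how much of each parent's measurable
phenotype does the hybrid still express?** `phenoprop` answers it with a
classification-based statistic. For each characterization component
(seed morphometry, pod morphometry, physiology, yield):

1. Descriptor panels are screened for multivariate outliers (kNN distance
   score, Tukey fence) and standardized to [0, 1].
2. PCA on the parents yields per-descriptor contributions,
   `contrib[j,k] = 100 · loading[j,k]² / Σ_j loading[j,k]²`; the PCs
   reaching 80% cumulative explained variance are combined into one
   weight per descriptor.
3. A 100-tree random forest is trained on a stratified 70/30 split of the
   four classes (3 parents + hybrid), with OOB error, permutation (MDA)
   and Gini importances, and a held-out confusion matrix.
4. The **phenomic proportion** of the hybrid with respect to parent *c*
   is the percentage of held-out hybrid units the forest predicts as
   class *c* — the hybrid row of the confusion matrix — averaged over 25
   replicated splits.
5. Group differences are tested with the modified ANOVA-type statistic

   Q_N = N (T ȳ)ᵀ (T D̂_N Tᵀ)⁺ (T ȳ),

   where ȳ stacks the group means, D̂_N is the diagonal of the stacked
   empirical covariances scaled by N/nᵢ and T = P_a ⊗ I_d, with
   parametric-bootstrap (paramBS) p-values at 10,000 iterations and
   pairwise post-hoc contrasts (unadjusted + Holm).

An image-morphometry module supplies the twelve ImageJ-compatible shape
descriptors (Area, Perimeter, Width, Height, Major, Minor, Feret,
MinFeret, AR, Circularity, Roundness, Solidity) from seed/pod photographs
via maximum-entropy (Kapur) or Huang thresholding, 8-connected ROI
extraction and calibrated measurement. A synthetic-data module generates
panels and images with known ground truth — the hybrid is a finite
mixture over the parent distributions plus a hybrid-unique component, so
the true proportions are known and recoverable.

## Worked example

Generate a seed-morphometry panel for three parents plus a hybrid whose
observations are drawn 20% from parent1, 10% from parent2, 0% from
parent3 and 70% from its own distribution, then estimate the proportions:

```r
library(phenoprop)

models <- default_study_models("seed_morph", n_parent = 150,
                               n_hybrid = 150,
                               weights = c(parent1 = 0.20, parent2 = 0.10,
                                           parent3 = 0.00, self = 0.70))
panel <- generate_panel(models$parents, models$hybrid,
                        component = "seed_morph", seed = 42)
desc <- setdiff(names(panel), c("unit_id", "component", "class", ".latent"))
scaled <- minmax_standardize(panel[, desc])
parents <- panel$class != "hybrid"
wts <- descriptor_weights(fit_pca(scaled$values[parents, ]))
weighted <- apply_weights(scaled$values, wts)

est <- phenomic_proportions(weighted, panel$class, replicates = 25,
                            seed = 43, component = "seed_morph")
print(est)
#> <proportion_estimate> seed_morph (25 replicates)
#>  hybrid parent1 parent2 parent3
#>   66.13   19.02   14.04    0.80
```

The estimate tracks the generating weights (70, 20, 10, 0); at 150
hybrid units a 30% validation split holds only ~45 hybrid observations,
so individual components carry a few points of split noise (the
`dispersion` column of `proportion_report(est)` quantifies it; at 1000
units the maximum error drops to ~2 points). The same panel under the
MATS test rejects equality of the four accessions decisively:

```r
res <- param_bootstrap_p(split_groups(weighted, panel$class),
                         iterations = 10000, seed = 44)
print(res)
#> <mats_result> Q = 6281.2694, bootstrap p = 0 (10000 iterations)
```

Morphometry on an analytic fixture, a 50×50 px filled square at
50 px/cm:

```r
sq <- matrix(FALSE, 60, 60); sq[6:55, 6:55] <- TRUE
measure_shape(labeled_mask(sq, scale = 50))
#>   area perimeter width height    major    minor    feret min_feret
#> 1    1   3.83432     1      1 1.154701 1.154701 1.385929      0.98
#>   aspect_ratio circularity roundness solidity degenerate
#> 1            1   0.8547383 0.9549297        1      FALSE
```

## The analysis workflow

The `analysis/` directory runs the full study on synthetic data, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # panels + seed/pod images + truth
Rscript analysis/02_morphometry.R         # image protocol -> descriptor CSV
Rscript analysis/03_classify_parents.R    # PCA, weights, RF, confusion
Rscript analysis/04_phenomic_proportions.R# proportions per component
Rscript analysis/05_group_comparison.R    # MATS + post-hoc contrasts
```

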