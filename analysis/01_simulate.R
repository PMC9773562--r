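#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- a four-component phenotype panel
# (3 parental accessions + 1 interspecific hybrid with known mixture
# weights) and a set of synthetic seed/pod images with known geometry.
#
# Writes: results/panel_long.csv, results/truth.yaml, results/images/*.png

suppressMessages({ library(phenoprop); library(yaml) })
seed <- 20240115
dir.create("results/images", showWarnings = FALSE, recursive = TRUE)

weights <- c(parent1 = 0.20, parent2 = 0.10, parent3 = 0.00, self = 0.70)
panel <- generate_study_panel(n_parent = 150L, n_hybrid = 150L,
                              weights = weights, separation_sd = 6,
                              seed = seed)
write.csv(panel, "results/panel_long.csv", row.names = FALSE)
cat(sprintf("panel: %d rows, %d components, classes: %s\n", nrow(panel),
            length(unique(panel$component)),
            paste(sort(unique(panel$class)), collapse = ", ")))

# seeds: ellipses of varying elongation; pods: capsules of varying curvature
set.seed(seed)
img_truth <- list()
for (i in 1:6) {
  a <- sample(80:140, 1); b <- sample(seq(40, a, by = 5), 1)
  img <- generate_seed_image(c(a, b), noise_sd = 4, seed = seed + i)
  write_gray_png(img, sprintf("results/images/seed_%02d.png", i))
  img_truth[[sprintf("seed_%02d", i)]] <- attr(img, "truth")
}
for (i in 1:6) {
  curv <- (i - 1) * 0.06
  img <- generate_pod_image(150, 28, curvature = curv, noise_sd = 4,
                            margin_px = 16, seed = seed + 10 + i)
  write_gray_png(img, sprintf("results/images/pod_%02d.png", i))
  img_truth[[sprintf("pod_%02d", i)]] <- attr(img, "truth")
}
write_yaml(c(list(seed = seed, mixture_weights = as.list(weights)),
             images = list(img_truth)), "results/truth.yaml")
cat("wrote 12 images and ground-truth metadata under results/\n")
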