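prep_weighted <- function(pan) {
  desc <- panel_descriptors(pan)
  sc <- minmax_standardize(pan[, desc])
  parents <- pan$class != "hybrid"
  w <- descriptor_weights(fit_pca(sc$values[parents, ]))
  apply_weights(sc$values, w)
}

test_that("a hybrid identical to its self model is attributed to itself", {
  pan <- make_wide_panel(n_parent = 120, n_hybrid = 120,
                         weights = c(parent1 = 0, parent2 = 0,
                                     parent3 = 0, self = 1),
                         separation_sd = 6, seed = 41)
  est <- phenomic_proportions(prep_weighted(pan), pan$class,
                              replicates = 5, seed = 42)
  expect_gte(est$proportions[["hybrid"]], 95)
  expect_true(all(est$proportions[c("parent1", "parent2",
                                    "parent3")] <= 3))
  expect_equal(sum(est$proportions), 100, tolerance = 1e-6)
})

test_that("proportions always sum to 100 across replicates", {
  pan <- make_wide_panel(n_parent = 80, n_hybrid = 80, seed = 43)
  est <- phenomic_proportions(prep_weighted(pan), pan$class,
                              replicates = 4, seed = 44)
  expect_equal(sum(est$proportions), 100, tolerance = 1e-6)
  expect_equal(unname(rowSums(est$per_replicate)),
               rep(100, est$replicates), tolerance = 1e-6)
  expect_true(all(est$proportions >= 0))
})

test_that("increasing a parent's true weight never lowers its estimate", {
  settings <- list(c(parent1 = 0.05, parent2 = 0.10, parent3 = 0,
                     self = 0.85),
                   c(parent1 = 0.20, parent2 = 0.10, parent3 = 0,
                     self = 0.70),
                   c(parent1 = 0.40, parent2 = 0.10, parent3 = 0,
                     self = 0.50))
  got <- vapply(seq_along(settings), function(i) {
    pan <- make_wide_panel(n_parent = 150, n_hybrid = 300,
                           weights = settings[[i]], seed = 50 + i)
    est <- phenomic_proportions(prep_weighted(pan), pan$class,
                                replicates = 5, seed = 60 + i)
    est$proportions[["parent1"]]
  }, numeric(1))
  expect_true(all(diff(got) > -3))  # allowance for replicate noise
})

test_that("an unidentifiable parent/self split still has a stable sum", {
  # parent1's distribution equals the hybrid-self distribution
  m <- default_study_models("seed_morph", n_parent = 120, n_hybrid = 120,
                            weights = c(parent1 = 0.3, parent2 = 0.1,
                                        parent3 = 0, self = 0.6))
  m$parents[[1]] <- class_model("parent1", m$hybrid$self_model$mean,
                                m$hybrid$self_model$cov, n = 120L)
  pan <- generate_panel(m$parents, m$hybrid, seed = 45)
  est <- phenomic_proportions(prep_weighted(pan), pan$class,
                              replicates = 8, seed = 46)
  joint <- est$proportions[["parent1"]] + est$proportions[["hybrid"]]
  expect_lt(abs(joint - 90), 5)
})

test_that("proportion_report lays out one row per component and class", {
  pan <- make_wide_panel(n_parent = 60, n_hybrid = 60, seed = 47)
  wx <- prep_weighted(pan)
  e1 <- phenomic_proportions(wx, pan$class, replicates = 1, seed = 48,
                             component = "seed_morph")
  expect_equal(unname(e1$dispersion), rep(0, 4))
  rep1 <- proportion_report(e1)
  expect_equal(nrow(rep1), 4L)
  e2 <- phenomic_proportions(wx, pan$class, replicates = 2, seed = 49,
                             component = "pod_morph")
  rep2 <- proportion_report(list(e1, e2))
  expect_equal(nrow(rep2), 8L)
  expect_setequal(unique(rep2$component), c("seed_morph", "pod_morph"))
})

test_that("degenerate panels are rejected", {
  pan <- make_wide_panel(n_parent = 30, n_hybrid = 30, seed = 51)
  desc <- panel_descriptors(pan)
  parents_only <- pan$class != "hybrid"
  expect_error(phenomic_proportions(pan[parents_only, desc],
                                    pan$class[parents_only]),
               class = "bad_config")
})
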