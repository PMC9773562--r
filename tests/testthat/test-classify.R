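test_that("PCA contributions follow the squared-loading accounting", {
  set.seed(21)
  x <- matrix(rnorm(60 * 5), 60, 5)
  colnames(x) <- letters[1:5]
  p <- fit_pca(x)
  expect_equal(unname(colSums(p$contributions)),
               rep(100, ncol(p$contributions)), tolerance = 1e-6)
  expect_equal(sum(p$explained_variance_ratio), 1, tolerance = 1e-9)
  # contributions are 100 * squared loadings (unit-norm loading columns)
  expect_equal(p$contributions, 100 * p$loadings^2, tolerance = 1e-9)
})

test_that("two perfectly correlated descriptors split PC1 contributions 50/50", {
  set.seed(22)
  a <- rnorm(50)
  suppressWarnings(p <- fit_pca(cbind(a = a, b = 2 * a + 3)))
  expect_equal(unname(p$contributions[, 1]), c(50, 50), tolerance = 1e-6)
  expect_equal(unname(p$explained_variance_ratio[1]), 1, tolerance = 1e-9)
})

test_that("PC1 aligns with the dominant descriptor when unscaled variance differs", {
  # unit-scaled internally, so craft dominance in correlation structure:
  # descriptor a drives two correlated columns, c is independent noise
  set.seed(23)
  a <- rnorm(200)
  x <- cbind(a1 = a + rnorm(200, 0, 0.1), a2 = a + rnorm(200, 0, 0.1),
             c = rnorm(200))
  p <- fit_pca(x)
  expect_gt(sum(p$contributions[c("a1", "a2"), 1]), 95)
})

test_that("descriptor weights renormalize PC contributions", {
  set.seed(24)
  x <- matrix(rnorm(80 * 6), 80, 6)
  colnames(x) <- letters[1:6]
  p <- fit_pca(x)
  w1 <- descriptor_weights(p, retained = 1)
  expect_equal(sum(w1), 1, tolerance = 1e-9)
  expect_equal(unname(w1), unname(p$loadings[, 1]^2), tolerance = 1e-9)
  wall <- descriptor_weights(p, retained = ncol(p$contributions))
  expect_equal(sum(wall), 1, tolerance = 1e-9)
})

test_that("exchangeable descriptors receive equal weights", {
  set.seed(25)
  n <- 400; pdim <- 6
  z <- rnorm(n)
  x <- sapply(seq_len(pdim), function(i) z + rnorm(n))  # equicorrelated
  colnames(x) <- letters[1:pdim]
  p <- fit_pca(x)
  w <- descriptor_weights(p, retained = 1)
  expect_lt(max(abs(w - 1 / pdim)), 0.02)
})

test_that("a dominant descriptor is learned and ranked first by the forest", {
  set.seed(26)
  n <- 100
  x <- data.frame(sig = c(rnorm(n), rnorm(n, 10)),
                  noise1 = rnorm(2 * n), noise2 = rnorm(2 * n))
  y <- rep(c("a", "b"), each = n)
  fr <- train_forest(x, y, seed = 31)
  expect_lte(fr$oob_error, 2)
  expect_identical(names(which.max(fr$importance_mda)), "sig")
  expect_identical(names(which.max(fr$importance_gini)), "sig")
})

test_that("permuted labels give chance-level OOB error", {
  set.seed(27)
  x <- data.frame(matrix(rnorm(240 * 4), 240, 4))
  y <- sample(rep(c("a", "b", "c"), each = 80))
  fr <- train_forest(x, y, seed = 32)
  # chance = 66.7%; allow generous binomial noise around it
  expect_gt(fr$oob_error, 50)
})

test_that("forest reports are reproducible and the confusion matrix conserves counts", {
  pan <- make_wide_panel(n_parent = 60, n_hybrid = 60, seed = 28)
  desc <- panel_descriptors(pan)
  f1 <- train_forest(pan[, desc], pan$class, seed = 33)
  f2 <- train_forest(pan[, desc], pan$class, seed = 33)
  expect_identical(f1$confusion, f2$confusion)
  expect_equal(f1$oob_error, f2$oob_error)
  # row sums equal the per-class validation counts
  valid <- table(pan$class[-f1$train_idx])
  expect_equal(as.vector(rowSums(f1$confusion)),
               as.vector(valid[rownames(f1$confusion)]))
  expect_equal(sum(f1$confusion), nrow(pan) - length(f1$train_idx))
})

test_that("feature selection applies both thresholds with top-5 fallback", {
  set.seed(29)
  n <- 80
  x <- data.frame(sig = c(rnorm(n), rnorm(n, 8)),
                  n1 = rnorm(2 * n), n2 = rnorm(2 * n),
                  n3 = rnorm(2 * n), n4 = rnorm(2 * n),
                  n5 = rnorm(2 * n), n6 = rnorm(2 * n))
  fr <- train_forest(x, rep(c("a", "b"), each = n), seed = 34)
  expect_setequal(select_features(fr, 0, 0), names(x))
  expect_true("sig" %in% select_features(fr, gini_min = 1,
                                         mda_min = 0.01))
  expect_warning(top <- select_features(fr, gini_min = 1e6,
                                        mda_min = 1e6), "top 5")
  expect_length(top, 5L)
  expect_error(select_features(fr, -1, 0), class = "bad_config")
})

test_that("classes with fewer than two units are rejected", {
  x <- data.frame(a = rnorm(5))
  expect_error(train_forest(x, c("a", "a", "b", "b", "c"), seed = 1),
               class = "bad_config")
})
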