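test_that("identical group means give Q = 0 and bootstrap p = 1", {
  x <- matrix(rnorm(20 * 3), 20, 3)
  g <- list(a = x, b = x)  # same sample -> same means
  expect_equal(mats_statistic(g), 0, tolerance = 1e-20)
  res <- param_bootstrap_p(g, iterations = 200, seed = 61)
  expect_equal(res$p_boot, 1)
})

test_that("two-group one-descriptor Q matches independent scalar arithmetic", {
  y1 <- c(1.2, 0.8, 1.5, 1.1, 0.9)
  y2 <- c(2.0, 2.3, 1.7, 2.2, 2.4)
  Q <- mats_statistic(list(matrix(y1), matrix(y2)))
  # scalar derivation: T ybar = (m1-m2)/2 * (1,-1); D = N/n_i * s_i^2;
  # Q = N * (d/2, -d/2) (T D T')^+ (d/2, -d/2)' computed by hand
  N <- 10; d <- mean(y1) - mean(y2)
  D <- diag(c(N / 5 * var(y1), N / 5 * var(y2)))
  Tm <- matrix(c(0.5, -0.5, -0.5, 0.5), 2)
  v <- Tm %*% c(mean(y1), mean(y2))
  Q_hand <- N * t(v) %*% MASS::ginv(Tm %*% D %*% t(Tm)) %*% v
  expect_equal(Q, as.numeric(Q_hand), tolerance = 1e-10)
  # and against the fully scalar closed form for the balanced 2-group case:
  # TDT' has eigenvalue (D11+D22)/2 on the contrast direction (1,-1)/sqrt2
  Q_scalar <- N * (d^2 / 2) / (N / 5 * var(y1) / 2 + N / 5 * var(y2) / 2)
  expect_equal(Q, Q_scalar, tolerance = 1e-10)
})

test_that("Q is invariant to positive per-descriptor rescaling and column order", {
  set.seed(62)
  g <- lapply(1:3, function(i) matrix(rnorm(12 * 4, mean = i), 12, 4))
  Q0 <- mats_statistic(g)
  scl <- c(3, 0.01, 7, 100)
  g_s <- lapply(g, function(m) sweep(m, 2, scl, "*"))
  expect_equal(mats_statistic(g_s), Q0, tolerance = 1e-8)
  perm <- c(3, 1, 4, 2)
  g_p <- lapply(g, function(m) m[, perm])
  expect_equal(mats_statistic(g_p), Q0, tolerance = 1e-8)
})

test_that("bootstrap p is reproducible and seed-stable at high iteration counts", {
  set.seed(63)
  g <- lapply(1:2, function(i) matrix(rnorm(15 * 3, mean = 0.4 * i),
                                      15, 3))
  r1 <- param_bootstrap_p(g, iterations = 2000, seed = 64)
  r2 <- param_bootstrap_p(g, iterations = 2000, seed = 64)
  expect_equal(r1$p_boot, r2$p_boot)
  r3 <- param_bootstrap_p(g, iterations = 2000, seed = 65)
  expect_lt(abs(r1$p_boot - r3$p_boot), 0.05)
})

test_that("strong mean shifts are detected with high power", {
  set.seed(66)
  rejected <- vapply(1:20, function(i) {
    g <- list(matrix(rnorm(15 * 3), 15, 3),
              cbind(rnorm(15, 3), matrix(rnorm(15 * 2), 15, 2)))
    param_bootstrap_p(g, iterations = 300, seed = 600 + i)$p_boot <= 0.01
  }, logical(1))
  expect_gte(mean(rejected), 0.95)
})

test_that("post-hoc table enumerates all pairs with monotone Holm adjustment", {
  set.seed(67)
  g <- setNames(lapply(1:4, function(i)
    matrix(rnorm(10 * 3, mean = 0.5 * i), 10, 3)),
    c("p1", "p2", "p3", "hyb"))
  tab <- posthoc_pairwise(g, iterations = 200, seed = 68)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$p_holm >= tab$p_boot))
  expect_true(all(tab$p_boot >= 0 & tab$p_boot <= 1))
})

test_that("null bootstrap p-values are approximately uniform", {
  set.seed(69)
  ps <- vapply(1:200, function(i) {
    g <- list(matrix(rnorm(10 * 3), 10, 3), matrix(rnorm(10 * 3), 10, 3))
    param_bootstrap_p(g, iterations = 300, seed = 700 + i)$p_boot
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate group input is handled", {
  g0 <- list(matrix(0, 5, 2), matrix(0, 6, 2))
  expect_error(mats_statistic(g0), class = "degenerate_groups")
  expect_error(mats_statistic(list(matrix(rnorm(10), 5, 2))),
               class = "bad_config")
  # one all-constant descriptor is absorbed by the pseudo-inverse
  g1 <- list(cbind(rnorm(8), 1), cbind(rnorm(8, 2), 1))
  expect_gt(mats_statistic(g1), 0)
})

test_that("mats_manova bundles the global test and post-hoc contrasts", {
  pan <- make_wide_panel(n_parent = 25, n_hybrid = 25, seed = 70)
  desc <- panel_descriptors(pan)
  res <- mats_manova(pan[, desc], pan$class, iterations = 200, seed = 71)
  expect_s3_class(res$global, "mats_result")
  expect_lte(res$global$p_boot, 0.05)  # classes are well separated
  expect_equal(nrow(res$pairwise), 6L)
})
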