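#' One-way contrast projection for a multivariate group comparison
#'
#' The global all-groups-equal null uses T = (P_a %x% I_d), where P_a =
#' I_a - J_a / a is the one-way centering projection over the a groups
#' and d is the descriptor dimension.
#'
#' @param a number of groups.
#' @param d descriptor dimension.
#' @return (a d) x (a d) projection matrix.
#' @export
contrast_matrix <- function(a, d) {
  Pa <- diag(a) - matrix(1 / a, a, a)
  Pa %x% diag(d)
}

#' Split a descriptor table into per-group matrices
#'
#' @param features units x descriptors table.
#' @param labels group label per unit.
#' @return named list of numeric matrices, one per group.
#' @export
split_groups <- function(features, labels) {
  labels <- as.character(labels)
  x <- as.matrix(features)
  lapply(split(seq_along(labels), labels), function(i)
    x[i, , drop = FALSE])
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_phenoprop("need >= 2 groups", "bad_config")
  groups <- lapply(groups, as.matrix)
  d <- unique(vapply(groups, ncol, integer(1)))
  if (length(d) != 1L)
    stop_phenoprop("groups must share the descriptor dimension",
                   "bad_config")
  if (any(vapply(groups, nrow, integer(1)) < 2L))
    stop_phenoprop("each group needs >= 2 observations", "bad_config")
  groups
}

# Q = N (T ybar)' (T D T')^+ (T ybar), D = diag of stacked N/n_i cov_i.
# When `d` is given (contrasts of the H %x% I_d form, as in the one-way
# layout), each descriptor is first divided by its root-mean scaled
# variance: Q is mathematically invariant under this rescaling, and the
# preconditioning keeps the pseudo-inverse well-conditioned when
# descriptors live on very different scales.
mats_quadform <- function(ybar, dvec, Tm, N, d = NULL) {
  if (!is.null(d)) {
    desc <- rep(seq_len(d), length.out = length(dvec))
    cj2 <- stats::ave(dvec, desc)
    cj2[cj2 <= 0] <- 1
    ybar <- ybar / sqrt(cj2)
    dvec <- dvec / cj2
  }
  Ty <- Tm %*% ybar
  M <- sweep(Tm, 2L, dvec, "*") %*% t(Tm)
  as.numeric(N * crossprod(Ty, MASS::ginv(M) %*% Ty))
}

#' Modified ANOVA-type statistic (MATS)
#'
#' Q_N = N (T ybar)' (T D_N T')^+ (T ybar), where ybar stacks the group
#' mean vectors, D_N is the diagonal matrix of the stacked empirical
#' covariances scaled by N / n_i, N = sum n_i, and ^+ is the
#' Moore-Penrose inverse. The diagonal standardization makes Q_N
#' invariant to positive per-descriptor rescaling and well-defined under
#' heteroscedastic and singular covariances.
#'
#' @param groups list of numeric matrices (one per group, rows =
#'   observations, columns = descriptors; each group >= 2 rows), e.g.
#'   from [split_groups()].
#' @param contrast contrast projection T; default [contrast_matrix()]
#'   for the all-groups-equal null.
#' @return the non-negative statistic Q_N (0 iff T ybar = 0).
#' @export
mats_statistic <- function(groups, contrast = NULL) {
  groups <- check_groups(groups)
  a <- length(groups); d <- ncol(groups[[1L]])
  ns <- vapply(groups, nrow, integer(1)); N <- sum(ns)
  precondition <- is.null(contrast)           # default one-way H %x% I_d
  if (is.null(contrast)) contrast <- contrast_matrix(a, d)
  # d x a matrix, column-major flatten = (group 1 descriptors, group 2, ...)
  ybar <- as.vector(vapply(groups, colMeans, numeric(d)))
  vars <- vapply(groups, function(g) apply(g, 2L, stats::var),
                 numeric(d))
  dvec <- as.vector(vars) * rep(N / ns, each = d)
  if (all(dvec == 0))
    stop_phenoprop("all groups have zero variance in every descriptor",
                   "degenerate_groups")
  mats_quadform(ybar, dvec, contrast, N, d = if (precondition) d)
}

# W with W'W = Sigma (eigen factor; negative eigenvalues clamped to 0).
psd_factor <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    warning("empirical covariance not PSD; projecting to nearest PSD")
  ev <- pmax(e$values, 0)
  diag(sqrt(ev), length(ev)) %*% t(e$vectors)
}

#' Parametric-bootstrap p-value for the MATS statistic
#'
#' Implements the paramBS scheme: in each iteration, every group is
#' redrawn from a mean-zero multivariate normal with that group's
#' empirical covariance and original size (the null construction), Q* is
#' recomputed, and p = #\{Q* >= Q_obs\} / iterations.
#'
#' @inheritParams mats_statistic
#' @param iterations bootstrap iterations (default 10000).
#' @param seed RNG seed.
#' @return object of class `mats_result`: list with `statistic`,
#'   `p_boot`, `iterations`, `contrast`, `per_group` (n, mean,
#'   covariance per group).
#' @export
param_bootstrap_p <- function(groups, contrast = NULL,
                              iterations = 10000L, seed = NULL) {
  groups <- check_groups(groups)
  if (iterations < 1L) stop_phenoprop("iterations must be >= 1",
                                      "bad_config")
  a <- length(groups); d <- ncol(groups[[1L]])
  ns <- vapply(groups, nrow, integer(1)); N <- sum(ns)
  precondition <- is.null(contrast)
  Tm <- if (is.null(contrast)) contrast_matrix(a, d) else contrast
  Q_obs <- mats_statistic(groups, if (precondition) NULL else Tm)
  covs <- lapply(groups, stats::cov)
  Ws <- lapply(covs, psd_factor)
  B <- as.integer(iterations)
  scale_i <- rep(N / ns, each = d)
  # draw in blocks to bound the memory of the vectorized normal draws
  block <- max(1L, min(B, as.integer(2e6 / (max(ns) * d))))
  Qs <- local_seed(seed, {
    q <- numeric(B)
    done <- 0L
    while (done < B) {
      nb <- min(block, B - done)
      means <- vars <- vector("list", a)
      for (i in seq_len(a)) {
        Z <- matrix(stats::rnorm(nb * ns[i] * d), nb * ns[i], d)
        X <- Z %*% Ws[[i]]
        g <- rep(seq_len(nb), each = ns[i])
        s1 <- rowsum(X, g)
        s2 <- rowsum(X * X, g)
        means[[i]] <- s1 / ns[i]                    # nb x d
        vars[[i]] <- (s2 - ns[i] * (s1 / ns[i])^2) / (ns[i] - 1L)
      }
      for (b in seq_len(nb)) {
        yb <- unlist(lapply(means, function(m) m[b, ]),
                     use.names = FALSE)
        db <- unlist(lapply(vars, function(v) v[b, ]),
                     use.names = FALSE) * scale_i
        q[done + b] <- mats_quadform(yb, db, Tm, N,
                                     d = if (precondition) d)
      }
      done <- done + nb
    }
    q
  })
  structure(list(
    statistic = Q_obs,
    p_boot = mean(Qs >= Q_obs),
    iterations = B,
    contrast = Tm,
    per_group = lapply(groups, function(g)
      list(n = nrow(g), mean = colMeans(g), cov = stats::cov(g)))),
    class = "mats_result")
}

#' @export
print.mats_result <- function(x, ...) {
  cat(sprintf("<mats_result> Q = %.4f, bootstrap p = %.4g (%d iterations)\n",
              x$statistic, x$p_boot, x$iterations))
  invisible(x)
}

#' Pairwise post-hoc MATS contrasts
#'
#' For every unordered pair of groups, runs the two-group MATS parametric
#' bootstrap. Unadjusted p-values are reported together with
#' Holm-adjusted ones, since whether the study's pairwise contrasts were
#' multiplicity-adjusted is not stated.
#'
#' @param groups named list of group matrices (>= 2 groups).
#' @param iterations bootstrap iterations per pair.
#' @param seed RNG seed; per-pair seeds are derived from it.
#' @return data frame with `group_a`, `group_b`, `statistic`, `p_boot`,
#'   `p_holm`.
#' @export
posthoc_pairwise <- function(groups, iterations = 10000L, seed = NULL) {
  groups <- check_groups(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2L)
  seeds <- derive_seeds(seed, ncol(pairs))
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    res <- param_bootstrap_p(groups[c(i, j)], iterations = iterations,
                             seed = seeds[[k]])
    data.frame(group_a = nm[i], group_b = nm[j],
               statistic = res$statistic, p_boot = res$p_boot)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_boot, method = "holm")
  out
}

#' Per-component MATS comparison of the accession groups
#'
#' Convenience wrapper: global MATS test plus pairwise post-hoc
#' contrasts for one wide component panel.
#'
#' @param features units x descriptors table.
#' @param labels group (accession) label per unit.
#' @param iterations bootstrap iterations.
#' @param seed RNG seed.
#' @return list with `global` (a `mats_result`) and `pairwise` (the
#'   post-hoc table).
#' @export
mats_manova <- function(features, labels, iterations = 10000L,
                        seed = NULL) {
  groups <- split_groups(features, labels)
  seeds <- derive_seeds(seed, 2L)
  list(global = param_bootstrap_p(groups, iterations = iterations,
                                  seed = seeds[[1L]]),
       pairwise = posthoc_pairwise(groups, iterations = iterations,
                                   seed = seeds[[2L]]))
}
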