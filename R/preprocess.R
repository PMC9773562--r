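#' kNN-distance multivariate outlyingness scores
#'
#' Scores each observation by its mean Euclidean distance to its k
#' nearest neighbours, computed on per-descriptor z-scaled data so that
#' the score is invariant to affine rescaling of any descriptor. Higher
#' scores mean more outlying. Constant descriptors carry no information
#' and are dropped with a warning before scoring.
#'
#' @param x numeric matrix or data frame (rows = experimental units,
#'   columns = descriptors).
#' @param k number of neighbours; default `min(10, n - 1)`.
#' @return numeric vector of non-negative scores, one per row.
#' @export
outlier_scores <- function(x, k = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop_phenoprop("descriptors must be numeric",
                                     "bad_config")
  n <- nrow(x)
  if (is.null(k)) k <- min(10L, n - 1L)
  if (!(n > k && k >= 1L))
    stop_phenoprop("need n > k >= 1", "bad_config")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant descriptor(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) == 0L)
      stop_phenoprop("no non-constant descriptors left", "bad_config")
    sds <- sds[sds > 0]
  }
  z <- scale(x)
  d <- as.matrix(stats::dist(z))
  vapply(seq_len(n),
         function(i) mean(sort(d[i, -i])[seq_len(k)]), numeric(1))
}

#' Flag outlying units by the Tukey upper fence
#'
#' Units whose outlyingness score exceeds Q3 + 1.5 IQR of the scores are
#' flagged. Flagged units are meant to be excluded downstream but logged,
#' never silently dropped.
#'
#' @param scores non-negative scores from [outlier_scores()].
#' @param fence IQR multiplier (1.5 = Tukey's rule).
#' @return logical vector, `TRUE` = flagged.
#' @export
flag_outliers <- function(scores, fence = 1.5) {
  if (length(scores) == 0L) return(logical(0))
  if (any(scores < 0)) stop_phenoprop("scores must be non-negative",
                                      "bad_config")
  q <- stats::quantile(scores, c(0.25, 0.75), names = FALSE)
  scores > q[2L] + fence * (q[2L] - q[1L])
}

#' Min-max standardization to [0, 1]
#'
#' Standardizes each descriptor to `(value - min) / (max - min)` with the
#' range fitted on a chosen subset of units (by default all of them, i.e.
#' parents and hybrid jointly). Values outside the fitted range — e.g. a
#' hybrid descriptor below the parental minimum when the scaling is
#' fitted on parents only — are clipped to [0, 1] and counted.
#'
#' @param x numeric matrix or data frame of descriptor values.
#' @param fit_on logical or integer index of rows used to fit the ranges;
#'   default all rows.
#' @return object of class `scaled_panel`: list with `values` (data frame
#'   in [0, 1]), `scaling` (data frame with descriptor, min, max) and
#'   `n_clipped`.
#' @export
minmax_standardize <- function(x, fit_on = NULL) {
  xm <- as.matrix(x)
  if (is.null(fit_on)) fit_on <- seq_len(nrow(xm))
  fit <- xm[fit_on, , drop = FALSE]
  mins <- apply(fit, 2L, min)
  maxs <- apply(fit, 2L, max)
  if (any(maxs <= mins))
    stop_phenoprop(paste0("constant descriptor(s) on the fitting subset: ",
                          paste(colnames(xm)[maxs <= mins],
                                collapse = ", ")),
                   "constant_descriptor")
  sc <- sweep(sweep(xm, 2L, mins), 2L, maxs - mins, "/")
  n_clipped <- sum(sc < 0 | sc > 1)
  sc[sc < 0] <- 0; sc[sc > 1] <- 1
  structure(list(values = as.data.frame(sc),
                 scaling = data.frame(descriptor = colnames(xm),
                                      min = unname(mins),
                                      max = unname(maxs)),
                 n_clipped = n_clipped),
            class = "scaled_panel")
}

#' @export
print.scaled_panel <- function(x, ...) {
  cat(sprintf("<scaled_panel> %d units x %d descriptors (%d clipped)\n",
              nrow(x$values), ncol(x$values), x$n_clipped))
  invisible(x)
}

#' Screen a wide panel: drop incomplete rows, score and flag outliers
#'
#' @param wide wide component panel ([panel_wide()]): metadata columns
#'   plus descriptor columns.
#' @param k neighbours for [outlier_scores()].
#' @return list with `clean` (wide panel without flagged/incomplete
#'   rows), `flags` (data frame unit_id, score, flagged), `n_missing`.
#' @export
screen_panel <- function(wide, k = NULL) {
  meta <- intersect(c("unit_id", "class", ".latent", "component"),
                    names(wide))
  desc <- setdiff(names(wide), meta)
  complete <- stats::complete.cases(wide[, desc, drop = FALSE])
  n_missing <- sum(!complete)
  w <- wide[complete, , drop = FALSE]
  sc <- outlier_scores(w[, desc, drop = FALSE], k = k)
  fl <- flag_outliers(sc)
  list(clean = w[!fl, , drop = FALSE],
       flags = data.frame(unit_id = w$unit_id, score = sc, flagged = fl),
       n_missing = n_missing)
}
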