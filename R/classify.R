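#' PCA with variable contributions
#'
#' Principal component analysis of a (parental) descriptor table,
#' centered and unit-scaled internally, returning loadings, explained
#' variance ratios and per-PC variable contributions in percent:
#' contribution[j, k] = 100 * loading[j, k]^2 / sum_j loading[j, k]^2.
#'
#' @param x numeric matrix or data frame (units x descriptors), typically
#'   the parent rows of a standardized panel.
#' @return object of class `pca_summary`: list with `loadings`,
#'   `explained_variance_ratio`, `contributions`, `sdev`.
#' @export
fit_pca <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L || nrow(x) < 3L)
    stop_phenoprop("PCA needs >= 2 descriptors and >= 3 units",
                   "bad_config")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop_phenoprop(paste0("constant descriptor(s): ",
                          paste(colnames(x)[sds == 0], collapse = ", ")),
                   "constant_descriptor")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  r <- sum(pc$sdev > pc$sdev[1L] * 1e-10)
  if (r < length(pc$sdev))
    warning(sprintf("rank-deficient input: keeping %d of %d PCs", r,
                    length(pc$sdev)))
  load <- pc$rotation[, seq_len(r), drop = FALSE]
  evr <- pc$sdev[seq_len(r)]^2 / sum(pc$sdev^2)
  contrib <- 100 * sweep(load^2, 2L, colSums(load^2), "/")
  structure(list(loadings = load, explained_variance_ratio = evr,
                 contributions = contrib, sdev = pc$sdev[seq_len(r)]),
            class = "pca_summary")
}

#' Number of PCs reaching a cumulative explained-variance target
#'
#' @param p a `pca_summary`.
#' @param target cumulative explained-variance fraction (default 0.80).
#' @return smallest number of leading PCs whose cumulative explained
#'   variance ratio reaches `target`.
#' @export
retained_pcs <- function(p, target = 0.80) {
  which(cumsum(p$explained_variance_ratio) >= target - 1e-12)[1L]
}

#' PC-contribution weights for the phenomic descriptors
#'
#' Combines the retained PCs' variable contributions into one weight per
#' descriptor: weight_j = sum_{k <= retained} contribution[j, k] *
#' explained_variance_ratio[k], renormalized to sum to 1. The weighted
#' descriptor value used downstream is weight_j times the standardized
#' value.
#'
#' @param p a `pca_summary` from [fit_pca()].
#' @param retained number of leading PCs to use; default the
#'   [retained_pcs()] 80%-variance rule.
#' @return named weight vector summing to 1.
#' @export
descriptor_weights <- function(p, retained = NULL) {
  if (is.null(retained)) retained <- retained_pcs(p)
  if (retained < 1L || retained > ncol(p$contributions))
    stop_phenoprop("retained PCs out of range", "bad_config")
  w <- as.vector(p$contributions[, seq_len(retained), drop = FALSE] %*%
                   p$explained_variance_ratio[seq_len(retained)])
  names(w) <- rownames(p$contributions)
  w / sum(w)
}

#' Apply descriptor weights to a standardized table
#'
#' @param x standardized descriptor table (units x descriptors).
#' @param weights named weights from [descriptor_weights()].
#' @return weighted table (same shape).
#' @export
apply_weights <- function(x, weights) {
  x <- as.matrix(x)
  if (!setequal(colnames(x), names(weights)))
    stop_phenoprop("weights do not match descriptor columns", "bad_config")
  as.data.frame(sweep(x, 2L, weights[colnames(x)], "*"))
}

# Stratified split: for each class, round(frac * n_c) units to training.
stratified_split <- function(labels, frac = 0.7) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_tr <- round(frac * length(idx))
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

#' Random-forest classification with OOB error and validation confusion
#'
#' Trains a 100-tree random forest on a stratified 70% split, reports the
#' out-of-bag error (from bagging, on the training partition), unscaled
#' permutation importance (mean decrease in accuracy), Gini importance,
#' and the confusion matrix on the held-out 30%. Prediction ties are
#' broken toward the alphabetically first class.
#'
#' @param features units x descriptors table.
#' @param labels class label per unit (>= 2 classes, >= 2 units each).
#' @param n_trees number of trees (default 100).
#' @param train_fraction fraction per class used for training (0.7).
#' @param seed RNG seed for the split and the forest.
#' @return object of class `forest_report`: list with `n_trees`, `split`,
#'   `oob_error` (percent), `importance_mda`, `importance_gini`,
#'   `confusion` (rows = truth, cols = prediction, held-out units),
#'   `forest`, `train_idx`, `seed`.
#' @export
train_forest <- function(features, labels, n_trees = 100L,
                         train_fraction = 0.7, seed = NULL) {
  x <- as.data.frame(features)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2L) stop_phenoprop("need >= 2 classes", "bad_config")
  if (any(tab < 2L))
    stop_phenoprop("every class needs >= 2 units", "bad_config")
  classes <- sort(names(tab))
  local_seed(seed, {
    train <- stratified_split(labels, train_fraction)
    y_tr <- factor(labels[train], levels = classes)
    rf <- randomForest::randomForest(
      x = x[train, , drop = FALSE], y = y_tr, ntree = n_trees,
      importance = TRUE)
    oob <- as.numeric(utils::tail(rf$err.rate[, "OOB"], 1L)) * 100
    imp <- randomForest::importance(rf, scale = FALSE)
    votes <- stats::predict(rf, x[!train, , drop = FALSE], type = "vote")
    pred <- factor(classes[max.col(votes, ties.method = "first")],
                   levels = classes)
    truth <- factor(labels[!train], levels = classes)
    confusion <- table(truth = truth, prediction = pred)
    structure(list(
      n_trees = n_trees,
      split = c(train_fraction = train_fraction,
                valid_fraction = 1 - train_fraction),
      oob_error = oob,
      importance_mda = imp[, "MeanDecreaseAccuracy"],
      importance_gini = imp[, "MeanDecreaseGini"],
      confusion = confusion,
      forest = rf,
      train_idx = which(train),
      seed = seed), class = "forest_report")
  })
}

#' @export
print.forest_report <- function(x, ...) {
  cat(sprintf("<forest_report> %d trees, OOB error %.2f%%\n",
              x$n_trees, x$oob_error))
  print(x$confusion)
  invisible(x)
}

#' Feature selection by dual importance thresholds
#'
#' Keeps descriptors whose Gini importance and (unscaled) mean decrease
#' in accuracy both meet their thresholds, ordered by MDA descending.
#' Negative permutation importances are sampling noise around zero and
#' are treated as zero when thresholding. If nothing survives, falls
#' back to the top 5 by MDA with a warning.
#'
#' @param report a `forest_report`.
#' @param gini_min minimum Gini importance.
#' @param mda_min minimum mean decrease in accuracy.
#' @return character vector of descriptor names.
#' @export
select_features <- function(report, gini_min = 0, mda_min = 0) {
  if (gini_min < 0 || mda_min < 0)
    stop_phenoprop("thresholds must be >= 0", "bad_config")
  mda <- report$importance_mda
  gini <- report$importance_gini
  keep <- names(mda)[pmax(mda, 0) >= mda_min & gini >= gini_min]
  if (length(keep) == 0L) {
    warning("no descriptor meets both thresholds; falling back to top 5",
            " by mean decrease in accuracy")
    keep <- names(sort(mda, decreasing = TRUE))[seq_len(min(5L,
                                                            length(mda)))]
    return(keep)
  }
  keep[order(mda[keep], decreasing = TRUE)]
}
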