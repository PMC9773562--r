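#' Phenomic proportions of a hybrid with respect to its parents
#'
#' The headline statistic: a 4-class random forest (three parents + the
#' hybrid) is trained on a stratified 70% split; the held-out hybrid
#' units are tabulated by predicted class, and the percentage predicted
#' as each parent is read off as the hybrid's phenomic proportion with
#' respect to that parent (the hybrid row of the confusion matrix). The
#' split + forest is replicated (default 25 replicates) and proportions
#' averaged, since a single 70/30 split of a small panel is
#' high-variance; `replicates = 1` reproduces the single-split protocol.
#'
#' @param features standardized (and optionally PC-contribution weighted)
#'   descriptor table, units x descriptors.
#' @param labels class per unit; exactly 4 classes, one of which is
#'   `hybrid_label`.
#' @param n_trees trees per forest (default 100).
#' @param train_fraction training fraction per class (default 0.7).
#' @param replicates number of replicated splits (default 25).
#' @param seed RNG seed; per-replicate seeds are derived from it.
#' @param hybrid_label label of the hybrid class.
#' @param component component name carried into the result.
#' @return object of class `proportion_estimate`: list with `component`,
#'   `proportions` (named percentages over the 4 classes, mean over
#'   replicates, summing to 100), `dispersion` (per-class sd over
#'   replicates), `n_hybrid_validated` (mean hybrid validation count),
#'   `replicates`, `per_replicate` (replicates x classes matrix).
#' @export
phenomic_proportions <- function(features, labels, n_trees = 100L,
                                 train_fraction = 0.7, replicates = 25L,
                                 seed = NULL, hybrid_label = "hybrid",
                                 component = "panel") {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 4L)
    stop_phenoprop("phenomic proportions need exactly 4 classes",
                   "bad_config")
  if (!hybrid_label %in% classes)
    stop_phenoprop("hybrid class not present", "bad_config")
  seeds <- derive_seeds(seed, replicates)
  per_rep <- matrix(NA_real_, replicates, length(classes),
                    dimnames = list(NULL, classes))
  n_val <- numeric(replicates)
  for (r in seq_len(replicates)) {
    fr <- train_forest(features, labels, n_trees = n_trees,
                       train_fraction = train_fraction,
                       seed = seeds[[r]])
    hyb_row <- fr$confusion[hybrid_label, ]
    n_val[r] <- sum(hyb_row)
    if (n_val[r] == 0L)
      stop_phenoprop("no hybrid units in the validation split",
                     "no_hybrid_validation")
    per_rep[r, ] <- 100 * hyb_row / n_val[r]
  }
  disp <- if (replicates == 1L)
    stats::setNames(rep(0, length(classes)), classes)
  else apply(per_rep, 2L, stats::sd)
  structure(list(
    component = component,
    proportions = colMeans(per_rep),
    dispersion = disp,
    n_hybrid_validated = mean(n_val),
    replicates = replicates,
    per_replicate = per_rep), class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("<proportion_estimate> %s (%d replicates)\n", x$component,
              x$replicates))
  print(round(x$proportions, 2))
  invisible(x)
}

#' Summary table of phenomic proportions across components
#'
#' @param estimates list of `proportion_estimate` objects (one per
#'   characterization component).
#' @return data frame with one row per (component, class): `component`,
#'   `class`, `proportion` (percent), `dispersion` (sd over replicates),
#'   `replicates`.
#' @export
proportion_report <- function(estimates) {
  if (inherits(estimates, "proportion_estimate"))
    estimates <- list(estimates)
  if (length(estimates) == 0L)
    stop_phenoprop("need at least one estimate", "bad_config")
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(component = e$component,
               class = names(e$proportions),
               proportion = unname(e$proportions),
               dispersion = unname(e$dispersion),
               replicates = e$replicates,
               row.names = NULL)
  }))
}
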