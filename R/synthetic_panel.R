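#' Multivariate-normal class model for one characterization component
#'
#' Describes the descriptor distribution of one accession class: a mean
#' vector, a covariance matrix and a class size.
#'
#' @param label class name (e.g. `"parent1"`, `"hybrid"`).
#' @param mean named numeric vector of descriptor means.
#' @param cov covariance matrix (symmetric positive semi-definite);
#'   a single number is expanded to `diag(cov, length(mean))`.
#' @param n number of experimental units drawn for this class.
#' @export
class_model <- function(label, mean, cov, n = 100L) {
  p <- length(mean)
  if (is.null(names(mean)))
    names(mean) <- paste0("d", seq_len(p))
  if (length(cov) == 1L) cov <- diag(as.numeric(cov), p)
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(cov, t(cov), tolerance = 1e-8)))
    stop_phenoprop("covariance must be symmetric", "bad_config")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop_phenoprop("covariance must be positive semi-definite", "bad_config")
  structure(list(label = label, mean = mean, cov = cov, n = as.integer(n)),
            class = "class_model")
}

#' Hybrid mixture model
#'
#' The hybrid's observations are drawn from a finite mixture over the
#' parental descriptor distributions plus a hybrid-unique ("self")
#' component. The mixture weights are the ground-truth phenomic
#' proportions that the downstream estimator should recover.
#'
#' @param weights named numeric vector over the parent labels plus
#'   `"self"`; non-negative, summing to 1.
#' @param self_model [class_model()] of the hybrid-unique component; its
#'   `n` is the number of hybrid units drawn.
#' @export
hybrid_mixture <- function(weights, self_model) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop_phenoprop("weights must be non-negative and sum to 1",
                   "bad_config")
  if (!"self" %in% names(weights))
    stop_phenoprop("weights must include a 'self' component", "bad_config")
  structure(list(weights = weights, self_model = self_model),
            class = "hybrid_mixture")
}

draw_mvn <- function(n, model) {
  if (n == 0L)
    return(matrix(numeric(0), 0L, length(model$mean),
                  dimnames = list(NULL, names(model$mean))))
  x <- MASS::mvrnorm(n, mu = model$mean, Sigma = model$cov)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  colnames(x) <- names(model$mean)
  x
}

#' Generate a phenotype panel for one characterization component
#'
#' Parent rows are drawn from each parent's multivariate normal; each
#' hybrid row is drawn from mixture component c with probability
#' `weights[c]`. The latent component of every hybrid row is recorded in
#' the `.latent` column for ground-truth tracking.
#'
#' @param parents list of three [class_model()]s.
#' @param hybrid a [hybrid_mixture()]; its weights must be named by the
#'   parent labels plus `"self"`.
#' @param component component name stored in the output.
#' @param seed RNG seed for reproducibility.
#' @return data frame with columns `unit_id`, `class`, `component`,
#'   `.latent`, then one column per descriptor.
#' @export
generate_panel <- function(parents, hybrid, component = "panel",
                           seed = NULL) {
  stopifnot(length(parents) >= 1L)
  dims <- vapply(parents, function(p) length(p$mean), integer(1))
  if (length(unique(dims)) != 1L ||
      dims[1L] != length(hybrid$self_model$mean))
    stop_phenoprop("descriptor dimensions differ across classes",
                   "bad_config")
  labels <- vapply(parents, `[[`, character(1), "label")
  wl <- setdiff(names(hybrid$weights), "self")
  if (!setequal(wl, labels))
    stop_phenoprop("mixture weights must be named by the parent labels",
                   "bad_config")
  local_seed(seed, {
    blocks <- lapply(parents, function(p) {
      cbind(data.frame(class = p$label, .latent = p$label,
                       stringsAsFactors = FALSE),
            as.data.frame(draw_mvn(p$n, p)))
    })
    nh <- hybrid$self_model$n
    comp <- sample(names(hybrid$weights), nh, replace = TRUE,
                   prob = hybrid$weights)
    models <- c(stats::setNames(parents, labels),
                list(self = hybrid$self_model))
    hx <- matrix(NA_real_, nh, dims[1L],
                 dimnames = list(NULL, names(hybrid$self_model$mean)))
    for (cl in unique(comp)) {
      sel <- comp == cl
      hx[sel, ] <- draw_mvn(sum(sel), models[[cl]])
    }
    blocks$hybrid <- cbind(data.frame(class = "hybrid", .latent = comp,
                                      stringsAsFactors = FALSE),
                           as.data.frame(hx))
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    cbind(data.frame(unit_id = seq_len(nrow(out)), component = component,
                     stringsAsFactors = FALSE), out)
  })
}

#' Pod harvest index
#'
#' PHI = 100 * (seed dry weight at harvest) / (whole-pod dry weight at
#' harvest), in percent.
#'
#' @param seed_dry_weight seed dry weight, g.
#' @param pod_whole_weight whole-pod (seed + valves) dry weight, g.
#' @return percentage in [0, 100].
#' @examples
#' compute_phi(8, 10)  # 80
#' @export
compute_phi <- function(seed_dry_weight, pod_whole_weight) {
  if (any(pod_whole_weight <= 0))
    stop_phenoprop("pod weight must be positive", "domain_error")
  if (any(seed_dry_weight < 0) || any(seed_dry_weight > pod_whole_weight))
    stop_phenoprop("seed weight must lie in [0, pod weight]",
                   "domain_error")
  100 * seed_dry_weight / pod_whole_weight
}

# Descriptor names of the four characterization components.
component_descriptors <- function() {
  list(
    seed_morph = c("Area", "Perimeter", "Width", "Height", "Major",
                   "Minor", "Feret", "MinFeret", "AR", "Circularity",
                   "Roundness", "Solidity"),
    pod_morph = c("Area", "Perimeter", "Width", "Height", "Major",
                  "Minor", "Feret", "MinFeret", "AR", "Circularity",
                  "Roundness", "Solidity"),
    physiology = c("Phi2", "PhiNPQ", "PhiNO", "Chl", "LEF", "LTD",
                   "FmPrime", "FoPrime", "FsPrime", "FvFmPrime", "qL",
                   "qP", "RFd", "LeafThickness"),
    yield = c("PSW", "PW", "VW", "SN", "PHI"))
}

#' Default synthetic study models for one component
#'
#' Builds three well-separated parent classes plus a hybrid mixture over
#' them, on the descriptor set of the requested characterization
#' component. Class mean vectors are placed `separation_sd` standard
#' deviations apart along distinct directions (unit within-class sd per
#' descriptor), emulating accessions that a classifier can distinguish
#' while keeping within-class variability realistic.
#'
#' @param component one of `"seed_morph"`, `"pod_morph"`, `"physiology"`,
#'   `"yield"`.
#' @param n_parent units per parent class.
#' @param n_hybrid hybrid units.
#' @param weights mixture weights (parent1, parent2, parent3, self).
#' @param separation_sd distance between class means in within-class sd.
#' @return list with `parents` (list of 3 [class_model()]s) and `hybrid`
#'   (a [hybrid_mixture()]).
#' @export
default_study_models <- function(component = "seed_morph",
                                 n_parent = 150L, n_hybrid = 150L,
                                 weights = c(parent1 = 0.20,
                                             parent2 = 0.10,
                                             parent3 = 0.00,
                                             self = 0.70),
                                 separation_sd = 6) {
  desc <- component_descriptors()[[component]]
  if (is.null(desc))
    stop_phenoprop("unknown component", "bad_config")
  p <- length(desc)
  base <- stats::setNames(rep(10, p), desc)
  if (component == "yield") {
    # PW and PHI are derived (PW = VW + PSW, PHI = 100 PSW / PW), so the
    # class structure must live in the free descriptors: a regular
    # 4-vertex simplex over (PSW, VW, SN) keeps every pair of class
    # means separation_sd apart after derivation
    tetra <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1), 3)
    disp <- matrix(0, p, 4, dimnames = list(desc, NULL))
    disp[c("PSW", "VW", "SN"), ] <- tetra * separation_sd / (2 * sqrt(2))
  } else {
    # orthonormal displacement directions; each class mean is
    # separation_sd away from every other in Mahalanobis distance
    dirs <- qr.Q(qr(matrix(c(rep(1, p),
                             rep(c(1, -1), length.out = p),
                             rep(c(1, 1, -1), length.out = p),
                             rep(c(1, -1, -1, 1), length.out = p)),
                           p, 4)))
    disp <- dirs * separation_sd / sqrt(2)
  }
  mk <- function(i, label, n)
    class_model(label, base + disp[, i], cov = 1, n = n)
  parents <- list(mk(1L, "parent1", n_parent),
                  mk(2L, "parent2", n_parent),
                  mk(3L, "parent3", n_parent))
  self <- mk(4L, "self", n_hybrid)
  list(parents = parents, hybrid = hybrid_mixture(weights, self))
}

#' Generate the full four-component synthetic study panel
#'
#' One panel per characterization component (seed morphometry, pod
#' morphometry, physiology, yield), bound into a single long-format
#' table. Yield columns are post-processed to satisfy the accounting
#' constraints PW = VW + PSW and PHI = 100 * PSW / PW.
#'
#' @inheritParams default_study_models
#' @param seed RNG seed.
#' @return data frame stacking the four per-component panels.
#' @export
generate_study_panel <- function(n_parent = 150L, n_hybrid = 150L,
                                 weights = c(parent1 = 0.20,
                                             parent2 = 0.10,
                                             parent3 = 0.00,
                                             self = 0.70),
                                 separation_sd = 6, seed = NULL) {
  comps <- names(component_descriptors())
  seeds <- derive_seeds(seed, length(comps))
  panels <- lapply(seq_along(comps), function(i) {
    m <- default_study_models(comps[i], n_parent = n_parent,
                              n_hybrid = n_hybrid, weights = weights,
                              separation_sd = separation_sd)
    pan <- generate_panel(m$parents, m$hybrid, component = comps[i],
                          seed = seeds[[i]])
    if (comps[i] == "yield") {
      pan$PSW <- abs(pan$PSW)
      pan$VW <- abs(pan$VW)
      pan$SN <- pmax(1, round(pan$SN))
      pan$PW <- pan$VW + pan$PSW
      pan$PHI <- compute_phi(pan$PSW, pan$PW)
    }
    pan
  })
  out <- do.call(rbind, lapply(panels, function(p) {
    long <- stats::reshape(
      p, direction = "long",
      varying = setdiff(names(p), c("unit_id", "component", "class",
                                    ".latent")),
      v.names = "value", timevar = "descriptor",
      times = setdiff(names(p), c("unit_id", "component", "class",
                                  ".latent")))
    rownames(long) <- NULL
    long$id <- NULL
    long
  }))
  rownames(out) <- NULL
  out
}

#' Pivot a long panel to one wide matrix-like data frame per component
#'
#' @param panel long panel from [generate_study_panel()] (columns
#'   `unit_id`, `component`, `class`, `.latent`, `descriptor`, `value`).
#' @param component component to extract.
#' @return wide data frame: `unit_id`, `class`, `.latent`, descriptors.
#' @export
panel_wide <- function(panel, component) {
  p <- panel[panel$component == component, , drop = FALSE]
  if (nrow(p) == 0L) stop_phenoprop("component not present", "bad_config")
  wide <- stats::reshape(
    p[, c("unit_id", "class", ".latent", "descriptor", "value")],
    direction = "wide", idvar = c("unit_id", "class", ".latent"),
    timevar = "descriptor")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
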