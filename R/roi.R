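#' Label connected foreground components
#'
#' 8-connectivity labelling (the ImageJ particle-analysis default) by
#' iterated minimum-label propagation: every foreground pixel starts with a
#' unique label and repeatedly adopts the smallest label among itself and
#' its 8 neighbours until a fixed point; labels are then compacted to
#' 1..n_components in raster order of their first pixel.
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @return integer matrix, 0 = background, k = component k.
#' @export
label_components <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop_phenoprop("mask must be a logical matrix", "bad_mask")
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  # pad with a zero border so shifts never wrap
  p <- matrix(0L, nr + 2L, nc + 2L)
  core_r <- 2:(nr + 1L); core_c <- 2:(nc + 1L)
  p[core_r, core_c] <- lab
  fg <- p > 0L
  repeat {
    m <- p
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nb <- p[core_r + dr, core_c + dc]
      cur <- m[core_r, core_c]
      take <- fg[core_r, core_c] & nb > 0L & nb < cur
      if (any(take)) cur[take] <- nb[take]
      m[core_r, core_c] <- cur
    }
    if (identical(m, p)) break
    p <- m
  }
  lab <- p[core_r, core_c]
  ids <- unique(as.vector(lab[lab > 0L]))
  compact <- match(lab, ids)           # NA for background
  compact[is.na(compact)] <- 0L
  matrix(as.integer(compact), nr, nc)
}

#' Extract regions of interest from a binary mask
#'
#' Finds 8-connected foreground components with at least `min_area_px`
#' pixels and returns one labelled mask per component, ordered top-left to
#' bottom-right by centroid (row-major reading order).
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @param min_area_px minimum component area, in pixels.
#' @param scale pixels per centimetre attached to each returned ROI.
#' @return list of `labeled_mask` objects (possibly empty); each has
#'   fields `mask` (logical matrix), `scale` and `roi_id`.
#' @export
extract_rois <- function(mask, min_area_px = 1L, scale = 1) {
  lab <- label_components(mask)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(ids) == 0L) return(list())
  keep <- ids[tabulate(lab[lab > 0L], nbins = max(ids))[ids] >= min_area_px]
  if (length(keep) == 0L) return(list())
  cent <- t(vapply(keep, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    c(mean(w[, 1L]), mean(w[, 2L]))
  }, numeric(2)))
  ord <- order(cent[, 1L], cent[, 2L])  # top-left to bottom-right
  out <- vector("list", length(keep))
  for (i in seq_along(ord)) {
    id <- keep[ord[i]]
    out[[i]] <- labeled_mask(lab == id, scale = scale, roi_id = i)
  }
  out
}

#' Construct a labelled mask (one region of interest)
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @param scale pixels per centimetre (> 0).
#' @param roi_id integer identifier.
#' @export
labeled_mask <- function(mask, scale = 1, roi_id = 1L) {
  if (!is.matrix(mask) || !is.logical(mask) || !any(mask))
    stop_phenoprop("mask needs at least one foreground pixel", "bad_mask")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop_phenoprop("scale (pixels per cm) must be a positive number",
                   "bad_mask")
  structure(list(mask = mask, scale = scale, roi_id = as.integer(roi_id)),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("<labeled_mask> roi %d: %d px foreground, %.4g px/cm\n",
              x$roi_id, sum(x$mask), x$scale))
  invisible(x)
}
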