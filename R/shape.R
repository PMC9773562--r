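# Clockwise Moore neighbourhood, 0 = E: E SE S SW W NW N NE (row, col)
.moore <- matrix(c(0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1, -1, 0, -1, 1),
                 ncol = 2, byrow = TRUE)

# Trace the outer boundary of a single 8-connected component.
# Returns the chain code (vector of direction indices 0..7) of the clockwise
# boundary walk, or integer(0) for a single-pixel region.
trace_boundary <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 1L) return(integer(0))
  start <- w[order(w[, 1L], w[, 2L])[1L], ]   # topmost, then leftmost
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  chain <- integer(0)
  cur <- start
  d <- 0L                                     # pretend we arrived moving E
  first_move <- NA_integer_
  max_steps <- 4L * nrow(w) + 8L
  for (step in seq_len(max_steps)) {
    s <- (d + 6L) %% 8L                       # start scan 90 deg to the left
    found <- FALSE
    for (k in 0:7) {
      dd <- (s + k) %% 8L
      nb <- cur + .moore[dd + 1L, ]
      if (at(nb[1L], nb[2L])) {
        if (is.na(first_move)) first_move <- dd
        else if (all(cur == start) && dd == first_move) return(chain)
        chain <- c(chain, dd)
        cur <- nb; d <- dd; found <- TRUE
        break
      }
    }
    if (!found) return(chain)                 # isolated pixel (no neighbour)
  }
  chain
}

#' Corner-corrected boundary perimeter, in pixels
#'
#' Traces the outer boundary clockwise and applies the
#' Vossepoel-Smeulders chain-code estimator: 0.980 per axial step, 1.406
#' per diagonal step, -0.091 per corner (direction change). This is the
#' ImageJ-style convention under which a digitized circle has
#' circularity close to 1.
#'
#' @param mask logical matrix holding one connected component.
#' @return perimeter estimate in pixel units; a single pixel counts 4.
#' @export
perimeter_px <- function(mask) {
  chain <- trace_boundary(mask)
  if (length(chain) == 0L) return(4)
  ne <- sum(chain %% 2L == 0L)
  no <- sum(chain %% 2L == 1L)
  nc <- sum(chain != c(chain[length(chain)], chain[-length(chain)]))
  0.980 * ne + 1.406 * no - 0.091 * nc
}

#' Ellipse with matching second-order moments
#'
#' Fits the ellipse having the same normalized second central moments as
#' the pixel region (each pixel treated as a unit square, adding 1/12 to
#' the axial moments). Axis lengths follow the regionprops/ImageJ
#' convention: full axes, 4 * sqrt(eigenvalue).
#'
#' @param m a [labeled_mask()].
#' @return list with `major_px`, `minor_px` (full axis lengths, pixels),
#'   `orientation_deg` (major axis vs the horizontal, counterclockwise,
#'   in (-90, 90]), and `degenerate` (TRUE when the region is
#'   collinear and the minor axis reflects only pixel extent).
#' @export
fit_ellipse_moments <- function(m) {
  mask <- as_mask(m)
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) < 5L)
    stop_phenoprop("ellipse fit needs >= 5 foreground pixels", "bad_mask")
  x <- w[, 2L]; y <- -w[, 1L]                 # math coords, y up
  xc <- x - mean(x); yc <- y - mean(y)
  mxx <- mean(xc^2) + 1 / 12
  myy <- mean(yc^2) + 1 / 12
  mxy <- mean(xc * yc)
  common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  l1 <- (mxx + myy + common) / 2
  l2 <- (mxx + myy - common) / 2
  degenerate <- l2 <= 1 / 12 + 1e-12          # collinear pixels
  l2 <- max(l2, 1 / 12)                       # 1-pixel-wide equivalent
  theta <- 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  list(major_px = 4 * sqrt(l1), minor_px = 4 * sqrt(l2),
       orientation_deg = theta, degenerate = degenerate)
}

as_mask <- function(m) {
  if (inherits(m, "labeled_mask")) m$mask
  else if (is.matrix(m) && is.logical(m)) m
  else stop_phenoprop("expected a labeled_mask or logical matrix", "bad_mask")
}

# Convex hull vertices of the foreground pixel centers, (x = col, y = row).
hull_centers <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  pts <- cbind(x = w[, 2L], y = w[, 1L])
  if (nrow(pts) <= 2L) return(pts)
  pts[grDevices::chull(pts), , drop = FALSE]
}

#' Maximum and minimum caliper (Feret) diameters, in pixels
#'
#' Feret is the largest distance between pixel centers (computed over the
#' convex-hull vertices); MinFeret is the smallest projection width over
#' a caliper sweep in 0.1 degree steps.
#'
#' @param m a [labeled_mask()] or logical matrix with >= 2 foreground
#'   pixels.
#' @return list with `feret_px` and `min_feret_px`.
#' @export
feret_diameters <- function(m) {
  mask <- as_mask(m)
  if (sum(mask) < 2L)
    stop_phenoprop("Feret diameters need >= 2 foreground pixels", "bad_mask")
  h <- hull_centers(mask)
  d2 <- as.matrix(stats::dist(h))
  feret <- max(d2)
  ang <- seq(0, 180 - 0.1, by = 0.1) * pi / 180
  U <- rbind(cos(ang), sin(ang))
  proj <- h %*% U                             # vertices x angles
  widths <- apply(proj, 2L, max) - apply(proj, 2L, min)
  list(feret_px = feret, min_feret_px = min(widths))
}

# Area of the convex hull of the foreground pixel centers (shoelace).
# Collinear regions have zero hull area; callers handle that case.
hull_area_px <- function(mask) {
  v <- hull_centers(mask)
  n <- nrow(v)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L])) / 2
}

#' Morphometric descriptors of one region of interest
#'
#' Computes the twelve ImageJ-compatible shape descriptors of a seed or
#' pod region: Area (cm^2), Perimeter (cm), Width, Height, Major, Minor,
#' Feret, MinFeret (cm), Aspect Ratio, Circularity, Roundness, Solidity.
#'
#' @param m a [labeled_mask()].
#' @return one-row data frame with columns `area`, `perimeter`, `width`,
#'   `height`, `major`, `minor`, `feret`, `min_feret`, `aspect_ratio`,
#'   `circularity`, `roundness`, `solidity`, `degenerate`.
#' @examples
#' sq <- matrix(FALSE, 60, 60); sq[6:55, 6:55] <- TRUE
#' measure_shape(labeled_mask(sq, scale = 50))
#' @export
measure_shape <- function(m) {
  if (!inherits(m, "labeled_mask"))
    stop_phenoprop("measure_shape expects a labeled_mask", "bad_mask")
  mask <- m$mask; s <- m$scale
  w <- which(mask, arr.ind = TRUE)
  area <- nrow(w) / s^2
  perim <- perimeter_px(mask) / s
  height <- (max(w[, 1L]) - min(w[, 1L]) + 1L) / s
  width <- (max(w[, 2L]) - min(w[, 2L]) + 1L) / s
  ell <- fit_ellipse_moments(m)
  fer <- feret_diameters(m)
  major <- ell$major_px / s
  minor <- ell$minor_px / s
  # solidity on the pixel-center hull, clipped at 1: the pixel-count area
  # can exceed the center-hull area by up to half a boundary pixel for
  # convex regions, which is below the measurement resolution
  hull <- hull_area_px(mask) / s^2
  solidity <- if (hull > 0) min(1, area / hull) else 1
  data.frame(
    area = area,
    perimeter = perim,
    width = width,
    height = height,
    major = major,
    minor = minor,
    feret = fer$feret_px / s,
    min_feret = fer$min_feret_px / s,
    aspect_ratio = major / minor,
    circularity = 4 * pi * area / perim^2,
    roundness = 4 * area / (pi * major^2),
    solidity = solidity,
    degenerate = ell$degenerate)
}

#' Read an image file as a grayscale intensity matrix
#'
#' PNG and TIFF are supported; RGB(A) images are converted to grayscale by
#' luminance (0.299 R + 0.587 G + 0.114 B). Intensities are returned on
#' the 0..255 scale.
#'
#' @param path image file (.png, .tif/.tiff).
#' @return numeric matrix of intensities in [0, 255].
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_phenoprop(sprintf("unsupported image format '%s'", ext),
                   "bad_image"))
  if (length(dim(a)) == 3L) {
    if (dim(a)[3L] >= 3L)
      a <- 0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
    else a <- a[, , 1L]
  }
  a * 255
}

#' Measure every seed/pod region in an image
#'
#' Runs the full image protocol: binarization (maximum-entropy or Huang
#' threshold), region-of-interest extraction, and descriptor measurement
#' in calibrated units.
#'
#' @param img grayscale matrix in [0, 255], or a PNG/TIFF path.
#' @param scale_px_per_cm pixels per centimetre.
#' @param method `"max_entropy"` (default for seeds) or `"huang"`
#'   (default for pods).
#' @param min_area_px minimum particle area in pixels.
#' @param object `"dark"` object on light background, or `"light"`.
#' @param image_id identifier copied into the output.
#' @return data frame, one row per ROI, with `image_id`, `roi_id` and the
#'   columns `area_cm2`, `perimeter_cm`, `width_cm`, `height_cm`,
#'   `major_cm`, `minor_cm`, `feret_cm`, `min_feret_cm`, `ar`,
#'   `circularity`, `roundness`, `solidity`.
#' @export
measure_image <- function(img, scale_px_per_cm,
                          method = c("max_entropy", "huang"),
                          min_area_px = 50L, object = "dark",
                          image_id = "img") {
  method <- match.arg(method)
  if (is.character(img)) img <- read_gray_image(img)
  lev <- if (method == "max_entropy") threshold_max_entropy(img)
         else threshold_huang(img)
  mask <- binarize(img, lev, object = object)
  rois <- extract_rois(mask, min_area_px = min_area_px,
                       scale = scale_px_per_cm)
  if (length(rois) == 0L) {
    out <- data.frame(image_id = character(0), roi_id = integer(0),
                      area_cm2 = numeric(0), perimeter_cm = numeric(0),
                      width_cm = numeric(0), height_cm = numeric(0),
                      major_cm = numeric(0), minor_cm = numeric(0),
                      feret_cm = numeric(0), min_feret_cm = numeric(0),
                      ar = numeric(0), circularity = numeric(0),
                      roundness = numeric(0), solidity = numeric(0))
    return(out)
  }
  rows <- lapply(rois, function(r) {
    s <- measure_shape(r)
    data.frame(image_id = image_id, roi_id = r$roi_id,
               area_cm2 = s$area, perimeter_cm = s$perimeter,
               width_cm = s$width, height_cm = s$height,
               major_cm = s$major, minor_cm = s$minor,
               feret_cm = s$feret, min_feret_cm = s$min_feret,
               ar = s$aspect_ratio, circularity = s$circularity,
               roundness = s$roundness, solidity = s$solidity)
  })
  do.call(rbind, rows)
}
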