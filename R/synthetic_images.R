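#' Synthetic seed image (dark ellipse on light background)
#'
#' Renders a filled ellipse with full axes `axes_px = c(a, b)` (a >= b),
#' dark object (intensity ~ 40) on light background (~ 220), with additive
#' Gaussian noise. Ground-truth geometry is attached as attributes so the
#' measured descriptors can be checked against analytic values.
#'
#' @param axes_px numeric length-2, full major and minor axes in pixels.
#' @param noise_sd standard deviation of the additive intensity noise.
#' @param angle_deg rotation of the major axis, counterclockwise.
#' @param margin_px background margin around the object.
#' @param seed RNG seed (NULL = current stream).
#' @return intensity matrix in [0, 255] with attribute `truth` (list with
#'   `area_px`, `major_px`, `minor_px`, `angle_deg`).
#' @export
generate_seed_image <- function(axes_px, noise_sd = 5, angle_deg = 0,
                                margin_px = 12L, seed = NULL) {
  a <- axes_px[1L]; b <- axes_px[2L]
  if (!(a >= b && b > 0))
    stop_phenoprop("axes must satisfy a >= b > 0", "bad_config")
  half <- ceiling(max(a, b) / 2)
  n <- 2L * (half + margin_px) + 1L
  cx <- (n + 1) / 2
  th <- angle_deg * pi / 180
  idx <- expand.grid(r = seq_len(n), c = seq_len(n))
  x <- idx$c - cx; y <- -(idx$r - cx)
  xr <- cos(th) * x + sin(th) * y
  yr <- -sin(th) * x + cos(th) * y
  inside <- (xr / (a / 2))^2 + (yr / (b / 2))^2 <= 1
  img <- matrix(220, n, n)
  img[cbind(idx$r, idx$c)[inside, , drop = FALSE]] <- 40
  img <- add_noise(img, noise_sd, seed)
  attr(img, "truth") <- list(area_px = pi * a * b / 4, major_px = a,
                             minor_px = b, angle_deg = angle_deg)
  img
}

#' Synthetic pod image (curved capsule)
#'
#' Renders a pod as the set of pixels within `width_px / 2` of a circular
#' arc. `curvature` is the sagitta-to-length ratio of the centerline: 0
#' gives a straight capsule (solidity near 1); larger values bend the pod
#' and lower its solidity, emulating the curved-pod accessions.
#'
#' @param length_px straight-line (chord) length of the centerline.
#' @param width_px pod thickness in pixels.
#' @param curvature sagitta / chord-length ratio, >= 0 (values up to ~0.5
#'   are sensible).
#' @param noise_sd additive Gaussian intensity noise.
#' @param seed RNG seed.
#' @return intensity matrix in [0, 255] with attribute `truth`.
#' @export
generate_pod_image <- function(length_px, width_px, curvature = 0,
                               noise_sd = 5, margin_px = 12L, seed = NULL) {
  if (curvature < 0) stop_phenoprop("curvature must be >= 0", "bad_config")
  if (length_px <= 0 || width_px <= 0)
    stop_phenoprop("length and width must be positive", "bad_config")
  L <- length_px; sag <- curvature * L
  nw <- ceiling(L + width_px) + 2L * margin_px
  nh <- ceiling(sag + width_px) + 2L * margin_px
  img <- matrix(220, nh, nw)
  # centerline: quadratic arc y = sag * (1 - (2x/L)^2), x in [-L/2, L/2],
  # rasterized by exact point-to-segment distance on a fine polyline
  tseq <- seq(-L / 2, L / 2, length.out = max(40L, ceiling(L / 4)))
  cxs <- nw / 2 + tseq
  cys <- margin_px + width_px / 2 + sag * (1 - (2 * tseq / L)^2)
  idx <- expand.grid(r = seq_len(nh), c = seq_len(nw))
  d2 <- matrix(Inf, nh, nw)
  for (i in seq_len(length(tseq) - 1L)) {
    vx <- cxs[i + 1L] - cxs[i]; vy <- cys[i + 1L] - cys[i]
    tt <- pmin(pmax(((idx$c - cxs[i]) * vx + (idx$r - cys[i]) * vy) /
                      (vx^2 + vy^2), 0), 1)
    dd <- (idx$c - (cxs[i] + tt * vx))^2 + (idx$r - (cys[i] + tt * vy))^2
    d2[] <- pmin(d2, dd)
  }
  img[d2 <= (width_px / 2)^2] <- 40
  if (!any(img == 40) || any(img[1L, ] == 40) || any(img[nh, ] == 40) ||
      any(img[, 1L] == 40) || any(img[, nw] == 40))
    stop_phenoprop("pod exceeds canvas", "bad_config")
  img <- add_noise(img, noise_sd, seed)
  attr(img, "truth") <- list(length_px = L, width_px = width_px,
                             curvature = curvature)
  img
}

add_noise <- function(img, noise_sd, seed) {
  if (noise_sd > 0) {
    noise <- local_seed(seed, stats::rnorm(length(img), 0, noise_sd))
    img <- img + noise
    img[img < 0] <- 0; img[img > 255] <- 255
  }
  tr <- attr(img, "truth")
  img <- matrix(img, nrow(img), ncol(img))
  attr(img, "truth") <- tr
  img
}

#' Write a grayscale matrix as a PNG file
#'
#' @param img intensity matrix in [0, 255].
#' @param path output .png path.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(img / 255, target = path)
  invisible(path)
}
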