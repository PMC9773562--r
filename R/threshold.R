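#' Grayscale image histogram on 256 bins
#'
#' @param img numeric matrix of intensities in [0, 255] (fractional values
#'   are binned by truncation, as in 8-bit image software).
#' @return integer vector of length 256, counts for levels 0..255.
#' @keywords internal
image_histogram <- function(img) {
  check_gray_image(img)
  lev <- floor(as.vector(img))
  lev[lev > 255] <- 255L
  tabulate(lev + 1L, nbins = 256L)
}

check_gray_image <- function(img) {
  if (!is.matrix(img) || length(img) == 0L)
    stop_phenoprop("image must be a non-empty numeric matrix", "bad_image")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop_phenoprop("intensities must lie in [0, 255]", "bad_image")
  invisible(img)
}

#' Maximum-entropy (Kapur) threshold
#'
#' Selects the level that maximizes the summed Shannon entropies of the
#' background (levels 0..t) and foreground (levels t+1..255) histogram
#' classes, the criterion of Kapur, Sahoo and Wong. This is one of the two
#' binarization methods used in the seed/pod image protocol.
#'
#' @param img numeric matrix with intensities in [0, 255].
#' @return integer threshold level t in 0..254; pixels with intensity
#'   \code{<= t} form one non-empty class and the rest the other.
#' @examples
#' img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
#' threshold_max_entropy(img)
#' @export
threshold_max_entropy <- function(img) {
  h <- image_histogram(img)
  if (sum(h > 0L) < 2L)
    stop_phenoprop("degenerate image: fewer than 2 distinct intensities",
                   "degenerate_image")
  p <- h / sum(h)
  P <- cumsum(p)                       # P[t+1] = mass of levels 0..t
  # classwise entropies; zero-probability bins contribute nothing
  plogp <- ifelse(p > 0, p * log(p), 0)
  S <- cumsum(plogp)
  Stot <- S[256L]
  crit <- rep(-Inf, 255L)
  for (t in 1:255) {                   # threshold level t-1; classes 0..t-1 | t..255
    w0 <- P[t]; w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    Hb <- log(w0) - S[t] / w0
    Hf <- log(w1) - (Stot - S[t]) / w1
    crit[t] <- Hb + Hf
  }
  which.max(crit) - 1L
}

#' Huang fuzzy threshold
#'
#' Selects the level minimizing Huang and Wang's measure of fuzziness: each
#' pixel's membership to its class is u = 1 / (1 + |g - mu_class| / C) with
#' C the intensity range, and the fuzziness is the mean Shannon entropy
#' -u log u - (1-u) log(1-u) over pixels. The second binarization method of
#' the image protocol.
#'
#' @inheritParams threshold_max_entropy
#' @return integer threshold level in 0..254 (pixels \code{<= t} vs rest).
#' @export
threshold_huang <- function(img) {
  h <- image_histogram(img)
  if (sum(h > 0L) < 2L)
    stop_phenoprop("degenerate image: fewer than 2 distinct intensities",
                   "degenerate_image")
  g <- 0:255
  first <- min(which(h > 0L)) - 1L
  last <- max(which(h > 0L)) - 1L
  C <- last - first
  W <- cumsum(h * g); N <- cumsum(h)
  Wt <- W[256L]; Nt <- N[256L]
  crit <- rep(Inf, 255L)
  shannon <- function(u) {
    s <- numeric(length(u))
    ok <- u > 0 & u < 1
    s[ok] <- -u[ok] * log(u[ok]) - (1 - u[ok]) * log(1 - u[ok])
    s
  }
  for (t in 1:255) {                   # classes: levels 0..t-1 | t..255
    n0 <- N[t]; n1 <- Nt - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- W[t] / n0
    mu1 <- (Wt - W[t]) / n1
    mu <- c(rep(mu0, t), rep(mu1, 256L - t))
    u <- 1 / (1 + abs(g - mu) / C)
    crit[t] <- sum(h * shannon(u)) / Nt
  }
  which.min(crit) - 1L
}

#' Binarize a grayscale image at a threshold level
#'
#' @param img numeric matrix in [0, 255].
#' @param level threshold level (e.g. from [threshold_max_entropy()]).
#' @param object `"dark"` if the object is darker than the background
#'   (foreground = intensity <= level), `"light"` otherwise.
#' @return logical matrix, `TRUE` = foreground.
#' @export
binarize <- function(img, level, object = c("dark", "light")) {
  object <- match.arg(object)
  check_gray_image(img)
  if (object == "dark") img <= level else img > level
}
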