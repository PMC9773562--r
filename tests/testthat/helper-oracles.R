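# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with R/: direct per-candidate criterion
# evaluation, scalar flood fill, all-pixel caliper sweeps, direct algebra.

# Kapur criterion evaluated naively for every candidate level.
oracle_kapur <- function(img) {
  h <- tabulate(floor(as.vector(img)) + 1L, 256L)
  p <- h / sum(h)
  best <- -Inf; bt <- NA_integer_
  for (t in 0:254) {
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    p0 <- p[1:(t + 1)] / w0; p0 <- p0[p0 > 0]
    p1 <- p[(t + 2):256] / w1; p1 <- p1[p1 > 0]
    H <- -sum(p0 * log(p0)) - sum(p1 * log(p1))
    if (H > best) { best <- H; bt <- t }
  }
  bt
}

# Huang fuzziness evaluated naively for every candidate level.
oracle_huang <- function(img) {
  v <- floor(as.vector(img))
  h <- tabulate(v + 1L, 256L)
  g <- 0:255
  C <- max(v) - min(v)
  best <- Inf; bt <- NA_integer_
  for (t in 0:254) {
    lo <- g <= t
    if (sum(h[lo]) == 0 || sum(h[!lo]) == 0) next
    mu0 <- sum(h[lo] * g[lo]) / sum(h[lo])
    mu1 <- sum(h[!lo] * g[!lo]) / sum(h[!lo])
    mu <- ifelse(lo, mu0, mu1)
    u <- 1 / (1 + abs(g - mu) / C)
    s <- ifelse(u > 0 & u < 1, -u * log(u) - (1 - u) * log(1 - u), 0)
    E <- sum(h * s) / sum(h)
    if (E < best) { best <- E; bt <- t }
  }
  bt
}

# Scalar queue-based flood fill, 8-connectivity: number of components.
oracle_component_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    count <- count + 1L
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(stack) > 0L) {
      px <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- px[1] + dr; c <- px[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  count
}

# Max caliper: largest pairwise distance over all foreground pixel centers.
oracle_feret <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  max(stats::dist(w))
}

# Min caliper: projection widths of all pixel centers, 0.1 degree sweep.
oracle_min_feret <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  ang <- seq(0, 180 - 0.1, by = 0.1) * pi / 180
  U <- rbind(cos(ang), sin(ang))
  proj <- w %*% U
  min(apply(proj, 2L, max) - apply(proj, 2L, min))
}

# Gift-wrapping (Jarvis march) hull area over pixel center points.
oracle_hull_area <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  pts <- cbind(w[, 1], w[, 2])
  n <- nrow(pts)
  start <- which.min(pts[, 1] + pts[, 2] * 1e-9)
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1L) 2L else 1L
    for (j in seq_len(n)) {
      if (j == cur) next
      cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
            (pts[cand, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      if (cand == cur || cr < 0 ||
          (cr == 0 && sum((pts[j, ] - pts[cur, ])^2) >
                      sum((pts[cand, ] - pts[cur, ])^2)))
        cand <- j
    }
    cur <- cand
    if (cur == hull[1L]) break
    if (length(hull) > n) stop("gift wrapping failed")
  }
  v <- pts[hull, , drop = FALSE]
  j <- c(2:nrow(v), 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# Random connected blob: union of overlapping disks all containing the
# canvas center, so the union is guaranteed 8-connected.
make_blob <- function(seed, size = 48L) {
  set.seed(seed)
  k <- sample(2:5, 1L)
  ctr <- size / 2
  mask <- matrix(FALSE, size, size)
  rr <- matrix(rep(seq_len(size), size), size)
  cc <- t(rr)
  for (i in seq_len(k)) {
    rad <- runif(1, 5, 9)
    off <- runif(2, -3.4, 3.4)
    mask <- mask | ((rr - (ctr + off[1]))^2 + (cc - (ctr + off[2]))^2 <=
                      rad^2)
  }
  mask
}

# Filled disk mask.
make_disk <- function(r, size = 2L * r + 21L) {
  ctr <- (size + 1) / 2
  outer(seq_len(size), seq_len(size),
        function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

# Axis-aligned filled rectangle mask (nr x nc of foreground).
make_rect <- function(nr, nc, pad = 5L) {
  m <- matrix(FALSE, nr + 2L * pad, nc + 2L * pad)
  m[pad + seq_len(nr), pad + seq_len(nc)] <- TRUE
  m
}

# Two-Gaussian synthetic grayscale image (means 60/180, sd 15).
make_bimodal_image <- function(seed, n = 10000L) {
  set.seed(seed)
  v <- c(rnorm(n / 2, 60, 15), rnorm(n / 2, 180, 15))
  v <- pmin(pmax(round(v), 0), 255)
  matrix(v, 100)
}

# Default well-separated 4-class panel in wide form, with latent truth.
make_wide_panel <- function(component = "seed_morph", n_parent = 150L,
                            n_hybrid = 150L,
                            weights = c(parent1 = 0.20, parent2 = 0.10,
                                        parent3 = 0.00, self = 0.70),
                            separation_sd = 6, seed = 1L) {
  m <- default_study_models(component, n_parent = n_parent,
                            n_hybrid = n_hybrid, weights = weights,
                            separation_sd = separation_sd)
  generate_panel(m$parents, m$hybrid, component = component, seed = seed)
}

panel_descriptors <- function(pan)
  setdiff(names(pan), c("unit_id", "component", "class", ".latent"))
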