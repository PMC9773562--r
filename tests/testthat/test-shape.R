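rotate90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

test_that("moment ellipse is symmetric for a disk and analytic for a rectangle", {
  disk <- make_disk(50)
  e <- fit_ellipse_moments(labeled_mask(disk))
  expect_lt(abs(e$major_px / e$minor_px - 1), 0.01)
  rect <- make_rect(40, 100)
  e <- fit_ellipse_moments(labeled_mask(rect))
  expect_lt(abs(e$orientation_deg), 1e-6)
  expect_lt(abs(e$major_px / e$minor_px - 100 / 40), 0.02 * 2.5)
  # ellipse area matches pixel area for round convex blobs (disk: exact)
  ed <- fit_ellipse_moments(labeled_mask(disk))
  expect_lt(abs(pi * ed$major_px * ed$minor_px / 4 - sum(disk)) /
              sum(disk), 0.01)
})

test_that("90-degree rotation swaps width/height but preserves axes", {
  rect <- make_rect(40, 100)
  e1 <- fit_ellipse_moments(labeled_mask(rect))
  e2 <- fit_ellipse_moments(labeled_mask(rotate90(rect)))
  expect_lt(abs(e1$major_px - e2$major_px) / e1$major_px, 0.01)
  expect_lt(abs(e1$minor_px - e2$minor_px) / e1$minor_px, 0.01)
  s1 <- measure_shape(labeled_mask(rect, scale = 10))
  s2 <- measure_shape(labeled_mask(rotate90(rect), scale = 10))
  expect_equal(s1$width, s2$height)
  expect_equal(s1$height, s2$width)
  for (f in c("area", "perimeter", "major", "minor", "feret",
              "min_feret", "circularity", "roundness", "solidity"))
    expect_lt(abs(s1[[f]] - s2[[f]]) / s1[[f]], 0.015)
})

test_that("Feret diameters follow the pixel-center caliper convention", {
  rect <- make_rect(50, 200)
  f <- feret_diameters(rect)
  expect_lt(abs(f$feret_px - sqrt(199^2 + 49^2)), 0.05)
  expect_gte(f$min_feret_px, 49)
  expect_lte(f$min_feret_px, 50)
  disk <- make_disk(60)
  fd <- feret_diameters(disk)
  expect_lt(abs(fd$feret_px - 120) / 120, 0.01)
  # pixel-center min caliper runs up to one pixel below the max for a disk
  expect_lte(fd$min_feret_px, fd$feret_px)
  expect_gte(fd$min_feret_px, fd$feret_px - 1.5)
})

test_that("analytic square fixture measures exactly", {
  sq <- make_rect(50, 50)
  s <- measure_shape(labeled_mask(sq, scale = 50))
  expect_equal(s$area, 1.0, tolerance = 1e-9)
  expect_equal(s$width, 1.0, tolerance = 1e-9)
  expect_equal(s$height, 1.0, tolerance = 1e-9)
  expect_equal(s$solidity, 1.0, tolerance = 1e-6)
  expect_equal(s$aspect_ratio, 1.0, tolerance = 1e-6)
})

test_that("rasterized disk has near-unit circularity and roundness", {
  s <- measure_shape(labeled_mask(make_disk(100), scale = 1))
  expect_gte(s$circularity, 0.95)
  expect_lte(s$circularity, 1.02)
  expect_gte(s$roundness, 0.97)
  expect_lte(s$roundness, 1.03)
})

test_that("a curved C-shape has low solidity while its hull does not", {
  n <- 101; ctr <- 51
  rr <- matrix(rep(1:n, n), n); cc <- t(rr)
  d <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
  cshape <- d >= 25 & d <= 40 & cc <= ctr  # half annulus
  s <- measure_shape(labeled_mask(cshape, scale = 1))
  expect_lt(s$solidity, 0.95)
  expect_equal(s$area / oracle_hull_area(cshape), s$solidity,
               tolerance = 1e-6)
})

test_that("measurements are scale-equivariant and dimensionless descriptors invariant", {
  blob <- make_blob(7)
  s1 <- measure_shape(labeled_mask(blob, scale = 10))
  s2 <- measure_shape(labeled_mask(blob, scale = 20))
  for (f in c("perimeter", "width", "height", "major", "minor", "feret",
              "min_feret"))
    expect_equal(s1[[f]] / s2[[f]], 2, tolerance = 1e-9)
  expect_equal(s1$area / s2$area, 4, tolerance = 1e-9)
  for (f in c("aspect_ratio", "circularity", "roundness", "solidity"))
    expect_equal(s1[[f]], s2[[f]], tolerance = 1e-12)
})

test_that("convex-hull area matches the gift-wrapping oracle on random blobs", {
  for (s in 1:10) {
    blob <- make_blob(200 + s)
    expect_equal(phenoprop:::hull_area_px(blob), oracle_hull_area(blob),
                 tolerance = 1e-8)
  }
})

test_that("measure_image runs the full protocol on a synthetic seed image", {
  img <- generate_seed_image(c(80, 40), noise_sd = 3, seed = 5)
  out <- measure_image(img, scale_px_per_cm = 40, method = "max_entropy",
                       min_area_px = 100, image_id = "seed1")
  expect_equal(nrow(out), 1L)
  expect_equal(names(out),
               c("image_id", "roi_id", "area_cm2", "perimeter_cm",
                 "width_cm", "height_cm", "major_cm", "minor_cm",
                 "feret_cm", "min_feret_cm", "ar", "circularity",
                 "roundness", "solidity"))
  expect_lt(abs(out$ar - 2), 0.05 * 2)
  expect_lt(abs(out$area_cm2 - pi * 2 * 1 / 4), 0.05)
  # empty result when nothing survives the area filter
  expect_equal(nrow(measure_image(img, 40, min_area_px = 1e6)), 0L)
})

test_that("PNG round trip preserves intensities and luminance conversion works", {
  img <- matrix(round(seq(0, 255, length.out = 120)), 10, 12)
  path <- withr::local_tempfile(fileext = ".png")
  write_gray_png(img, path)
  back <- read_gray_image(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1)
})
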