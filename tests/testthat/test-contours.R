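# helpers to build synthetic per-ray fits on a known shape
fits_on_radius <- function(radius, wt = 1, invalid = integer(0)) {
  n <- length(radius)
  lapply(seq_len(n), function(i) {
    if (i %in% invalid) bronchoquant:::invalid_fit(i - 1L, "bright_outside")
    else bronchoquant:::wall_fit(i - 1L, inner = radius[i],
                                 outer = radius[i] + wt,
                                 inner_hu = -500, valid = TRUE)
  })
}

test_that("ellipse completion restores missing points on a circle", {
  n <- 128L
  fits <- fits_on_radius(rep(5, n), invalid = 1:32)
  ct <- complete_inner_standard(fits, center = c(0, 0))
  expect_equal(nrow(ct$points), n)
  expect_true(all(abs(ct$radius[1:32] - 5) < 0.01))
  expect_identical(unique(ct$source[1:32]), "ellipse_completed")
  expect_identical(unique(ct$source[33:n]), "measured")
})

test_that("ellipse completion reproduces the polar form of an ellipse", {
  n <- 128L
  ang <- bronchoquant:::ray_angles(n)
  a <- 6; b <- 4
  r_true <- a * b / sqrt(b^2 * cos(ang)^2 + a^2 * sin(ang)^2)
  fits <- fits_on_radius(r_true, invalid = c(10:20, 70:80))
  ct <- complete_inner_standard(fits, center = c(0, 0))
  expect_lt(max(abs(ct$radius - r_true)), 0.02)
})

test_that("ellipse completion needs at least five valid points", {
  fits <- fits_on_radius(rep(5, 16), invalid = 5:16)
  expect_error(complete_inner_standard(fits, c(0, 0)),
               "insufficient wall points")
})

test_that("median-HU completion interpolates the threshold crossing", {
  n <- 8L
  fits <- fits_on_radius(rep(5, n), invalid = 2L)
  # valid inner HU values -500 each -> threshold T = -500
  pos <- seq(0, 10, by = 0.1)
  hu <- rep(-1000, length(pos))
  hu[pos >= 5.0] <- -400          # sample at 4.9 is -1000, at 5.0 is -400
  prof <- structure(list(index = 1L, angle_rad = bronchoquant:::ray_angles(n)[2],
                         step_mm = 0.1, positions = pos, hu = hu,
                         tainted = FALSE), class = "ray_profile")
  profiles <- rep(list(prof), n)
  ct <- complete_inner_modified(fits, profiles, center = c(0, 0))
  expect_equal(ct$radius[2], 4.9 + 500 / 600 * 0.1, tolerance = 1e-6)
  expect_identical(ct$source[2], "medianhu_completed")
})

test_that("median-HU completion is a no-op when all rays are valid", {
  n <- 16L
  fits <- fits_on_radius(rep(4, n))
  ct <- complete_inner_modified(fits, vector("list", n), center = c(0, 0))
  expect_true(all(ct$radius == 4))
  expect_identical(unique(ct$source), "measured")
})

test_that("rays never reaching the threshold fall back to the ellipse", {
  n <- 16L
  fits <- fits_on_radius(rep(5, n), invalid = 3L)
  pos <- seq(0, 10, by = 0.1)
  dark <- structure(list(index = 2L, angle_rad = 0, step_mm = 0.1,
                         positions = pos, hu = rep(-1000, length(pos)),
                         tainted = FALSE), class = "ray_profile")
  profiles <- rep(list(dark), n)
  ct <- complete_inner_modified(fits, profiles, center = c(0, 0))
  expect_identical(ct$source[3], "ellipse_completed_fallback")
  expect_lt(abs(ct$radius[3] - 5), 0.01)
})

test_that("outer completion offsets the inner contour by the median wall", {
  n <- 16L
  fits <- fits_on_radius(rep(5, n), wt = 1, invalid = 7L)
  # perturb three valid rays so the median is taken over {0.9, 1.0, 1.3, 1 x 12}
  fits[[1]]$outer_pos_mm <- 5.9
  fits[[2]]$outer_pos_mm <- 6.3
  inner <- complete_inner_standard(fits, c(0, 0))
  outer <- complete_outer(fits, inner, c(0, 0))
  expect_equal(outer$radius[7], inner$radius[7] + 1)   # median WT = 1
  expect_identical(outer$source[7], "offset_completed")
  expect_true(all(outer$radius[-7] == vapply(fits[-7], `[[`, numeric(1),
                                             "outer_pos_mm")))
})

test_that("polygon area and centroid follow the shoelace formulas", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(bronchoquant:::polygon_area(sq), 1)
  expect_equal(bronchoquant:::polygon_centroid(sq), c(0.5, 0.5))
})

test_that("metrics on regular 128-gons match the closed forms", {
  n <- 128L
  fits <- fits_on_radius(rep(5, n), wt = 1)
  inner <- complete_inner_standard(fits, c(0, 0))
  outer <- complete_outer(fits, inner, c(0, 0))
  m <- compute_metrics(inner, outer, fits, algorithm = "standard_ibm")
  gon <- function(r) 0.5 * n * r^2 * sin(2 * pi / n)
  expect_equal(m$LA_mm2, gon(5), tolerance = 1e-9)
  expect_equal(m$WA_mm2, gon(6) - gon(5), tolerance = 1e-9)
  expect_equal(m$TD_mm, 12)        # antipodal vertices of an even polygon
  expect_equal(m$WT_mm, 1)
  expect_equal(m$n_valid_rays, n)

  # equivalent-circle diameter variant
  m2 <- compute_metrics(inner, outer, fits, td_mode = "equivalent_circle")
  expect_equal(m2$TD_mm, 2 * sqrt(gon(6) / pi), tolerance = 1e-9)
})

test_that("wall thickness uses valid rays only and resists outliers", {
  n <- 8L
  fits <- fits_on_radius(rep(5, n))
  fits[[1]]$outer_pos_mm <- 5.8
  fits[[2]]$outer_pos_mm <- 5.9
  fits[[3]]$outer_pos_mm <- 6.1
  fits[[4]]$outer_pos_mm <- 10    # gross outlier on one ray
  inner <- complete_inner_standard(fits, c(0, 0))
  outer <- complete_outer(fits, inner, c(0, 0))
  m <- compute_metrics(inner, outer, fits)
  expect_equal(m$WT_mm, 1)        # median {0.8,0.9,1.1,5,1,1,1,1} = 1
})

test_that("contour inversion is reported as an error", {
  n <- 8L
  fits <- fits_on_radius(rep(5, n), wt = 1)
  inner <- complete_inner_standard(fits, c(0, 0))
  small <- fits_on_radius(rep(2, n), wt = 0.1)
  outer_small <- complete_outer(small, complete_inner_standard(small, c(0, 0)),
                                c(0, 0))
  expect_error(compute_metrics(inner, outer_small, fits),
               "outer inside inner")
})
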