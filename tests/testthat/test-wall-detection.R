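test_that("level estimation finds the wall peak and the two plateaus", {
  p <- model_profile(5, 6, sigma = 0.5)
  lv <- estimate_levels(p, psf_sigma_mm = 0.5)
  expect_gt(lv$peak_pos_mm, 5)
  expect_lt(lv$peak_pos_mm, 6)
  # a 1 mm wall blurred with sigma 0.5 is partial-volume depressed: the
  # peak reaches the mid-bar value of the model, far below the wall HU
  mid <- bronchoquant:::model_hu_exact(5.5, 5, 6, 0.5, -1000, -850, 0, "planar")
  expect_lt(abs(lv$hu_peak - mid), 15)
  expect_lt(abs(lv$hu_lumen - (-1000)), 5)
  expect_lt(abs(lv$hu_outer - (-850)), 5)
  expect_error(estimate_levels(model_profile(5, 6, 0.5, max_len = 1)),
               "fewer than 10 samples")
})

test_that("a profile that ends before the outer window yields a missing plateau", {
  p <- model_profile(5, 6, sigma = 0.5, max_len = 7)
  lv <- estimate_levels(p, psf_sigma_mm = 0.5)
  expect_true(is.na(lv$hu_outer))
})

test_that("FWHM edges sit at the half-maximum crossings", {
  # near-sharp edges: the half-max of a step is at the step
  p <- model_profile(5, 5.5, sigma = 0.05)
  lv <- estimate_levels(p, psf_sigma_mm = 0.05)
  fw <- fwhm_edges(p, lv)
  expect_lt(abs(fw[["inner"]] - 5), 0.05)
  expect_lt(abs(fw[["outer"]] - 5.5), 0.05)

  # blurred thin wall: the FWHM width exceeds the true width
  p2 <- model_profile(5, 5.5, sigma = 0.6)
  fw2 <- fwhm_edges(p2, estimate_levels(p2, psf_sigma_mm = 0.6))
  expect_gt(fw2[["outer"]] - fw2[["inner"]], 0.5)

  # monotone profile with no wall: no crossings to report
  flat <- model_profile(5, 6, sigma = 0.5)
  flat$hu <- seq(-1000, -850, length.out = length(flat$hu))
  lvf <- estimate_levels(flat, psf_sigma_mm = 0.5)
  expect_true(anyNA(fwhm_edges(flat, lvf)))
})

test_that("integral fit recovers the generating edges to 0.02 mm (self-consistency)", {
  cfg <- ibm_config(psf_sigma_mm = 0.6, model = "planar",
                    wall_hu_mode = "fixed", wall_hu_fixed = 0)
  cases <- list(c(5.00, 5.40), c(3.00, 3.80), c(2.00, 4.20))
  for (cs in cases) {
    p <- model_profile(cs[1], cs[2], sigma = 0.6, model = "planar")
    lv <- estimate_levels(p, psf_sigma_mm = 0.6)
    ft <- integral_fit(p, lv, cfg, wall_hu = 0)
    expect_true(ft$valid)
    expect_lt(abs(ft$inner_pos_mm - cs[1]), 0.02)
    expect_lt(abs(ft$outer_pos_mm - cs[2]), 0.02)
    # the matched window integrals agree by construction
    expect_lt(abs(ft$inner_resid_hu_mm), 0.5)
    expect_lt(abs(ft$outer_resid_hu_mm), 0.5)
  }
  # the annular model family is self-consistent in the same way
  cfga <- ibm_config(psf_sigma_mm = 0.6, model = "annular",
                     wall_hu_mode = "fixed", wall_hu_fixed = 0)
  pa <- model_profile(2.0, 2.4, sigma = 0.6, model = "annular")
  fta <- integral_fit(pa, estimate_levels(pa, psf_sigma_mm = 0.6), cfga, 0)
  expect_lt(abs(fta$inner_pos_mm - 2.0), 0.02)
  expect_lt(abs(fta$outer_pos_mm - 2.4), 0.02)
})

test_that("with vanishing blur the integral fit agrees with the FWHM edges", {
  p <- model_profile(5, 6, sigma = 0.05)
  lv <- estimate_levels(p, psf_sigma_mm = 0.05)
  cfg <- ibm_config(psf_sigma_mm = 0.05, model = "planar",
                    wall_hu_mode = "fixed", wall_hu_fixed = 0)
  ft <- integral_fit(p, lv, cfg, wall_hu = 0)
  fw <- fwhm_edges(p, lv)
  expect_lt(abs(ft$inner_pos_mm - fw[["inner"]]), 0.1)
  expect_lt(abs(ft$outer_pos_mm - fw[["outer"]]), 0.1)
})

test_that("IBM resists blur on thin walls where FWHM overestimates", {
  # true WT 0.5 mm, sigma 0.6 mm, noiseless analytic profile
  p <- model_profile(5, 5.5, sigma = 0.6, model = "planar")
  lv <- estimate_levels(p, psf_sigma_mm = 0.6)
  cfg <- ibm_config(psf_sigma_mm = 0.6, model = "planar",
                    wall_hu_mode = "fixed", wall_hu_fixed = 0)
  ft <- integral_fit(p, lv, cfg, wall_hu = 0)
  wt_ibm <- ft$outer_pos_mm - ft$inner_pos_mm
  fw <- fwhm_edges(p, lv)
  wt_fwhm <- fw[["outer"]] - fw[["inner"]]
  expect_lt(abs(wt_ibm - 0.5) / 0.5, 0.10)
  expect_gt(abs(wt_fwhm - 0.5) / 0.5, 0.30)
})

test_that("IBM error stays small as blur grows while FWHM error grows with it", {
  cfg0 <- function(s) ibm_config(psf_sigma_mm = s, model = "planar",
                                 wall_hu_mode = "fixed", wall_hu_fixed = 0)
  sigmas <- c(0.4, 0.6, 0.8)
  err_ibm <- err_fwhm <- numeric(0)
  for (s in sigmas) {
    p <- model_profile(4, 4.8, sigma = s, model = "planar")
    lv <- estimate_levels(p, psf_sigma_mm = s)
    ft <- integral_fit(p, lv, cfg0(s), wall_hu = 0)
    fw <- fwhm_edges(p, lv)
    err_ibm <- c(err_ibm, abs(ft$outer_pos_mm - ft$inner_pos_mm - 0.8) / 0.8)
    err_fwhm <- c(err_fwhm, abs(fw[["outer"]] - fw[["inner"]] - 0.8) / 0.8)
  }
  expect_true(all(err_ibm <= 0.02))
  expect_true(all(diff(err_fwhm) > 0))
})

test_that("validity classification separates taint, vessels and weak walls", {
  p <- model_profile(5, 6, sigma = 0.5)
  lv <- estimate_levels(p, psf_sigma_mm = 0.5)
  cfg <- ibm_config(psf_sigma_mm = 0.5)
  ok <- bronchoquant:::wall_fit(0L, 5, 6, -500, valid = TRUE)

  expect_identical(classify_validity(lv, ok, p, cfg)$invalid_reason, "none")

  tainted <- p; tainted$tainted <- TRUE
  expect_identical(classify_validity(lv, ok, tainted, cfg)$invalid_reason,
                   "border_taint")

  lv_vessel <- lv; lv_vessel$hu_outer <- 32     # non-enhanced blood outside
  out <- classify_validity(lv_vessel, ok, p, cfg)
  expect_identical(out$invalid_reason, "bright_outside")
  expect_true(is.na(out$inner_pos_mm))           # no fabricated positions

  lv_weak <- lv; lv_weak$hu_peak <- lv$hu_outer + 120
  cfg150 <- ibm_config(psf_sigma_mm = 0.5, prominence_min_hu = 150)
  expect_identical(classify_validity(lv_weak, ok, p, cfg150)$invalid_reason,
                   "low_prominence")
})

test_that("vessel-contact rays are invalid while an isolated airway keeps all rays", {
  spec <- phantom_spec(1.75, 0.75, vessel_radius_mm = 4, vessel_hu = 32,
                       psf_sigma_mm = 0.6, noise_sd_hu = 0)
  img <- render_phantom(spec)
  st <- bronchoquant:::detect_walls(img, spec$airway_center_mm, "standard_ibm",
                                    study_cfg(), 128L, 0.1, 14)
  reasons <- vapply(st$fits, `[[`, character(1), "invalid_reason")
  expect_identical(reasons[1], "bright_outside")   # ray 0 points at the vessel
  expect_gt(sum(reasons == "bright_outside"), 5)

  free <- phantom_spec(1.75, 0.75, psf_sigma_mm = 0.6, noise_sd_hu = 0)
  st2 <- bronchoquant:::detect_walls(render_phantom(free),
                                     free$airway_center_mm, "standard_ibm",
                                     study_cfg(), 128L, 0.1, 14)
  expect_equal(sum(vapply(st2$fits, `[[`, logical(1), "valid")), 128L)
})

test_that("wall attenuation selection honours its modes", {
  spec <- phantom_spec(2.5, 2.5, psf_sigma_mm = 0.3, noise_sd_hu = 0,
                       image_size_mm = 24)
  img <- render_phantom(spec)
  profs <- cast_profiles(img, spec$airway_center_mm, max_len_mm = 10)
  lvs <- lapply(profs, estimate_levels, psf_sigma_mm = 0.3)
  # resolved wall (WT >> sigma): the tallest peak reads the true wall HU
  cfg <- ibm_config(psf_sigma_mm = 0.3, wall_hu_mode = "auto_max_peak")
  expect_lt(abs(auto_wall_hu(lvs, cfg) - 0), 10)

  cfg_fix <- ibm_config(psf_sigma_mm = 0.3, wall_hu_mode = "fixed",
                        wall_hu_fixed = -50)
  expect_equal(auto_wall_hu(lvs, cfg_fix), -50)

  # every ray facing soft tissue -> no usable wall signal
  lvs_bad <- lapply(lvs, function(lv) { lv$hu_outer <- 40; lv })
  expect_error(auto_wall_hu(lvs_bad, cfg), "no wall signal")
})

test_that("identical profile and config give identical fits (determinism)", {
  spec <- phantom_spec(2, 0.8, noise_sd_hu = 20, seed = 5L)
  img <- render_phantom(spec)
  p <- cast_profiles(img, spec$airway_center_mm, max_len_mm = 10)[[17]]
  lv <- estimate_levels(p, psf_sigma_mm = study_cfg()$psf_sigma_mm)
  f1 <- integral_fit(p, lv, study_cfg(), wall_hu = 0)
  f2 <- integral_fit(p, lv, study_cfg(), wall_hu = 0)
  expect_identical(f1, f2)
})
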