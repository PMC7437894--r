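#' Measure an airway on a CT slice
#'
#' Semi-automatic airway morphometry from a user-supplied lumen seed
#' point. The pipeline casts radial density profiles from the current
#' centre, estimates per-ray levels and the wall attenuation, localizes
#' the inner and outer wall border on every ray (integral-based fit for
#' the IBM variants, half-maximum crossings for `"fwhm"`), classifies ray
#' validity, completes the inner contour (least-squares ellipse for
#' `"standard_ibm"` and `"fwhm"`, median-HU rule for `"modified_ibm"`),
#' and re-centres on the inner-polygon centroid. Centre refinement
#' repeats until the centre moves less than `center_tol_mm` or
#' `max_center_iter` iterations; the outer contour is then completed and
#' the metrics computed. The whole procedure is deterministic.
#'
#' @param image an [hu_image].
#' @param seed seed point c(x, y) in mm, inside the lumen.
#' @param algorithm `"standard_ibm"`, `"modified_ibm"` or `"fwhm"`.
#' @param cfg an [ibm_config].
#' @param n_rays,step_mm,max_len_mm profile casting parameters, see
#'   [cast_profiles()].
#' @param lumen_max_hu maximum attenuation accepted at the seed point
#'   (default -900 HU); blur brightens narrow lumens, so callers measuring
#'   small airways may need to relax this guard.
#' @param max_center_iter,center_tol_mm centre refinement controls.
#' @return an `airway_measurement` (see [compute_metrics()]).
#' @export
measure_airway <- function(image, seed,
                           algorithm = c("standard_ibm", "modified_ibm", "fwhm"),
                           cfg = ibm_config(),
                           n_rays = 128L, step_mm = 0.1, max_len_mm = 15,
                           lumen_max_hu = -900,
                           max_center_iter = 5L, center_tol_mm = 0.1) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(image, "hu_image"), inherits(cfg, "ibm_config"))
  if (!point_in_image(image, seed)) stop("seed point lies outside the image")
  seed_hu <- interp_hu(image, seed[1], seed[2])$hu
  if (seed_hu > lumen_max_hu)
    stop(sprintf("seed point is not in a dark lumen region (%.0f HU > %.0f HU)",
                 seed_hu, lumen_max_hu))

  center <- as.numeric(seed)
  state <- NULL
  for (iter in seq_len(max_center_iter)) {
    if (!point_in_image(image, center))
      stop("centre refinement left the image")
    state <- detect_walls(image, center, algorithm, cfg, n_rays, step_mm,
                          max_len_mm)
    inner <- switch(algorithm,
      modified_ibm = complete_inner_modified(state$fits, state$profiles, center),
      complete_inner_standard(state$fits, center))
    new_center <- polygon_centroid(inner$points)
    moved <- sqrt(sum((new_center - center)^2))
    state$inner <- inner
    state$center <- center
    if (moved < center_tol_mm) break
    center <- new_center
  }

  outer <- complete_outer(state$fits, state$inner, state$center)
  m <- compute_metrics(state$inner, outer, state$fits, algorithm = algorithm,
                       center = polygon_centroid(state$inner$points),
                       td_mode = cfg$td_mode)
  m$wall_hu <- state$wall_hu
  m
}

# One pass of per-ray detection at a fixed centre: profiles, levels, wall
# attenuation (with optional refinement rounds), fits, validity.
detect_walls <- function(image, center, algorithm, cfg, n_rays, step_mm,
                         max_len_mm) {
  # keep every sample on the grid of pixel centres so that no ray is
  # border-tainted merely because the requested length brushes the edge
  sp <- image$spacing_mm
  xr <- image$origin[1] + c(0, (ncol(image$pixels) - 1) * sp)
  yr <- image$origin[2] + c(0, (nrow(image$pixels) - 1) * sp)
  reach <- min(center[1] - xr[1], xr[2] - center[1],
               center[2] - yr[1], yr[2] - center[2])
  max_len_mm <- min(max_len_mm, floor(reach / step_mm) * step_mm)
  profiles <- cast_profiles(image, center, n_rays = n_rays,
                            step_mm = step_mm, max_len_mm = max_len_mm)
  levels_list <- lapply(profiles, estimate_levels,
                        psf_sigma_mm = cfg$psf_sigma_mm)

  fit_all <- function(wall_hu) {
    lapply(seq_along(profiles), function(i) {
      ft <- if (algorithm == "fwhm") {
        fw <- fwhm_edges(profiles[[i]], levels_list[[i]])
        if (anyNA(fw)) invalid_fit(profiles[[i]]$index, "order_violation")
        else wall_fit(profiles[[i]]$index, inner = fw[["inner"]],
                      outer = fw[["outer"]],
                      inner_hu = stats::approx(profiles[[i]]$positions,
                                               profiles[[i]]$hu,
                                               xout = fw[["inner"]])$y,
                      valid = TRUE)
      } else {
        integral_fit(profiles[[i]], levels_list[[i]], cfg, wall_hu)
      }
      classify_validity(levels_list[[i]], ft, profiles[[i]], cfg)
    })
  }

  wall_hu <- if (algorithm == "fwhm") NA_real_ else auto_wall_hu(levels_list, cfg)
  fits <- fit_all(wall_hu)
  if (algorithm != "fwhm" && cfg$wall_hu_mode == "auto_refine") {
    for (round in seq_len(cfg$n_wall_refine)) {
      new_w <- refine_wall_hu(profiles, fits, levels_list, cfg, wall_hu)
      if (abs(new_w - wall_hu) < 1) break
      wall_hu <- new_w
      fits <- fit_all(wall_hu)
    }
  }
  fits <- drop_outlier_walls(fits)
  list(profiles = profiles, levels = levels_list, fits = fits,
       wall_hu = wall_hu)
}

# Second-pass validity: a ray grazing an adjacent vessel can fuse wall and
# vessel into one apparent wall (fitted thickness far above the airway's)
# or latch onto the vessel smear beyond the true wall (fitted thickness
# far below it, with the inner edge dragged outward). Such fits pass the
# plateau checks but are gross thickness outliers against the per-airway
# median; honest measurement noise stays well inside a factor of two, so
# rays outside it are invalidated.
drop_outlier_walls <- function(fits, factor = 2) {
  valid <- vapply(fits, function(f) isTRUE(f$valid), logical(1))
  if (sum(valid) < 5L) return(fits)
  wts <- vapply(fits[valid], function(f) f$outer_pos_mm - f$inner_pos_mm,
                numeric(1))
  med <- stats::median(wts)
  for (i in which(valid)) {
    wt_i <- fits[[i]]$outer_pos_mm - fits[[i]]$inner_pos_mm
    if (wt_i > factor * med || wt_i < med / factor)
      fits[[i]] <- invalid_fit(fits[[i]]$ray_index, "outlier_wall")
  }
  fits
}
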