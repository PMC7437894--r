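#' Configuration of the integral-based wall detector
#'
#' Tunable parameters of the per-ray edge detection. The defaults target
#' soft-kernel CT of airways in aerated lung: a PSF SD of 0.6 mm, a wall
#' prominence threshold that accepts parenchyma-backed walls but rejects
#' indistinct ones, and an outer-plateau ceiling of -500 HU that flags
#' rays running into soft tissue or vessels (enhanced or not).
#'
#' @param psf_sigma_mm assumed in-plane point-spread SD, mm (> 0 for
#'   integral fitting).
#' @param prominence_min_hu minimum rise of the wall peak above the outer
#'   plateau for a ray to count as a wall, HU. Default 50: even walls far
#'   thinner than the PSF retain over 100 HU of prominence in front of
#'   -850 HU parenchyma, the tallest noise excursion on a wall-free
#'   profile stays below 50 HU at typical noise levels, and rays whose
#'   outer plateau is soft tissue or vessel lose their prominence
#'   entirely. Setting the threshold well below the prominence of real
#'   thin walls also avoids noise-driven selection of rays, which would
#'   bias thin-wall statistics.
#' @param outer_max_hu maximum acceptable outer-plateau attenuation, HU;
#'   brighter outer plateaus mark an adjacent vessel/mediastinum ray.
#' @param wall_hu_mode how the (single, per-airway) wall attenuation used
#'   by the model is obtained. `"fixed"` (default, with
#'   `wall_hu_fixed = 0`) assumes a soft-tissue wall: for walls thinner
#'   than about two PSF SDs the image cannot separate wall density from
#'   wall thickness (the partial-volume degeneracy), so the model density
#'   is an assumption of the method rather than a measurement.
#'   `"auto_max_peak"` uses the tallest wall peak over eligible rays,
#'   which is accurate once the wall is thick enough to show a resolved
#'   plateau; `"auto_refine"` additionally re-estimates the density from
#'   the fitted edges, useful for partially resolved walls on clean data.
#' @param wall_hu_fixed wall attenuation used when `wall_hu_mode = "fixed"`,
#'   default 0 HU (soft tissue).
#' @param max_alternations maximum inner/outer alternation sweeps of the
#'   integral fit.
#' @param convergence_mm stop when both edges move less than this; the
#'   default (0.0002 mm) keeps the residual integral mismatch of the
#'   matched windows below ~0.5 HU mm.
#' @param model ideal airway model family along a ray: `"annular"`
#'   (default) uses the exact radial profile of a Gaussian-blurred set of
#'   concentric discs, which accounts for boundary curvature in small
#'   airways; `"planar"` uses the two-CDF blurred-step profile, adequate
#'   when radii are large against the PSF.
#' @param lumen_hu_mode `"fixed"` (default) takes the lumen attenuation as
#'   `lumen_hu_fixed` (air), which stays correct when blur brightens the
#'   centre of a narrow lumen; `"estimate"` uses the near-centre plateau
#'   estimate.
#' @param lumen_hu_fixed lumen attenuation for `lumen_hu_mode = "fixed"`.
#' @param n_wall_refine number of wall-density refinement rounds for
#'   `wall_hu_mode = "auto_refine"`.
#' @param td_mode how the total diameter is computed from the outer
#'   contour: `"antipodal"` (default) averages distances between opposite
#'   rays' outer points; `"equivalent_circle"` uses the diameter of the
#'   circle with the outer polygon's area.
#' @return an object of class `ibm_config`.
#' @export
ibm_config <- function(psf_sigma_mm = 0.6,
                       prominence_min_hu = 50,
                       outer_max_hu = -500,
                       wall_hu_mode = c("fixed", "auto_max_peak", "auto_refine"),
                       wall_hu_fixed = 0,
                       max_alternations = 12L,
                       convergence_mm = 2e-4,
                       model = c("annular", "planar"),
                       lumen_hu_mode = c("fixed", "estimate"),
                       lumen_hu_fixed = -1000,
                       n_wall_refine = 2L,
                       td_mode = c("antipodal", "equivalent_circle")) {
  wall_hu_mode <- match.arg(wall_hu_mode)
  model <- match.arg(model)
  lumen_hu_mode <- match.arg(lumen_hu_mode)
  td_mode <- match.arg(td_mode)
  if (!is.finite(psf_sigma_mm) || psf_sigma_mm <= 0)
    stop("`psf_sigma_mm` must be positive for integral fitting")
  if (wall_hu_mode == "fixed" && !is.finite(wall_hu_fixed))
    stop("`wall_hu_fixed` must be given when wall_hu_mode = 'fixed'")
  stopifnot(is.finite(prominence_min_hu), is.finite(outer_max_hu),
            is.finite(convergence_mm), convergence_mm > 0,
            max_alternations >= 1L, n_wall_refine >= 0L)
  structure(list(psf_sigma_mm = psf_sigma_mm,
                 prominence_min_hu = prominence_min_hu,
                 outer_max_hu = outer_max_hu,
                 wall_hu_mode = wall_hu_mode,
                 wall_hu_fixed = wall_hu_fixed,
                 max_alternations = as.integer(max_alternations),
                 convergence_mm = convergence_mm,
                 model = model,
                 lumen_hu_mode = lumen_hu_mode,
                 lumen_hu_fixed = lumen_hu_fixed,
                 n_wall_refine = as.integer(n_wall_refine),
                 td_mode = td_mode),
            class = "ibm_config")
}

#' Effective in-plane blur of a sampled CT slice
#'
#' The blur seen by a radial profile is wider than the scanner
#' point-spread function alone: rasterization averages the scene over the
#' pixel area (a box of width one pixel, variance spacing^2/12 per axis)
#' and bilinear resampling along the ray smooths over roughly one further
#' pixel (a tent kernel; its along-ray variance depends on the ray angle
#' and averages about spacing^2/8). Treating these as independent
#' Gaussian-equivalent contributions gives
#' `sqrt(psf_sigma^2 + spacing^2/12 + spacing^2/8)`, the value the
#' integral fit should use as its model sigma when measuring images with
#' non-negligible pixel spacing.
#'
#' @param psf_sigma_mm scanner/kernel PSF SD, mm.
#' @param spacing_mm pixel spacing, mm.
#' @return effective Gaussian SD in mm.
#' @export
effective_psf_sigma <- function(psf_sigma_mm, spacing_mm) {
  sqrt(psf_sigma_mm^2 + spacing_mm^2 / 12 + spacing_mm^2 / 8)
}

ibm_config_from_list <- function(vals) {
  if (is.null(vals)) return(ibm_config())
  known <- names(formals(ibm_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown ibm config keys: ", paste(bad, collapse = ", "))
  do.call(ibm_config, vals)
}

# ---------------------------------------------------------------------------
# Ideal airway model along a ray.
#
# The scene along a radial trajectory is a superposition of concentric
# discs: parenchyma + (wall - parenchyma) * disc(c_out) +
# (lumen - wall) * disc(c_in). After isotropic Gaussian blur the radial
# profile of a unit disc of radius R is exactly
#   B(r; R) = P(chisq_2(ncp = (r/sigma)^2) <= (R/sigma)^2),
# the noncentral chi-square CDF with 2 degrees of freedom. The planar
# variant replaces B(r; R) with 1 - Phi((r - R)/sigma), the blurred
# half-plane profile, which B converges to as R/sigma grows.

blurred_disc <- function(r, R, sigma) {
  if (R <= 0) return(numeric(length(r)))
  stats::pchisq((R / sigma)^2, df = 2, ncp = (r / sigma)^2)
}

# Lookup table for B(r; R) on a fixed sample grid r (positions), linear in
# R. Rebuilding the table is the expensive part, so it is cached per
# (sigma, step, length) in the package environment.
.lut_cache <- new.env(parent = emptyenv())

disc_lut <- function(positions, sigma, dR = 0.02) {
  key <- sprintf("%.6g|%.6g|%d|%.6g", sigma, positions[2] - positions[1],
                 length(positions), dR)
  hit <- .lut_cache[[key]]
  if (!is.null(hit)) return(hit)
  Rmax <- max(positions) + 1
  Rgrid <- seq(dR, Rmax, by = dR)
  ncp <- (positions / sigma)^2
  M <- vapply(Rgrid, function(R) stats::pchisq((R / sigma)^2, df = 2, ncp = ncp),
              numeric(length(positions)))
  lut <- list(M = M, dR = dR, Rmax = max(Rgrid), positions = positions)
  .lut_cache[[key]] <- lut
  lut
}

# B(positions[rows]; R) via the lookup table (linear interpolation in R).
disc_lut_eval <- function(lut, rows, R) {
  if (R <= 0) return(numeric(length(rows)))
  R <- min(R, lut$Rmax)
  j <- max(1L, min(floor(R / lut$dR), ncol(lut$M) - 1L))
  w <- R / lut$dR - j
  lut$M[rows, j] * (1 - w) + lut$M[rows, j + 1L] * w
}

# Model attenuation at the sample positions indexed by `rows`.
model_hu_at <- function(rows, c_in, c_out, pars) {
  if (pars$model == "planar") {
    r <- pars$positions[rows]
    pars$hu_l +
      (pars$W - pars$hu_l) * stats::pnorm((r - c_in) / pars$sigma) +
      (pars$hu_p - pars$W) * stats::pnorm((r - c_out) / pars$sigma)
  } else {
    Bi <- disc_lut_eval(pars$lut, rows, c_in)
    Bo <- disc_lut_eval(pars$lut, rows, c_out)
    pars$hu_p + (pars$W - pars$hu_p) * Bo + (pars$hu_l - pars$W) * Bi
  }
}

# Exact (non-LUT) model evaluation at arbitrary positions.
model_hu_exact <- function(r, c_in, c_out, sigma, hu_l, hu_p, W,
                           model = "annular") {
  if (model == "planar") {
    hu_l + (W - hu_l) * stats::pnorm((r - c_in) / sigma) +
      (hu_p - W) * stats::pnorm((r - c_out) / sigma)
  } else {
    hu_p + (W - hu_p) * blurred_disc(r, c_out, sigma) +
      (hu_l - W) * blurred_disc(r, c_in, sigma)
  }
}

trapz_uniform <- function(y, step) {
  n <- length(y)
  step * (sum(y) - (y[1] + y[n]) / 2)
}

# ---------------------------------------------------------------------------

#' Plateau and peak levels of a radial profile
#'
#' Locates the wall peak (tallest sample beyond `search_min_mm`; the
#' innermost sample wins ties) and estimates the lumen-side plateau (mean
#' of the near-centre samples) and the outer plateau (median of a 1.5 mm
#' window starting 3 PSF SDs beyond the peak). When the profile is too
#' short for the outer window, `hu_outer` is `NA` and the ray is later
#' classified invalid.
#'
#' @param profile a `ray_profile`.
#' @param search_min_mm minimum distance from the centre for the peak
#'   search, default 0.3 mm.
#' @param psf_sigma_mm PSF SD used to place the outer window, default 0.6.
#' @return an object of class `level_estimate` with fields `hu_lumen`,
#'   `hu_peak`, `peak_pos_mm`, `hu_outer`.
#' @export
estimate_levels <- function(profile, search_min_mm = 0.3, psf_sigma_mm = 0.6) {
  pos <- profile$positions
  hu <- profile$hu
  sel <- which(pos >= search_min_mm)
  if (length(sel) < 10L)
    stop("profile has fewer than 10 samples beyond search_min_mm")
  ipk <- sel[which.max(hu[sel])]
  hu_peak <- hu[ipk]
  peak_pos <- pos[ipk]
  lum_hi <- max(0.2 * peak_pos, 2 * profile$step_mm)
  hu_lumen <- mean(hu[pos <= lum_hi])
  w0 <- peak_pos + 3 * psf_sigma_mm
  osel <- pos >= w0 & pos <= w0 + 1.5
  # a clipped window with fewer than 5 samples is no plateau estimate
  hu_outer <- if (sum(osel) >= 5L) stats::median(hu[osel]) else NA_real_
  structure(list(hu_lumen = hu_lumen, hu_peak = hu_peak,
                 peak_pos_mm = peak_pos, hu_outer = hu_outer),
            class = "level_estimate")
}

#' Full-width-at-half-maximum edge positions
#'
#' Inner edge: first upward crossing of `(hu_lumen + hu_peak)/2` before
#' the peak; outer edge: first downward crossing of
#' `(hu_outer + hu_peak)/2` after the peak. Crossings are located by
#' linear interpolation between adjacent samples and reported in
#' continuous mm. A side with no crossing is `NA`.
#'
#' @param profile a `ray_profile`.
#' @param levels a `level_estimate` for that profile.
#' @return numeric `c(inner_mm, outer_mm)`, either possibly `NA`.
#' @export
fwhm_edges <- function(profile, levels) {
  pos <- profile$positions
  hu <- profile$hu
  ipk <- which.min(abs(pos - levels$peak_pos_mm))
  inner <- NA_real_
  if (ipk >= 2L) {
    h <- (levels$hu_lumen + levels$hu_peak) / 2
    k <- which(hu[seq_len(ipk - 1L)] < h & hu[2:ipk] >= h)
    if (length(k)) {
      k <- k[1]
      inner <- pos[k] + (h - hu[k]) / (hu[k + 1L] - hu[k]) * profile$step_mm
    }
  }
  outer <- NA_real_
  if (!is.na(levels$hu_outer) && ipk < length(pos)) {
    h <- (levels$hu_outer + levels$hu_peak) / 2
    kk <- ipk:(length(pos) - 1L)
    k <- kk[hu[kk] >= h & hu[kk + 1L] < h]
    if (length(k)) {
      k <- k[1]
      outer <- pos[k] + (hu[k] - h) / (hu[k] - hu[k + 1L]) * profile$step_mm
    }
  }
  c(inner = inner, outer = outer)
}

wall_fit <- function(ray_index, inner = NA_real_, outer = NA_real_,
                     inner_hu = NA_real_, valid = FALSE,
                     reason = "none", inner_resid = NA_real_,
                     outer_resid = NA_real_) {
  structure(list(ray_index = ray_index,
                 inner_pos_mm = inner, outer_pos_mm = outer,
                 inner_hu = inner_hu, valid = valid,
                 invalid_reason = reason,
                 inner_resid_hu_mm = inner_resid,
                 outer_resid_hu_mm = outer_resid),
            class = "wall_fit")
}

invalid_fit <- function(ray_index, reason) wall_fit(ray_index, reason = reason)

#' Integral-based edge fit on one profile
#'
#' Fits the ideal airway model along the ray so that the model's density
#' integral matches the measured profile's integral on windows around each
#' edge. Starting from the FWHM edges, the inner and outer edge are
#' alternately re-solved by monotone root finding: the inner edge on the
#' window from `c_in - 4 sigma` (clipped at 0) to the current mid-wall
#' position `(c_in + c_out)/2`, the outer edge from the mid-wall position
#' to `c_out + 4 sigma` (clipped at the profile end), each window integral
#' being trapezoidal on the sample grid. The mid-wall split is used rather
#' than the sampled peak position because the blurred peak of a sub-PSF
#' wall is nearly flat, making its argmax an unreliable divider between
#' the two edges. Iteration stops when both edges move less than
#' `cfg$convergence_mm` or after `cfg$max_alternations` sweeps.
#'
#' @param profile a `ray_profile`.
#' @param levels a `level_estimate` for that profile.
#' @param cfg an [ibm_config].
#' @param wall_hu wall attenuation used by the model (see
#'   [auto_wall_hu()]); must exceed both plateaus by at least 50 HU.
#' @return a `wall_fit`; invalid (with `invalid_reason = "order_violation"`)
#'   when the FWHM initialization is missing or a root bracket fails.
#' @export
integral_fit <- function(profile, levels, cfg, wall_hu) {
  idx <- profile$index
  if (is.na(levels$hu_outer)) return(invalid_fit(idx, "bright_outside"))
  hu_l <- if (cfg$lumen_hu_mode == "fixed") cfg$lumen_hu_fixed else levels$hu_lumen
  if (!is.finite(wall_hu) || wall_hu < max(hu_l, levels$hu_outer) + 50)
    return(invalid_fit(idx, "low_prominence"))
  init <- fwhm_edges(profile, levels)
  if (anyNA(init)) return(invalid_fit(idx, "order_violation"))

  pos <- profile$positions
  hu <- profile$hu
  step <- profile$step_mm
  sigma <- cfg$psf_sigma_mm
  pk <- levels$peak_pos_mm
  pars <- list(model = cfg$model, sigma = sigma, hu_l = hu_l,
               hu_p = levels$hu_outer, W = wall_hu, positions = pos,
               lut = if (cfg$model == "annular") disc_lut(pos, sigma) else NULL)

  solve_edge <- function(rows, bracket, other, side) {
    target <- trapz_uniform(hu[rows], step)
    g <- function(cc) {
      m <- if (side == "inner") model_hu_at(rows, cc, other, pars)
      else model_hu_at(rows, other, cc, pars)
      trapz_uniform(m, step) - target
    }
    glo <- g(bracket[1]); ghi <- g(bracket[2])
    if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) return(NA_real_)
    stats::uniroot(g, bracket, f.lower = glo, f.upper = ghi,
                   tol = 1e-5)$root
  }

  c_in <- init[["inner"]]; c_out <- init[["outer"]]
  if (!(c_in < c_out)) return(invalid_fit(idx, "order_violation"))
  ok <- TRUE
  mid <- (c_in + c_out) / 2
  for (it in seq_len(cfg$max_alternations)) {
    mid <- (c_in + c_out) / 2
    lo <- max(0, c_in - 4 * sigma)
    rows_in <- which(pos >= lo - 1e-9 & pos <= mid + 1e-9)
    if (length(rows_in) < 3L) { ok <- FALSE; break }
    # the bracket runs to just short of the opposite edge: with a poor
    # initialization the root can lie beyond the window split
    new_in <- solve_edge(rows_in, c(max(step / 2, lo), c_out - step / 2),
                         c_out, "inner")
    if (is.na(new_in)) { ok <- FALSE; break }
    hi <- min(max(pos), c_out + 4 * sigma)
    rows_out <- which(pos >= mid - 1e-9 & pos <= hi + 1e-9)
    if (length(rows_out) < 3L) { ok <- FALSE; break }
    new_out <- solve_edge(rows_out, c(new_in + step / 2, hi), new_in, "outer")
    if (is.na(new_out)) { ok <- FALSE; break }
    moved <- max(abs(new_in - c_in), abs(new_out - c_out))
    c_in <- new_in; c_out <- new_out
    if (moved < cfg$convergence_mm) break
  }
  if (!ok || !(c_in > 0 && c_in < c_out))
    return(invalid_fit(idx, "order_violation"))

  # residual integral mismatch on the final windows (diagnostic; ~0 at
  # convergence by construction)
  mid <- (c_in + c_out) / 2
  rows_in <- which(pos >= max(0, c_in - 4 * sigma) - 1e-9 & pos <= mid + 1e-9)
  rows_out <- which(pos >= mid - 1e-9 &
                    pos <= min(max(pos), c_out + 4 * sigma) + 1e-9)
  rin <- trapz_uniform(model_hu_at(rows_in, c_in, c_out, pars), step) -
    trapz_uniform(hu[rows_in], step)
  rout <- trapz_uniform(model_hu_at(rows_out, c_in, c_out, pars), step) -
    trapz_uniform(hu[rows_out], step)
  inner_hu <- stats::approx(pos, hu, xout = c_in)$y
  wall_fit(idx, inner = c_in, outer = c_out, inner_hu = inner_hu,
           valid = TRUE, inner_resid = rin, outer_resid = rout)
}

#' Classify per-ray validity
#'
#' Marks a fit invalid with a reason: `border_taint` if the profile left
#' the image; `bright_outside` if the outer plateau is missing or brighter
#' than `cfg$outer_max_hu` (an adjacent vessel or mediastinum, with or
#' without contrast); `low_prominence` if the wall peak rises less than
#' `cfg$prominence_min_hu` above the outer plateau (the near-centre lumen
#' estimate is deliberately not used here: blur brightens the centre of
#' narrow lumens, which would mask genuinely detectable thin walls, while
#' an indistinct wall is already fully characterized by its contrast
#' against the tissue outside it); otherwise the fit's
#' own state (including `order_violation`) passes through. Invalid fits
#' carry no edge positions.
#'
#' @param levels a `level_estimate`.
#' @param fit_attempt a `wall_fit` from [integral_fit()] or FWHM.
#' @param profile the `ray_profile`.
#' @param cfg an [ibm_config].
#' @return a `wall_fit`.
#' @export
classify_validity <- function(levels, fit_attempt, profile, cfg) {
  reason <- NULL
  if (isTRUE(profile$tainted)) {
    reason <- "border_taint"
  } else if (is.na(levels$hu_outer) || levels$hu_outer > cfg$outer_max_hu) {
    reason <- "bright_outside"
  } else if (levels$hu_peak - levels$hu_outer < cfg$prominence_min_hu) {
    reason <- "low_prominence"
  }
  if (is.null(reason)) return(fit_attempt)
  invalid_fit(fit_attempt$ray_index, reason)
}

#' Wall attenuation for the airway model
#'
#' In `auto_max_peak` mode returns the tallest wall peak over all rays not
#' flagged `bright_outside`, clamped to [-300, 200] HU (the tallest peak
#' is the least partial-volume-depressed sample of the wall density); in
#' `fixed` mode returns `cfg$wall_hu_fixed`. At least one eligible ray
#' must clear the prominence threshold.
#'
#' @param levels_list list of `level_estimate`, one per ray.
#' @param cfg an [ibm_config].
#' @return wall attenuation in HU.
#' @export
auto_wall_hu <- function(levels_list, cfg) {
  if (cfg$wall_hu_mode == "fixed") return(cfg$wall_hu_fixed)
  eligible <- vapply(levels_list, function(lv)
    !is.na(lv$hu_outer) && lv$hu_outer <= cfg$outer_max_hu, logical(1))
  prom <- vapply(levels_list, function(lv) {
    if (is.na(lv$hu_outer)) return(-Inf)
    lv$hu_peak - lv$hu_outer
  }, numeric(1))
  if (!any(eligible & prom >= cfg$prominence_min_hu))
    stop("no wall signal: no eligible ray clears the prominence threshold")
  pk <- max(vapply(levels_list[eligible], function(lv) lv$hu_peak, numeric(1)))
  min(max(pk, -300), 200)
}

# Re-estimate the wall attenuation from fitted edges: the model is linear
# in W, so the observed attenuation at the wall midpoint determines W per
# ray; the median over valid rays is clamped like auto_max_peak. This
# corrects the partial-volume depression of the observed peak for walls
# thinner than the PSF.
refine_wall_hu <- function(profiles, fits, levels_list, cfg, wall_hu) {
  sigma <- cfg$psf_sigma_mm
  est <- vapply(seq_along(fits), function(i) {
    ft <- fits[[i]]
    if (!isTRUE(ft$valid)) return(NA_real_)
    lv <- levels_list[[i]]
    hu_l <- if (cfg$lumen_hu_mode == "fixed") cfg$lumen_hu_fixed else lv$hu_lumen
    r_mid <- (ft$inner_pos_mm + ft$outer_pos_mm) / 2
    f_obs <- stats::approx(profiles[[i]]$positions, profiles[[i]]$hu,
                           xout = r_mid)$y
    f_mod <- model_hu_exact(r_mid, ft$inner_pos_mm, ft$outer_pos_mm, sigma,
                            hu_l, lv$hu_outer, wall_hu, cfg$model)
    dW <- if (cfg$model == "planar") {
      stats::pnorm((r_mid - ft$inner_pos_mm) / sigma) -
        stats::pnorm((r_mid - ft$outer_pos_mm) / sigma)
    } else {
      blurred_disc(r_mid, ft$outer_pos_mm, sigma) -
        blurred_disc(r_mid, ft$inner_pos_mm, sigma)
    }
    if (!is.finite(dW) || dW < 0.05) return(NA_real_)
    wall_hu + (f_obs - f_mod) / dW
  }, numeric(1))
  est <- est[is.finite(est)]
  if (!length(est)) return(wall_hu)
  min(max(stats::median(est), -300), 200)
}
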