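# Contour completion and airway metrics.
#
# Valid rays contribute their measured edge points directly; rays where
# wall detection failed (typically along the contact arc with an adjacent
# vessel) get their inner point completed either by a least-squares
# ellipse through the measured points (standard method) or by the
# median-HU threshold rule (modified method). Outer points on failed rays
# are offset from the inner contour by the median measured wall
# thickness.

airway_contour <- function(points, radius, source) {
  structure(list(points = points, radius = radius, source = source),
            class = "airway_contour")
}

ray_angles <- function(n_rays) 2 * pi * (seq_len(n_rays) - 1L) / n_rays

# Direct least-squares ellipse fit (algebraic conic fit constrained to an
# ellipse), solved via the partitioned eigenproblem; coordinates are
# centred for conditioning. Returns the conic coefficients
# (A, B, C, D, E, F) in the centred frame plus the frame offset.
fit_ellipse <- function(x, y) {
  if (length(x) < 5L) stop("insufficient wall points: ellipse fitting needs >= 5")
  mx <- mean(x); my <- mean(y)
  X <- x - mx; Y <- y - my
  D1 <- cbind(X^2, X * Y, Y^2)
  D2 <- cbind(X, Y, rep(1, length(X)))
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  e <- eigen(M)
  vecs <- Re(e$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  pick <- which(cond > 1e-12)
  if (!length(pick)) stop("degenerate point set: no ellipse solution")
  a1 <- vecs[, pick[1]]
  coef <- c(a1, as.numeric(Tm %*% a1))
  names(coef) <- c("A", "B", "C", "D", "E", "F")
  structure(list(coef = coef, offset = c(mx, my)), class = "fitted_ellipse")
}

# Distance along the ray (origin o, unit direction u) to the fitted
# ellipse: nearer positive intersection, or the along-ray closest approach
# when the ray misses (flagged by attribute "missed").
ellipse_ray_radius <- function(ell, origin, direction) {
  p0 <- origin - ell$offset
  co <- ell$coef
  ux <- direction[1]; uy <- direction[2]
  x0 <- p0[1]; y0 <- p0[2]
  a2 <- co["A"] * ux^2 + co["B"] * ux * uy + co["C"] * uy^2
  b2 <- 2 * co["A"] * x0 * ux + co["B"] * (x0 * uy + y0 * ux) +
    2 * co["C"] * y0 * uy + co["D"] * ux + co["E"] * uy
  c2 <- co["A"] * x0^2 + co["B"] * x0 * y0 + co["C"] * y0^2 +
    co["D"] * x0 + co["E"] * y0 + co["F"]
  disc <- b2^2 - 4 * a2 * c2
  missed <- FALSE
  if (disc >= 0 && abs(a2) > 1e-12) {
    roots <- (-b2 + c(-1, 1) * sqrt(disc)) / (2 * a2)
    pos <- roots[roots > 0]
    t <- if (length(pos)) min(pos) else { missed <- TRUE; -b2 / (2 * a2) }
  } else {
    missed <- TRUE
    t <- if (abs(a2) > 1e-12) -b2 / (2 * a2) else NA_real_
  }
  if (!is.finite(t) || t <= 0) { missed <- TRUE; t <- abs(t) }
  structure(unname(t), missed = missed)
}

#' Complete the inner contour with an ellipse (standard method)
#'
#' Fits a least-squares ellipse through the inner wall points of all
#' valid rays and replaces each invalid ray's inner point by the
#' intersection of that ray with the ellipse (the nearer intersection in
#' the ray direction). Valid rays keep their measured points.
#'
#' @param fits list of `wall_fit`, one per ray, in ray order.
#' @param center ray origin (mm).
#' @return an `airway_contour` with per-point `source` of `"measured"` or
#'   `"ellipse_completed"`.
#' @export
complete_inner_standard <- function(fits, center) {
  n <- length(fits)
  ang <- ray_angles(n)
  valid <- vapply(fits, function(f) isTRUE(f$valid), logical(1))
  if (sum(valid) < 5L)
    stop("insufficient wall points: need >= 5 valid rays for ellipse completion")
  r_meas <- vapply(fits, function(f) f$inner_pos_mm %||% NA_real_, numeric(1))
  xs <- center[1] + r_meas[valid] * cos(ang[valid])
  ys <- center[2] + r_meas[valid] * sin(ang[valid])
  ell <- fit_ellipse(xs, ys)
  radius <- r_meas
  source <- ifelse(valid, "measured", "ellipse_completed")
  for (i in which(!valid)) {
    t <- ellipse_ray_radius(ell, center, c(cos(ang[i]), sin(ang[i])))
    radius[i] <- as.numeric(t)
    if (isTRUE(attr(t, "missed"))) source[i] <- "ellipse_completed_flagged"
  }
  pts <- cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang))
  airway_contour(pts, radius, source)
}

#' Complete the inner contour by the median-HU rule (modified method)
#'
#' Determines the median attenuation of all detectable inner wall points
#' (profile value at the fitted inner edge of each valid ray) and, on
#' rays where detection failed, places the inner point at the first
#' position — scanning outward from the lumen centre, with linear
#' interpolation between samples — where the profile reaches that median
#' attenuation. A ray that never reaches the threshold falls back to
#' ellipse completion (when at least 5 valid points exist) and is
#' flagged.
#'
#' @param fits list of `wall_fit`, one per ray, in ray order.
#' @param profiles list of `ray_profile` matching `fits`.
#' @param center ray origin (mm).
#' @return an `airway_contour` with per-point `source` of `"measured"`,
#'   `"medianhu_completed"` or `"ellipse_completed_fallback"`.
#' @export
complete_inner_modified <- function(fits, profiles, center) {
  n <- length(fits)
  ang <- ray_angles(n)
  valid <- vapply(fits, function(f) isTRUE(f$valid), logical(1))
  if (!any(valid))
    stop("no valid wall points: cannot derive the median inner attenuation")
  thr <- stats::median(vapply(fits[valid], function(f) f$inner_hu, numeric(1)))
  radius <- vapply(fits, function(f) f$inner_pos_mm %||% NA_real_, numeric(1))
  source <- ifelse(valid, "measured", "medianhu_completed")
  fallback <- integer(0)
  for (i in which(!valid)) {
    p <- profiles[[i]]
    hu <- p$hu
    r <- NA_real_
    if (hu[1] >= thr) {
      r <- 0
    } else {
      k <- which(hu[-1] >= thr & hu[-length(hu)] < thr)
      if (length(k)) {
        k <- k[1]
        r <- p$positions[k] +
          (thr - hu[k]) / (hu[k + 1L] - hu[k]) * p$step_mm
      }
    }
    if (is.na(r)) fallback <- c(fallback, i) else radius[i] <- r
  }
  if (length(fallback)) {
    if (sum(valid) < 5L)
      stop("rays never reach the median attenuation and too few valid points ",
           "remain for ellipse fallback")
    ell_contour <- complete_inner_standard(fits, center)
    radius[fallback] <- ell_contour$radius[fallback]
    source[fallback] <- "ellipse_completed_fallback"
  }
  pts <- cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang))
  airway_contour(pts, radius, source)
}

#' Complete the outer contour
#'
#' Valid rays use their measured outer edge; on invalid rays the outer
#' point is offset outward from the (completed) inner point by the median
#' measured wall thickness.
#'
#' @param fits list of `wall_fit`, one per ray, in ray order.
#' @param inner completed inner `airway_contour`.
#' @param center ray origin (mm).
#' @return an `airway_contour` with per-point `source` of `"measured"` or
#'   `"offset_completed"`.
#' @export
complete_outer <- function(fits, inner, center) {
  n <- length(fits)
  ang <- ray_angles(n)
  valid <- vapply(fits, function(f) isTRUE(f$valid), logical(1))
  if (!any(valid)) stop("no valid wall points: cannot complete the outer contour")
  wt_med <- stats::median(vapply(fits[valid], function(f)
    f$outer_pos_mm - f$inner_pos_mm, numeric(1)))
  radius <- ifelse(valid,
                   vapply(fits, function(f) f$outer_pos_mm %||% NA_real_,
                          numeric(1)),
                   inner$radius + wt_med)
  source <- ifelse(valid, "measured", "offset_completed")
  pts <- cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang))
  airway_contour(pts, radius, source)
}

polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

polygon_centroid <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(colMeans(pts))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Airway metrics from completed contours
#'
#' Computes the four airway metrics: lumen area LA as the shoelace area of
#' the inner polygon; wall area WA as the outer polygon area minus LA;
#' total diameter TD as the mean distance between the outer points of
#' antipodal ray pairs (or the equivalent-circle diameter of the outer
#' polygon when `td_mode = "equivalent_circle"`); and wall thickness WT as
#' the median of the per-ray edge separations over valid rays only —
#' completed rays shape the contours and areas but never WT.
#'
#' @param inner,outer completed `airway_contour`s with one point per ray.
#' @param fits list of `wall_fit` matching the contours.
#' @param algorithm label stored in the result.
#' @param center ray origin (mm), stored in the result.
#' @param td_mode `"antipodal"` or `"equivalent_circle"`.
#' @return an object of class `airway_measurement` with fields `TD_mm`,
#'   `LA_mm2`, `WA_mm2`, `WT_mm`, `algorithm`, `n_valid_rays`, `center_mm`
#'   and `flags`.
#' @export
compute_metrics <- function(inner, outer, fits, algorithm = "standard_ibm",
                            center = c(NA_real_, NA_real_),
                            td_mode = "antipodal") {
  n <- nrow(inner$points)
  if (n %% 2L != 0L || nrow(outer$points) != n)
    stop("contours must have the same even number of points")
  la <- polygon_area(inner$points)
  oa <- polygon_area(outer$points)
  wa <- oa - la
  if (wa < 0) stop("outer inside inner: contour inversion")
  td <- if (td_mode == "equivalent_circle") {
    2 * sqrt(oa / pi)
  } else {
    half <- n %/% 2L
    mean(sqrt(rowSums((outer$points[seq_len(half), , drop = FALSE] -
                       outer$points[half + seq_len(half), , drop = FALSE])^2)))
  }
  valid <- vapply(fits, function(f) isTRUE(f$valid), logical(1))
  wt <- stats::median(vapply(fits[valid], function(f)
    f$outer_pos_mm - f$inner_pos_mm, numeric(1)))
  flags <- character(0)
  if (any(grepl("flagged|fallback", c(inner$source, outer$source))))
    flags <- c(flags, "completion_fallback")
  structure(list(TD_mm = td, LA_mm2 = la, WA_mm2 = wa, WT_mm = wt,
                 algorithm = algorithm, n_valid_rays = sum(valid),
                 center_mm = center, flags = flags),
            class = "airway_measurement")
}

#' @export
print.airway_measurement <- function(x, ...) {
  cat(sprintf(
    "<airway_measurement> [%s] TD %.3f mm | LA %.3f mm^2 | WA %.3f mm^2 | WT %.3f mm (%d rays valid)\n",
    x$algorithm, x$TD_mm, x$LA_mm2, x$WA_mm2, x$WT_mm, x$n_valid_rays))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
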