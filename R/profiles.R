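#' Cast radial density profiles from a lumen centre
#'
#' Samples the slice along `n_rays` equally spaced directions radiating
#' from `center`, at uniform steps from 0 to `max_len_mm`, by bilinear
#' interpolation. Ray i points at angle `2 * pi * i / n_rays`, so ray i and
#' ray i + n_rays/2 are antiparallel. Samples falling outside the image are
#' clamped to the edge value and the profile is flagged `tainted`.
#'
#' @param image an [hu_image].
#' @param center ray origin, c(x, y) in mm; must lie inside the image.
#' @param n_rays number of rays, even and >= 8; default 128.
#' @param step_mm sample step along each ray, default 0.1 mm; must not
#'   exceed the pixel spacing.
#' @param max_len_mm profile length, default 15 mm.
#' @return list of `ray_profile` objects with fields `index` (0-based),
#'   `angle_rad`, `step_mm`, `positions`, `hu`, `tainted`.
#' @export
cast_profiles <- function(image, center, n_rays = 128L, step_mm = 0.1,
                          max_len_mm = 15) {
  n_rays <- as.integer(n_rays)
  if (n_rays < 8L || n_rays %% 2L != 0L)
    stop("`n_rays` must be even and >= 8")
  if (step_mm <= 0 || step_mm > image$spacing_mm)
    stop("`step_mm` must be positive and <= the pixel spacing")
  if (!point_in_image(image, center))
    stop("profile centre lies outside the image")
  t <- seq(0, max_len_mm, by = step_mm)
  angles <- 2 * pi * (seq_len(n_rays) - 1L) / n_rays
  q <- interp_hu(image,
                 center[1] + as.vector(outer(t, cos(angles))),
                 center[2] + as.vector(outer(t, sin(angles))))
  hu <- matrix(q$hu, nrow = length(t))
  cl <- matrix(q$clamped, nrow = length(t))
  lapply(seq_len(n_rays), function(i) {
    structure(list(index = i - 1L,
                   angle_rad = angles[i],
                   step_mm = step_mm,
                   positions = t,
                   hu = hu[, i],
                   tainted = any(cl[, i])),
              class = "ray_profile")
  })
}

#' Dump profiles to CSV for debugging
#'
#' @param profiles list of `ray_profile` as returned by [cast_profiles()].
#' @param path output CSV path (columns ray, angle_rad, position_mm, hu).
#' @return the path, invisibly.
#' @export
profiles_to_csv <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(ray = p$index, angle_rad = p$angle_rad,
               position_mm = p$positions, hu = p$hu)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
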