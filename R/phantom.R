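#' Synthetic airway phantom specification
#'
#' Describes a 2D CT scene: an annular airway wall (soft-tissue HU)
#' embedded in lung parenchyma, an air-filled lumen, and optionally an
#' adjacent vessel disc whose attenuation mimics a contrast-enhancement
#' phase. Rendering is a pure function of the spec (same seed gives a
#' bit-identical image).
#'
#' @param lumen_radius_mm inner (lumen) radius, mm, > 0.
#' @param wall_thickness_mm wall thickness, mm, > 0.
#' @param airway_center_mm physical centre of the airway, c(x, y) mm;
#'   default `NULL` places it at the image centre.
#' @param hu_lumen lumen attenuation, default -1000 (air).
#' @param hu_wall wall attenuation, default 0 (soft tissue).
#' @param hu_parenchyma background lung attenuation, default -850.
#' @param vessel_radius_mm adjacent vessel radius, mm; 0 (default) means no
#'   vessel.
#' @param vessel_hu vessel attenuation, default 32 (non-enhanced blood);
#'   see [phase_preset()] for contrast-phase values.
#' @param vessel_gap_mm signed gap between the airway outer border and the
#'   vessel border; values <= 0 are clipped to tangency (contact), the
#'   configuration in which vessel smear biases wall detection.
#' @param vessel_angle_deg direction of the vessel centre from the airway
#'   centre, degrees.
#' @param psf_sigma_mm isotropic Gaussian blur SD modelling a soft
#'   reconstruction kernel, default 0.6 mm.
#' @param noise_sd_hu additive white Gaussian noise SD in HU, default 0.
#' @param image_size_mm physical edge length of the square image, default 30.
#' @param spacing_mm pixel spacing, default 0.5 mm.
#' @param seed integer seed for the noise draw.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(lumen_radius_mm, wall_thickness_mm,
                         airway_center_mm = NULL,
                         hu_lumen = -1000, hu_wall = 0, hu_parenchyma = -850,
                         vessel_radius_mm = 0, vessel_hu = 32,
                         vessel_gap_mm = 0, vessel_angle_deg = 0,
                         psf_sigma_mm = 0.6, noise_sd_hu = 0,
                         image_size_mm = 30, spacing_mm = 0.5, seed = 1L) {
  num1 <- function(v, name, lo = -Inf) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < lo)
      stop("`", name, "` must be a single finite number >= ", lo)
    as.numeric(v)
  }
  spec <- list(
    lumen_radius_mm = num1(lumen_radius_mm, "lumen_radius_mm"),
    wall_thickness_mm = num1(wall_thickness_mm, "wall_thickness_mm"),
    hu_lumen = num1(hu_lumen, "hu_lumen"),
    hu_wall = num1(hu_wall, "hu_wall"),
    hu_parenchyma = num1(hu_parenchyma, "hu_parenchyma"),
    vessel_radius_mm = num1(vessel_radius_mm, "vessel_radius_mm", lo = 0),
    vessel_hu = num1(vessel_hu, "vessel_hu"),
    vessel_gap_mm = num1(vessel_gap_mm, "vessel_gap_mm"),
    vessel_angle_deg = num1(vessel_angle_deg, "vessel_angle_deg"),
    psf_sigma_mm = num1(psf_sigma_mm, "psf_sigma_mm", lo = 0),
    noise_sd_hu = num1(noise_sd_hu, "noise_sd_hu", lo = 0),
    image_size_mm = num1(image_size_mm, "image_size_mm"),
    spacing_mm = num1(spacing_mm, "spacing_mm"),
    seed = as.integer(seed))
  if (spec$lumen_radius_mm <= 0 || spec$wall_thickness_mm <= 0)
    stop("lumen radius and wall thickness must be positive")
  if (spec$spacing_mm <= 0 || spec$image_size_mm <= 0)
    stop("image size and spacing must be positive")
  n <- round(spec$image_size_mm / spec$spacing_mm)
  if (n < 4) stop("image too small for the given spacing")
  if (is.null(airway_center_mm))
    airway_center_mm <- rep((n - 1) / 2 * spec$spacing_mm, 2)
  spec$airway_center_mm <- as.numeric(airway_center_mm)
  r_out <- spec$lumen_radius_mm + spec$wall_thickness_mm
  if (r_out >= spec$image_size_mm / 2 - 3 * spec$psf_sigma_mm)
    stop("airway too large for the image: lumen_radius + wall_thickness must be ",
         "< image half-width - 3 * psf_sigma")
  structure(spec, class = "phantom_spec")
}

# Vessel centre implied by the spec; gap <= 0 is clipped to tangency.
vessel_center <- function(spec) {
  r_out <- spec$lumen_radius_mm + spec$wall_thickness_mm
  d <- r_out + spec$vessel_radius_mm + max(spec$vessel_gap_mm, 0)
  a <- spec$vessel_angle_deg * pi / 180
  spec$airway_center_mm + d * c(cos(a), sin(a))
}

#' Analytic ground truth of a phantom
#'
#' Closed-form airway metrics of the continuous scene: total diameter
#' TD = 2 (r + WT), lumen area LA = pi r^2, wall area
#' WA = pi ((r + WT)^2 - r^2), and wall thickness WT.
#'
#' @param spec a [phantom_spec].
#' @return an object of class `airway_truth` with fields `TD_mm`, `LA_mm2`,
#'   `WA_mm2`, `WT_mm`.
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  r <- spec$lumen_radius_mm
  wt <- spec$wall_thickness_mm
  structure(list(TD_mm = 2 * (r + wt),
                 LA_mm2 = pi * r^2,
                 WA_mm2 = pi * ((r + wt)^2 - r^2),
                 WT_mm = wt),
            class = "airway_truth")
}

#' Vessel attenuation preset for a contrast phase
#'
#' Returns the attenuation (HU) used for the adjacent vessel in each
#' contrast-enhancement phase: non-enhanced blood (NE) 32 HU,
#' pulmonary-arterial peak (PA) 725 HU, systemic-arterial peak (SA)
#' 503 HU, and the pooled venous level (VE) 96 HU.
#'
#' @param phase one of `"NE"`, `"PA"`, `"SA"`, `"VE"`.
#' @return vessel attenuation in HU.
#' @export
phase_preset <- function(phase) {
  presets <- c(NE = 32, PA = 725, SA = 503, VE = 96)
  if (!is.character(phase) || length(phase) != 1L || !phase %in% names(presets))
    stop("unknown contrast phase: ", paste(phase, collapse = ","),
         " (expected NE, PA, SA or VE)")
  unname(presets[phase])
}

# 1D Gaussian convolution matrix with reflective padding, kernel truncated
# at 4 sd. sigma in units of grid cells.
gauss_conv_matrix <- function(n, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  off <- -half:half
  kern <- exp(-off^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  K <- matrix(0, n, n)
  for (j in seq_along(off)) {
    idx <- seq_len(n) + off[j]
    idx[idx < 1L] <- 2L - idx[idx < 1L]
    idx[idx > n] <- 2L * n - idx[idx > n]
    cells <- cbind(seq_len(n), idx)
    K[cells] <- K[cells] + kern[j]
  }
  K
}

#' Render a phantom to an HU slice
#'
#' Rasterizes the continuous scene (parenchyma background, vessel disc,
#' airway annulus painted over it, air lumen on top) by k x k
#' supersampling per pixel, convolves with an isotropic Gaussian point
#' spread function of SD `psf_sigma_mm` (truncated at 4 sd, reflective
#' padding), block-averages back to the pixel grid, and finally adds
#' i.i.d. Gaussian noise drawn from the spec's seed. The caller's RNG
#' state is left untouched.
#'
#' @param spec a [phantom_spec].
#' @param supersample supersampling factor per pixel edge, default 8.
#' @return an [hu_image].
#' @export
render_phantom <- function(spec, supersample = 8L) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing_mm
  n <- round(spec$image_size_mm / sp)
  k <- as.integer(supersample)
  nk <- n * k
  fs <- sp / k
  # fine-cell centres tiling the pixel areas; pixel (1,1) centre at (0,0)
  f <- -sp / 2 + (seq_len(nk) - 0.5) * fs
  ac <- spec$airway_center_mm
  r_in <- spec$lumen_radius_mm
  r_out <- r_in + spec$wall_thickness_mm

  A <- matrix(spec$hu_parenchyma, nk, nk)
  if (spec$vessel_radius_mm > 0) {
    vc <- vessel_center(spec)
    if (sqrt(sum((vc - ac)^2)) < r_in + spec$vessel_radius_mm - 1e-9)
      stop("vessel overlaps the airway lumen: geometrically meaningless scene")
    dv2 <- outer((f - vc[2])^2, (f - vc[1])^2, `+`)
    A[dv2 <= spec$vessel_radius_mm^2] <- spec$vessel_hu
  }
  da2 <- outer((f - ac[2])^2, (f - ac[1])^2, `+`)
  A[da2 <= r_out^2] <- spec$hu_wall
  A[da2 <= r_in^2] <- spec$hu_lumen

  if (spec$psf_sigma_mm > 0) {
    K <- gauss_conv_matrix(nk, spec$psf_sigma_mm / fs)
    A <- K %*% A %*% t(K)
  }
  # block-average k x k fine cells into each pixel
  P <- matrix(0, n, nk)
  P[cbind(rep(seq_len(n), each = k), seq_len(nk))] <- 1 / k
  pixels <- P %*% A %*% t(P)

  if (spec$noise_sd_hu > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(spec$seed)
    pixels <- pixels + matrix(stats::rnorm(n * n, 0, spec$noise_sd_hu), n, n)
  }
  hu_image(pixels, spacing_mm = sp)
}

#' Read a phantom specification from YAML
#'
#' @param path YAML file whose top-level keys are [phantom_spec()] argument
#'   names (unknown keys are rejected).
#' @return a `phantom_spec`.
#' @export
read_phantom_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  phantom_spec_from_list(vals)
}

phantom_spec_from_list <- function(vals) {
  if (!is.list(vals)) stop("phantom config must be a mapping of parameters")
  known <- names(formals(phantom_spec))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown phantom config keys: ", paste(bad, collapse = ", "))
  do.call(phantom_spec, vals)
}

#' Write a rendered phantom and its ground truth
#'
#' Renders the spec, writes the slice as NIfTI and the analytic truth as a
#' JSON side-car (`<prefix>.nii.gz`, `<prefix>_truth.json`).
#'
#' @param spec a [phantom_spec].
#' @param prefix output path prefix.
#' @return named character vector of the two paths written, invisibly.
#' @export
write_phantom <- function(spec, prefix) {
  img <- render_phantom(spec)
  truth <- ground_truth(spec)
  nii <- paste0(prefix, ".nii.gz")
  js <- paste0(prefix, "_truth.json")
  write_slice(img, nii)
  jsonlite::write_json(c(unclass(truth),
                         list(airway_center_mm = spec$airway_center_mm,
                              spacing_mm = spec$spacing_mm)),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(image = nii, truth = js))
}
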