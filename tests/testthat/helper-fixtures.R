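# Fixtures built in code: analytic radial profiles, tiny DICOM files and
# convenience wrappers shared across the test files.

# Radial profile sampled exactly from the ideal airway model (no image, no
# interpolation): the independent oracle for the edge-fitting tests.
model_profile <- function(c_in, c_out, sigma, hu_l = -1000, hu_p = -850,
                          W = 0, step = 0.1, max_len = 15,
                          model = "planar") {
  pos <- seq(0, max_len, by = step)
  hu <- bronchoquant:::model_hu_exact(pos, c_in, c_out, sigma, hu_l, hu_p, W,
                                      model = model)
  structure(list(index = 0L, angle_rad = 0, step_mm = step,
                 positions = pos, hu = hu, tainted = FALSE),
            class = "ray_profile")
}

# Constant-attenuation image.
flat_image <- function(hu = -1000, n = 40L, spacing = 0.5) {
  hu_image(matrix(hu, n, n), spacing_mm = spacing)
}

# Minimal explicit-little-endian single-frame DICOM writer (test fixture
# generator; the package reader is verified against these bytes).
write_test_dicom <- function(path, stored, spacing = c(0.5, 0.5),
                             slope = 1, intercept = -1024) {
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  pad_even <- function(s, pad) {
    r <- charToRaw(s)
    if (length(r) %% 2L == 1L) r <- c(r, as.raw(pad))
    r
  }
  short_elem <- function(group, elem, vr, value_raw) {
    c(u16(group), u16(elem), charToRaw(vr), u16(length(value_raw)), value_raw)
  }
  long_elem <- function(group, elem, vr, value_raw) {
    c(u16(group), u16(elem), charToRaw(vr), as.raw(c(0, 0)),
      u32(length(value_raw)), value_raw)
  }
  ts <- pad_even("1.2.840.10008.1.2.1", 0)
  px <- writeBin(as.integer(t(stored)), raw(), size = 2L, endian = "little")
  body <- c(
    short_elem(0x0002, 0x0010, "UI", ts),
    short_elem(0x0028, 0x0010, "US", u16(nrow(stored))),
    short_elem(0x0028, 0x0011, "US", u16(ncol(stored))),
    short_elem(0x0028, 0x0030, "DS",
               pad_even(paste(spacing, collapse = "\\"), 0x20)),
    short_elem(0x0028, 0x0100, "US", u16(16)),
    short_elem(0x0028, 0x0103, "US", u16(0)),
    short_elem(0x0028, 0x1052, "DS", pad_even(format(intercept), 0x20)),
    short_elem(0x0028, 0x1053, "DS", pad_even(format(slope), 0x20)),
    long_elem(0x7fe0, 0x0010, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}

# Default measurement config for images rendered at the standard study
# conditions (PSF 0.6 mm, spacing 0.5 mm).
study_cfg <- function(psf = 0.6, spacing = 0.5, ...) {
  ibm_config(psf_sigma_mm = effective_psf_sigma(psf, spacing), ...)
}
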