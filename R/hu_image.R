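#' 2D Hounsfield-unit CT slice
#'
#' Container for a single axial CT slice stored as a numeric matrix of
#' attenuation values in Hounsfield units (HU) with isotropic pixel spacing.
#' All geometry in the package is expressed in physical millimetres: the
#' centre of pixel (row r, col c) sits at
#' `origin + ((c-1) * spacing_mm, (r-1) * spacing_mm)`, i.e. x runs along
#' columns and y along rows. Positions between pixel centres are defined by
#' bilinear interpolation of the four surrounding pixel centres.
#'
#' @param pixels numeric matrix of HU values (rows = y, columns = x).
#' @param spacing_mm single positive number, pixel edge length in mm
#'   (isotropic).
#' @param origin physical position (mm) of the centre of pixel (1,1),
#'   default `c(0, 0)`.
#' @return an object of class `hu_image` with fields `pixels`, `spacing_mm`
#'   and `origin`.
#' @export
hu_image <- function(pixels, spacing_mm, origin = c(0, 0)) {
  if (!is.matrix(pixels) || !is.numeric(pixels) ||
      nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("`pixels` must be a numeric matrix with at least 2 rows and columns")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L ||
      !is.finite(spacing_mm) || spacing_mm <= 0)
    stop("`spacing_mm` must be a single positive number")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("all pixel values must be finite")
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("`origin` must be two finite numbers (mm)")
  attributes(pixels) <- list(dim = dim(pixels))
  structure(list(pixels = pixels,
                 spacing_mm = as.numeric(spacing_mm),
                 origin = as.numeric(origin)),
            class = "hu_image")
}

#' @export
print.hu_image <- function(x, ...) {
  cat(sprintf("<hu_image> %d x %d pixels, spacing %.4g mm, HU range [%.0f, %.0f]\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Physical extents of the image (pixel-edge bounds), as c(xmin, xmax, ymin, ymax).
image_extent <- function(image) {
  sp <- image$spacing_mm
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  c(image$origin[1] - sp / 2, image$origin[1] + (nc - 1) * sp + sp / 2,
    image$origin[2] - sp / 2, image$origin[2] + (nr - 1) * sp + sp / 2)
}

point_in_image <- function(image, p) {
  e <- image_extent(image)
  p[1] >= e[1] && p[1] <= e[2] && p[2] >= e[3] && p[2] <= e[4]
}

#' Bilinear HU lookup at physical positions
#'
#' Samples the slice at arbitrary physical positions (mm) by bilinear
#' interpolation between pixel centres. Queries outside the grid of pixel
#' centres are clamped to the edge value and reported via the `clamped`
#' flag so that consumers (e.g. ray profiles) can mark themselves tainted.
#'
#' @param image an [hu_image].
#' @param x,y numeric vectors of physical coordinates (mm).
#' @return list with numeric `hu` and logical `clamped`, both of length
#'   `length(x)`.
#' @export
interp_hu <- function(image, x, y) {
  sp <- image$spacing_mm
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  fc <- (x - image$origin[1]) / sp + 1
  fr <- (y - image$origin[2]) / sp + 1
  clamped <- fc < 1 | fc > nc | fr < 1 | fr > nr
  fc <- pmin(pmax(fc, 1), nc)
  fr <- pmin(pmax(fr, 1), nr)
  c0 <- pmin(floor(fc), nc - 1L)
  r0 <- pmin(floor(fr), nr - 1L)
  tx <- fc - c0
  ty <- fr - r0
  px <- image$pixels
  hu <- px[cbind(r0, c0)] * (1 - tx) * (1 - ty) +
    px[cbind(r0, c0 + 1L)] * tx * (1 - ty) +
    px[cbind(r0 + 1L, c0)] * (1 - tx) * ty +
    px[cbind(r0 + 1L, c0 + 1L)] * tx * ty
  list(hu = hu, clamped = clamped)
}

#' Mean attenuation in a circular region of interest
#'
#' Places a circular ROI of the given area at a physical position and
#' returns the mean HU of all pixels whose centres fall inside the circle
#' (pixel-centre membership, no partial-area weighting — the usual scanner
#' console semantics). The default 1 cm^2 ROI has radius
#' sqrt(100/pi) = 5.6419 mm.
#'
#' @param image an [hu_image].
#' @param center physical centre of the ROI, c(x, y) in mm.
#' @param area_cm2 ROI area in cm^2, default 1.
#' @return mean HU (single number).
#' @export
roi_mean_hu <- function(image, center, area_cm2 = 1) {
  if (!is.numeric(area_cm2) || length(area_cm2) != 1L || area_cm2 <= 0)
    stop("`area_cm2` must be a single positive number")
  r <- sqrt(area_cm2 * 100 / pi)
  e <- image_extent(image)
  if (center[1] - r < e[1] || center[1] + r > e[2] ||
      center[2] - r < e[3] || center[2] + r > e[4])
    stop("ROI circle exits the image bounds")
  sp <- image$spacing_mm
  xs <- image$origin[1] + (seq_len(ncol(image$pixels)) - 1) * sp
  ys <- image$origin[2] + (seq_len(nrow(image$pixels)) - 1) * sp
  d2 <- outer((ys - center[2])^2, (xs - center[1])^2, `+`)
  inside <- d2 <= r^2
  if (!any(inside))
    stop("no pixel centres inside the ROI (pixel spacing too coarse)")
  mean(image$pixels[inside])
}

#' Read a single axial CT slice
#'
#' Reads a slice from a single-frame DICOM file or a NIfTI-1 file and
#' returns it as an [hu_image] in true Hounsfield units. DICOM stored
#' values are rescaled with RescaleSlope/RescaleIntercept (defaulting to
#' 1 and 0 when absent); pixel spacing must be isotropic within 1%.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"dicom"`, `"nifti"`; `"auto"` decides
#'   from the file extension and the DICM magic bytes.
#' @return an [hu_image].
#' @export
read_slice <- function(path, format = c("auto", "dicom", "nifti")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    lower <- tolower(path)
    format <- if (grepl("\\.nii(\\.gz)?$", lower)) "nifti"
    else if (grepl("\\.(dcm|ima)$", lower)) "dicom"
    else if (is_dicom_file(path)) "dicom"
    else "nifti"
  }
  if (format == "dicom") read_dicom_slice(path) else read_nifti_slice(path)
}

read_nifti_slice <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 2L) {
    if (all(d[-(1:2)] == 1L)) {
      dim(img) <- d[1:2]
    } else {
      stop("file contains a 3D volume; extract a single axial slice first")
    }
  }
  pd <- RNifti::pixdim(img)[1:2]
  check_isotropic(pd)
  # NIfTI dim 1 is x (our columns), dim 2 is y (our rows)
  m <- matrix(as.numeric(img), nrow = dim(img)[1])
  hu_image(t(m), spacing_mm = mean(pd))
}

check_isotropic <- function(spacing) {
  if (any(spacing <= 0) || abs(spacing[1] - spacing[2]) / mean(spacing) > 0.01)
    stop(sprintf("anisotropic spacing (%.4g x %.4g mm) is not supported",
                 spacing[1], spacing[2]))
  invisible(TRUE)
}

#' Write a slice as NIfTI-1
#'
#' Writes the slice losslessly (float64) with the spacing recorded in the
#' NIfTI pixdim, so that `read_slice()` recovers pixels and spacing
#' exactly.
#'
#' @param image an [hu_image].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_slice <- function(image, path) {
  img <- RNifti::asNifti(t(image$pixels))
  RNifti::pixdim(img) <- c(image$spacing_mm, image$spacing_mm)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
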