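# Minimal single-frame DICOM reader.
#
# Supports uncompressed single-frame CT images in implicit or explicit
# little-endian transfer syntax, which covers the scanner exports this
# package targets. Only the tags needed to reconstruct an HU raster are
# interpreted: Rows, Columns, PixelSpacing, BitsAllocated,
# PixelRepresentation, RescaleSlope, RescaleIntercept and PixelData.
# There is no installed R DICOM parser in this stack, hence the
# hand-written reader; anything it cannot parse is rejected with a
# message rather than guessed at.

is_dicom_file <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 132) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 132)
  identical(rawToChar(hdr[129:132]), "DICM")
}

dcm_uint16 <- function(raw, at) {
  readBin(raw[at:(at + 1L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}

dcm_uint32 <- function(raw, at) {
  v <- readBin(raw[at:(at + 3L)], "integer", size = 4L, endian = "little")
  if (v < 0) v + 2^32 else v
}

# Explicit VRs that carry a 2-byte reserved field and a 4-byte length.
.dcm_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  p <- if (length(raw) >= 132 && identical(rawToChar(raw[129:132]), "DICM"))
    133L else 1L

  tags <- list()
  explicit <- TRUE         # file meta group is always explicit little-endian
  syntax <- NULL
  n <- length(raw)
  while (p + 7L <= n) {
    group <- dcm_uint16(raw, p)
    elem <- dcm_uint16(raw, p + 2L)
    if (group != 0x0002L && is.null(syntax)) {
      # leaving the file meta group: switch to the negotiated syntax
      syntax <- tags[["0002,0010"]]
      ts <- if (is.null(syntax)) "1.2.840.10008.1.2.1" else trimws(syntax)
      if (ts == "1.2.840.10008.1.2") {
        explicit <- FALSE
      } else if (ts != "1.2.840.10008.1.2.1") {
        stop("unsupported DICOM transfer syntax: ", ts)
      }
      syntax <- ts
    }
    if (explicit || group == 0x0002L) {
      vr <- rawToChar(raw[(p + 4L):(p + 5L)])
      if (vr %in% .dcm_long_vrs) {
        len <- dcm_uint32(raw, p + 8L)
        data_at <- p + 12L
      } else {
        len <- dcm_uint16(raw, p + 6L)
        data_at <- p + 8L
      }
    } else {
      vr <- NA_character_
      len <- dcm_uint32(raw, p + 4L)
      data_at <- p + 8L
    }
    if (len == 4294967295) # 0xFFFFFFFF: undefined length (sequences, encapsulation)
      stop("undefined-length DICOM elements are not supported (compressed or sequence data)")
    key <- sprintf("%04x,%04x", group, elem)
    if (data_at + len - 1L > n)
      stop("truncated DICOM element ", key)
    keep <- c("0002,0010", "0028,0010", "0028,0011", "0028,0030",
              "0028,0100", "0028,0103", "0028,1052", "0028,1053",
              "0028,0008", "7fe0,0010")
    if (key %in% keep) {
      bytes <- if (len > 0L) raw[data_at:(data_at + len - 1L)] else raw(0)
      tags[[key]] <- if (key == "7fe0,0010") bytes else rawToChar(bytes[bytes != as.raw(0)])
      if (key %in% c("0028,0010", "0028,0011", "0028,0100", "0028,0103"))
        tags[[key]] <- dcm_uint16(bytes, 1L)
    }
    p <- data_at + len + (len %% 2L)  # element lengths are even in practice
  }

  frames <- tags[["0028,0008"]]
  if (!is.null(frames) && as.integer(frames) > 1L)
    stop("file contains a multi-frame volume; extract a single axial slice first")
  rows <- tags[["0028,0010"]]; cols <- tags[["0028,0011"]]
  pix <- tags[["7fe0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(pix))
    stop("not a readable single-frame DICOM image (missing Rows/Columns/PixelData)")
  bits <- tags[["0028,0100"]]
  if (is.null(bits)) bits <- 16L
  if (bits != 16L) stop("only 16-bit DICOM pixel data is supported")
  signed <- !is.null(tags[["0028,0103"]]) && tags[["0028,0103"]] == 1L
  if (length(pix) < 2L * rows * cols)
    stop("PixelData shorter than Rows x Columns")
  stored <- readBin(pix, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
  if (!signed) stored[stored < 0] <- stored[stored < 0] + 65536

  spacing_str <- tags[["0028,0030"]]
  if (is.null(spacing_str)) stop("PixelSpacing (0028,0030) missing")
  spacing <- as.numeric(strsplit(trimws(spacing_str), "\\\\")[[1]])
  if (length(spacing) != 2L || anyNA(spacing)) stop("unparseable PixelSpacing")
  check_isotropic(spacing)

  slope <- if (is.null(tags[["0028,1053"]])) 1 else as.numeric(tags[["0028,1053"]])
  intercept <- if (is.null(tags[["0028,1052"]])) 0 else as.numeric(tags[["0028,1052"]])

  # DICOM PixelData is row-major, top row first
  pixels <- matrix(stored * slope + intercept, nrow = rows, ncol = cols,
                   byrow = TRUE)
  hu_image(pixels, spacing_mm = mean(spacing))
}
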