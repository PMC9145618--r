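#' 3D CT volume container
#'
#' A `aroi_volume` holds a stack of integer-valued CT slices together with the
#' geometry metadata every downstream stage (segmentation, compression,
#' evaluation) consumes. Pixels are stored as an integer array of dimension
#' `rows x cols x n_slices` with values in the unsigned 16-bit range, matching
#' uncompressed CT DICOM storage.
#'
#' @param pixels integer array of dimension `rows x cols x n_slices` (a matrix
#'   is promoted to a single-slice volume); values must lie in `[0, 65535]`.
#' @param pixel_spacing numeric length-2, in-plane pixel size in mm
#'   (row spacing, column spacing).
#' @param slice_thickness numeric, slice thickness in mm.
#' @param rescale_slope,rescale_intercept linear mapping from stored values to
#'   Hounsfield units (`HU = slope * stored + intercept`). The compression
#'   path always operates on stored values; the mapping is carried as
#'   metadata only.
#'
#' @return an object of class `aroi_volume`.
#' @export
aroi_volume <- function(pixels,
                        pixel_spacing = c(0.7, 0.7),
                        slice_thickness = 1.25,
                        rescale_slope = 1,
                        rescale_intercept = 0) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(dim(pixels), 1L))
  }
  assert_that(is.array(pixels) && length(dim(pixels)) == 3L,
              "pixels must be a rows x cols x n_slices array")
  storage.mode(pixels) <- "integer"
  rng <- range(pixels)
  assert_that(!anyNA(pixels), "pixels must not contain NA")
  assert_that(rng[1] >= 0L && rng[2] <= 65535L,
              "pixel values must lie in the unsigned 16-bit range [0, 65535]")
  assert_that(length(pixel_spacing) == 2L && all(pixel_spacing > 0),
              "pixel_spacing must be two positive numbers (mm)")
  assert_that(slice_thickness > 0, "slice_thickness must be positive (mm)")
  structure(
    list(pixels = pixels,
         pixel_spacing = as.numeric(pixel_spacing),
         slice_thickness = as.numeric(slice_thickness),
         rescale_slope = as.numeric(rescale_slope),
         rescale_intercept = as.numeric(rescale_intercept)),
    class = "aroi_volume"
  )
}

#' @export
dim.aroi_volume <- function(x) dim(x$pixels)

#' Number of slices in a volume
#' @param volume an `aroi_volume`.
#' @return integer slice count.
#' @export
n_slices <- function(volume) dim(volume$pixels)[3L]

#' Extract one slice as a matrix
#' @param volume an `aroi_volume`.
#' @param i slice index (1-based, proximal to distal).
#' @return integer matrix `rows x cols`.
#' @export
volume_slice <- function(volume, i) volume$pixels[, , i]

#' @export
print.aroi_volume <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<aroi_volume> %d slice(s) of %d x %d, 16-bit\n", d[3], d[1], d[2]))
  cat(sprintf("  pixel spacing %g x %g mm, slice thickness %g mm\n",
              x$pixel_spacing[1], x$pixel_spacing[2], x$slice_thickness))
  cat(sprintf("  stored value range [%d, %d]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Write a volume as raw binary plus a JSON sidecar
#'
#' The pixel array is written as little-endian unsigned 16-bit values in
#' slice-major, column-major order to `<prefix>.raw`; shape and geometry go to
#' `<prefix>.json`. This is the exchange format for tools that do not speak
#' DICOM; [write_dicom_series()] is the DICOM route.
#'
#' @param volume an `aroi_volume`.
#' @param prefix output path prefix (without extension).
#' @return invisibly, the paths written.
#' @export
write_raw_volume <- function(volume, prefix) {
  raw_path <- paste0(prefix, ".raw")
  json_path <- paste0(prefix, ".json")
  writeBin(u16_pack(as.vector(volume$pixels)), raw_path)
  meta <- list(
    shape = dim(volume$pixels),
    dtype = "uint16-le",
    order = "rows-fastest (column-major within slice), slices last",
    pixel_spacing_mm = volume$pixel_spacing,
    slice_thickness_mm = volume$slice_thickness,
    rescale_slope = volume$rescale_slope,
    rescale_intercept = volume$rescale_intercept
  )
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(raw = raw_path, json = json_path))
}

#' Read a volume written by [write_raw_volume()]
#' @param prefix path prefix used when writing.
#' @return an `aroi_volume`.
#' @export
read_raw_volume <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  bytes <- readBin(paste0(prefix, ".raw"), "raw", n = 2 * n + 2)
  assert_that(length(bytes) == 2 * n,
              sprintf("raw volume size mismatch: expected %d bytes", 2 * n))
  px <- array(u16_unpack(bytes, n), dim = shape)
  aroi_volume(px,
              pixel_spacing = meta$pixel_spacing_mm,
              slice_thickness = meta$slice_thickness_mm,
              rescale_slope = meta$rescale_slope %||% 1,
              rescale_intercept = meta$rescale_intercept %||% 0)
}
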