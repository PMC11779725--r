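#' @include AllClasses.R
NULL

# Field sizes (um) of the square acquisition presets at native 1024 px.
MAGNIFICATION_FIELDS_UM <- c("350x" = 767, "900x" = 298)

#' Construct a calibrated image
#'
#' Wraps a gray-level matrix with its physical calibration. If a
#' magnification preset is given (\code{"350x"}: 767 um field; \code{"900x"}:
#' 298 um field), the scale is derived from the pixel grid; otherwise an
#' explicit \code{umPerPx} must be supplied.
#'
#' @param pixels numeric matrix of gray levels in [0, 255] (rows = y).
#' @param magnification \code{"350x"}, \code{"900x"} or \code{"other"}.
#' @param umPerPx explicit scale override (required for \code{"other"}).
#' @return a [CalibratedImage-class].
#' @examples
#' img <- calibratedImage(matrix(0, 64, 64), "other", umPerPx = 298 / 64)
#' umPerPx(img)
#' @export
calibratedImage <- function(pixels,
                            magnification = c("350x", "900x", "other"),
                            umPerPx = NULL) {
  magnification <- match.arg(magnification)
  pixels <- as.matrix(pixels)
  if (magnification == "other") {
    if (is.null(umPerPx))
      stop("unknown magnification: supply an explicit 'umPerPx' scale")
  } else {
    field <- MAGNIFICATION_FIELDS_UM[[magnification]]
    derived <- field / ncol(pixels)
    if (is.null(umPerPx)) umPerPx <- derived
  }
  new("CalibratedImage",
      pixels = pixels, umPerPx = umPerPx,
      fieldWidthUm = umPerPx * ncol(pixels),
      fieldHeightUm = umPerPx * nrow(pixels),
      magnificationTag = magnification)
}

#' Read a grayscale micrograph with physical calibration
#'
#' Reads an 8-bit PNG or TIFF micrograph, collapsing RGB to luminance, and
#' attaches the micrometre-per-pixel scale from the magnification preset
#' (field size divided by the pixel count per side) or from an explicit
#' override.
#'
#' @param path image file (.png or .tif/.tiff).
#' @inheritParams calibratedImage
#' @return a [CalibratedImage-class].
#' @export
readCalibratedImage <- function(path,
                                magnification = c("350x", "900x", "other"),
                                umPerPx = NULL) {
  magnification <- match.arg(magnification)
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' is required to read TIFF images")
    tiff::readTIFF(path)
  } else stop("unsupported image format: .", ext)
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3]
    arr <- if (nch >= 3L)
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    else arr[, , 1]
  }
  calibratedImage(round(arr * 255), magnification, umPerPx)
}

#' Resize a calibrated image, conserving the physical field
#'
#' Resampling changes the pixel grid, not the specimen: the physical field
#' dimensions are conserved and the scale is rescaled accordingly (e.g.
#' 1024 px at 0.291 um/px becomes 512 px at 0.582 um/px). Intensity images
#' use bilinear interpolation; binary masks must use \code{"nearest"} so the
#' output stays strictly 2-valued.
#'
#' @param img a [CalibratedImage-class].
#' @param side target side length in pixels (>= 1).
#' @param interpolation \code{"bilinear"} (intensity) or \code{"nearest"}
#'   (label/mask images).
#' @return a [CalibratedImage-class] with \code{side x side} pixels.
#' @export
resizeImage <- function(img, side, interpolation = c("bilinear", "nearest")) {
  stopifnot(is(img, "CalibratedImage"), side >= 1)
  interpolation <- match.arg(interpolation)
  side <- as.integer(side)
  p <- img@pixels
  if (side == ncol(p) && side == nrow(p)) return(img)
  filt <- if (interpolation == "bilinear") "bilinear" else "none"
  res <- EBImage::resize(EBImage::Image(t(p) / 255), w = side, h = side,
                         filter = filt)
  out <- t(matrix(as.numeric(res), side, side)) * 255
  out <- pmin(pmax(out, 0), 255)
  if (interpolation == "nearest") out <- round(out)
  new("CalibratedImage",
      pixels = out,
      umPerPx = img@fieldWidthUm / side,
      fieldWidthUm = img@fieldWidthUm,
      fieldHeightUm = img@fieldHeightUm,
      magnificationTag = img@magnificationTag)
}
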