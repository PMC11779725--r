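#' @import methods
NULL

#' Calibrated epidermis micrograph
#'
#' An 8-bit grayscale image together with its physical calibration: the
#' micrometre-per-pixel scale and the physical field-of-view dimensions.
#' Rapid scanning electron micrographs of maize abaxial epidermis are
#' acquired at fixed magnifications with known field sizes (350x: a
#' 767 um x 767 um field; 900x: 298 um x 298 um), so the scale follows
#' from the pixel grid; \code{magnificationTag} records which preset was
#' used (or \code{"other"} for an explicit scale).
#'
#' @slot pixels integer-valued matrix of gray levels in [0, 255]; rows are
#'   image rows (y), columns are image columns (x).
#' @slot umPerPx positive micrometres per pixel.
#' @slot fieldWidthUm,fieldHeightUm physical field size in micrometres.
#' @slot magnificationTag one of \code{"350x"}, \code{"900x"}, \code{"other"}.
#'
#' @seealso [readCalibratedImage()], [resizeImage()], [stomatalDensity()]
#' @export
setClass("CalibratedImage",
  slots = c(
    pixels           = "matrix",
    umPerPx          = "numeric",
    fieldWidthUm     = "numeric",
    fieldHeightUm    = "numeric",
    magnificationTag = "character"
  )
)

setValidity("CalibratedImage", function(object) {
  msg <- NULL
  p <- object@pixels
  if (!is.numeric(p) || length(dim(p)) != 2L)
    msg <- c(msg, "'pixels' must be a numeric matrix")
  else {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 255))
      msg <- c(msg, "'pixels' must lie in [0, 255]")
    # calibration consistency: scale x pixel count = field length within 0.5%
    if (abs(object@umPerPx * ncol(p) - object@fieldWidthUm) >
        0.005 * object@fieldWidthUm)
      msg <- c(msg, "umPerPx * width (px) must equal fieldWidthUm within 0.5%")
    if (abs(object@umPerPx * nrow(p) - object@fieldHeightUm) >
        0.005 * object@fieldHeightUm)
      msg <- c(msg, "umPerPx * height (px) must equal fieldHeightUm within 0.5%")
  }
  if (length(object@umPerPx) != 1L || object@umPerPx <= 0)
    msg <- c(msg, "'umPerPx' must be a single positive number")
  if (!object@magnificationTag %in% c("350x", "900x", "other"))
    msg <- c(msg, "'magnificationTag' must be one of '350x', '900x', 'other'")
  if (is.null(msg)) TRUE else msg
})

#' Parameters of the synthetic epidermis generator
#'
#' Describes one simulated abaxial maize epidermis field of view: physical
#' geometry, the target stomatal density, the per-stoma size/shape
#' distributions, the file (row) layout, the three rendered gray levels and
#' the additive noise level. Defaults emulate the 350x acquisition geometry
#' (767 um x 767 um, 1024 px) and realistic maize trait ranges (stomatal
#' length about 85-105 um, width 52-59 um, density 70-95 per mm^2,
#' guard-cell-and-pore area fraction about 0.45-0.55).
#'
#' @slot fieldWidthUm,fieldHeightUm physical field size, micrometres.
#' @slot pixelsPerSide image side length in pixels (square frame).
#' @slot targetDensity target stomatal density, stomata per mm^2.
#' @slot lengthDist,widthDist numeric of length 2: (mean, sd) of stomatal
#'   complex length/width in micrometres. Length mean must exceed width mean.
#' @slot gcpFractionDist numeric of length 2: (mean, sd) of the
#'   guard-cell-and-pore area fraction GCPA/SA, mean in (0, 1).
#' @slot orientationJitterDeg nonnegative; stoma long axes deviate from the
#'   file direction by uniform(-jitter, +jitter) degrees.
#' @slot rowSpacingUm spacing between adjacent stomatal files, micrometres.
#' @slot intensityLevels named numeric: gray levels for \code{background},
#'   \code{subsidiary} and \code{gcp} pixels, pairwise at least 20 levels
#'   apart (the reference segmenter's contract).
#' @slot noiseSd sd of additive Gaussian gray-level noise (clipped to [0,255]).
#' @slot seed integer seed; identical parameters give bit-identical scenes.
#' @slot allowBorderClipped if TRUE stomata may be clipped by the frame edge
#'   (for exercising border policies); default FALSE.
#'
#' @seealso [sceneParams()], [generateScene()]
#' @export
setClass("SceneParams",
  slots = c(
    fieldWidthUm         = "numeric",
    fieldHeightUm        = "numeric",
    pixelsPerSide        = "integer",
    targetDensity        = "numeric",
    lengthDist           = "numeric",
    widthDist            = "numeric",
    gcpFractionDist      = "numeric",
    orientationJitterDeg = "numeric",
    rowSpacingUm         = "numeric",
    intensityLevels      = "numeric",
    noiseSd              = "numeric",
    seed                 = "integer",
    allowBorderClipped   = "logical"
  )
)

setValidity("SceneParams", function(object) {
  msg <- NULL
  if (object@fieldWidthUm <= 0 || object@fieldHeightUm <= 0)
    msg <- c(msg, "field dimensions must be positive")
  if (object@pixelsPerSide < 1L)
    msg <- c(msg, "'pixelsPerSide' must be a positive integer")
  if (object@targetDensity < 0)
    msg <- c(msg, "'targetDensity' must be nonnegative")
  if (length(object@lengthDist) != 2L || length(object@widthDist) != 2L)
    msg <- c(msg, "'lengthDist' and 'widthDist' must be (mean, sd) pairs")
  else if (object@lengthDist[1] <= object@widthDist[1])
    msg <- c(msg, "stomatal length mean must exceed width mean")
  if (length(object@gcpFractionDist) != 2L ||
      object@gcpFractionDist[1] <= 0 || object@gcpFractionDist[1] >= 1)
    msg <- c(msg, "'gcpFractionDist' mean must lie in (0, 1)")
  if (object@orientationJitterDeg < 0)
    msg <- c(msg, "'orientationJitterDeg' must be nonnegative")
  if (object@rowSpacingUm <= 0)
    msg <- c(msg, "'rowSpacingUm' must be positive")
  iv <- object@intensityLevels
  if (!all(c("background", "subsidiary", "gcp") %in% names(iv)))
    msg <- c(msg, "'intensityLevels' needs background, subsidiary, gcp entries")
  else {
    if (any(iv < 0 | iv > 255))
      msg <- c(msg, "intensity levels must lie in [0, 255]")
    if (min(dist(iv[c("background", "subsidiary", "gcp")])) < 20)
      msg <- c(msg, "intensity levels must be pairwise >= 20 gray levels apart")
  }
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be nonnegative")
  if (is.null(msg)) TRUE else msg
})

#' A generated epidermis scene with exact ground truth
#'
#' Output of [generateScene()]: the rendered calibrated image, the two
#' ground-truth semantic masks (whole stomatal complexes; guard cells and
#' pore), tight per-stoma bounding boxes, and the analytic per-stoma trait
#' table computed in closed form from the generating ellipses.
#'
#' @slot image a [CalibratedImage-class].
#' @slot complexMask,gcpMask 0/1 integer matrices, same shape as the image;
#'   the guard-cell-and-pore mask is a pixel subset of the complex mask.
#' @slot boxes data.frame of tight boxes (x0, y0, x1, y1), 0-based
#'   half-open pixel coordinates, pairwise non-overlapping.
#' @slot truthTraits data.frame of analytic per-stoma traits (SA, SL, SW,
#'   SP, GCPA, SCA, SR, SE, PGCPA, PSCA, centre, orientation, pixel area).
#' @slot achievedDensity placed stomata per mm^2 of field area (exact).
#' @slot params the generating [SceneParams-class].
#' @export
setClass("SyntheticScene",
  slots = c(
    image           = "CalibratedImage",
    complexMask     = "matrix",
    gcpMask         = "matrix",
    boxes           = "data.frame",
    truthTraits     = "data.frame",
    achievedDensity = "numeric",
    params          = "SceneParams"
  )
)

setValidity("SyntheticScene", function(object) {
  msg <- NULL
  if (!identical(dim(object@complexMask), dim(object@gcpMask)))
    msg <- c(msg, "masks must share one shape")
  if (any(object@gcpMask > object@complexMask))
    msg <- c(msg, "gcpMask must be a pixel subset of complexMask")
  b <- object@boxes
  if (nrow(b) > 1L) {
    for (i in seq_len(nrow(b) - 1L)) {
      j <- (i + 1L):nrow(b)
      ox <- pmin(b$x1[j], b$x1[i]) - pmax(b$x0[j], b$x0[i])
      oy <- pmin(b$y1[j], b$y1[i]) - pmax(b$y0[j], b$y0[i])
      if (any(ox > 0 & oy > 0)) {
        msg <- c(msg, "ground-truth boxes must be pairwise non-overlapping")
        break
      }
    }
  }
  tt <- object@truthTraits
  if (!is.null(tt$borderTouching)) tt <- tt[!tt$borderTouching, , drop = FALSE]
  if (nrow(tt) > 0L) {
    # clipped (border-touching) stomata are exempt: their rasterized area
    # is truncated by the frame, the analytic ellipse is not
    s2 <- object@image@umPerPx^2
    rel <- abs(tt$SA - tt$pixelArea * s2) / tt$SA
    if (any(rel > 0.02))
      msg <- c(msg, "analytic SA must match rasterized pixel area within 2%")
  }
  if (is.null(msg)) TRUE else msg
})

#' A semantic mask pair (stomatal complex; guard cells and pore)
#'
#' The two binary semantic layers produced by segmentation: the intact
#' stomatal complexes and the guard-cells-and-pore regions, on one pixel
#' grid with a shared physical scale. [fuseMasks()] combines them into the
#' refined stomatal structure mask.
#'
#' @slot complexMask,gcpMask 0/1 integer matrices of equal shape.
#' @slot umPerPx micrometres per pixel.
#' @export
setClass("MaskPair",
  slots = c(complexMask = "matrix", gcpMask = "matrix", umPerPx = "numeric")
)

setValidity("MaskPair", function(object) {
  msg <- NULL
  if (!identical(dim(object@complexMask), dim(object@gcpMask)))
    msg <- c(msg, "masks must share one shape")
  if (object@umPerPx <= 0) msg <- c(msg, "'umPerPx' must be positive")
  if (any(!object@complexMask %in% c(0, 1)) || any(!object@gcpMask %in% c(0, 1)))
    msg <- c(msg, "masks must be binary (0/1)")
  if (is.null(msg)) TRUE else msg
})

#' One connected stomatal complex instance
#'
#' A single stoma extracted from the fused structure mask by 8-connectivity:
#' its pixel set (linear indices into the mask grid), the subset of pixels
#' belonging to the guard-cells-and-pore layer, its tight bounding box, and
#' whether it touches the frame border (truncated geometry).
#'
#' @slot label integer instance id (scan order of the first pixel).
#' @slot pixels sorted integer vector of linear pixel indices.
#' @slot gcpPixels subset of \code{pixels} in the guard-cell-and-pore mask.
#' @slot bbox numeric (x0, y0, x1, y1), 0-based half-open pixels.
#' @slot borderTouching TRUE if any pixel lies on the frame edge.
#' @slot maskDim dimensions (nrow, ncol) of the source grid.
#' @export
setClass("StomaInstance",
  slots = c(
    label          = "integer",
    pixels         = "integer",
    gcpPixels      = "integer",
    bbox           = "numeric",
    borderTouching = "logical",
    maskDim        = "integer"
  )
)

setValidity("StomaInstance", function(object) {
  msg <- NULL
  if (length(object@pixels) == 0L) msg <- c(msg, "instance must be non-empty")
  if (!all(object@gcpPixels %in% object@pixels))
    msg <- c(msg, "gcpPixels must be a subset of pixels")
  if (length(object@bbox) != 4L) msg <- c(msg, "bbox must be (x0, y0, x1, y1)")
  if (is.null(msg)) TRUE else msg
})

#' Detection result for one field of view
#'
#' Scored stomatal bounding boxes for one image, as produced by any detector
#' honouring the detector contract (see [referenceDetect()]).
#'
#' @slot boxes data.frame with columns x0, y0, x1, y1 (0-based half-open
#'   pixels) and confidence in [0, 1].
#' @slot sourceImage identifier of the image the boxes belong to.
#' @slot count number of detections (equals \code{nrow(boxes)}).
#' @export
setClass("DetectionResult",
  slots = c(boxes = "data.frame", sourceImage = "character", count = "integer")
)

setValidity("DetectionResult", function(object) {
  msg <- NULL
  if (object@count != nrow(object@boxes))
    msg <- c(msg, "'count' must equal nrow(boxes)")
  if (nrow(object@boxes) > 0L) {
    if (!all(c("x0", "y0", "x1", "y1", "confidence") %in% names(object@boxes)))
      msg <- c(msg, "boxes need columns x0, y0, x1, y1, confidence")
    else if (any(object@boxes$confidence < 0 | object@boxes$confidence > 1))
      msg <- c(msg, "confidences must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})
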