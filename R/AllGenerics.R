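#' @include AllClasses.R
NULL

#' Accessors for calibrated images, scenes and instances
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param object an object of the documented classes.
#' @return \code{pixels}: the gray-level matrix; \code{umPerPx}: the scale in
#'   micrometres per pixel; \code{fieldAreaMm2}: the physical field area in
#'   mm^2; \code{truthTraits}, \code{truthBoxes}: the scene's analytic trait
#'   table / ground-truth boxes; \code{detectionBoxes}: scored boxes;
#'   \code{detectionCount}: number of detections.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("umPerPx", function(object) standardGeneric("umPerPx"))
#' @rdname accessors
#' @export
setGeneric("fieldAreaMm2", function(object) standardGeneric("fieldAreaMm2"))
#' @rdname accessors
#' @export
setGeneric("truthTraits", function(object) standardGeneric("truthTraits"))
#' @rdname accessors
#' @export
setGeneric("truthBoxes", function(object) standardGeneric("truthBoxes"))
#' @rdname accessors
#' @export
setGeneric("detectionBoxes", function(object) standardGeneric("detectionBoxes"))
#' @rdname accessors
#' @export
setGeneric("detectionCount", function(object) standardGeneric("detectionCount"))

#' @rdname accessors
#' @export
setMethod("pixels", "CalibratedImage", function(object) object@pixels)
#' @rdname accessors
#' @export
setMethod("umPerPx", "CalibratedImage", function(object) object@umPerPx)
#' @rdname accessors
#' @export
setMethod("fieldAreaMm2", "CalibratedImage", function(object)
  object@fieldWidthUm * object@fieldHeightUm * 1e-6)
#' @rdname accessors
#' @export
setMethod("pixels", "SyntheticScene", function(object) object@image@pixels)
#' @rdname accessors
#' @export
setMethod("umPerPx", "SyntheticScene", function(object) object@image@umPerPx)
#' @rdname accessors
#' @export
setMethod("fieldAreaMm2", "SyntheticScene", function(object)
  fieldAreaMm2(object@image))
#' @rdname accessors
#' @export
setMethod("truthTraits", "SyntheticScene", function(object) object@truthTraits)
#' @rdname accessors
#' @export
setMethod("truthBoxes", "SyntheticScene", function(object) object@boxes)
#' @rdname accessors
#' @export
setMethod("umPerPx", "MaskPair", function(object) object@umPerPx)
#' @rdname accessors
#' @export
setMethod("detectionBoxes", "DetectionResult", function(object) object@boxes)
#' @rdname accessors
#' @export
setMethod("detectionCount", "DetectionResult", function(object) object@count)

setMethod("show", "CalibratedImage", function(object) {
  cat(sprintf(
    "CalibratedImage: %d x %d px, %.4f um/px (%s), field %.0f x %.0f um\n",
    ncol(object@pixels), nrow(object@pixels), object@umPerPx,
    object@magnificationTag, object@fieldWidthUm, object@fieldHeightUm))
})

setMethod("show", "SceneParams", function(object) {
  cat(sprintf(
    paste0("SceneParams: field %.0f x %.0f um @ %d px, target density %.1f/mm^2\n",
           "  length %.1f+/-%.1f um, width %.1f+/-%.1f um, GCP fraction %.2f+/-%.2f\n",
           "  row spacing %.0f um, jitter %.1f deg, noise sd %.1f, seed %d\n"),
    object@fieldWidthUm, object@fieldHeightUm, object@pixelsPerSide,
    object@targetDensity, object@lengthDist[1], object@lengthDist[2],
    object@widthDist[1], object@widthDist[2],
    object@gcpFractionDist[1], object@gcpFractionDist[2],
    object@rowSpacingUm, object@orientationJitterDeg, object@noiseSd,
    object@seed))
})

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf(
    "SyntheticScene: %d stomata, achieved density %.2f/mm^2, seed %d\n",
    nrow(object@boxes), object@achievedDensity, object@params@seed))
  show(object@image)
})

setMethod("show", "MaskPair", function(object) {
  cat(sprintf(
    "MaskPair: %d x %d px @ %.4f um/px; complex %d px, guard-cell-and-pore %d px\n",
    ncol(object@complexMask), nrow(object@complexMask), object@umPerPx,
    sum(object@complexMask), sum(object@gcpMask)))
})

setMethod("show", "StomaInstance", function(object) {
  cat(sprintf(
    "StomaInstance %d: %d px (%d guard-cell-and-pore), bbox [%d,%d)x[%d,%d)%s\n",
    object@label, length(object@pixels), length(object@gcpPixels),
    object@bbox[1], object@bbox[3], object@bbox[2], object@bbox[4],
    if (object@borderTouching) ", border-touching" else ""))
})

setMethod("show", "DetectionResult", function(object) {
  cat(sprintf("DetectionResult: %d boxes on '%s'\n",
              object@count, object@sourceImage))
})
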