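#' @include AllClasses.R calibrated-image.R
NULL

#' Classical reference detector for stomatal complexes
#'
#' A deterministic detector honouring the pluggable detector contract
#' (calibrated image in, scored boxes out). Intended for synthetic imagery
#' following the generator's intensity contract (stomatal pixels darker
#' than the background): pixels at or below \code{intensityThreshold} are
#' taken as stomatal, a morphological closing bridges noise gaps,
#' 8-connected components are filtered to the physical area window
#' \code{[minAreaUm2, maxAreaUm2]}, and tight bounding boxes are emitted
#' with confidence 1.0. A learned detector can be plugged in anywhere a
#' [DetectionResult-class] is consumed.
#'
#' @param img a [CalibratedImage-class].
#' @param intensityThreshold gray level at or below which a pixel counts as
#'   stomatal (default 150, midway between the default subsidiary and
#'   background rendering levels).
#' @param minAreaUm2,maxAreaUm2 component area window in square
#'   micrometres; components outside it are discarded.
#' @param closingRadius radius (px) of the disc brush for morphological
#'   closing; 0 disables it.
#' @param sourceImage identifier stored in the result.
#' @return a [DetectionResult-class].
#' @export
referenceDetect <- function(img, intensityThreshold = 150,
                            minAreaUm2 = 500, maxAreaUm2 = 20000,
                            closingRadius = 3, sourceImage = "image") {
  stopifnot(is(img, "CalibratedImage"))
  m <- matrix(as.integer(img@pixels <= intensityThreshold),
              nrow(img@pixels), ncol(img@pixels))
  if (closingRadius > 0 && any(m == 1L)) {
    brush <- EBImage::makeBrush(2 * closingRadius + 1, shape = "disc")
    m <- t(matrix(as.integer(
      EBImage::closing(EBImage::Image(t(m)), brush) > 0),
      ncol(m), nrow(m)))
  }
  lab <- label8(m)
  s2 <- img@umPerPx^2
  boxes <- data.frame(x0 = numeric(0), y0 = numeric(0),
                      x1 = numeric(0), y1 = numeric(0),
                      confidence = numeric(0))
  if (any(lab > 0L)) {
    for (id in seq_len(max(lab))) {
      w <- which(lab == id, arr.ind = TRUE)
      areaUm2 <- nrow(w) * s2
      if (areaUm2 < minAreaUm2 || areaUm2 > maxAreaUm2) next
      bb <- pixelBbox(w[, 1], w[, 2])
      boxes[nrow(boxes) + 1L, ] <-
        list(bb[["x0"]], bb[["y0"]], bb[["x1"]], bb[["y1"]], 1.0)
    }
  }
  new("DetectionResult", boxes = boxes, sourceImage = sourceImage,
      count = nrow(boxes))
}

#' Stomatal density from a count over a calibrated field
#'
#' SD = count / field area, with the field area taken from the image
#' calibration (physical area is conserved under resizing, so density is
#' resolution-invariant).
#'
#' @param count nonnegative number of stomata in the field of view.
#' @param img the [CalibratedImage-class] the count refers to.
#' @return stomatal density in stomata per mm^2.
#' @examples
#' img <- calibratedImage(matrix(180, 64, 64), "other", umPerPx = 767 / 64)
#' stomatalDensity(47, img)  # 47 / 0.588 mm^2 = 79.9 per mm^2
#' @export
stomatalDensity <- function(count, img) {
  stopifnot(count >= 0)
  area <- fieldAreaMm2(img)
  if (area <= 0) stop("field area must be positive")
  count / area
}
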