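#' @include AllClasses.R calibrated-image.R
NULL

#' Classical reference segmenter for the two semantic layers
#'
#' A deterministic stand-in for a learned semantic segmenter, honouring the
#' pluggable segmenter contract (calibrated image in, [MaskPair-class]
#' out). It assumes the generator's intensity-band contract: guard-cell-
#' and-pore pixels fall in one gray-level band, subsidiary-cell pixels in
#' another, background above both. The complex mask is the union of the
#' two stomatal bands, the guard-cell-and-pore mask is the darker band
#' alone; each layer is hole-filled per connected component.
#'
#' @param img a [CalibratedImage-class].
#' @param bands list with inclusive gray-level ranges \code{gcp = c(lo, hi)}
#'   and \code{subsidiary = c(lo, hi)}; the two bands must not overlap.
#'   Defaults bracket the default rendering levels (50 and 120) at their
#'   midpoints with the background (180).
#' @param minAreaUm2 connected components smaller than this physical area
#'   (square micrometres) are removed from each layer as noise speckles;
#'   real stomatal structures are orders of magnitude larger. 0 disables.
#' @return a [MaskPair-class].
#' @export
referenceSegment <- function(img,
                             bands = list(gcp = c(0, 85),
                                          subsidiary = c(86, 150)),
                             minAreaUm2 = 50) {
  stopifnot(is(img, "CalibratedImage"))
  g <- bands$gcp; sb <- bands$subsidiary
  if (is.null(g) || is.null(sb) || length(g) != 2L || length(sb) != 2L)
    stop("'bands' must carry gcp = c(lo, hi) and subsidiary = c(lo, hi)")
  if (max(min(g), min(sb)) <= min(max(g), max(sb)) &&
      !(max(g) < min(sb) || max(sb) < min(g)))
    stop("gcp and subsidiary intensity bands must not overlap")
  p <- img@pixels
  gcp <- matrix(as.integer(p >= g[1] & p <= g[2]), nrow(p), ncol(p))
  sub <- matrix(as.integer(p >= sb[1] & p <= sb[2]), nrow(p), ncol(p))
  complexMask <- matrix(as.integer(gcp | sub), nrow(p), ncol(p))
  complexMask <- fillHoles(complexMask)
  gcp <- fillHoles(gcp)
  if (minAreaUm2 > 0) {
    minPx <- ceiling(minAreaUm2 / img@umPerPx^2)
    complexMask <- removeSmallComponents(complexMask, minPx)
    gcp <- removeSmallComponents(gcp, minPx)
  }
  new("MaskPair", complexMask = complexMask, gcpMask = gcp,
      umPerPx = img@umPerPx)
}

# drop 8-connected components below minPx pixels
removeSmallComponents <- function(mask, minPx) {
  if (minPx <= 1L || !any(mask == 1L)) return(mask)
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0L])
  small <- which(sizes < minPx)
  if (length(small)) mask[lab %in% small] <- 0L
  mask
}

# per-component hole filling via EBImage (labels, fillHull, back to binary)
fillHoles <- function(mask) {
  b <- asBinary(mask)
  if (!any(b == 1L)) return(b)
  lab <- EBImage::bwlabel(t(b))
  filled <- EBImage::fillHull(lab)
  t(matrix(as.integer(filled > 0), nrow(filled), ncol(filled)))
}

#' Fuse the two semantic masks into the refined structure mask
#'
#' The stomatal-complex and guard-cell-and-pore masks are combined by
#' pixelwise union into the refined stomatal structure mask, from which
#' individual stomata are extracted by connectivity. Union is idempotent
#' and never removes a foreground pixel, so guard-cell-and-pore pixels
#' that fall outside the predicted complex are recovered.
#'
#' @param pair a [MaskPair-class], or a 0/1 matrix together with
#'   \code{gcpMask}.
#' @param gcpMask when \code{pair} is a plain matrix: the second mask.
#' @return a 0/1 integer matrix, the fused structure mask.
#' @export
fuseMasks <- function(pair, gcpMask = NULL) {
  if (is(pair, "MaskPair")) {
    a <- pair@complexMask; b <- pair@gcpMask
  } else {
    a <- asBinary(pair); b <- asBinary(gcpMask)
  }
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  matrix(as.integer(a | b), nrow(a), ncol(a))
}

#' Extract individual stomata by mask connectivity
#'
#' Partitions the fused structure mask into 8-connected components, one
#' [StomaInstance-class] per component, each carrying the subset of its
#' pixels that belong to the guard-cell-and-pore layer and a flag marking
#' frame-border contact (truncated geometry). The \code{borderPolicy} is
#' recorded for downstream trait extraction: under \code{"drop_for_traits"}
#' border-touching instances are excluded from size/shape traits (their
#' geometry is clipped) but still reported and counted.
#'
#' @param fused 0/1 matrix, the fused structure mask.
#' @param gcpMask 0/1 matrix, the guard-cell-and-pore layer.
#' @param borderPolicy \code{"keep"} or \code{"drop_for_traits"}.
#' @return list of [StomaInstance-class], ordered by first pixel in scan
#'   order, with attribute \code{borderPolicy}.
#' @export
labelStomata <- function(fused, gcpMask,
                         borderPolicy = c("drop_for_traits", "keep")) {
  borderPolicy <- match.arg(borderPolicy)
  fused <- asBinary(fused); gcpMask <- asBinary(gcpMask)
  if (!identical(dim(fused), dim(gcpMask)))
    stop("mask shapes differ")
  lab <- label8(fused)
  nr <- nrow(fused); nc <- ncol(fused)
  gcpIdx <- which(gcpMask == 1L)
  out <- list()
  if (any(lab > 0L)) {
    for (id in seq_len(max(lab))) {
      idx <- which(lab == id)
      w <- arrayInd(idx, dim(lab))
      bb <- pixelBbox(w[, 1], w[, 2])
      border <- any(w[, 1] == 1L | w[, 1] == nr | w[, 2] == 1L | w[, 2] == nc)
      out[[id]] <- new("StomaInstance",
                       label = id, pixels = sort(idx),
                       gcpPixels = sort(intersect(idx, gcpIdx)),
                       bbox = c(bb[["x0"]], bb[["y0"]], bb[["x1"]], bb[["y1"]]),
                       borderTouching = border,
                       maskDim = c(nr, nc))
    }
  }
  attr(out, "borderPolicy") <- borderPolicy
  out
}
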