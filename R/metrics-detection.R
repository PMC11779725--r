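#' @include AllClasses.R
NULL

# area and intersection helpers on (x0, y0, x1, y1) half-open boxes
boxArea <- function(b) max(0, b[3] - b[1]) * max(0, b[4] - b[2])

boxIntersection <- function(a, b) {
  w <- min(a[3], b[3]) - max(a[1], b[1])
  h <- min(a[4], b[4]) - max(a[2], b[2])
  if (w <= 0 || h <= 0) 0 else w * h
}

#' Bounding-box IoU, generalized IoU and GIoU loss
#'
#' For prediction X and target Y (axis-aligned half-open boxes) with Z the
#' smallest enclosing box of both:
#' \deqn{GIoU = |X \cap Y| / |X \cup Y| - |Z \setminus (X \cup Y)| / |Z|}
#' and the loss is \code{1 - GIoU}, in [0, 2). GIoU equals IoU whenever the
#' enclosing box is filled by the union (e.g. nested boxes) and tends to -1
#' for distant boxes.
#'
#' @param pred,target numeric (x0, y0, x1, y1) or one-row data.frames.
#' @return \code{boxIoU}: IoU in [0, 1]; \code{giou}: generalized IoU in
#'   (-1, 1]; \code{giouLoss}: 1 - GIoU.
#' @examples
#' giouLoss(c(0, 0, 1, 1), c(2, 2, 3, 3))  # 1.7778: union 2, enclosing 9
#' @export
boxIoU <- function(pred, target) {
  pred <- as.numeric(pred)[1:4]; target <- as.numeric(target)[1:4]
  inter <- boxIntersection(pred, target)
  union <- boxArea(pred) + boxArea(target) - inter
  if (union <= 0) stop("degenerate (zero-area) box")
  inter / union
}

#' @rdname boxIoU
#' @export
giou <- function(pred, target) {
  pred <- as.numeric(pred)[1:4]; target <- as.numeric(target)[1:4]
  if (boxArea(pred) <= 0 || boxArea(target) <= 0)
    stop("degenerate (zero-area) box")
  inter <- boxIntersection(pred, target)
  union <- boxArea(pred) + boxArea(target) - inter
  z <- c(min(pred[1], target[1]), min(pred[2], target[2]),
         max(pred[3], target[3]), max(pred[4], target[4]))
  za <- boxArea(z)
  inter / union - (za - union) / za
}

#' @rdname boxIoU
#' @export
giouLoss <- function(pred, target) 1 - giou(pred, target)

#' Precision and recall from match counts
#'
#' P = TP / (TP + FP), R = TP / (TP + FN) (the universal definitions).
#' An undefined ratio (zero denominator) is returned as NA with a
#' \code{"reason"} attribute rather than a silent zero.
#'
#' @param counts named numeric/integer with TP, FP, FN (all >= 0), e.g. the
#'   \code{counts} element of [matchDetections()].
#' @return named list with \code{precision} and \code{recall}.
#' @examples
#' precisionRecall(c(TP = 8, FP = 2, FN = 4))  # P 0.8, R 0.667
#' @export
precisionRecall <- function(counts) {
  TP <- counts[["TP"]]; FP <- counts[["FP"]]; FN <- counts[["FN"]]
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  P <- if (TP + FP > 0) TP / (TP + FP) else
    structure(NA_real_, reason = "no predictions: precision undefined")
  R <- if (TP + FN > 0) TP / (TP + FN) else
    structure(NA_real_, reason = "no ground truth: recall undefined")
  list(precision = P, recall = R)
}

#' Match predicted boxes to ground truth at an IoU threshold
#'
#' Greedy one-to-one matching in descending confidence order: each
#' prediction claims the unconsumed truth box of highest IoU, provided the
#' IoU reaches the threshold (ties broken on higher IoU, then lower truth
#' index). Unmatched predictions are false positives, unclaimed truths
#' false negatives.
#'
#' @param pred data.frame of boxes (x0, y0, x1, y1, confidence) or a
#'   [DetectionResult-class].
#' @param truth data.frame of ground-truth boxes (x0, y0, x1, y1).
#' @param iouThreshold minimum IoU for a match (0.5 for AP50).
#' @return list with \code{counts} (TP, FP, FN), \code{ranked}
#'   (data.frame confidence/isMatch in descending confidence order) and
#'   \code{mTruth} (number of truth boxes).
#' @export
matchDetections <- function(pred, truth, iouThreshold = 0.5) {
  if (is(pred, "DetectionResult")) pred <- pred@boxes
  nP <- nrow(pred); nT <- nrow(truth)
  conf <- if (nP && "confidence" %in% names(pred) &&
              !all(is.na(pred$confidence))) pred$confidence else rep(1, nP)
  ord <- if (nP) order(-conf, seq_len(nP)) else integer(0)
  consumed <- rep(FALSE, nT)
  isMatch <- logical(nP)
  for (k in seq_len(nP)) {
    i <- ord[k]
    pb <- as.numeric(pred[i, c("x0", "y0", "x1", "y1")])
    best <- 0; bestJ <- 0L
    for (j in seq_len(nT)) {
      if (consumed[j]) next
      tb <- as.numeric(truth[j, c("x0", "y0", "x1", "y1")])
      v <- boxIoU(pb, tb)
      if (v > best + 1e-12) { best <- v; bestJ <- j }
    }
    if (bestJ > 0L && best >= iouThreshold) {
      consumed[bestJ] <- TRUE
      isMatch[k] <- TRUE
    }
  }
  TP <- sum(isMatch)
  list(counts = c(TP = TP, FP = nP - TP, FN = nT - TP),
       ranked = data.frame(confidence = conf[ord], isMatch = isMatch),
       mTruth = nT)
}

#' Average precision at IoU 0.5 (AP50)
#'
#' Area under the interpolated precision-recall curve of a ranked
#' detection list. All-point interpolation is the default (the integral
#' \eqn{\int P(R) dR} of the precision envelope); the 101-point variant is
#' available behind a flag. AP is invariant to uniform rescaling of the
#' confidences (only the ranking matters).
#'
#' @param ranked data.frame with \code{confidence} and logical
#'   \code{isMatch} (descending-confidence detection list), or the result
#'   of [matchDetections()].
#' @param mTruth total number of ground-truth boxes (taken from a
#'   [matchDetections()] result automatically).
#' @param interpolation \code{"all"} (default) or \code{"101"}.
#' @return AP in [0, 1]. With zero truths and zero predictions AP is
#'   defined as 1 (perfect agreement on absence) with a warning.
#' @export
ap50 <- function(ranked, mTruth = NULL, interpolation = c("all", "101")) {
  interpolation <- match.arg(interpolation)
  if (is.list(ranked) && !is.data.frame(ranked) && !is.null(ranked$ranked)) {
    mTruth <- ranked$mTruth
    ranked <- ranked$ranked
  }
  if (is.null(mTruth)) stop("'mTruth' (number of truth boxes) is required")
  n <- nrow(ranked)
  if (mTruth == 0L && n == 0L) {
    warning("no truths and no predictions: AP defined as 1")
    return(1)
  }
  if (mTruth == 0L) return(0)
  if (n == 0L) return(0)
  ord <- order(-ranked$confidence, seq_len(n))
  m <- ranked$isMatch[ord]
  cum <- cumsum(m)
  prec <- cum / seq_len(n)
  rec <- cum / mTruth
  env <- rev(cummax(rev(prec)))           # precision envelope
  if (interpolation == "101") {
    grid <- seq(0, 1, length.out = 101)
    pAt <- vapply(grid, function(r) {
      ok <- rec >= r - 1e-12
      if (any(ok)) max(env[ok]) else 0
    }, numeric(1))
    return(mean(pAt))
  }
  dr <- diff(c(0, rec))
  sum(dr * env)
}
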