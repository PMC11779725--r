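#' @include AllClasses.R segmentation.R annotations-io.R
NULL

# ---- low-level shape measures -------------------------------------------

# Sub-pixel outer-contour length of a binary mask, in pixel units.
# Marching squares (grDevices::contourLines at level 0.5 on the padded
# mask) gives the 0/1 midpoint polygon; three passes of 1-2-1 vertex
# smoothing remove the staircase bias (a rasterized disk then measures
# within ~1% of 2*pi*r, so circularity lands at 1 for circles).
maskPerimeter <- function(mask, smoothIters = 3L) {
  b <- asBinary(mask)
  if (!any(b == 1L)) stop("empty mask has no perimeter")
  pad <- matrix(0L, nrow(b) + 4L, ncol(b) + 4L)
  pad[3:(2 + nrow(b)), 3:(2 + ncol(b))] <- b
  cl <- grDevices::contourLines(seq_len(nrow(pad)), seq_len(ncol(pad)),
                                pad, levels = 0.5)
  if (!length(cl)) stop("no contour found")
  shoelace <- function(p) {
    x <- p$x; y <- p$y
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  outer <- cl[[which.max(vapply(cl, shoelace, numeric(1)))]]
  x <- outer$x; y <- outer$y
  n <- length(x)
  if (abs(x[1] - x[n]) < 1e-12 && abs(y[1] - y[n]) < 1e-12) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  if (n >= 3L) {
    for (k in seq_len(smoothIters)) {
      xs <- (x[c(n, 1:(n - 1))] + 2 * x + x[c(2:n, 1)]) / 4
      ys <- (y[c(n, 1:(n - 1))] + 2 * y + y[c(2:n, 1)]) / 4
      x <- xs; y <- ys
    }
  }
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# Minimum-area rotated bounding rectangle of a pixel set, via rotating
# calipers over the convex hull of the pixel corner points.
# rows, cols: 1-based pixel indices. Returns c(long, short) side lengths px.
minAreaRect <- function(rows, cols) {
  stopifnot(length(rows) > 0L)
  hull0 <- grDevices::chull(cols, rows)
  hc <- cols[hull0]; hr <- rows[hull0]
  corners <- cbind(
    x = c(hc - 0.5, hc + 0.5, hc + 0.5, hc - 0.5),
    y = c(hr - 0.5, hr - 0.5, hr + 0.5, hr + 0.5))
  h <- grDevices::chull(corners[, 1], corners[, 2])
  px <- corners[h, 1]; py <- corners[h, 2]
  n <- length(px)
  if (n == 1L) return(c(long = 1, short = 1))
  best <- c(Inf, NA, NA)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- px[j] - px[i]; ey <- py[j] - py[i]
    len <- sqrt(ex^2 + ey^2)
    if (len < 1e-12) next
    ux <- ex / len; uy <- ey / len          # edge direction
    p1 <- px * ux + py * uy                  # projections
    p2 <- -px * uy + py * ux
    w <- max(p1) - min(p1); h2 <- max(p2) - min(p2)
    if (w * h2 < best[1]) best <- c(w * h2, w, h2)
  }
  sides <- sort(best[2:3], decreasing = TRUE)
  c(long = sides[1], short = sides[2])
}

# Eccentricity of the moment ellipse of a pixel set: sqrt(1 - l2/l1) from
# the eigenvalues of the second central moment matrix (pixels treated as
# unit squares: +1/12 on the diagonal).
momentEccentricity <- function(rows, cols) {
  n <- length(rows)
  mr <- mean(rows); mc <- mean(cols)
  mxx <- sum((cols - mc)^2) / n + 1 / 12
  myy <- sum((rows - mr)^2) / n + 1 / 12
  mxy <- sum((cols - mc) * (rows - mr)) / n
  half <- (mxx + myy) / 2
  d <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- half + d; l2 <- max(half - d, 0)
  sqrt(max(0, 1 - l2 / l1))
}

# ---- trait extraction ----------------------------------------------------

#' Measure the size and shape traits of one stoma
#'
#' Computes the per-stoma traits from an extracted instance:
#' \itemize{
#'   \item SA: pixel count x scale^2 (um^2)
#'   \item SP: sub-pixel marching-squares outer contour length x scale (um)
#'   \item SL, SW: longer/shorter side of the minimum-area rotated bounding
#'     rectangle of the pixel set (um)
#'   \item GCPA: guard-cell-and-pore pixel count x scale^2; SCA = SA - GCPA
#'   \item SR: circularity 4*pi*SA / SP^2 (1 for a circle)
#'   \item SE: moment-ellipse eccentricity sqrt(1 - l2/l1)
#'   \item PGCPA = GCPA/SA; PSCA = SCA/SA (so PGCPA + PSCA = 1)
#' }
#'
#' @param inst a [StomaInstance-class].
#' @param umPerPx micrometres per pixel of the source grid.
#' @return one-row data.frame with the 10 per-stoma trait columns plus
#'   \code{label} and \code{borderTouching}.
#' @export
measureStoma <- function(inst, umPerPx) {
  stopifnot(is(inst, "StomaInstance"), umPerPx > 0)
  if (length(inst@pixels) == 0L) stop("empty instance cannot be measured")
  s <- umPerPx
  w <- arrayInd(inst@pixels, inst@maskDim)
  rows <- w[, 1]; cols <- w[, 2]
  r0 <- min(rows); c0 <- min(cols)
  sub <- matrix(0L, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
  sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- 1L
  SA <- length(inst@pixels) * s^2
  SP <- maskPerimeter(sub) * s
  rect <- minAreaRect(rows, cols) * s
  GCPA <- length(inst@gcpPixels) * s^2
  SCA <- SA - GCPA
  data.frame(
    label = inst@label,
    SW = rect[["short"]], SL = rect[["long"]], SA = SA, SP = SP,
    GCPA = GCPA, SCA = SCA,
    SR = 4 * pi * SA / SP^2,
    SE = momentEccentricity(rows, cols),
    PGCPA = GCPA / SA, PSCA = SCA / SA,
    borderTouching = inst@borderTouching)
}

#' Trait table for a set of extracted stomata
#'
#' Applies [measureStoma()] to every instance, honouring the border policy
#' (under \code{"drop_for_traits"}, frame-truncated instances are excluded
#' from the size/shape table since their geometry is clipped), and attaches
#' the field-of-view stomatal density and grouping keys so the result is a
#' complete 11-trait table.
#'
#' @param instances list of [StomaInstance-class] (as from [labelStomata()]).
#' @param umPerPx micrometres per pixel.
#' @param SD field-of-view stomatal density to attach (per mm^2).
#' @param borderPolicy overrides the policy recorded on \code{instances}.
#' @param cultivar,sampling_day,layer,replicate,field_of_view grouping keys.
#' @return data.frame with the 11 trait columns plus grouping keys.
#' @export
stomaTraitTable <- function(instances, umPerPx, SD = NA_real_,
                            borderPolicy = NULL,
                            cultivar = "unknown", sampling_day = 1L,
                            layer = "middle", replicate = 1L,
                            field_of_view = 1L) {
  if (is.null(borderPolicy))
    borderPolicy <- attr(instances, "borderPolicy") %||% "drop_for_traits"
  recs <- lapply(instances, measureStoma, umPerPx = umPerPx)
  tab <- if (length(recs)) do.call(rbind, recs) else
    measureStomaEmpty()
  if (borderPolicy == "drop_for_traits")
    tab <- tab[!tab$borderTouching, , drop = FALSE]
  rownames(tab) <- NULL
  cbind(data.frame(cultivar = cultivar, sampling_day = sampling_day,
                   layer = layer, replicate = replicate,
                   field_of_view = field_of_view)[rep(1L, nrow(tab)), ,
                                                  drop = FALSE],
        SD = rep(SD, nrow(tab)), tab, row.names = NULL)
}

measureStomaEmpty <- function() {
  data.frame(label = integer(0), SW = numeric(0), SL = numeric(0),
             SA = numeric(0), SP = numeric(0), GCPA = numeric(0),
             SCA = numeric(0), SR = numeric(0), SE = numeric(0),
             PGCPA = numeric(0), PSCA = numeric(0),
             borderTouching = logical(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Circularity (roundness) of a shape
#'
#' SR = 4*pi*SA / SP^2: 1 for a perfect circle, pi/4 for a square, smaller
#' for elongated shapes (isoperimetric inequality).
#'
#' @param SA area (um^2), positive.
#' @param SP perimeter (um), positive.
#' @return the dimensionless roundness.
#' @examples
#' roundness(pi * 50^2, 2 * pi * 50)  # circle: 1
#' roundness(4140.05, 288.45)         # published cultivar-mean check: 0.63
#' @export
roundness <- function(SA, SP) {
  if (any(SA <= 0) || any(SP <= 0))
    stop("'SA' and 'SP' must be positive")
  4 * pi * SA / SP^2
}

#' Aggregate a trait table into grouped mean +/- SD summaries
#'
#' Per-group mean, sample standard deviation (n - 1 denominator; reported
#' as 0 when n = 1, with the singleton flagged) and count for each trait
#' column present, in stable (sorted) group order.
#'
#' @param table a trait data.frame.
#' @param by character vector of grouping columns.
#' @param traits trait columns to summarise (defaults to the 11 standard
#'   ones that are present).
#' @return long-format data.frame: grouping keys, trait, mean, sd, n,
#'   singleton.
#' @export
aggregateTraits <- function(table, by,
                            traits = intersect(TRAIT_COLUMNS, names(table))) {
  stopifnot(all(by %in% names(table)), length(traits) > 0)
  if (nrow(table) == 0L) stop("cannot aggregate an empty trait table")
  key <- interaction(table[by], drop = TRUE, lex.order = TRUE)
  groups <- sort(unique(as.character(key)))
  out <- list()
  for (g in groups) {
    sel <- as.character(key) == g
    keyRow <- table[which(sel)[1], by, drop = FALSE]
    for (tr in traits) {
      v <- table[[tr]][sel]
      v <- v[!is.na(v)]
      n <- length(v)
      out[[length(out) + 1L]] <- cbind(
        keyRow,
        data.frame(trait = tr, mean = mean(v),
                   sd = if (n > 1L) stats::sd(v) else 0,
                   n = n, singleton = n == 1L),
        row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
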