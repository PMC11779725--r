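#' @include AllClasses.R
NULL

#' Dice coefficient, IoU and Dice loss between binary masks
#'
#' Set-overlap similarity between a predicted mask X and a reference mask
#' Y on one pixel grid:
#' \deqn{DICE = 2|X \cap Y| / (|X| + |Y|), \quad IOU = |X \cap Y| / |X \cup Y|}
#' with the algebraic identity IOU = DICE / (2 - DICE), and
#' \code{diceLoss = 1 - DICE}. When both masks are empty the similarity is
#' defined as 1 (perfect agreement on absence) with a warning.
#'
#' @param x,y binary matrices (nonzero = foreground) of equal shape.
#' @return a number in [0, 1] (\code{diceLoss}: in [0, 1] as 1 - Dice).
#' @examples
#' a <- matrix(0, 4, 4); a[1:2, 1] <- 1
#' b <- matrix(0, 4, 4); b[2:3, 1] <- 1
#' dice(a, b)  # 0.5
#' iou(a, b)   # 1/3
#' @export
dice <- function(x, y) {
  o <- maskOverlapCounts(x, y)
  if (o["nx"] + o["ny"] == 0) {
    warning("both masks empty: Dice defined as 1")
    return(1)
  }
  unname(2 * o["inter"] / (o["nx"] + o["ny"]))
}

#' @rdname dice
#' @export
iou <- function(x, y) {
  o <- maskOverlapCounts(x, y)
  u <- o["nx"] + o["ny"] - o["inter"]
  if (u == 0) {
    warning("both masks empty: IoU defined as 1")
    return(1)
  }
  unname(o["inter"] / u)
}

#' @rdname dice
#' @export
diceLoss <- function(x, y) 1 - dice(x, y)

maskOverlapCounts <- function(x, y) {
  if (!identical(dim(x), dim(y)))
    stop("mask shapes differ: ", paste(dim(x), collapse = "x"), " vs ",
         paste(dim(y), collapse = "x"))
  bx <- x != 0; by <- y != 0
  c(inter = sum(bx & by), nx = sum(bx), ny = sum(by))
}

#' Reliability regression of automated against manual measurements
#'
#' Ordinary least-squares fit of the manual values on the automated
#' outputs, reporting the coefficient of determination (equal to the
#' squared Pearson correlation for simple OLS) and the root-mean-square
#' error of the raw automated/manual pairs:
#' \deqn{RMSE = \sqrt{\sum_i (x_i - y_i)^2 / n}}
#'
#' @param x automated output values (n >= 3, finite, non-constant).
#' @param y manually measured values, same length.
#' @return list with \code{r_squared}, \code{rmse}, \code{slope},
#'   \code{intercept}, \code{n}.
#' @examples
#' fitReliability(c(1, 2, 3), c(2, 3, 4))  # R^2 = 1, RMSE = 1
#' @export
fitReliability <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("at least 3 finite pairs are required")
  if (stats::var(x) == 0) stop("zero variance in automated values")
  fit <- stats::lm(y ~ x)
  list(r_squared = unname(stats::cor(x, y)^2),
       rmse = sqrt(sum((x - y)^2) / n),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = n)
}
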