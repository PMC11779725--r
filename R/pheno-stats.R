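#' @include AllClasses.R annotations-io.R
NULL

#' Pearson correlation matrix over trait columns
#'
#' Pairwise-complete Pearson correlations with two-sided p-values from the
#' t distribution on n - 2 degrees of freedom. A zero-variance trait gives
#' NA for its pairs, with the reason recorded rather than silently dropped.
#'
#' @param table a trait data.frame.
#' @param traits columns to correlate (default: the 11 standard trait
#'   columns present in the table).
#' @return object of class \code{"corrMatrix"}: list with symmetric
#'   matrices \code{r}, \code{p}, \code{n}, and \code{reasons} (character
#'   notes for undefined entries).
#' @export
pearsonMatrix <- function(table,
                          traits = intersect(TRAIT_COLUMNS, names(table))) {
  stopifnot(length(traits) >= 2)
  k <- length(traits)
  X <- as.matrix(table[traits])
  if (sum(stats::complete.cases(X)) < 3)
    stop("at least 3 complete rows are required")
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  reasons <- character(0)
  diag(r) <- 1; diag(p) <- 0
  diag(n) <- colSums(!is.na(X))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- is.finite(X[, i]) & is.finite(X[, j])
    nij <- sum(ok)
    n[i, j] <- n[j, i] <- nij
    if (nij < 3) {
      reasons <- c(reasons, paste0(traits[i], "~", traits[j],
                                   ": fewer than 3 complete pairs"))
      next
    }
    if (stats::sd(X[ok, i]) == 0 || stats::sd(X[ok, j]) == 0) {
      reasons <- c(reasons, paste0(traits[i], "~", traits[j],
                                   ": zero-variance trait"))
      next
    }
    rij <- stats::cor(X[ok, i], X[ok, j])
    r[i, j] <- r[j, i] <- rij
    if (abs(rij) >= 1) {
      p[i, j] <- p[j, i] <- 0
    } else {
      tt <- rij * sqrt((nij - 2) / (1 - rij^2))
      p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), nij - 2)
    }
  }
  structure(list(r = r, p = p, n = n, reasons = reasons),
            class = "corrMatrix")
}

#' @export
print.corrMatrix <- function(x, digits = 3, ...) {
  cat("Pearson correlation matrix (", ncol(x$r), " traits)\n", sep = "")
  print(round(x$r, digits))
  if (length(x$reasons))
    cat("undefined pairs:\n ", paste(x$reasons, collapse = "\n  "), "\n")
  invisible(x)
}

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Fits a one-way ANOVA, runs Tukey's HSD on all group pairs at level
#' \code{alpha}, and summarises the pairwise pattern as a compact letter
#' display via the insert-and-absorb algorithm: two groups share a letter
#' if and only if their Tukey comparison is non-significant. Groups are
#' ordered by descending mean and lettering starts at "a".
#'
#' @param values numeric response.
#' @param groups grouping factor (>= 2 observations per group when more
#'   than one group is present).
#' @param alpha significance level for the pairwise comparisons.
#' @return object of class \code{"cldResult"}: data.frame \code{display}
#'   (group, mean, n, letters, descending mean order), plus \code{fStat},
#'   \code{pValue} of the overall test, the Tukey p-value matrix
#'   \code{pTukey}, and \code{alpha}.
#' @examples
#' v <- c(rnorm(20, 0, .1), rnorm(20, 0, .1), rnorm(20, 10, .1))
#' g <- rep(c("A", "B", "C"), each = 20)
#' anovaCld(v, g)$display
#' @export
anovaCld <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  lev <- levels(groups)
  nPer <- table(groups)
  if (length(lev) == 1L) {
    return(structure(list(
      display = data.frame(group = lev, mean = mean(values),
                           n = as.integer(nPer), letters = "a"),
      fStat = NA_real_, pValue = NA_real_, pTukey = NULL, alpha = alpha),
      class = "cldResult"))
  }
  if (any(nPer < 2L))
    stop("every group needs at least 2 observations (offending: ",
         paste(names(nPer)[nPer < 2], collapse = ", "), ")")
  fit <- stats::aov(values ~ groups, data = data.frame(values, groups))
  an <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  k <- length(lev)
  pmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  diag(pmat) <- 1
  prs <- strsplit(rownames(tuk), "-", fixed = TRUE)
  for (i in seq_along(prs)) {
    a <- prs[[i]][1]; b <- prs[[i]][2]
    pmat[a, b] <- pmat[b, a] <- tuk[i, "p adj"]
  }
  means <- tapply(values, groups, mean)
  ord <- order(-means)
  levOrd <- lev[ord]
  sig <- pmat[levOrd, levOrd, drop = FALSE] < alpha
  letters <- insertAbsorbCld(sig)
  structure(list(
    display = data.frame(group = levOrd, mean = as.numeric(means[ord]),
                         n = as.integer(nPer[ord]), letters = letters,
                         row.names = NULL),
    fStat = an[["F value"]][1], pValue = an[["Pr(>F)"]][1],
    pTukey = pmat, alpha = alpha), class = "cldResult")
}

#' @export
print.cldResult <- function(x, ...) {
  cat("One-way ANOVA with Tukey HSD letters (alpha =", x$alpha, ")\n")
  if (!is.na(x$fStat))
    cat(sprintf("F = %.3f, p = %.4g\n", x$fStat, x$pValue))
  print(x$display)
  invisible(x)
}

# Insert-and-absorb compact letter display. sig: k x k logical matrix of
# significant pairs, groups already in display (descending-mean) order.
# Returns one letter string per group; groups share a letter iff their
# comparison is non-significant.
insertAbsorbCld <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k))          # start: one letter containing all groups
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!isTRUE(sig[i, j])) next
    touched <- FALSE
    newCols <- list()
    for (cc in cols) {
      if (i %in% cc && j %in% cc) {
        touched <- TRUE
        newCols <- c(newCols, list(setdiff(cc, i)), list(setdiff(cc, j)))
      } else newCols <- c(newCols, list(cc))
    }
    if (touched) {
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(newCols))
      for (a in seq_along(newCols)) for (b in seq_along(newCols)) {
        if (a != b && keep[a] && keep[b] &&
            all(newCols[[a]] %in% newCols[[b]]) &&
            !(length(newCols[[a]]) == length(newCols[[b]]) && a < b))
          keep[a] <- FALSE
      }
      cols <- newCols[keep]
    }
  }
  # letter order: by the best-ranked (lowest index) group in each column
  ordCols <- order(vapply(cols, min, numeric(1)))
  cols <- cols[ordCols]
  out <- character(k)
  for (ci in seq_along(cols))
    for (g in cols[[ci]])
      out[g] <- paste0(out[g], letters[ci])
  out
}

#' PCA of z-scored traits via the correlation matrix
#'
#' Standardizes each trait to zero mean and unit sample variance (n - 1
#' denominator), eigendecomposes the correlation matrix, and reports
#' eigenvalues, loadings (eigenvectors with a deterministic sign
#' convention: the largest-magnitude loading of each component is
#' positive), per-component variance contribution ratios (summing to
#' 100\%), cumulative ratios, and the component scores of every row.
#'
#' @param table a trait data.frame.
#' @param traits columns to use (default: standard trait columns present).
#'   Zero-variance traits are dropped with a warning.
#' @return object of class \code{"stomataPCA"}: list with
#'   \code{eigenvalues}, \code{loadings}, \code{contributions},
#'   \code{cumulative}, \code{scores}, \code{traits}.
#' @export
pcaTraits <- function(table,
                      traits = intersect(TRAIT_COLUMNS, names(table))) {
  X <- as.matrix(table[traits])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3L) stop("at least 3 complete rows are required")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance trait(s): ",
            paste(traits[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    traits <- colnames(X)
  }
  if (ncol(X) < 2L) stop("at least 2 non-constant traits are required")
  Z <- scale(X)                      # sample sd (n - 1)
  C <- stats::cor(X)
  ev <- eigen(C, symmetric = TRUE)
  V <- ev$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(traits, paste0("PC", seq_len(ncol(V))))
  lambda <- pmax(ev$values, 0)
  contrib <- lambda / length(traits) * 100
  structure(list(
    eigenvalues = lambda,
    loadings = V,
    contributions = contrib,
    cumulative = cumsum(contrib),
    scores = Z %*% V,
    traits = traits), class = "stomataPCA")
}

#' @export
print.stomataPCA <- function(x, ...) {
  cat("PCA of", length(x$traits), "z-scored traits\n")
  print(data.frame(eigenvalue = round(x$eigenvalues, 4),
                   contribution = round(x$contributions, 2),
                   cumulative = round(x$cumulative, 2)))
  invisible(x)
}

#' Heterosis rates of a hybrid relative to its parents
#'
#' For an F1 hybrid mean and its two parental means, the three standard
#' conventions:
#' \itemize{
#'   \item mid-parent rate: \code{(F1 - MP) / MP}, MP = (P1 + P2)/2
#'   \item over-high-parent rate: \code{(F1 - max(P1, P2)) / max(P1, P2)}
#'   \item over-low-parent rate: \code{(F1 - min(P1, P2)) / min(P1, P2)}
#' }
#' All three are scale-invariant. A positive over-high-parent rate means
#' the hybrid exceeds its better parent ("super-parental" heterosis); a
#' negative mid-parent rate means it falls below the parental average.
#'
#' @param f1,p1,p2 positive trait means (vectorized over traits).
#' @param trait optional trait labels.
#' @return data.frame with the means and the three rates per trait.
#' @examples
#' heterosisRates(74.95, 87.21, 78.64, trait = "SD")  # mid-parent -0.096
#' @export
heterosisRates <- function(f1, p1, p2, trait = NULL) {
  if (any(p1 <= 0) || any(p2 <= 0))
    stop("parent means must be positive")
  mp <- (p1 + p2) / 2
  hi <- pmax(p1, p2); lo <- pmin(p1, p2)
  data.frame(
    trait = if (is.null(trait)) paste0("trait", seq_along(f1)) else trait,
    F1 = f1, P1 = p1, P2 = p2,
    midParentRate = (f1 - mp) / mp,
    overHighParentRate = (f1 - hi) / hi,
    overLowParentRate = (f1 - lo) / lo)
}
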