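# Independent brute-force oracles used to cross-check the implementation.

TRAIT_COLUMNS_EXPECTED <- c("SD", "SW", "SL", "SA", "SP", "GCPA", "SCA",
                            "SR", "SE", "PGCPA", "PSCA")

# --- 8-connected components by BFS flood fill ----------------------------
floodFill8 <- function(mask) {
  mask <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (start in which(mask == 1L)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        idx <- (cc - 1L) * nr + rr
        if (mask[idx] == 1L && !seen[idx]) {
          seen[idx] <- TRUE
          queue <- c(queue, idx)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# canonical form of a pixel partition for set comparison
partitionKey <- function(comps) {
  sort(vapply(comps, function(x) paste(x, collapse = ","), character(1)))
}

# --- independent marching-squares contour walk ---------------------------
# Builds the 0.5-level segments cell by cell from the standard case table,
# chains them into loops, picks the largest loop, applies the same 1-2-1
# vertex smoothing, and measures length. Shapes used with this oracle must
# not contain saddle cells (convex blobs with axes >= 4 px are safe).
msPerimeterOracle <- function(mask, smoothIters = 3L) {
  b <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  pad <- matrix(0L, nrow(b) + 4L, ncol(b) + 4L)
  pad[3:(2 + nrow(b)), 3:(2 + ncol(b))] <- b
  nr <- nrow(pad); nc <- ncol(pad)
  segs <- list()
  for (i in seq_len(nr - 1)) for (j in seq_len(nc - 1)) {
    v00 <- pad[i, j]; v01 <- pad[i, j + 1]
    v10 <- pad[i + 1, j]; v11 <- pad[i + 1, j + 1]
    code <- v00 + 2 * v01 + 4 * v10 + 8 * v11
    if (code %in% c(0L, 15L)) next
    # edge midpoints in (x = row, y = col) coordinates
    top <- c(i, j + 0.5); bottom <- c(i + 1, j + 0.5)
    left <- c(i + 0.5, j); right <- c(i + 0.5, j + 1)
    add <- function(p, q) segs[[length(segs) + 1L]] <<- c(p, q)
    if (code %in% c(1L, 14L)) add(top, left)
    else if (code %in% c(2L, 13L)) add(top, right)
    else if (code %in% c(3L, 12L)) add(left, right)
    else if (code %in% c(4L, 11L)) add(bottom, left)
    else if (code %in% c(7L, 8L)) add(bottom, right)
    else if (code %in% c(5L, 10L)) add(top, bottom)
    else stop("saddle cell encountered; oracle undefined")
  }
  key <- function(p) sprintf("%.4f_%.4f", p[1], p[2])
  adj <- new.env()
  for (k in seq_along(segs)) {
    s <- segs[[k]]
    for (ends in list(c(1, 2, 3, 4), c(3, 4, 1, 2))) {
      a <- key(s[ends[1:2]])
      adj[[a]] <- c(adj[[a]], k)
    }
  }
  used <- rep(FALSE, length(segs))
  loops <- list()
  for (k0 in seq_along(segs)) {
    if (used[k0]) next
    pts <- list(segs[[k0]][1:2], segs[[k0]][3:4])
    used[k0] <- TRUE
    repeat {
      cur <- pts[[length(pts)]]
      cand <- adj[[key(cur)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      k <- cand[1]
      s <- segs[[k]]
      nxt <- if (identical(key(s[1:2]), key(cur))) s[3:4] else s[1:2]
      used[k] <- TRUE
      if (identical(key(nxt), key(pts[[1]]))) break
      pts[[length(pts) + 1L]] <- nxt
    }
    loops[[length(loops) + 1L]] <- do.call(rbind, pts)
  }
  area <- vapply(loops, function(m) {
    x <- m[, 1]; y <- m[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1))
  m <- loops[[which.max(area)]]
  x <- m[, 1]; y <- m[, 2]; n <- length(x)
  for (it in seq_len(smoothIters)) {
    xs <- (x[c(n, 1:(n - 1))] + 2 * x + x[c(2:n, 1)]) / 4
    ys <- (y[c(n, 1:(n - 1))] + 2 * y + y[c(2:n, 1)]) / 4
    x <- xs; y <- ys
  }
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# --- all-point-interpolation AP by the per-truth formulation -------------
# AP = (1/m) * sum over t = 1..m of the best precision among prefixes
# that have recovered at least t truths (0 if t is never reached).
apOracle <- function(isMatch, mTruth) {
  n <- length(isMatch)
  if (mTruth == 0 || n == 0) return(if (mTruth == 0 && n == 0) 1 else 0)
  cum <- cumsum(isMatch)
  prec <- cum / seq_len(n)
  vals <- vapply(seq_len(mTruth), function(t) {
    ok <- cum >= t
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1))
  mean(vals)
}

# --- misc fixture builders ------------------------------------------------
ellipseMask <- function(a, b, nr = NULL, nc = NULL, cx = NULL, cy = NULL,
                        theta = 0) {
  if (is.null(nr)) nr <- ceiling(2 * max(a, b)) + 8
  if (is.null(nc)) nc <- nr
  if (is.null(cx)) cx <- nc / 2
  if (is.null(cy)) cy <- nr / 2
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  dx <- g$col - cx; dy <- g$row - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  matrix(as.integer((u / a)^2 + (v / b)^2 <= 1), nr, nc)
}

randomMask <- function(nr, nc, p = 0.4) {
  matrix(rbinom(nr * nc, 1, p), nr, nc)
}

randomBox <- function(lim = 40) {
  x <- sort(sample(0:lim, 2)); y <- sort(sample(0:lim, 2))
  if (x[2] == x[1]) x[2] <- x[1] + 1
  if (y[2] == y[1]) y[2] <- y[1] + 1
  c(x[1], y[1], x[2], y[2])
}

# instance in a standalone grid from a mask + gcp mask
makeInstance <- function(mask, gcp = NULL) {
  if (is.null(gcp)) gcp <- matrix(0L, nrow(mask), ncol(mask))
  inst <- labelStomata(mask, gcp, borderPolicy = "keep")
  stopifnot(length(inst) == 1L)
  inst[[1]]
}
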