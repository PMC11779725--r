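# Internal helpers shared across modules.

# Evaluate expr under a private RNG stream, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# 0/1 integer matrix from any numeric/logical matrix (nonzero = foreground).
asBinary <- function(m) {
  stopifnot(is.matrix(m))
  b <- matrix(as.integer(m != 0), nrow(m), ncol(m))
  b
}

# Exact ellipse circumference for semi-axes a >= b (numeric quadrature).
ellipsePerimeter <- function(a, b) {
  stopifnot(a > 0, b > 0)
  4 * stats::integrate(function(t) sqrt((a * sin(t))^2 + (b * cos(t))^2),
                       0, pi / 2, rel.tol = 1e-12)$value
}

# Label 8-connected components of a binary matrix. EBImage::bwlabel is
# 4-connected, so diagonal-only neighbours are merged with a union-find pass;
# labels are renumbered 1..k in scan (column-major) order of first pixel.
label8 <- function(mask) {
  b <- asBinary(mask)
  if (!any(b == 1L)) return(matrix(0L, nrow(b), ncol(b)))
  lab <- EBImage::bwlabel(t(b))       # EBImage images are [x, y]
  lab <- t(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  nr <- nrow(lab); nc <- ncol(lab)
  parent <- seq_len(max(lab))
  findRoot <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- findRoot(i); rj <- findRoot(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  if (nr > 1L && nc > 1L) {
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right diagonal
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # down-left diagonal
    pairs <- rbind(
      cbind(as.vector(a1), as.vector(b1)),
      cbind(as.vector(a2), as.vector(b2)))
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                   drop = FALSE]
    if (nrow(pairs) > 0L) {
      pairs <- unique(pairs)
      for (k in seq_len(nrow(pairs))) unite(pairs[k, 1], pairs[k, 2])
    }
  }
  roots <- vapply(seq_along(parent), findRoot, integer(1))
  merged <- matrix(0L, nr, nc)
  nz <- lab > 0L
  merged[nz] <- roots[lab[nz]]
  # renumber by first occurrence in column-major scan order
  ids <- merged[nz]
  first <- !duplicated(ids)
  remap <- integer(max(merged))
  remap[ids[first]] <- seq_len(sum(first))
  merged[nz] <- remap[ids]
  merged
}

# Tight 0-based half-open bbox of TRUE cells given (row, col) indices.
pixelBbox <- function(rows, cols) {
  c(x0 = min(cols) - 1, y0 = min(rows) - 1, x1 = max(cols), y1 = max(rows))
}
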