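#' @include AllClasses.R
NULL

# The 11 trait columns every trait table must carry (field abbreviations).
TRAIT_COLUMNS <- c("SD", "SW", "SL", "SA", "SP", "GCPA", "SCA",
                   "SR", "SE", "PGCPA", "PSCA")

# Grouping keys carried alongside the traits when present.
TRAIT_GROUP_KEYS <- c("cultivar", "sampling_day", "layer", "replicate",
                      "field_of_view")

POLYGON_LABELS <- c("stomatal_complex", "guard_cell_and_pore")

#' Parse and write YOLO-format bounding boxes
#'
#' YOLO box files carry one line per box: \code{class cx cy w h [conf]},
#' all coordinates normalized to [0, 1] relative to the image frame.
#' Parsing converts to 0-based half-open pixel boxes via
#' \code{x0 = round((cx - w/2) * W)} (and likewise for the other edges);
#' writing is the inverse and round-trips within one pixel.
#'
#' @param text character vector of lines, or a length-1 path to a file.
#' @param imageW,imageH image dimensions in pixels.
#' @return \code{parseYoloBoxes}: data.frame with columns class, x0, y0,
#'   x1, y1 and confidence (NA when absent).
#' @export
parseYoloBoxes <- function(text, imageW, imageH) {
  stopifnot(imageW >= 1, imageH >= 1)
  if (length(text) == 1L && file.exists(text)) text <- readLines(text)
  text <- text[nzchar(trimws(text))]
  out <- data.frame(class = integer(0), x0 = numeric(0), y0 = numeric(0),
                    x1 = numeric(0), y1 = numeric(0), confidence = numeric(0))
  for (i in seq_along(text)) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(text[i]), "\\s+")[[1]]))
    if (length(f) < 5L || length(f) > 6L || any(is.na(f)))
      stop("malformed YOLO line ", i, ": '", text[i], "'")
    cx <- f[2]; cy <- f[3]; w <- f[4]; h <- f[5]
    if (any(c(cx, cy, w, h) < 0) || any(c(cx, cy, w, h) > 1))
      stop("YOLO line ", i, ": normalized values outside [0, 1]")
    x0 <- round((cx - w / 2) * imageW); x1 <- round((cx + w / 2) * imageW)
    y0 <- round((cy - h / 2) * imageH); y1 <- round((cy + h / 2) * imageH)
    if (x1 <= x0 || y1 <= y0)
      stop("YOLO line ", i, ": degenerate (zero-area) box")
    conf <- if (length(f) == 6L) f[6] else NA_real_
    if (!is.na(conf) && (conf < 0 || conf > 1))
      stop("YOLO line ", i, ": confidence outside [0, 1]")
    out[nrow(out) + 1L, ] <- list(as.integer(f[1]), x0, y0, x1, y1, conf)
  }
  out
}

#' @rdname parseYoloBoxes
#' @param boxes data.frame with columns x0, y0, x1, y1, optional class and
#'   confidence.
#' @param path optional file to write to.
#' @return \code{writeYoloBoxes}: the lines, invisibly if written to a file.
#' @export
writeYoloBoxes <- function(boxes, imageW, imageH, path = NULL) {
  cls <- if ("class" %in% names(boxes)) boxes$class else rep(0L, nrow(boxes))
  lines <- character(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    cx <- (boxes$x0[i] + boxes$x1[i]) / 2 / imageW
    cy <- (boxes$y0[i] + boxes$y1[i]) / 2 / imageH
    w <- (boxes$x1[i] - boxes$x0[i]) / imageW
    h <- (boxes$y1[i] - boxes$y0[i]) / imageH
    lines[i] <- sprintf("%d %.8f %.8f %.8f %.8f", cls[i], cx, cy, w, h)
    if ("confidence" %in% names(boxes) && !is.na(boxes$confidence[i]))
      lines[i] <- sprintf("%s %.8f", lines[i], boxes$confidence[i])
  }
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Parse, write and rasterize labelme-style polygon annotations
#'
#' Polygon annotation documents carry a list of labelled polygons
#' (\code{shapes}, each with a \code{label} and a vertex list in pixel
#' coordinates) plus the image dimensions. Accepted labels are
#' \code{"stomatal_complex"} and \code{"guard_cell_and_pore"}.
#'
#' @param doc a JSON string, a path to a JSON file, or a parsed list.
#' @return \code{parsePolygons}: list with \code{shapes} (each a list with
#'   \code{label} and an n x 2 vertex matrix \code{points}),
#'   \code{imageWidth}, \code{imageHeight}.
#' @export
parsePolygons <- function(doc) {
  if (is.character(doc) && length(doc) == 1L) {
    parsed <- jsonlite::fromJSON(doc, simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  } else parsed <- doc
  shapes <- lapply(parsed$shapes, function(s) {
    if (!s$label %in% POLYGON_LABELS)
      stop("unknown polygon label '", s$label, "'; accepted labels: ",
           paste(POLYGON_LABELS, collapse = ", "))
    pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p))))
    list(label = s$label, points = pts)
  })
  list(shapes = shapes,
       imageWidth = as.integer(parsed$imageWidth),
       imageHeight = as.integer(parsed$imageHeight))
}

#' @rdname parsePolygons
#' @param polygons a polygon set as returned by \code{parsePolygons}.
#' @param path optional file to write the JSON document to.
#' @export
writePolygons <- function(polygons, path = NULL) {
  doc <- list(
    shapes = lapply(polygons$shapes, function(s) list(
      label = s$label,
      points = lapply(seq_len(nrow(s$points)),
                      function(i) as.numeric(s$points[i, ])),
      shape_type = "polygon")),
    imageWidth = polygons$imageWidth,
    imageHeight = polygons$imageHeight)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(json, path); return(invisible(json)) }
  json
}

# Even-odd (crossing number) point-in-polygon test for pixel centres.
# pts: n x 2 polygon vertices; cx, cy: query coordinates (vectors).
pointsInPolygonEvenOdd <- function(cx, cy, pts) {
  n <- nrow(pts)
  inside <- rep(FALSE, length(cx))
  j <- n
  for (i in seq_len(n)) {
    xi <- pts[i, 1]; yi <- pts[i, 2]; xj <- pts[j, 1]; yj <- pts[j, 2]
    crosses <- ((yi > cy) != (yj > cy)) &
      (cx < (xj - xi) * (cy - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' @rdname parsePolygons
#' @param imageShape integer (nrow, ncol) of the target mask grid.
#' @return \code{polygonsToMasks}: a [MaskPair-class]-shaped list with 0/1
#'   matrices \code{complexMask} and \code{gcpMask}. Polygon interiors are
#'   filled under the even-odd rule; a pixel is foreground when its centre
#'   lies inside. Guard-cell-and-pore pixels outside any complex are kept
#'   (mask fusion reconciles the layers downstream).
#' @export
polygonsToMasks <- function(polygons, imageShape) {
  nr <- imageShape[1]; nc <- imageShape[2]
  complexMask <- matrix(0L, nr, nc)
  gcpMask <- matrix(0L, nr, nc)
  for (s in polygons$shapes) {
    pts <- s$points
    x0 <- max(1L, floor(min(pts[, 1]) + 0.5))
    x1 <- min(nc, ceiling(max(pts[, 1]) + 0.5))
    y0 <- max(1L, floor(min(pts[, 2]) + 0.5))
    y1 <- min(nr, ceiling(max(pts[, 2]) + 0.5))
    if (x1 < x0 || y1 < y0) next
    g <- expand.grid(col = x0:x1, row = y0:y1)
    inside <- pointsInPolygonEvenOdd(g$col - 0.5, g$row - 0.5, pts)
    idx <- cbind(g$row[inside], g$col[inside])
    if (s$label == "stomatal_complex") complexMask[idx] <- 1L
    else gcpMask[idx] <- 1L
  }
  list(complexMask = complexMask, gcpMask = gcpMask)
}

#' Read and write binary masks as 8-bit PNG
#'
#' Masks are stored as 0/255 single-channel 8-bit PNG; on read, any nonzero
#' gray level counts as foreground.
#'
#' @param mask a 0/1 (or logical) matrix.
#' @param path PNG file path.
#' @return \code{readMaskPng}: a 0/1 integer matrix.
#' @export
writeMaskPng <- function(mask, path) {
  b <- asBinary(mask)
  png::writePNG(b * 1.0, path)
  invisible(path)
}

#' @rdname writeMaskPng
#' @export
readMaskPng <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  matrix(as.integer(arr != 0), nrow(arr), ncol(arr))
}

#' Read and write trait tables as CSV
#'
#' A trait table carries one row per measured stoma (or per field of view
#' for density) with the 11 trait columns SD, SW, SL, SA, SP, GCPA, SCA,
#' SR, SE, PGCPA, PSCA plus any grouping keys (cultivar, sampling_day,
#' layer, replicate, field_of_view). Numeric values round-trip at full
#' binary precision; the column order is preserved.
#'
#' @param table a data.frame with (at least) the 11 trait columns.
#' @param path CSV file path.
#' @export
writeTraitCsv <- function(table, path) {
  missing <- setdiff(TRAIT_COLUMNS, names(table))
  if (length(missing))
    stop("trait table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  out <- table
  for (nm in names(out))
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeTraitCsv
#' @export
readTraitCsv <- function(path) {
  if (!file.exists(path)) stop("trait CSV not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  missing <- setdiff(TRAIT_COLUMNS, names(tab))
  if (length(missing))
    stop("trait CSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  for (nm in TRAIT_COLUMNS) tab[[nm]] <- as.numeric(tab[[nm]])
  tab
}
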