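#' @include AllClasses.R calibrated-image.R annotations-io.R
NULL

#' Construct generator parameters
#'
#' Builds a validated [SceneParams-class]. Defaults emulate the 350x
#' acquisition geometry (767 um x 767 um field, 1024 px frame) and realistic
#' maize abaxial-epidermis trait ranges: stomatal complexes about
#' 85-105 um long and 52-59 um wide, arranged in parallel longitudinal
#' files, at 70-95 stomata per mm^2, with the guard-cell-and-pore region
#' occupying about half of each complex.
#'
#' @param fieldWidthUm,fieldHeightUm physical field size, micrometres.
#' @param pixelsPerSide frame side length in pixels.
#' @param targetDensity target stomata per mm^2.
#' @param lengthDist,widthDist (mean, sd) of complex length/width, um.
#' @param gcpFractionDist (mean, sd) of the guard-cell-and-pore fraction.
#' @param orientationJitterDeg max deviation of long axes from the file
#'   direction, degrees (uniform jitter).
#' @param rowSpacingUm spacing between stomatal files, um.
#' @param intensityLevels named gray levels (background, subsidiary, gcp),
#'   pairwise >= 20 apart.
#' @param noiseSd sd of additive Gaussian gray-level noise.
#' @param seed integer seed (one private generator per scene).
#' @param allowBorderClipped allow frame-edge-clipped stomata (tests of the
#'   border policy); default FALSE.
#' @return a [SceneParams-class].
#' @examples
#' p <- sceneParams(targetDensity = 80, seed = 7)
#' p
#' @export
sceneParams <- function(fieldWidthUm = 767, fieldHeightUm = 767,
                        pixelsPerSide = 1024, targetDensity = 80,
                        lengthDist = c(95, 5), widthDist = c(55, 2),
                        gcpFractionDist = c(0.50, 0.02),
                        orientationJitterDeg = 6, rowSpacingUm = 78,
                        intensityLevels = c(background = 180,
                                            subsidiary = 120, gcp = 50),
                        noiseSd = 4, seed = 1L,
                        allowBorderClipped = FALSE) {
  new("SceneParams",
      fieldWidthUm = fieldWidthUm, fieldHeightUm = fieldHeightUm,
      pixelsPerSide = as.integer(pixelsPerSide),
      targetDensity = targetDensity,
      lengthDist = lengthDist, widthDist = widthDist,
      gcpFractionDist = gcpFractionDist,
      orientationJitterDeg = orientationJitterDeg,
      rowSpacingUm = rowSpacingUm, intensityLevels = intensityLevels,
      noiseSd = noiseSd, seed = as.integer(seed),
      allowBorderClipped = allowBorderClipped)
}

# truncated-normal draw via rejection (few iterations at 3 sd truncation)
rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' Generate a synthetic epidermis scene with exact ground truth
#'
#' Renders one abaxial-epidermis field of view: stomatal complexes are
#' ellipses placed on jittered parallel files (the longitudinal stomatal
#' rows of a grass leaf), each containing a concentric elliptical
#' guard-cell-and-pore region scaled to the requested area fraction; the
#' flanking remainder represents the subsidiary cells. Pixels are rendered
#' at three gray levels (background / subsidiary / guard-cell-and-pore),
#' Gaussian noise is added and clipped to [0, 255]. The number of stomata
#' is \code{round(targetDensity x field area in mm^2)} when geometrically
#' feasible; otherwise the maximum placeable number is used with a warning.
#' All randomness comes from one private generator seeded by
#' \code{params@seed}, so identical parameters give bit-identical scenes.
#'
#' @param params a [SceneParams-class].
#' @return a [SyntheticScene-class] carrying the rendered image, both
#'   ground-truth masks, tight non-overlapping bounding boxes and the
#'   analytic per-stoma trait table.
#' @examples
#' sc <- generateScene(sceneParams(pixelsPerSide = 256, fieldWidthUm = 300,
#'                                 fieldHeightUm = 300, targetDensity = 40,
#'                                 seed = 2))
#' sc
#' @export
generateScene <- function(params) {
  stopifnot(is(params, "SceneParams"))
  validObject(params)
  fw <- params@fieldWidthUm; fh <- params@fieldHeightUm
  np <- params@pixelsPerSide
  s <- fw / np
  areaMm2 <- fw * fh * 1e-6
  nTarget <- round(params@targetDensity * areaMm2)

  meanL <- params@lengthDist[1]; sdL <- params@lengthDist[2]
  meanW <- params@widthDist[1];  sdW <- params@widthDist[2]
  if (meanL + 3 * sdL >= 0.95 * min(fw, fh))
    stop("infeasible geometry: stomata (length ~", meanL,
         " um) are too large for a ", fw, " x ", fh, " um field")

  withLocalSeed(params@seed, {
    # --- jittered parallel files (vertical), slot grid along each file ---
    maxW <- meanW + 3 * sdW
    maxL <- meanL + 3 * sdL
    # minimum physical gap between neighbouring complexes: adjacent stomata
    # are separated by pavement cells, never abutting
    gapUm <- max(8, 2 * s)
    marginX <- maxW / 2 + 2 * s
    nFiles <- max(0L, floor((fw - 2 * marginX) / params@rowSpacingUm) + 1L)
    pitch <- maxL + gapUm + 2 * s
    nSlots <- max(0L, floor(fh / pitch))
    placed <- list()
    accepted <- matrix(numeric(0), 0, 4)  # um-space bboxes x0 y0 x1 y1
    if (nTarget > 0L && nFiles > 0L && nSlots > 0L) {
      xFiles <- (fw - (nFiles - 1) * params@rowSpacingUm) / 2 +
        (seq_len(nFiles) - 1) * params@rowSpacingUm +
        stats::runif(nFiles, -0.08, 0.08) * params@rowSpacingUm
      ySlots <- (fh - nSlots * pitch) / 2 + (seq_len(nSlots) - 0.5) * pitch
      slots <- expand.grid(file = seq_len(nFiles), slot = seq_len(nSlots))
      slots <- slots[sample(nrow(slots)), , drop = FALSE]
      jr <- params@orientationJitterDeg * pi / 180
      forceClip <- params@allowBorderClipped
      k <- 0L
      for (si in seq_len(nrow(slots))) {
        if (length(placed) >= nTarget) break
        ok <- FALSE
        for (try in 1:40) {
          L <- rtruncnorm1(meanL, sdL, meanL - 3 * sdL, meanL + 3 * sdL)
          W <- rtruncnorm1(meanW, sdW, meanW - 3 * sdW, min(meanW + 3 * sdW,
                                                           0.95 * L))
          f <- rtruncnorm1(params@gcpFractionDist[1], params@gcpFractionDist[2],
                           0.05, 0.95)
          th <- stats::runif(1, -jr, jr)
          a <- L / 2; b <- W / 2
          ex <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
          ey <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
          cx <- xFiles[slots$file[si]]
          cy <- ySlots[slots$slot[si]]
          if (forceClip && length(placed) == 0L) {
            cy <- 0  # first stoma straddles the top frame edge
          } else {
            freeY <- pitch / 2 - ey - gapUm / 2
            if (freeY > 0) cy <- cy + stats::runif(1, -freeY, freeY)
            freeX <- params@rowSpacingUm / 2 - ex - gapUm / 2
            if (freeX > 0) cx <- cx + stats::runif(1, -freeX, freeX) * 0.4
          }
          bb <- c(cx - ex, cy - ey, cx + ex, cy + ey)
          if (!forceClip || length(placed) > 0L) {
            if (bb[1] < s || bb[2] < s || bb[3] > fw - s || bb[4] > fh - s)
              next
          }
          if (nrow(accepted) > 0L) {
            ox <- pmin(accepted[, 3], bb[3]) - pmax(accepted[, 1], bb[1])
            oy <- pmin(accepted[, 4], bb[4]) - pmax(accepted[, 2], bb[2])
            if (any(ox > -gapUm & oy > -gapUm)) next
          }
          accepted <- rbind(accepted, bb)
          k <- k + 1L
          placed[[k]] <- list(cx = cx, cy = cy, a = a, b = b, f = f, th = th)
          ok <- TRUE
          break
        }
      }
    }
    nPlaced <- length(placed)
    if (nPlaced < nTarget)
      warning("requested ", nTarget, " stomata but only ", nPlaced,
              " could be placed without overlap")

    # --- rasterize masks and collect analytic truth ---
    complexMask <- matrix(0L, np, np)
    gcpMask <- matrix(0L, np, np)
    rows <- vector("list", nPlaced)
    for (i in seq_len(nPlaced)) {
      st <- placed[[i]]
      ex <- sqrt((st$a * sin(st$th))^2 + (st$b * cos(st$th))^2)
      ey <- sqrt((st$a * cos(st$th))^2 + (st$b * sin(st$th))^2)
      c0 <- max(1L, floor((st$cx - ex) / s)); c1 <- min(np, ceiling((st$cx + ex) / s) + 1L)
      r0 <- max(1L, floor((st$cy - ey) / s)); r1 <- min(np, ceiling((st$cy + ey) / s) + 1L)
      cc <- c0:c1; rr <- r0:r1
      pxX <- (cc - 0.5) * s; pxY <- (rr - 0.5) * s
      dx <- outer(rep(1, length(rr)), pxX - st$cx)
      dy <- outer(pxY - st$cy, rep(1, length(cc)))
      u <- dx * sin(st$th) + dy * cos(st$th)   # along the long axis
      v <- dx * cos(st$th) - dy * sin(st$th)
      insideC <- (u / st$a)^2 + (v / st$b)^2 <= 1
      ag <- st$a * sqrt(st$f); bg <- st$b * sqrt(st$f)
      insideG <- (u / ag)^2 + (v / bg)^2 <= 1
      if (!any(insideC)) next
      sub <- complexMask[rr, cc]; sub[insideC] <- 1L; complexMask[rr, cc] <- sub
      sub <- gcpMask[rr, cc]; sub[insideG] <- 1L; gcpMask[rr, cc] <- sub
      w <- which(insideC, arr.ind = TRUE)
      bboxPx <- pixelBbox(rr[w[, 1]], cc[w[, 2]])
      SA <- pi * st$a * st$b
      SP <- ellipsePerimeter(st$a, st$b)
      border <- bboxPx["x0"] <= 0 || bboxPx["y0"] <= 0 ||
        bboxPx["x1"] >= np || bboxPx["y1"] >= np
      rows[[i]] <- data.frame(
        stoma = i, centerXUm = st$cx, centerYUm = st$cy,
        orientationDeg = st$th * 180 / pi,
        SL = 2 * st$a, SW = 2 * st$b, SA = SA, SP = SP,
        GCPA = st$f * SA, SCA = (1 - st$f) * SA,
        SR = 4 * pi * SA / SP^2, SE = sqrt(1 - (st$b / st$a)^2),
        PGCPA = st$f, PSCA = 1 - st$f,
        pixelArea = sum(insideC), gcpPixelArea = sum(insideG),
        x0 = bboxPx[["x0"]], y0 = bboxPx[["y0"]],
        x1 = bboxPx[["x1"]], y1 = bboxPx[["y1"]],
        borderTouching = border)
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(stoma = integer(0), centerXUm = numeric(0),
                 centerYUm = numeric(0), orientationDeg = numeric(0),
                 SL = numeric(0), SW = numeric(0), SA = numeric(0),
                 SP = numeric(0), GCPA = numeric(0), SCA = numeric(0),
                 SR = numeric(0), SE = numeric(0), PGCPA = numeric(0),
                 PSCA = numeric(0), pixelArea = numeric(0),
                 gcpPixelArea = numeric(0), x0 = numeric(0), y0 = numeric(0),
                 x1 = numeric(0), y1 = numeric(0), borderTouching = logical(0))
    rownames(truth) <- NULL

    # --- render intensities ---
    iv <- params@intensityLevels
    img <- matrix(iv[["background"]], np, np)
    img[complexMask == 1L] <- iv[["subsidiary"]]
    img[gcpMask == 1L] <- iv[["gcp"]]
    if (params@noiseSd > 0)
      img <- img + matrix(stats::rnorm(np * np, 0, params@noiseSd), np, np)
    img <- round(pmin(pmax(img, 0), 255))

    cimg <- new("CalibratedImage", pixels = img, umPerPx = s,
                fieldWidthUm = fw, fieldHeightUm = fh,
                magnificationTag = if (abs(fw - 767) < 1e-6) "350x"
                                   else if (abs(fw - 298) < 1e-6) "900x"
                                   else "other")
    boxes <- truth[, c("x0", "y0", "x1", "y1"), drop = FALSE]
    rownames(boxes) <- NULL
    scene <- new("SyntheticScene", image = cimg, complexMask = complexMask,
                 gcpMask = gcpMask, boxes = boxes, truthTraits = truth,
                 achievedDensity = nrow(truth) / areaMm2, params = params)
    scene
  })
}

#' Export a scene as annotation files
#'
#' Writes the scene image and its ground truth in the interchange formats
#' the pipeline reads back: 8-bit PNG image, two 0/255 mask PNGs,
#' YOLO-format box text, a labelme-style polygon JSON (64-gon outlines per
#' stomatal complex and guard-cell-and-pore region) and the analytic truth
#' trait CSV. Reading the files back through the package parsers reproduces
#' the boxes exactly and the masks pixel-exactly.
#'
#' @param scene a [SyntheticScene-class].
#' @param dir output directory (created if needed).
#' @param basename file stem for all outputs.
#' @return named character vector of the written paths.
#' @export
sceneToAnnotations <- function(scene, dir, basename = "scene") {
  stopifnot(is(scene, "SyntheticScene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  np <- ncol(scene@image@pixels)
  s <- scene@image@umPerPx
  paths <- c(
    image = file.path(dir, paste0(basename, ".png")),
    complex_mask = file.path(dir, paste0(basename, "_complex_mask.png")),
    gcp_mask = file.path(dir, paste0(basename, "_gcp_mask.png")),
    boxes = file.path(dir, paste0(basename, "_boxes.txt")),
    polygons = file.path(dir, paste0(basename, "_polygons.json")),
    traits = file.path(dir, paste0(basename, "_truth.csv")))
  png::writePNG(scene@image@pixels / 255, paths[["image"]])
  writeMaskPng(scene@complexMask, paths[["complex_mask"]])
  writeMaskPng(scene@gcpMask, paths[["gcp_mask"]])
  writeYoloBoxes(scene@boxes, np, np, paths[["boxes"]])

  tt <- scene@truthTraits
  shapes <- list()
  if (nrow(tt) > 0L) {
    tpts <- seq(0, 2 * pi, length.out = 65)[-65]
    for (i in seq_len(nrow(tt))) {
      th <- tt$orientationDeg[i] * pi / 180
      mk <- function(a, b) {
        u <- a * cos(tpts); v <- b * sin(tpts)
        x <- (tt$centerXUm[i] + u * sin(th) + v * cos(th)) / s
        y <- (tt$centerYUm[i] + u * cos(th) - v * sin(th)) / s
        cbind(x, y)
      }
      aL <- tt$SL[i] / 2; bL <- tt$SW[i] / 2
      fr <- sqrt(tt$PGCPA[i])
      shapes[[length(shapes) + 1L]] <-
        list(label = "stomatal_complex", points = mk(aL, bL))
      shapes[[length(shapes) + 1L]] <-
        list(label = "guard_cell_and_pore", points = mk(aL * fr, bL * fr))
    }
  }
  writePolygons(list(shapes = shapes, imageWidth = np, imageHeight = np),
                paths[["polygons"]])
  utils::write.csv(tt, paths[["traits"]], row.names = FALSE)
  paths
}

#' Read and write generator configuration files
#'
#' Scene parameters map 1:1 to a structured YAML key/value file (nested
#' section \code{intensity_levels} for the three gray levels), so runs are
#' reproducible from a plain-text config.
#'
#' @param path config file path.
#' @return \code{readSceneConfig}: a [SceneParams-class].
#' @export
readSceneConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  iv <- unlist(cfg$intensity_levels)
  sceneParams(
    fieldWidthUm = cfg$field_width_um, fieldHeightUm = cfg$field_height_um,
    pixelsPerSide = cfg$pixels_per_side, targetDensity = cfg$target_density,
    lengthDist = unlist(cfg$length_dist), widthDist = unlist(cfg$width_dist),
    gcpFractionDist = unlist(cfg$gcp_fraction_dist),
    orientationJitterDeg = cfg$orientation_jitter_deg,
    rowSpacingUm = cfg$row_spacing_um,
    intensityLevels = iv[c("background", "subsidiary", "gcp")],
    noiseSd = cfg$noise_sd, seed = cfg$seed,
    allowBorderClipped = isTRUE(cfg$allow_border_clipped))
}

#' @rdname readSceneConfig
#' @param params a [SceneParams-class] to serialize.
#' @export
writeSceneConfig <- function(params, path) {
  stopifnot(is(params, "SceneParams"))
  cfg <- list(
    field_width_um = params@fieldWidthUm,
    field_height_um = params@fieldHeightUm,
    pixels_per_side = params@pixelsPerSide,
    target_density = params@targetDensity,
    length_dist = as.numeric(params@lengthDist),
    width_dist = as.numeric(params@widthDist),
    gcp_fraction_dist = as.numeric(params@gcpFractionDist),
    orientation_jitter_deg = params@orientationJitterDeg,
    row_spacing_um = params@rowSpacingUm,
    intensity_levels = as.list(params@intensityLevels),
    noise_sd = params@noiseSd,
    seed = params@seed,
    allow_border_clipped = params@allowBorderClipped)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Simulate an analytic trait table without rasterization
#'
#' Draws per-stoma trait records directly from the generator's size/shape
#' distributions (closed-form ellipse traits, no image rendering), grouped
#' into fields of view with a field-level stomatal density. Useful for
#' exercising the statistical layer at scale; by construction
#' \code{PGCPA + PSCA = 1} per record.
#'
#' @param n number of stomata.
#' @param params a [SceneParams-class] supplying the distributions.
#' @param seed integer seed (private generator).
#' @param cultivar,layer grouping labels attached to every record.
#' @return data.frame with the 11 trait columns plus grouping keys.
#' @export
simulateTraitTable <- function(n, params = sceneParams(), seed = params@seed,
                               cultivar = "synthetic", layer = "middle") {
  stopifnot(n >= 0)
  withLocalSeed(seed, {
    perFov <- max(1L, round(params@targetDensity *
                              params@fieldWidthUm * params@fieldHeightUm * 1e-6))
    fov <- rep(seq_len(ceiling(n / perFov)), each = perFov)[seq_len(n)]
    sdFov <- stats::rnorm(max(fov, 0), params@targetDensity,
                          0.05 * params@targetDensity)
    L <- vapply(seq_len(n), function(i)
      rtruncnorm1(params@lengthDist[1], params@lengthDist[2],
                  params@lengthDist[1] - 3 * params@lengthDist[2],
                  params@lengthDist[1] + 3 * params@lengthDist[2]), numeric(1))
    W <- vapply(seq_len(n), function(i)
      rtruncnorm1(params@widthDist[1], params@widthDist[2],
                  params@widthDist[1] - 3 * params@widthDist[2],
                  min(params@widthDist[1] + 3 * params@widthDist[2],
                      0.95 * L[i])), numeric(1))
    f <- vapply(seq_len(n), function(i)
      rtruncnorm1(params@gcpFractionDist[1], params@gcpFractionDist[2],
                  0.05, 0.95), numeric(1))
    a <- L / 2; b <- W / 2
    SA <- pi * a * b
    SP <- vapply(seq_len(n), function(i) ellipsePerimeter(a[i], b[i]),
                 numeric(1))
    data.frame(
      cultivar = cultivar, sampling_day = 1L, layer = layer,
      replicate = 1L, field_of_view = if (n) fov else integer(0),
      SD = if (n) sdFov[fov] else numeric(0),
      SW = W, SL = L, SA = SA, SP = SP,
      GCPA = f * SA, SCA = (1 - f) * SA,
      SR = 4 * pi * SA / SP^2, SE = sqrt(1 - (b / a)^2),
      PGCPA = f, PSCA = 1 - f)
  })
}
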