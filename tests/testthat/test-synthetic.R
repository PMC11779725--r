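test_that("stoma count follows the target density over the field area", {
  sc <- noisyScene()
  # 80 / mm^2 over a 767 x 767 um field: round(80 * 0.588289) = 47
  expect_equal(nrow(truthBoxes(sc)), 47L)
  expect_equal(sc@achievedDensity, 47 / (767 * 767 * 1e-6))
  # bookkeeping is exact: boxes / area equals the reported density
  expect_identical(nrow(truthBoxes(sc)) / fieldAreaMm2(sc),
                   sc@achievedDensity)
})

test_that("identical parameters produce bit-identical scenes", {
  p <- sceneParams(fieldWidthUm = 300, fieldHeightUm = 300,
                   pixelsPerSide = 256, targetDensity = 40, noiseSd = 5,
                   seed = 42)
  a <- generateScene(p); b <- generateScene(p)
  expect_identical(pixels(a), pixels(b))
  expect_identical(a@complexMask, b@complexMask)
  expect_identical(a@gcpMask, b@gcpMask)
  expect_identical(truthTraits(a), truthTraits(b))
  # and a different seed changes the scene
  c2 <- generateScene(sceneParams(fieldWidthUm = 300, fieldHeightUm = 300,
                                  pixelsPerSide = 256, targetDensity = 40,
                                  noiseSd = 5, seed = 43))
  expect_false(identical(pixels(a), pixels(c2)))
})

test_that("zero target density yields a pure background scene", {
  sc <- generateScene(sceneParams(fieldWidthUm = 200, fieldHeightUm = 200,
                                  pixelsPerSide = 128, targetDensity = 0,
                                  noiseSd = 2, seed = 1))
  expect_equal(nrow(truthBoxes(sc)), 0L)
  expect_equal(sum(sc@complexMask), 0)
  expect_equal(sum(sc@gcpMask), 0)
  expect_equal(sc@achievedDensity, 0)
})

test_that("per-stoma pixel conservation: gcp + subsidiary = complex", {
  sc <- smallScene()
  inst <- labelStomata(sc@complexMask, sc@gcpMask, borderPolicy = "keep")
  for (i in inst) {
    nGcp <- length(i@gcpPixels)
    nSub <- length(setdiff(i@pixels, i@gcpPixels))
    expect_identical(nGcp + nSub, length(i@pixels))
  }
  # masks nest: every gcp pixel is a complex pixel
  expect_true(all(sc@gcpMask <= sc@complexMask))
})

test_that("analytic truth matches the rasterized masks", {
  sc <- noisyScene()
  tr <- truthTraits(sc)
  s <- umPerPx(sc)
  expect_true(all(abs(tr$SA - tr$pixelArea * s^2) / tr$SA <= 0.02))
  # eccentricity of the rasterized blob agrees with the generating ellipse
  inst <- labelStomata(sc@complexMask, sc@gcpMask, borderPolicy = "keep")
  mt <- matchedTraits(sc, inst,
                      do.call(rbind, lapply(inst, measureStoma, umPerPx = s)))
  expect_true(all(abs(mt$measured$SE - mt$truth$SE) <= 0.02))
})

test_that("infeasible geometry is rejected with a diagnostic", {
  expect_error(
    generateScene(sceneParams(fieldWidthUm = 80, fieldHeightUm = 80,
                              pixelsPerSide = 64, targetDensity = 100,
                              seed = 1)),
    "infeasible")
})

test_that("overfull density requests place what fits and warn", {
  expect_warning(
    sc <- generateScene(sceneParams(fieldWidthUm = 300, fieldHeightUm = 300,
                                    pixelsPerSide = 256,
                                    targetDensity = 400, seed = 3)),
    "could be placed")
  expect_lt(nrow(truthBoxes(sc)), round(400 * 0.09))
  expect_gt(nrow(truthBoxes(sc)), 0)
})

test_that("border clipping flag produces a frame-truncated stoma", {
  sc <- generateScene(sceneParams(fieldWidthUm = 300, fieldHeightUm = 300,
                                  pixelsPerSide = 256, targetDensity = 30,
                                  noiseSd = 0, seed = 9,
                                  allowBorderClipped = TRUE))
  expect_true(any(truthTraits(sc)$borderTouching))
})

test_that("generator parameter invariants are enforced", {
  expect_error(sceneParams(lengthDist = c(50, 2), widthDist = c(60, 2)),
               "length mean must exceed width")
  expect_error(sceneParams(gcpFractionDist = c(1.2, 0.1)), "in \\(0, 1\\)")
  expect_error(sceneParams(intensityLevels = c(background = 100,
                                               subsidiary = 90, gcp = 50)),
               "20 gray levels")
})

test_that("scene generation leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generateScene(sceneParams(fieldWidthUm = 200, fieldHeightUm = 200,
                                      pixelsPerSide = 128, targetDensity = 20,
                                      seed = 77)))
  expect_identical(.Random.seed, before)
})

test_that("annotation export round-trips boxes and masks exactly", {
  sc <- smallScene()
  dir <- withr::local_tempdir()
  paths <- sceneToAnnotations(sc, dir, "sc")
  np <- ncol(pixels(sc))
  boxes <- parseYoloBoxes(paths[["boxes"]], np, np)
  expect_equal(boxes[, c("x0", "y0", "x1", "y1")],
               truthBoxes(sc)[, c("x0", "y0", "x1", "y1")],
               ignore_attr = TRUE)
  expect_identical(readMaskPng(paths[["complex_mask"]]), sc@complexMask)
  expect_identical(readMaskPng(paths[["gcp_mask"]]), sc@gcpMask)
  # polygon rasterization approximates the true masks closely
  polys <- parsePolygons(paths[["polygons"]])
  masks <- polygonsToMasks(polys, dim(sc@complexMask))
  expect_gt(dice(masks$complexMask, sc@complexMask), 0.97)
  expect_gt(dice(masks$gcpMask, sc@gcpMask), 0.95)
})

test_that("simulated trait tables satisfy the analytic identities", {
  tab <- simulateTraitTable(200, seed = 4)
  expect_equal(nrow(tab), 200L)
  expect_true(all(TRAIT_COLUMNS_EXPECTED %in% names(tab)))
  expect_equal(tab$PGCPA + tab$PSCA, rep(1, 200))
  expect_equal(tab$GCPA + tab$SCA, tab$SA)
  expect_true(all(tab$SL > tab$SW))
  # deterministic under a fixed seed
  expect_identical(tab, simulateTraitTable(200, seed = 4))
})

test_that("scene config files map 1:1 to generator parameters", {
  p <- sceneParams(targetDensity = 72, noiseSd = 6, seed = 13,
                   rowSpacingUm = 90)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeSceneConfig(p, path)
  q <- readSceneConfig(path)
  for (sl in slotNames(p)) expect_equal(slot(q, sl), slot(p, sl), info = sl)
})
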