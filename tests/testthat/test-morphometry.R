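test_that("a rasterized disk measures as a circle", {
  s <- 0.582
  m <- ellipseMask(50, 50, 120)
  inst <- makeInstance(m)
  tr <- measureStoma(inst, s)
  expect_gte(tr$SR, 0.98); expect_lte(tr$SR, 1.02)
  expect_lte(tr$SE, 0.05)
  expect_equal(tr$SA, pi * (50 * s)^2, tolerance = 0.01)
  expect_equal(tr$SP, 2 * pi * 50 * s, tolerance = 0.01)
})

test_that("a rasterized 5:3 ellipse measures its closed-form shape", {
  s <- 0.5
  m <- ellipseMask(50, 30, 120)
  tr <- measureStoma(makeInstance(m), s)
  expect_equal(tr$SE, 0.8, tolerance = 0.02)       # sqrt(1 - (30/50)^2)
  expect_equal(tr$SL, 100 * s, tolerance = 0.03 * 100 * s)
  expect_equal(tr$SW, 60 * s, tolerance = 0.03 * 60 * s)
  # rotating the generating ellipse leaves the measurements stable
  m45 <- ellipseMask(50, 30, 140, theta = pi / 4)
  tr45 <- measureStoma(makeInstance(m45), s)
  expect_equal(tr45$SL, tr$SL, tolerance = 0.02 * tr$SL)
  expect_equal(tr45$SW, tr$SW, tolerance = 0.02 * tr$SW)
  expect_equal(tr45$SE, tr$SE, tolerance = 0.02)
})

test_that("areas and fractions equal a brute-force pixel enumeration", {
  set.seed(41)
  for (i in 1:20) {
    a <- runif(1, 5, 18); b <- runif(1, 4, min(a, 14))
    m <- ellipseMask(a, b, 40)
    gcp <- ellipseMask(a * 0.7, b * 0.7, 40)
    s <- runif(1, 0.3, 1)
    tr <- measureStoma(makeInstance(m, gcp), s)
    nC <- sum(m == 1); nG <- sum(m == 1 & gcp == 1)
    expect_identical(tr$SA, nC * s^2)
    expect_identical(tr$GCPA, nG * s^2)
    expect_identical(tr$SCA, nC * s^2 - nG * s^2)
    expect_equal(tr$PGCPA, nG / nC, tolerance = 1e-12)
    expect_equal(tr$PGCPA + tr$PSCA, 1, tolerance = 1e-12)
    expect_equal(tr$SCA + tr$GCPA, tr$SA, tolerance = 1e-9)
  }
})

test_that("perimeter agrees with an independent contour-walk oracle", {
  set.seed(43)
  for (i in 1:15) {
    a <- runif(1, 5, 16); b <- runif(1, 4, min(a, 12))
    th <- runif(1, 0, pi)
    m <- ellipseMask(a, b, 40, theta = th)
    s <- runif(1, 0.4, 1.2)
    tr <- measureStoma(makeInstance(m), s)
    expect_equal(tr$SP, msPerimeterOracle(m) * s, tolerance = 1e-9)
  }
  # rectangles exercise the straight-edge and corner cases
  m <- matrix(0L, 30, 30); m[8:22, 10:18] <- 1L
  expect_equal(measureStoma(makeInstance(m), 1)$SP, msPerimeterOracle(m),
               tolerance = 1e-9)
})

test_that("traits scale correctly with the pixel size", {
  m <- ellipseMask(14, 8, 40)
  gcp <- ellipseMask(10, 5, 40)
  inst <- makeInstance(m, gcp)
  t1 <- measureStoma(inst, 0.5)
  t2 <- measureStoma(inst, 1.0)
  expect_identical(t2$SA, 4 * t1$SA)
  expect_identical(t2$GCPA, 4 * t1$GCPA)
  expect_identical(t2$SCA, 4 * t1$SCA)
  expect_equal(t2$SP, 2 * t1$SP, tolerance = 1e-12)
  expect_equal(t2$SL, 2 * t1$SL, tolerance = 1e-12)
  expect_equal(t2$SW, 2 * t1$SW, tolerance = 1e-12)
  for (nm in c("SR", "SE", "PGCPA", "PSCA"))
    expect_identical(t2[[nm]], t1[[nm]])
})

test_that("a 90-degree rotation changes measurements only by rasterization", {
  m <- ellipseMask(16, 9, 44, theta = 0.3)
  rot <- t(m)[, rev(seq_len(nrow(m)))]  # 90-degree rotation
  t0 <- measureStoma(makeInstance(m), 1)
  t90 <- measureStoma(makeInstance(rot), 1)
  expect_identical(t90$SA, t0$SA)       # pixel count is preserved exactly
  expect_lt(abs(t90$SL - t0$SL) / t0$SL, 0.01)
  expect_lt(abs(t90$SW - t0$SW) / t0$SW, 0.01)
  expect_lt(abs(t90$SR - t0$SR), 0.02)
  expect_lt(abs(t90$SE - t0$SE), 0.02)
})

test_that("circularity never exceeds the isoperimetric bound", {
  set.seed(47)
  for (i in 1:15) {
    a <- runif(1, 10, 20); b <- runif(1, 10, min(a, 20))
    tr <- measureStoma(makeInstance(ellipseMask(a, b, 52)), 1)
    expect_lte(tr$SR, 1.05)
  }
  # square: 4*pi*s^2 / (4s)^2 = pi/4, up to corner smoothing
  sq <- matrix(0L, 50, 50); sq[11:40, 11:40] <- 1L
  expect_equal(measureStoma(makeInstance(sq), 1)$SR, pi / 4,
               tolerance = 0.07)
})

test_that("roundness formula matches its closed forms and domain", {
  expect_equal(roundness(pi * 7^2, 2 * pi * 7), 1, tolerance = 1e-12)
  expect_equal(roundness(4, 8), pi / 4, tolerance = 1e-12)
  expect_error(roundness(0, 5), "positive")
  expect_error(roundness(5, -1), "positive")
})

test_that("empty instances cannot be measured", {
  m <- matrix(0L, 8, 8); m[3, 3] <- 1L
  inst <- makeInstance(m)
  expect_error(measureStoma(inst, 0), "umPerPx")
})

test_that("border policy drops truncated stomata from trait tables", {
  m <- matrix(0L, 30, 30)
  m[1:6, 10:16] <- 1L    # clipped at the frame
  m[15:24, 10:19] <- 1L  # whole
  gcp <- matrix(0L, 30, 30); gcp[17:22, 12:17] <- 1L
  inst <- labelStomata(m, gcp, borderPolicy = "drop_for_traits")
  tab <- stomaTraitTable(inst, 1, SD = 10)
  expect_equal(nrow(tab), 1L)
  expect_false(any(tab$borderTouching))
  tabKeep <- stomaTraitTable(inst, 1, SD = 10, borderPolicy = "keep")
  expect_equal(nrow(tabKeep), 2L)
})

test_that("aggregation reproduces a two-pass reference computation", {
  set.seed(53)
  tab <- rbind(simulateTraitTable(40, seed = 1, cultivar = "A"),
               simulateTraitTable(25, seed = 2, cultivar = "B"))
  agg <- aggregateTraits(tab, by = "cultivar")
  for (cv in c("A", "B")) for (tr in c("SA", "SL", "PGCPA")) {
    v <- tab[[tr]][tab$cultivar == cv]
    row <- agg[agg$cultivar == cv & agg$trait == tr, ]
    expect_equal(row$mean, sum(v) / length(v), tolerance = 1e-12)
    expect_equal(row$sd,
                 sqrt(sum((v - mean(v))^2) / (length(v) - 1)),
                 tolerance = 1e-12)
    expect_equal(row$n, length(v))
  }
  # singleton and identical-record groups report sd 0
  one <- simulateTraitTable(1, seed = 3, cultivar = "solo")
  aggOne <- aggregateTraits(one, by = "cultivar")
  expect_true(all(aggOne$sd == 0) && all(aggOne$singleton))
  same <- rbind(one, one, one)
  aggSame <- aggregateTraits(same, by = "cultivar")
  expect_true(all(aggSame$sd == 0) && !any(aggSame$singleton))
  expect_error(aggregateTraits(tab[0, ], by = "cultivar"), "empty")
})
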