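test_that("generalized IoU matches its closed-form examples", {
  expect_equal(giouLoss(c(0, 0, 1, 1), c(0, 0, 1, 1)), 0)
  expect_equal(giou(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  # abutting unit squares: IoU 0, enclosing box fully covered by the union
  expect_equal(giou(c(0, 0, 1, 1), c(1, 0, 2, 1)), 0)
  expect_equal(giouLoss(c(0, 0, 1, 1), c(1, 0, 2, 1)), 1)
  # distant unit squares: union 2, enclosing 9 -> GIoU -7/9
  expect_equal(giou(c(0, 0, 1, 1), c(2, 2, 3, 3)), -7 / 9, tolerance = 1e-12)
  expect_equal(giouLoss(c(0, 0, 1, 1), c(2, 2, 3, 3)), 1 + 7 / 9,
               tolerance = 1e-12)
  expect_error(giou(c(0, 0, 0, 1), c(0, 0, 1, 1)), "degenerate")
})

test_that("GIoU stays in (-1, 1] and equals IoU for nested boxes", {
  set.seed(61)
  for (i in 1:300) {
    a <- randomBox(); b <- randomBox()
    g <- giou(a, b)
    expect_gt(g, -1); expect_lte(g, 1)
  }
  outer <- c(0, 0, 10, 10); inner <- c(2, 3, 7, 8)
  expect_equal(giou(outer, inner), boxIoU(outer, inner), tolerance = 1e-12)
})

test_that("precision and recall follow the standard definitions", {
  pr <- precisionRecall(c(TP = 10, FP = 0, FN = 0))
  expect_equal(c(pr$precision, pr$recall), c(1, 1))
  pr <- precisionRecall(c(TP = 8, FP = 2, FN = 4))
  expect_equal(pr$precision, 0.8)
  expect_equal(pr$recall, 8 / 12, tolerance = 1e-12)
  pr <- precisionRecall(c(TP = 0, FP = 5, FN = 3))
  expect_equal(c(pr$precision, pr$recall), c(0, 0))
  # undefined ratios surface as NA with a reason, never a silent zero
  pr <- precisionRecall(c(TP = 0, FP = 0, FN = 3))
  expect_true(is.na(pr$precision))
  expect_match(attr(pr$precision, "reason"), "undefined")
})

test_that("greedy matching consumes each truth box once", {
  truth <- data.frame(x0 = c(0, 20), y0 = c(0, 0), x1 = c(10, 30),
                      y1 = c(10, 10))
  # perfect predictions
  pred <- cbind(truth, confidence = 1)
  m <- matchDetections(pred, truth)
  expect_equal(unname(m$counts), c(2, 0, 0))
  # one prediction overlapping both truths: one TP, one FN
  pred1 <- data.frame(x0 = 0, y0 = 0, x1 = 10, y1 = 10, confidence = 0.9)
  m1 <- matchDetections(pred1, truth)
  expect_equal(unname(m1$counts), c(1, 0, 1))
  # no predictions: all truths missed
  m0 <- matchDetections(pred1[0, ], truth)
  expect_equal(unname(m0$counts), c(0, 0, 2))
  # sub-threshold overlap is a FP + FN
  predOff <- data.frame(x0 = 8, y0 = 8, x1 = 18, y1 = 18, confidence = 1)
  mOff <- matchDetections(predOff, truth["1", ])
  expect_equal(unname(mOff$counts), c(0, 1, 1))
})

test_that("AP50 integrates the hand-computed precision-recall staircase", {
  # (match, miss, match) on 2 truths: envelope 1 to recall .5, 2/3 after
  ranked <- data.frame(confidence = c(0.9, 0.8, 0.7),
                       isMatch = c(TRUE, FALSE, TRUE))
  expect_equal(ap50(ranked, mTruth = 2), 0.5 * 1 + 0.5 * 2 / 3,
               tolerance = 1e-12)
  expect_equal(ap50(data.frame(confidence = 1, isMatch = TRUE)[0, ],
                    mTruth = 3), 0)
  expect_equal(ap50(data.frame(confidence = c(1, 0.9),
                               isMatch = c(FALSE, FALSE)), mTruth = 2), 0)
  expect_warning(r <- ap50(data.frame(confidence = 1, isMatch = TRUE)[0, ],
                           mTruth = 0), "defined as 1")
  expect_equal(r, 1)
})

test_that("AP matches the enumeration oracle on every small detection set", {
  confs <- c(1, 0.9, 0.8, 0.7)
  for (n in 0:4) {
    patterns <- if (n == 0) list(logical(0)) else
      lapply(seq_len(2^n) - 1, function(k) as.logical(bitwAnd(
        k %/% 2^(seq_len(n) - 1), 1)))
    for (isMatch in patterns) {
      for (extra in 0:2) {
        m <- sum(isMatch) + extra
        if (m == 0 && n == 0) next
        ranked <- data.frame(confidence = confs[seq_len(n)],
                             isMatch = isMatch)
        expect_equal(ap50(ranked, mTruth = m), apOracle(isMatch, m),
                     tolerance = 1e-12,
                     info = paste(n, m, paste(isMatch, collapse = "")))
      }
    }
  }
})

test_that("AP is invariant to uniform confidence rescaling", {
  set.seed(67)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    ranked <- data.frame(confidence = sort(runif(n), decreasing = TRUE),
                         isMatch = sample(c(TRUE, FALSE), n, replace = TRUE))
    m <- sum(ranked$isMatch) + sample(0:2, 1)
    if (m == 0) next
    scaled <- ranked; scaled$confidence <- scaled$confidence * 0.37
    expect_identical(ap50(ranked, mTruth = m), ap50(scaled, mTruth = m))
  }
})

test_that("Dice and IoU match their closed-form examples", {
  a <- matrix(0, 4, 4); a[1:2, 1] <- 1
  b <- matrix(0, 4, 4); b[2:3, 1] <- 1
  expect_equal(dice(a, b), 0.5)
  expect_equal(iou(a, b), 1 / 3, tolerance = 1e-12)
  expect_equal(diceLoss(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  disj <- matrix(0, 4, 4); disj[4, 4] <- 1
  expect_equal(dice(a, disj), 0)
  expect_equal(diceLoss(a, disj), 1)
  expect_warning(v <- dice(matrix(0, 3, 3), matrix(0, 3, 3)), "empty")
  expect_equal(v, 1)
  expect_error(dice(matrix(0, 3, 3), matrix(0, 4, 4)), "differ")
})

test_that("mask-metric identities hold on 1000 fuzzed pairs", {
  set.seed(71)
  for (i in 1:1000) {
    nr <- sample(4:64, 1); nc <- sample(4:64, 1)
    x <- randomMask(nr, nc, runif(1, 0.05, 0.9))
    y <- randomMask(nr, nc, runif(1, 0.05, 0.9))
    if (sum(x) + sum(y) == 0) next
    d <- dice(x, y)
    expect_equal(iou(x, y), d / (2 - d), tolerance = 1e-12)
    expect_identical(diceLoss(x, y), 1 - d)
  }
})

test_that("reliability regression reports R2 and raw-pair RMSE", {
  r <- fitReliability(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$r_squared, 1)
  expect_equal(r$rmse, 0)
  r <- fitReliability(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$r_squared, 1)
  expect_equal(r$rmse, 1)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  set.seed(73)
  x <- rnorm(1000); y <- rnorm(1000)
  expect_lt(fitReliability(x, y)$r_squared, 0.01)
  expect_error(fitReliability(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(fitReliability(c(1, 2), c(1, 2)), "at least 3")
})
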