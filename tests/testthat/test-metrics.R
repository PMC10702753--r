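test_that("confusion matrix counts true/predicted pairs", {
  cm <- confusionMatrix(c("a", "a", "b"), c("a", "b", "b"), classes = c("a", "b"))
  expect_identical(counts(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2))

  perfect <- confusionMatrix(rep(c("a", "b"), 5), rep(c("a", "b"), 5),
                             classes = c("a", "b"))
  expect_true(all(counts(perfect)[upper.tri(counts(perfect))] == 0))
  expect_true(all(counts(perfect)[lower.tri(counts(perfect))] == 0))

  expect_warning(empty <- confusionMatrix(character(), character(),
                                          classes = c("a", "b")), "empty")
  expect_true(all(counts(empty) == 0))

  expect_error(confusionMatrix("a", "z", classes = c("a", "b")), "outside")
  expect_error(confusionMatrix(c("a", "b"), "a"), "equal length")
})

test_that("per-class metrics reproduce the published worked examples", {
  # F1 = harmonic mean of printed precision/recall, at 2-decimal rounding
  expect_equal(roundHalfUp(f1Score(0.96, 0.88)), 0.92)   # carrot
  expect_equal(roundHalfUp(f1Score(1.00, 0.93)), 0.96)   # broccoli
  expect_equal(roundHalfUp(f1Score(1.00, 0.94)), 0.97)   # radish
  expect_equal(roundHalfUp(f1Score(0.82, 0.97)), 0.89)   # potato
  expect_equal(roundHalfUp(f1Score(92.25, 93.00)), 92.62) # percent scale
  expect_equal(f1Score(1, 1), 1)
  expect_equal(f1Score(0, 0), 0)
})

test_that("per-class metrics agree with a brute-force one-vs-rest recount", {
  set.seed(77)
  classes <- c("a", "b", "c", "d")
  for (i in 1:50) {
    n <- sample(5:50, 1)
    true <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    cm <- confusionMatrix(true, pred, classes)
    got <- suppressWarnings(perClassMetrics(cm))
    for (cls in classes) {
      want <- oracleOvrMetrics(true, pred, cls)
      row <- got[got$class == cls, ]
      expect_equal(row$precision, want[["precision"]])
      expect_equal(row$recall, want[["recall"]])
      expect_equal(row$f1, want[["f1"]])
    }
    expect_equal(overallAccuracy(cm), mean(true == pred))

    # marginal identities: TP+FN = row sum, TP+FP = column sum
    for (k in seq_along(classes)) {
      o <- BlockCS:::.ovr(counts(cm), k)
      expect_equal(o$tp + o$fn, sum(counts(cm)[k, ]))
      expect_equal(o$tp + o$fp, sum(counts(cm)[, k]))
    }
    expect_equal(sum(counts(cm)), n)
  }
})

test_that("F1 lies below both the geometric mean and the maximum of P and R", {
  set.seed(78)
  for (i in 1:100) {
    p <- runif(1); r <- runif(1)
    f1 <- f1Score(p, r)
    expect_lte(f1, sqrt(p * r) + 1e-12)
    expect_lte(f1, max(p, r) + 1e-12)
    expect_gte(f1, min(p, r) - 1e-12)
  }
  expect_identical(f1Score(0, 0.5), 0)   # F1 = 0 iff P = 0 or R = 0
  expect_identical(f1Score(0.5, 0), 0)
})

test_that("zero-denominator metrics return 0 with a warning", {
  cm <- confusionMatrix(c("a", "a"), c("b", "b"), classes = c("a", "b"))
  w <- capture_warnings(m <- perClassMetrics(cm, "a"))
  expect_true(any(grepl("precision undefined", w)))
  expect_true(any(grepl("F1 undefined", w)))
  expect_equal(m$precision, 0)
  expect_equal(m$f1, 0)
})

test_that("overall accuracy is trace over total and permutation-invariant", {
  cm <- confusionMatrix(rep("a", 3), rep("a", 3), classes = c("a", "b"))
  expect_equal(overallAccuracy(cm), 1)

  # 112 of 120 correct -> 0.9333
  true <- rep(c("a", "b", "c", "d"), each = 30)
  pred <- true
  pred[c(1:3, 31:33, 61:62)] <- c("b", "c", "d", "a", "c", "d", "a", "b")
  cm2 <- confusionMatrix(true, pred, classes = c("a", "b", "c", "d"))
  expect_equal(sum(diag(counts(cm2))), 112)
  expect_equal(roundHalfUp(overallAccuracy(cm2), 4), 0.9333)

  # permuting the class order leaves accuracy unchanged
  cm3 <- confusionMatrix(true, pred, classes = c("d", "b", "a", "c"))
  expect_equal(overallAccuracy(cm3), overallAccuracy(cm2))

  # uniform off-diagonal, zero diagonal -> 0
  off <- confusionMatrix(rep(c("a", "b"), 4), rep(c("b", "a"), 4),
                         classes = c("a", "b"))
  expect_equal(overallAccuracy(off), 0)

  expect_warning(e <- confusionMatrix(character(), character(), classes = "a"))
  expect_error(overallAccuracy(e), "empty")
})

test_that("macro average is the unweighted mean across classes", {
  m <- data.frame(class = c("a", "b"), precision = c(1, 0),
                  recall = c(0.5, 0.5), f1 = c(0.4, 0.6))
  expect_equal(macroAverage(m),
               c(precision = 0.5, recall = 0.5, f1 = 0.5))

  same <- data.frame(class = c("a", "b"), precision = c(0.9, 0.9),
                     recall = c(0.8, 0.8), f1 = c(0.846, 0.846))
  expect_equal(unname(macroAverage(same)), c(0.9, 0.8, 0.846))
})

test_that("compression ratio is B^2 / M over the study's sweep", {
  expect_equal(compressionRatio(32), 2)
  expect_equal(compressionRatio(64), 1)
  expect_equal(compressionRatio(2), 32)
  expect_equal(sapply(c(32, 16, 8, 4, 2), compressionRatio),
               c(2, 4, 8, 16, 32))
  expect_equal(compressionRatio(CodecConfig(measurements = 4L)), 16)
  expect_error(compressionRatio(65), "exceeds")
  expect_error(compressionRatio(0), ">= 1")
})

test_that("metrics CSV mirrors the per-class table layout", {
  cm <- confusionMatrix(c("a", "a", "b", "b"), c("a", "b", "b", "b"),
                        classes = c("a", "b"))
  path <- tempfile(fileext = ".csv")
  writeMetricsCSV(cm, path)
  got <- read.csv(path)
  expect_identical(names(got), c("class", "precision", "recall", "f1"))
  expect_equal(got$precision[1], 1)
  expect_equal(got$recall[1], 0.5)
  expect_equal(got$f1[1], 0.67)   # half-up at 2 decimals
})

test_that("half-up rounding differs from banker's rounding where it should", {
  expect_equal(roundHalfUp(0.925), 0.93)
  expect_equal(roundHalfUp(92.625), 92.63)
  expect_equal(roundHalfUp(-0.925), -0.93)
  expect_equal(roundHalfUp(0.9333, 4), 0.9333)
})
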