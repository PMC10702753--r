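test_that("block splitting tiles the plane in row-major block order", {
  p <- matrix(seq_len(256), 16, 16)      # all-distinct values
  blocks <- splitIntoBlocks(p, 8)
  expect_length(blocks, 4L)
  ref <- oracleSplit(p, 8)
  for (j in 1:4) expect_identical(blocks[[j]], ref[[j]])

  expect_length(splitIntoBlocks(matrix(0, 256, 256), 8), 1024L)
  one <- splitIntoBlocks(matrix(rnorm(64), 8, 8), 8)
  expect_length(one, 1L)
  expect_equal(one[[1L]], matrix(one[[1L]], 8, 8))

  expect_error(splitIntoBlocks(matrix(0, 12, 12), 8), "12")
})

test_that("merge is the exact inverse of split", {
  p <- randomPlane(64, seed = 11)
  expect_identical(mergeBlocks(splitIntoBlocks(p, 8), c(64, 64)), p)

  b <- matrix(rnorm(64), 8, 8)
  expect_identical(mergeBlocks(list(b), c(8, 8)), b)

  # quadrant-constant plane fixes the ordering convention
  blocks <- lapply(1:4, function(v) matrix(v, 8, 8))
  plane <- mergeBlocks(blocks, c(16, 16))
  expect_true(all(plane[1:8, 1:8] == 1))     # block 1: top-left
  expect_true(all(plane[1:8, 9:16] == 2))    # block 2: top-right (row-major)
  expect_true(all(plane[9:16, 1:8] == 3))
  expect_true(all(plane[9:16, 9:16] == 4))

  expect_error(mergeBlocks(blocks[1:3], c(16, 16)), "tile")
})

test_that("2-D DCT is orthonormal with an exact inverse", {
  # constant block: all energy in the DC coefficient, value B*c
  cb <- forwardDCT2(matrix(3, 8, 8))
  expect_equal(cb[1, 1], 8 * 3, tolerance = 1e-12)
  expect_lt(max(abs(cb[-1])), 1e-12)

  # DC-only inverse: constant block d / B
  co <- matrix(0, 8, 8); co[1, 1] <- 16
  expect_equal(inverseDCT2(co), matrix(2, 8, 8), tolerance = 1e-12)
  expect_equal(inverseDCT2(matrix(0, 8, 8)), matrix(0, 8, 8))

  set.seed(21)
  for (i in 1:5) {
    x <- matrix(rnorm(64, sd = 50), 8, 8)
    X <- forwardDCT2(x)
    expect_lt(max(abs(inverseDCT2(X) - x)), 1e-10)
    expect_lt(abs(sum(X^2) - sum(x^2)) / sum(x^2), 1e-8)   # Parseval
  }
  expect_error(forwardDCT2(matrix(0, 8, 4)), "square")
})

test_that("vectorization follows the fixed column-major convention", {
  X <- matrix(seq_len(64), 8, 8)
  v <- vectorizeCoeffs(X)
  expect_length(v, 64L)
  expect_equal(v[1], X[1, 1])          # (0,0) -> index 0
  expect_equal(v[64], X[8, 8])         # (7,7) -> index 63
  expect_equal(v[(3 - 1) * 8 + 2], X[2, 3])   # (r,c) -> (c-1)*B + r
  expect_identical(devectorizeCoeffs(v, 8), X)

  set.seed(31)
  for (i in 1:3) {
    Y <- matrix(rnorm(64), 8, 8)
    expect_identical(devectorizeCoeffs(vectorizeCoeffs(Y), 8), Y)
    w <- rnorm(64)
    expect_identical(vectorizeCoeffs(devectorizeCoeffs(w, 8)), w)
  }
  expect_error(devectorizeCoeffs(rnorm(63), 8), "63")
})

test_that("measurement matrix is Gaussian, scaled, and seed-deterministic", {
  A <- makeMeasurementMatrix(32, 64, seed = 9)
  expect_equal(dim(A), c(32L, 64L))
  expect_identical(as.matrix(A), as.matrix(makeMeasurementMatrix(32, 64, seed = 9)))
  expect_false(identical(as.matrix(A),
                         as.matrix(makeMeasurementMatrix(32, 64, seed = 10))))

  # CLT bound: mean of ML iid N(0, 1/M) entries, |mean| < 4 sd/sqrt(ML)
  ent <- as.matrix(A)
  expect_lt(abs(mean(ent)), 4 * (1 / sqrt(32)) / sqrt(32 * 64))
  expect_equal(sd(ent), 1 / sqrt(32), tolerance = 0.1)

  expect_error(makeMeasurementMatrix(65, 64, seed = 1), "exceed")
  expect_error(makeMeasurementMatrix(0, 64, seed = 1), ">= 1")
})

test_that("acquisition is the linear map Y = A v", {
  A <- makeMeasurementMatrix(32, 64, seed = 2)
  v <- rnorm(64)
  expect_equal(acquire(A, numeric(64)), numeric(32))
  expect_equal(acquire(A, 2 * v), 2 * acquire(A, v), tolerance = 1e-12)
  expect_length(acquire(A, v), 32L)
  expect_equal(acquire(A, v), as.numeric(as.matrix(A) %*% v))
  expect_error(acquire(A, rnorm(63)), "63")
})

test_that("OMP handles the zero-measurement and full-measurement limits", {
  A <- makeMeasurementMatrix(16, 64, seed = 5)
  fit0 <- ompReconstruct(A, numeric(16))
  expect_equal(fit0@estimate, numeric(64))
  expect_length(fit0@support, 0L)
  expect_identical(fit0@iterations, 0L)

  # M = L with invertible A: estimate reproduces any v
  Afull <- makeMeasurementMatrix(64, 64, seed = 6)
  set.seed(61)
  v <- rnorm(64)
  fit <- ompReconstruct(Afull, acquire(Afull, v))
  expect_lt(sqrt(sum((fit@estimate - v)^2)) / sqrt(sum(v^2)), 1e-6)
})

test_that("OMP never reselects atoms and its residual is nonincreasing", {
  set.seed(71)
  for (i in 1:10) {
    A <- makeMeasurementMatrix(16, 64, seed = 100 + i)
    v <- generateSparseVector(64, 6, seed = 200 + i)
    fit <- ompReconstruct(A, acquire(A, v))
    expect_equal(anyDuplicated(fit@support), 0L)
    expect_lte(length(fit@support), 16L)
    expect_true(all(fit@estimate[-fit@support] == 0))
    expect_equal(fit@residualNorm,
                 sqrt(sum((acquire(A, v) - as.matrix(A) %*% fit@estimate)^2)),
                 tolerance = 1e-8)
    if (length(fit@residualTrace) > 1)
      expect_true(all(diff(fit@residualTrace) <= 1e-10))
  }
})

test_that("OMP skips all-zero columns during selection", {
  ent <- as.matrix(makeMeasurementMatrix(8, 16, seed = 8))
  ent[, 3] <- 0
  A <- new("MeasurementMatrix", entries = ent, seed = 8L)
  v <- numeric(16); v[3] <- 5; v[7] <- 2
  fit <- ompReconstruct(A, as.numeric(ent %*% v))
  expect_false(3L %in% fit@support)
})

test_that("exact-recovery rate is nondecreasing in the measurement count", {
  ntrials <- 200
  rate <- sapply(c(8, 16, 32, 64), function(M) {
    hits <- 0
    for (t in seq_len(ntrials)) {
      A <- makeMeasurementMatrix(M, 64, seed = 1000 * M + t)
      v <- generateSparseVector(64, 4, seed = 5000 + t)   # same signals for all M
      fit <- ompReconstruct(A, acquire(A, v))
      if (sqrt(sum((fit@estimate - v)^2)) / sqrt(sum(v^2)) < 1e-6) hits <- hits + 1
    }
    hits / ntrials
  })
  expect_true(all(diff(rate) >= 0))
  expect_equal(rate[4], 1)     # M = L always recovers
})
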