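# Independent oracles used across the suite. These deliberately avoid the
# package's own fast paths: direct indexing instead of the block rearrange,
# qr-based least squares instead of the OMP solver, and a plain recount
# instead of the confusion-matrix accessors.

# split a plane into B x B blocks by direct double-loop indexing,
# row-major block order
oracleSplit <- function(plane, B) {
  nB <- nrow(plane) / B
  out <- list()
  for (br in seq_len(nB)) {
    for (bc in seq_len(nB)) {
      out[[length(out) + 1L]] <-
        plane[((br - 1) * B + 1):(br * B), ((bc - 1) * B + 1):(bc * B)]
    }
  }
  out
}

# least squares of y on the columns of A indexed by support, embedded in L
oracleLSOnSupport <- function(A, y, support) {
  v <- numeric(ncol(A))
  if (length(support) > 0) {
    v[support] <- qr.solve(A[, support, drop = FALSE], y)
  }
  v
}

# best single atom by exhaustive search over all L one-column fits
oracleBestSingleAtom <- function(A, y) {
  L <- ncol(A)
  best <- list(res = Inf, j = NA_integer_, coef = NA_real_)
  for (j in seq_len(L)) {
    a <- A[, j]
    if (sum(a^2) == 0) next
    cf <- sum(a * y) / sum(a^2)
    res <- sum((y - cf * a)^2)
    if (res < best$res) best <- list(res = res, j = j, coef = cf)
  }
  best
}

# one-vs-rest precision/recall/f1 and accuracy recomputed directly from the
# label vectors, no confusion matrix involved
oracleOvrMetrics <- function(true, pred, cls) {
  tp <- sum(true == cls & pred == cls)
  fp <- sum(true != cls & pred == cls)
  fn <- sum(true == cls & pred != cls)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

randomPlane <- function(N, seed) {
  set.seed(seed)
  matrix(runif(N * N, 0, 255), N, N)
}

# tiny deterministic RGB array fixture
randomImage <- function(N, seed) {
  set.seed(seed)
  array(runif(N * N * 3, 0, 255), c(N, N, 3))
}
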