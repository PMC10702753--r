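#' @include AllClasses.R
NULL

# run code with a temporary, restored RNG state
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Orthonormal DCT-II matrix
#'
#' The B x B type-II discrete cosine transform matrix in the orthonormal
#' convention, so that \code{D \%*\% t(D)} is the identity and the 2-D
#' transform \code{D X t(D)} preserves energy (Parseval).
#'
#' @param B block side, >= 2
#' @return B x B numeric matrix
#' @export
dctMatrix <- function(B) {
  B <- as.integer(B)
  stopifnot(B >= 2L)
  k <- 0:(B - 1L)
  n <- 0:(B - 1L)
  D <- outer(k, n, function(k, n) cos(pi * (2 * n + 1) * k / (2 * B)))
  D <- D * sqrt(2 / B)
  D[1L, ] <- sqrt(1 / B)
  D
}

#' Forward / inverse 2-D DCT of a pixel block
#'
#' Orthonormal type-II 2-D DCT: \code{X = D x t(D)} and its exact inverse
#' \code{x = t(D) X D}. A constant block of value c maps to a single DC
#' coefficient equal to B*c.
#'
#' @param block square numeric matrix (pixel block)
#' @param coeff square numeric matrix (DCT coefficient block)
#' @return square numeric matrix of the same size
#' @examples
#' x <- matrix(rnorm(64), 8, 8)
#' max(abs(inverseDCT2(forwardDCT2(x)) - x))  # ~1e-15
#' @export
forwardDCT2 <- function(block) {
  if (!is.matrix(block) || nrow(block) != ncol(block))
    stop("block must be a square matrix")
  if (any(!is.finite(block))) stop("block entries must be finite")
  D <- dctMatrix(nrow(block))
  D %*% block %*% t(D)
}

#' @rdname forwardDCT2
#' @export
inverseDCT2 <- function(coeff) {
  if (!is.matrix(coeff) || nrow(coeff) != ncol(coeff))
    stop("coeff must be a square matrix")
  D <- dctMatrix(nrow(coeff))
  t(D) %*% coeff %*% D
}

# plane (N x N) -> L x nblocks matrix; column j is the column-major
# vectorization of block j, blocks ordered row-major over the block grid
planeToCols <- function(plane, B) {
  N <- nrow(plane)
  nB <- N %/% B
  a <- array(plane, c(B, nB, B, nB))         # (r, blockRow, c, blockCol)
  m <- aperm(a, c(1L, 3L, 4L, 2L))           # (r, c, blockCol, blockRow)
  dim(m) <- c(B * B, nB * nB)
  m
}

colsToPlane <- function(cols, N, B) {
  nB <- N %/% B
  a <- array(cols, c(B, B, nB, nB))
  a <- aperm(a, c(1L, 4L, 2L, 3L))           # back to (r, blockRow, c, blockCol)
  dim(a) <- c(N, N)
  a
}

#' Split an image plane into B x B blocks
#'
#' Tiles an N x N plane into (N/B)^2 square blocks in deterministic
#' row-major block order (left to right within a band of rows, bands top to
#' bottom). \code{mergeBlocks} is the exact inverse under the same ordering.
#'
#' @param plane N x N numeric matrix with N divisible by B
#' @param B block side
#' @return list of B x B matrices
#' @export
splitIntoBlocks <- function(plane, B) {
  B <- as.integer(B)
  if (!is.matrix(plane)) stop("plane must be a matrix")
  if (nrow(plane) %% B != 0L)
    stop(sprintf("plane row count %d is not divisible by block size %d",
                 nrow(plane), B))
  if (ncol(plane) %% B != 0L)
    stop(sprintf("plane column count %d is not divisible by block size %d",
                 ncol(plane), B))
  if (nrow(plane) != ncol(plane)) stop("plane must be square")
  cols <- planeToCols(plane, B)
  lapply(seq_len(ncol(cols)), function(j) matrix(cols[, j], B, B))
}

#' @rdname splitIntoBlocks
#' @param blocks list of B x B matrices as produced by \code{splitIntoBlocks}
#' @param dims length-2 integer vector (N, N)
#' @export
mergeBlocks <- function(blocks, dims) {
  if (length(blocks) == 0L) stop("no blocks to merge")
  B <- nrow(blocks[[1L]])
  ok <- vapply(blocks, function(b) is.matrix(b) && all(dim(b) == B), logical(1))
  if (!all(ok)) stop("all blocks must be square matrices of the same size")
  N <- as.integer(dims[1L])
  if (N != dims[2L]) stop("only square planes are supported")
  if (length(blocks) * B * B != N * N)
    stop(sprintf("block count %d x %d^2 does not tile a %d x %d plane",
                 length(blocks), B, N, N))
  cols <- vapply(blocks, as.vector, numeric(B * B))
  colsToPlane(cols, N, B)
}

#' Vectorize / devectorize a coefficient block
#'
#' Fixed column-major convention: matrix element (r, c), 1-based, maps to
#' vector index (c - 1) * B + r. Any fixed bijection would serve; this one is
#' R's native \code{as.vector} ordering and round-trips losslessly.
#'
#' @param coeff B x B numeric matrix
#' @param v numeric vector of length B^2
#' @param B block side
#' @return a length-B^2 vector, or a B x B matrix
#' @export
vectorizeCoeffs <- function(coeff) {
  if (!is.matrix(coeff) || nrow(coeff) != ncol(coeff))
    stop("coeff must be a square matrix")
  as.vector(coeff)
}

#' @rdname vectorizeCoeffs
#' @export
devectorizeCoeffs <- function(v, B) {
  B <- as.integer(B)
  if (length(v) != B * B)
    stop(sprintf("vector length %d does not match B^2 = %d", length(v), B * B))
  matrix(v, B, B)
}

#' Generate the Gaussian measurement matrix
#'
#' Draws an M x L matrix with i.i.d. N(0, 1/M) entries from the given seed.
#' The 1/M variance makes ||A v|| approximately ||v|| in expectation; columns
#' are additionally L2-normalized inside the OMP atom-selection step only.
#' The same seed always reproduces the same matrix bitwise.
#'
#' @param M measurement count, 1 <= M <= L
#' @param L ambient dimension (B^2 for B x B blocks)
#' @param seed integer RNG seed
#' @return a \linkS4class{MeasurementMatrix}
#' @export
makeMeasurementMatrix <- function(M, L, seed) {
  M <- as.integer(M); L <- as.integer(L)
  if (M < 1L) stop("M must be >= 1")
  if (M > L) stop(sprintf("M (%d) must not exceed L (%d): acquisition must be compressive", M, L))
  entries <- withSeed(as.integer(seed),
                      matrix(stats::rnorm(M * L, sd = 1 / sqrt(M)), M, L))
  new("MeasurementMatrix", entries = entries, seed = as.integer(seed))
}

#' Compressive acquisition of a coefficient vector
#'
#' Computes the linear measurements Y = A v.
#'
#' @param A a \linkS4class{MeasurementMatrix}
#' @param v numeric coefficient vector of length L = ncol(A)
#' @return numeric measurement vector of length M
#' @export
acquire <- function(A, v) {
  if (!is(A, "MeasurementMatrix")) stop("A must be a MeasurementMatrix")
  if (length(v) != ncol(A@entries))
    stop(sprintf("vector length %d does not match L = %d", length(v),
                 ncol(A@entries)))
  as.vector(A@entries %*% v)
}

#' Orthogonal matching pursuit reconstruction
#'
#' Greedy sparse recovery of a length-L coefficient vector from M < L linear
#' measurements. Per iteration the atom (column of A, L2-normalized for the
#' correlation only) with maximal absolute correlation to the current
#' residual is added to the support, the measurements are re-fit by least
#' squares on the accumulated support (via an incremental Cholesky
#' factorization of the Gram matrix), and the residual is updated. Stopping
#' is dual: residual norm <= tol * ||Y||, or maxAtoms atoms selected,
#' whichever occurs first. All-zero (or numerically dependent) columns are
#' skipped during selection and never enter the support.
#'
#' @param A a \linkS4class{MeasurementMatrix} (M x L)
#' @param y numeric measurement vector of length M
#' @param maxAtoms maximum support size; defaults to M, must be <= M
#' @param tol relative residual tolerance (default 1e-6)
#' @return an \linkS4class{OMPResult}
#' @examples
#' A <- makeMeasurementMatrix(8, 64, seed = 3)
#' v <- generateSparseVector(64, 1, seed = 4)
#' fit <- ompReconstruct(A, acquire(A, v))
#' fit@support  # the true nonzero's index
#' @export
ompReconstruct <- function(A, y, maxAtoms = NULL, tol = 1e-6) {
  if (!is(A, "MeasurementMatrix")) stop("A must be a MeasurementMatrix")
  M <- nrow(A@entries)
  if (length(y) != M)
    stop(sprintf("measurement length %d does not match M = %d", length(y), M))
  if (is.null(maxAtoms)) maxAtoms <- M
  maxAtoms <- as.integer(maxAtoms)
  if (maxAtoms < 0L || maxAtoms > M)
    stop("maxAtoms must lie in [0, M]")
  r <- .cpp_omp_single(A@entries, as.numeric(y), maxAtoms, tol)
  new("OMPResult",
    estimate = as.numeric(r$estimate),
    support = as.integer(r$support) + 1L,
    residualNorm = r$residual_norm,
    iterations = as.integer(r$iterations),
    residualTrace = as.numeric(r$residual_trace))
}
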