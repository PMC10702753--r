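#' @include cs_core.R
NULL

# coerce a path / EBImage Image / array to an H x W x 3 array in [0, 255]
.toRGBArray <- function(image) {
  if (is.character(image)) {
    if (!file.exists(image)) stop("cannot read image file: ", image)
    image <- EBImage::readImage(image)
  }
  if (is(image, "Image")) image <- EBImage::imageData(image) * 255
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("image must be a file path, an EBImage Image, or an H x W x C array")
  d <- dim(image)
  if (d[1L] < 1L || d[2L] < 1L) stop("zero-size image")
  if (d[3L] == 1L) {
    image <- array(rep(image, 3L), c(d[1L], d[2L], 3L))   # grayscale -> RGB
  } else if (d[3L] > 3L) {
    image <- image[, , 1:3, drop = FALSE]                 # drop alpha
  } else if (d[3L] == 2L) {
    stop("two-channel images are not supported")
  }
  image
}

#' Preprocess an image for the codec
#'
#' Reads an RGB image (PNG/JPEG path, EBImage Image, or array), resizes it to
#' N x N by bilinear interpolation, and returns the three colour planes as
#' N x N matrices with values in [0, 255]. Grayscale inputs are replicated to
#' three identical planes; an alpha channel, if present, is dropped.
#'
#' @param image file path, EBImage \code{Image}, or numeric array in [0, 255]
#' @param config a \linkS4class{CodecConfig} supplying the target side N
#' @return list of three N x N numeric matrices (R, G, B)
#' @export
preprocess <- function(image, config = CodecConfig()) {
  arr <- .toRGBArray(image)
  N <- config@resizeTo
  if (!all(dim(arr)[1:2] == N)) {
    img <- EBImage::Image(arr / 255, colormode = "Color")
    arr <- EBImage::imageData(EBImage::resize(img, w = N, h = N)) * 255
  }
  arr[arr < 0] <- 0
  arr[arr > 255] <- 255
  lapply(1:3, function(ch) matrix(arr[, , ch], N, N))
}

#' Encode an image by block-based compressive sensing
#'
#' The full acquisition chain, per colour channel: resize to N x N, split
#' into B x B blocks, centre pixel values by subtracting 128, transform each
#' block by the orthonormal 2-D DCT, vectorize to length L = B^2, and acquire
#' Y = A v with the shared M x L Gaussian measurement matrix regenerated from
#' the config seed. Deterministic given (image, config).
#'
#' @param image file path, EBImage Image, or H x W x 3 array in [0, 255]
#' @param config a \linkS4class{CodecConfig}
#' @return a \linkS4class{CompressedImage}
#' @examples
#' img <- generateClassImage("carrot", size = 64, seed = 1)
#' ci <- encodeImage(img, CodecConfig(resizeTo = 64L, measurements = 32L))
#' rec <- decodeImage(ci)
#' psnr(img, rec)
#' @export
encodeImage <- function(image, config = CodecConfig()) {
  planes <- preprocess(image, config)
  B <- config@blockSize
  A <- makeMeasurementMatrix(config@measurements, B * B, config@seed)
  D <- dctMatrix(B)
  TT <- D %x% D          # vec(D X t(D)) = (D kron D) vec(X)
  payload <- lapply(planes, function(p) {
    V <- TT %*% planeToCols(p - 128, B)
    unname(A@entries %*% V)
  })
  new("CompressedImage", config = config, channels = 3L, payload = payload)
}

#' Decode a compressed image
#'
#' Inverts the acquisition chain: regenerate A from the stored seed, recover
#' each block's DCT coefficient vector by OMP, devectorize, apply the inverse
#' DCT, add back the 128 centring offset, clip to [0, 255], merge the blocks,
#' and round to 8-bit. Deterministic given its input.
#'
#' @param compressed a \linkS4class{CompressedImage}
#' @param tol relative OMP residual tolerance (default 1e-6)
#' @return N x N x 3 numeric array with integer values in [0, 255]
#' @export
decodeImage <- function(compressed, tol = 1e-6) {
  stopifnot(is(compressed, "CompressedImage"))
  validObject(compressed)
  cfg <- compressed@config
  B <- cfg@blockSize; N <- cfg@resizeTo; M <- cfg@measurements
  A <- makeMeasurementMatrix(M, B * B, cfg@seed)
  D <- dctMatrix(B)
  TT <- D %x% D
  out <- array(0, c(N, N, compressed@channels))
  for (ch in seq_len(compressed@channels)) {
    V <- .cpp_omp_batch(A@entries, compressed@payload[[ch]], M, tol)
    p <- colsToPlane(crossprod(TT, V), N, B) + 128
    p[p < 0] <- 0
    p[p > 255] <- 255
    out[, , ch] <- round(p)
  }
  out
}

#' Peak signal-to-noise ratio
#'
#' 10 log10(255^2 / MSE) in decibels for 8-bit image data, computed over all
#' supplied channels. Identical inputs yield \code{Inf}.
#'
#' @param original,reconstructed numeric matrices or arrays of the same shape
#' @return PSNR in dB (\code{Inf} for identical inputs)
#' @export
psnr <- function(original, reconstructed) {
  if (!all(dim(original) == dim(reconstructed)))
    stop("original and reconstructed must have the same shape")
  mse <- mean((as.numeric(original) - as.numeric(reconstructed))^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

# ---- .bcs container -------------------------------------------------------
# magic "BCS1" | version int32 | N | B | M | seed | channels (all int32, LE)
# followed by channels * nblocks * M doubles (LE), channel-major, blocks in
# row-major order, each measurement vector contiguous.

#' Read and write the .bcs compressed container
#'
#' A single-file serialization of a \linkS4class{CompressedImage}: an
#' explicit little-endian header (magic, version, N, B, M, seed, channels)
#' followed by the raw measurement payload. The measurement matrix itself is
#' not stored; it is regenerated from the seed on decode.
#'
#' @param compressed a \linkS4class{CompressedImage}
#' @param path file path (conventional extension: .bcs)
#' @return \code{writeBCS} returns \code{path} invisibly; \code{readBCS}
#'   returns a \linkS4class{CompressedImage}
#' @export
writeBCS <- function(compressed, path) {
  stopifnot(is(compressed, "CompressedImage"))
  validObject(compressed)
  cfg <- compressed@config
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BCS1"), con)
  writeBin(as.integer(c(1L, cfg@resizeTo, cfg@blockSize, cfg@measurements,
                        cfg@seed, compressed@channels)),
           con, size = 4L, endian = "little")
  for (p in compressed@payload)
    writeBin(as.numeric(p), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname writeBCS
#' @export
readBCS <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, charToRaw("BCS1")))
    stop("not a .bcs container (bad magic): ", path)
  hdr <- readBin(con, "integer", 6L, size = 4L, endian = "little")
  if (length(hdr) != 6L || hdr[1L] != 1L)
    stop("unsupported .bcs version in ", path)
  N <- hdr[2L]; B <- hdr[3L]; M <- hdr[4L]; seed <- hdr[5L]; chn <- hdr[6L]
  cfg <- tryCatch(
    CodecConfig(resizeTo = N, blockSize = B, measurements = M, seed = seed),
    error = function(e) stop("corrupted .bcs header in ", path, ": ",
                             conditionMessage(e)))
  nb <- (N %/% B)^2
  want <- as.numeric(chn) * nb * M
  vals <- readBin(con, "numeric", want + 1L, size = 8L, endian = "little")
  if (length(vals) != want)
    stop(sprintf("corrupted .bcs payload in %s: expected %d values, found %d",
                 path, want, length(vals)))
  payload <- lapply(seq_len(chn), function(ch)
    matrix(vals[((ch - 1L) * nb * M + 1L):(ch * nb * M)], M, nb))
  new("CompressedImage", config = cfg, channels = as.integer(chn),
      payload = payload)
}

#' Write an RGB array as a PNG file
#'
#' @param img H x W x 3 numeric array with values in [0, 255]
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeImagePNG <- function(img, path) {
  EBImage::writeImage(EBImage::Image(img / 255, colormode = "Color"), path,
                      type = "png")
  invisible(path)
}

#' Encode and decode every image of a dataset
#'
#' Runs the full compressive-sensing round trip (encode at the configured M,
#' OMP decode) on every image, keeping labels, so classifiers can be trained
#' and tested on reconstructed data at a chosen compression ratio.
#'
#' @param ds a \linkS4class{LabeledDataset}
#' @param config a \linkS4class{CodecConfig}; its \code{resizeTo} determines
#'   the reconstructed image side
#' @return a \linkS4class{LabeledDataset} of reconstructed images
#' @export
transcodeDataset <- function(ds, config) {
  stopifnot(is(ds, "LabeledDataset"), is(config, "CodecConfig"))
  images <- lapply(ds@images, function(im)
    decodeImage(encodeImage(im, config)))
  new("LabeledDataset", images = images, labels = ds@labels,
      classes = ds@classes)
}
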