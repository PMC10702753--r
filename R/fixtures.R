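#' @include cs_core.R
NULL

#' Parametric style table for the synthetic classes
#'
#' Each of the four classes is defined by a base colour, a shape mask family
#' and a texture frequency/amplitude, all in one table so the separability
#' margins are auditable. Base colours (RGB in [0, 255]):
#' broccoli (60, 140, 50), carrot (230, 130, 30), potato (150, 110, 70),
#' radish (235, 225, 230). The minimum pairwise base-colour distance is
#' about 93 gray levels, so the mean colour of the foreground (object)
#' region separates any two styles by well over 40 gray levels — the margin
#' the fixture contract guarantees. (The background is a dark gray of 40, so
#' foreground pixels are recoverable by a brightness threshold of 80.)
#'
#' @return data.frame with one row per style, rownames = style names
#' @export
fixtureStyles <- function() {
  df <- data.frame(
    r = c(60, 230, 150, 235),
    g = c(140, 130, 110, 225),
    b = c(50, 30, 70, 230),
    shape = c("discs", "taper", "ellipse", "capsule"),
    frequency = c(14, 4, 7, 2),
    amplitude = c(25, 18, 12, 10),
    stringsAsFactors = FALSE)
  rownames(df) <- c("broccoli", "carrot", "potato", "radish")
  df
}

# shape masks on rotated/translated/scaled coordinates (u, v) in ~[-1, 1]
.shapeMask <- function(shape, u, v, phase) {
  switch(shape,
    discs = {
      mask <- matrix(FALSE, nrow(u), ncol(u))
      for (k in 1:7) {
        cx <- stats::runif(1, -0.3, 0.3)
        cy <- stats::runif(1, -0.3, 0.3)
        rad <- stats::runif(1, 0.18, 0.3)
        mask <- mask | ((u - cx)^2 + (v - cy)^2 < rad^2)
      }
      mask
    },
    taper = (u > -0.85 & u < 0.85) & (abs(v) < 0.03 + 0.16 * (0.85 - u)),
    ellipse = {
      wob <- 0.08 * sin(3 * atan2(v, u) + phase)
      (u / (0.62 + wob))^2 + (v / (0.42 + wob))^2 < 1
    },
    capsule = {
      du <- pmax(abs(u) - 0.35, 0)
      du^2 + v^2 < 0.28^2
    },
    stop("unknown shape: ", shape))
}

#' Generate one synthetic class image
#'
#' Deterministic given (style, seed): a shape mask (cluster of discs /
#' elongated taper / wobbled ellipse / capsule) filled with the style's base
#' colour, modulated by a sinusoidal texture at the style's frequency, under
#' a randomized rotation, translation and scale, on a dark background, with
#' additive Gaussian pixel noise on every channel. Values are clipped to
#' [0, 255] and rounded so the image survives a PNG round trip bit-exactly.
#'
#' @param style one of \code{rownames(fixtureStyles())}
#' @param size image side in pixels (any positive value; multiples of 8
#'   integrate with the codec)
#' @param seed integer seed
#' @param noiseSd pixel-noise standard deviation in gray levels (default 8)
#' @return size x size x 3 numeric array with integer values in [0, 255]
#' @export
generateClassImage <- function(style, size = 64L, seed = 1L, noiseSd = 8) {
  styles <- fixtureStyles()
  if (!style %in% rownames(styles))
    stop("unknown style: ", style, " (expected one of ",
         paste(rownames(styles), collapse = ", "), ")")
  st <- styles[style, ]
  size <- as.integer(size)
  stopifnot(size >= 8L)
  withSeed(as.integer(seed), {
    theta <- stats::runif(1, -pi, pi)
    tx <- stats::runif(1, -0.12, 0.12)
    ty <- stats::runif(1, -0.12, 0.12)
    sc <- stats::runif(1, 0.75, 1.05)
    phase <- stats::runif(1, 0, 2 * pi)
    psi <- stats::runif(1, 0, pi)
    g <- seq(-1, 1, length.out = size)
    x <- matrix(g, size, size)                 # varies along rows
    y <- matrix(g, size, size, byrow = TRUE)   # varies along columns
    u <- ((x - tx) * cos(theta) + (y - ty) * sin(theta)) / sc
    v <- (-(x - tx) * sin(theta) + (y - ty) * cos(theta)) / sc
    mask <- .shapeMask(st$shape, u, v, phase)
    tex <- st$amplitude *
      sin(st$frequency * pi * (u * cos(psi) + v * sin(psi)) + phase)
    bg <- 40
    base <- c(st$r, st$g, st$b)
    img <- array(0, c(size, size, 3L))
    for (ch in 1:3) {
      plane <- bg + mask * (base[ch] - bg + tex) +
        stats::rnorm(size * size, 0, noiseSd)
      plane[plane < 0] <- 0
      plane[plane > 255] <- 255
      img[, , ch] <- round(plane)
    }
    img
  })
}

#' Generate a balanced labelled dataset
#'
#' \code{imagesPerClass} images for each style in the spec, with
#' deterministic per-image seeds derived from the base seed, so the same
#' spec always reproduces the same dataset bit for bit.
#'
#' @param spec a \linkS4class{FixtureSpec}
#' @return a \linkS4class{LabeledDataset}
#' @examples
#' ds <- generateDataset(FixtureSpec(imagesPerClass = 5L, imageSize = 16L))
#' length(ds)  # 20
#' @export
generateDataset <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"))
  validObject(spec)
  n <- spec@imagesPerClass
  images <- vector("list", length(spec@classes) * n)
  labels <- character(length(images))
  k <- 0L
  for (ci in seq_along(spec@classes)) {
    for (j in seq_len(n)) {
      k <- k + 1L
      images[[k]] <- generateClassImage(
        spec@classes[ci], size = spec@imageSize,
        seed = spec@seed + (ci - 1L) * n + (j - 1L),
        noiseSd = spec@noiseSd)
      labels[k] <- spec@classes[ci]
    }
  }
  new("LabeledDataset", images = images,
      labels = factor(labels, levels = spec@classes),
      classes = spec@classes)
}

#' Generate an exactly K-sparse coefficient vector
#'
#' Support drawn uniformly without replacement; nonzero values have random
#' sign and magnitude uniform in \code{amplitudeRange}, bounded away from
#' zero.
#'
#' @param L ambient dimension
#' @param K number of nonzeros, 0 <= K <= L
#' @param amplitudeRange length-2 positive range of nonzero magnitudes
#' @param seed integer seed
#' @return numeric vector of length L with exactly K nonzeros
#' @export
generateSparseVector <- function(L, K, amplitudeRange = c(1, 3), seed = 1L) {
  L <- as.integer(L); K <- as.integer(K)
  if (K < 0L || K > L) stop(sprintf("K (%d) must lie in [0, L = %d]", K, L))
  stopifnot(length(amplitudeRange) == 2L, all(amplitudeRange > 0))
  v <- numeric(L)
  if (K > 0L) {
    withSeed(as.integer(seed), {
      sup <- sample.int(L, K)
      mag <- stats::runif(K, amplitudeRange[1L], amplitudeRange[2L])
      sgn <- sample(c(-1, 1), K, replace = TRUE)
      v[sup] <- sgn * mag
    })
  }
  v
}

#' Write a dataset as a directory tree of PNGs
#'
#' Layout: \code{<root>/<class>/<index>.png}, the conventional
#' image-dataset arrangement that \code{\link{loadDatasetDir}} reads back.
#'
#' @param ds a \linkS4class{LabeledDataset}
#' @param root output directory (created if needed)
#' @return number of files written, invisibly
#' @export
writeFixtureDir <- function(ds, root) {
  stopifnot(is(ds, "LabeledDataset"))
  counter <- integer(length(ds@classes))
  names(counter) <- ds@classes
  for (k in seq_along(ds@images)) {
    cls <- as.character(ds@labels[k])
    dir.create(file.path(root, cls), recursive = TRUE, showWarnings = FALSE)
    counter[cls] <- counter[cls] + 1L
    writeImagePNG(ds@images[[k]],
                  file.path(root, cls, sprintf("%04d.png", counter[cls])))
  }
  invisible(length(ds@images))
}

#' Load a dataset from a directory tree
#'
#' Expects \code{<root>/<class>/*.png|jpg}; one subdirectory per class.
#'
#' @param root dataset root directory
#' @param classes optional ordered class names; defaults to the sorted
#'   subdirectory names
#' @return a \linkS4class{LabeledDataset}
#' @export
loadDatasetDir <- function(root, classes = NULL) {
  if (!dir.exists(root)) stop("no such directory: ", root)
  if (is.null(classes))
    classes <- sort(basename(list.dirs(root, recursive = FALSE)))
  if (length(classes) == 0L) stop("no class subdirectories under ", root)
  images <- list()
  labels <- character(0)
  for (cls in classes) {
    files <- sort(list.files(file.path(root, cls),
                             pattern = "\\.(png|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    for (f in files) {
      images[[length(images) + 1L]] <- .toRGBArray(f)
      labels <- c(labels, cls)
    }
  }
  new("LabeledDataset", images = images,
      labels = factor(labels, levels = classes), classes = classes)
}
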