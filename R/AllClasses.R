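#' @import methods
NULL

#' Codec configuration
#'
#' Parameters of the block-based compressive-sensing codec: target image side
#' \code{resizeTo} (N), block side \code{blockSize} (B), number of Gaussian
#' measurements per block \code{measurements} (M), and the RNG seed used to
#' generate the shared measurement matrix. The ambient dimension per block is
#' L = B^2 and the nominal compression ratio is B^2 / M.
#'
#' @slot resizeTo integer, image side N after resizing (default 256)
#' @slot blockSize integer, block side B (default 8)
#' @slot measurements integer, measurements per block M, 1 <= M <= B^2
#' @slot seed integer seed for the measurement matrix
#' @export
setClass("CodecConfig",
  slots = c(
    resizeTo = "integer",
    blockSize = "integer",
    measurements = "integer",
    seed = "integer"
  )
)

setValidity("CodecConfig", function(object) {
  N <- object@resizeTo; B <- object@blockSize; M <- object@measurements
  if (length(N) != 1L || length(B) != 1L || length(M) != 1L)
    return("resizeTo, blockSize and measurements must be scalars")
  if (B < 2L) return("blockSize must be >= 2")
  if (N < B || N %% B != 0L)
    return(sprintf("resizeTo (%d) must be a positive multiple of blockSize (%d)", N, B))
  if (M < 1L || M > B * B)
    return(sprintf("measurements (%d) must satisfy 1 <= M <= B^2 = %d", M, B * B))
  TRUE
})

#' Construct a CodecConfig
#'
#' @param resizeTo image side N (default 256)
#' @param blockSize block side B (default 8)
#' @param measurements measurements per block M (default 32, i.e. CR = 2)
#' @param seed seed for the Gaussian measurement matrix
#' @return a \linkS4class{CodecConfig}
#' @examples
#' CodecConfig(measurements = 32L)
#' @export
CodecConfig <- function(resizeTo = 256L, blockSize = 8L, measurements = 32L,
                        seed = 1L) {
  new("CodecConfig",
    resizeTo = as.integer(resizeTo), blockSize = as.integer(blockSize),
    measurements = as.integer(measurements), seed = as.integer(seed))
}

#' Gaussian measurement matrix
#'
#' The shared M x L acquisition operator A with i.i.d. N(0, 1/M) entries,
#' regenerable from its seed. One matrix is generated per run and reused for
#' every block and channel, so encoder and decoder agree by exchanging the
#' seed alone.
#'
#' @slot entries M x L numeric matrix
#' @slot seed integer seed the entries were drawn from
#' @export
setClass("MeasurementMatrix",
  slots = c(entries = "matrix", seed = "integer"))

setValidity("MeasurementMatrix", function(object) {
  A <- object@entries
  if (!is.numeric(A)) return("entries must be numeric")
  if (nrow(A) > ncol(A)) return("M must not exceed L (compressive acquisition)")
  if (any(!is.finite(A))) return("entries must be finite")
  TRUE
})

#' Compressed image container
#'
#' Header (image side N, block side B, measurements M, matrix seed, channel
#' count) plus, per channel, an M x nblocks matrix of measurement vectors in
#' row-major block order. Decodable from the header alone: the measurement
#' matrix is regenerated from the stored seed.
#'
#' @slot config the \linkS4class{CodecConfig} used to encode
#' @slot channels integer channel count (3 for RGB)
#' @slot payload list of length \code{channels}; each element an M x nblocks matrix
#' @export
setClass("CompressedImage",
  slots = c(config = "CodecConfig", channels = "integer", payload = "list"))

setValidity("CompressedImage", function(object) {
  cfg <- object@config
  nb <- (cfg@resizeTo %/% cfg@blockSize)^2
  if (length(object@payload) != object@channels)
    return("payload must hold one matrix per channel")
  for (p in object@payload) {
    if (!is.matrix(p) || nrow(p) != cfg@measurements || ncol(p) != nb)
      return(sprintf("each payload matrix must be %d x %d", cfg@measurements, nb))
  }
  TRUE
})

#' OMP reconstruction result
#'
#' Output of orthogonal matching pursuit for one measurement vector: the
#' length-L coefficient estimate, the selected support (1-based indices), the
#' final residual norm, the iteration count, and the residual-norm trace
#' (one value per iteration, nonincreasing).
#'
#' @slot estimate numeric length-L estimate; nonzeros only on the support
#' @slot support integer vector of selected atom indices
#' @slot residualNorm final value of ||Y - A estimate||_2
#' @slot iterations number of atoms selected
#' @slot residualTrace residual norm after each iteration
#' @export
setClass("OMPResult",
  slots = c(
    estimate = "numeric", support = "integer",
    residualNorm = "numeric", iterations = "integer",
    residualTrace = "numeric"
  )
)

#' Labelled image dataset
#'
#' @slot images list of H x W x 3 numeric arrays with values in [0, 255]
#' @slot labels factor of class labels, one per image
#' @slot classes ordered character vector of class names
#' @export
setClass("LabeledDataset",
  slots = c(images = "list", labels = "factor", classes = "character"))

setValidity("LabeledDataset", function(object) {
  if (length(object@images) != length(object@labels))
    return("one label per image required")
  if (!all(levels(object@labels) == object@classes))
    return("label levels must equal the ordered class set")
  if (length(object@images) && !all(as.character(object@labels) %in% object@classes))
    return("all labels must belong to the class set")
  TRUE
})

#' Convolutional network architecture
#'
#' A stack of convolution / ReLU / max-pool stages followed by fully
#' connected layers with dropout and a softmax output. Built by
#' \code{\link{buildModel}}.
#'
#' @slot preset "small" or "alexnet"
#' @slot inputSize network input side in pixels
#' @slot channels input channel count
#' @slot numClasses softmax width
#' @slot dropout dropout rate on the hidden fully connected layers
#' @slot layers layer specification list consumed by the C++ engine
#' @export
setClass("ModelArch",
  slots = c(
    preset = "character", inputSize = "integer", channels = "integer",
    numClasses = "integer", dropout = "numeric", layers = "list"
  )
)

#' Training configuration
#'
#' Defaults follow the study's predetermined input parameters: SGD optimizer,
#' 100 epochs, batch size 64, dropout 0.4, learning rate 0.001. Momentum 0.9
#' is this package's documented choice (the optimizer family and rate alone
#' are prescribed).
#'
#' @slot optimizer character, currently only "sgd"
#' @slot epochs integer
#' @slot batchSize integer
#' @slot dropout numeric in [0, 1)
#' @slot learningRate numeric > 0
#' @slot momentum numeric in [0, 1)
#' @slot seed integer RNG seed (weights, shuffling, dropout)
#' @export
setClass("TrainConfig",
  slots = c(
    optimizer = "character", epochs = "integer", batchSize = "integer",
    dropout = "numeric", learningRate = "numeric", momentum = "numeric",
    seed = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  if (!identical(tolower(object@optimizer), "sgd"))
    return("only the SGD optimizer family is supported")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@dropout < 0 || object@dropout >= 1) return("dropout must be in [0, 1)")
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@momentum < 0 || object@momentum >= 1) return("momentum must be in [0, 1)")
  TRUE
})

#' Construct a TrainConfig
#'
#' @param optimizer optimizer family tag; only \code{"sgd"}
#' @param epochs training epochs (default 100)
#' @param batchSize minibatch size (default 64)
#' @param dropout dropout rate applied to the hidden dense layers (default 0.4)
#' @param learningRate SGD learning rate (default 0.001)
#' @param momentum SGD momentum (default 0.9)
#' @param seed RNG seed
#' @return a \linkS4class{TrainConfig}
#' @export
TrainConfig <- function(optimizer = "sgd", epochs = 100L, batchSize = 64L,
                        dropout = 0.4, learningRate = 0.001, momentum = 0.9,
                        seed = 1L) {
  new("TrainConfig",
    optimizer = optimizer, epochs = as.integer(epochs),
    batchSize = as.integer(batchSize), dropout = dropout,
    learningRate = learningRate, momentum = momentum, seed = as.integer(seed))
}

#' Trained classifier
#'
#' @slot arch the \linkS4class{ModelArch}
#' @slot params learned parameter list (one W/b pair per conv or dense layer)
#' @slot history data.frame with one row per epoch:
#'   epoch, train_loss, train_acc, val_loss, val_acc
#' @slot classes ordered class labels the softmax columns refer to
#' @export
setClass("TrainedModel",
  slots = c(
    arch = "ModelArch", params = "list", history = "data.frame",
    classes = "character"
  )
)

#' Confusion matrix
#'
#' C x C table of counts with rows indexing the true class and columns the
#' predicted class; the substrate for precision, recall, F1 and accuracy.
#'
#' @slot counts integer matrix, rows = true, columns = predicted
#' @slot classes ordered class labels
#' @export
setClass("ConfusionMatrix",
  slots = c(counts = "matrix", classes = "character"))

setValidity("ConfusionMatrix", function(object) {
  cm <- object@counts
  C <- length(object@classes)
  if (nrow(cm) != C || ncol(cm) != C)
    return("counts must be C x C for C classes")
  if (any(cm < 0) || any(cm != round(cm)))
    return("counts must be nonnegative integers")
  TRUE
})

#' Synthetic fixture specification
#'
#' Describes a synthetic four-class image set: per-class image count, image
#' side (divisible by 8), base seed, and the standard deviation of the
#' additive pixel noise (default 8 gray levels).
#'
#' @slot classes character styles, a subset of
#'   broccoli / carrot / potato / radish
#' @slot imagesPerClass integer >= 1
#' @slot imageSize integer side, divisible by 8
#' @slot seed integer base seed
#' @slot noiseSd numeric noise standard deviation in gray levels
#' @export
setClass("FixtureSpec",
  slots = c(
    classes = "character", imagesPerClass = "integer",
    imageSize = "integer", seed = "integer", noiseSd = "numeric"
  )
)

setValidity("FixtureSpec", function(object) {
  if (object@imagesPerClass < 1L) return("imagesPerClass must be >= 1")
  if (object@imageSize < 8L || object@imageSize %% 8L != 0L)
    return("imageSize must be a positive multiple of 8")
  if (!all(object@classes %in% rownames(fixtureStyles())))
    return("unknown style in classes")
  TRUE
})

#' Construct a FixtureSpec
#'
#' @param classes style names (default all four)
#' @param imagesPerClass images per class
#' @param imageSize image side, divisible by 8
#' @param seed base seed; image i of class c uses a deterministic offset of it
#' @param noiseSd additive Gaussian pixel-noise sd in gray levels
#' @return a \linkS4class{FixtureSpec}
#' @export
FixtureSpec <- function(classes = c("broccoli", "carrot", "potato", "radish"),
                        imagesPerClass = 10L, imageSize = 64L, seed = 1L,
                        noiseSd = 8) {
  new("FixtureSpec",
    classes = classes, imagesPerClass = as.integer(imagesPerClass),
    imageSize = as.integer(imageSize), seed = as.integer(seed),
    noiseSd = noiseSd)
}
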