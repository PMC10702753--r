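#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the codec and classifier containers.
#'
#' @param x an object
#' @return the corresponding slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("blockSize", function(x) standardGeneric("blockSize"))
#' @rdname accessors
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))
#' @rdname accessors
#' @export
setGeneric("resizeTo", function(x) standardGeneric("resizeTo"))
#' @rdname accessors
#' @export
setGeneric("codecSeed", function(x) standardGeneric("codecSeed"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname accessors
setMethod("blockSize", "CodecConfig", function(x) x@blockSize)
#' @rdname accessors
setMethod("measurements", "CodecConfig", function(x) x@measurements)
#' @rdname accessors
setMethod("resizeTo", "CodecConfig", function(x) x@resizeTo)
#' @rdname accessors
setMethod("codecSeed", "CodecConfig", function(x) x@seed)
#' @rdname accessors
setMethod("blockSize", "CompressedImage", function(x) x@config@blockSize)
#' @rdname accessors
setMethod("measurements", "CompressedImage", function(x) x@config@measurements)
#' @rdname accessors
setMethod("resizeTo", "CompressedImage", function(x) x@config@resizeTo)
#' @rdname accessors
setMethod("codecSeed", "CompressedImage", function(x) x@config@seed)
#' @rdname accessors
setMethod("classLabels", "LabeledDataset", function(x) x@classes)
#' @rdname accessors
setMethod("classLabels", "ConfusionMatrix", function(x) x@classes)
#' @rdname accessors
setMethod("classLabels", "TrainedModel", function(x) x@classes)
#' @rdname accessors
setMethod("counts", "ConfusionMatrix", function(x) x@counts)
#' @rdname accessors
setMethod("trainingHistory", "TrainedModel", function(x) x@history)

#' @describeIn accessors matrix form of a measurement matrix
#' @param ... ignored
#' @export
setMethod("as.matrix", "MeasurementMatrix", function(x, ...) x@entries)

#' @rdname accessors
setMethod("dim", "MeasurementMatrix", function(x) dim(x@entries))

#' Number of items in a dataset
#' @param x a LabeledDataset
#' @export
setMethod("length", "LabeledDataset", function(x) length(x@images))

setMethod("show", "CodecConfig", function(object) {
  cat(sprintf(
    "CodecConfig: N=%d, B=%d, M=%d (L=%d, CR=%.3g), seed=%d\n",
    object@resizeTo, object@blockSize, object@measurements,
    object@blockSize^2, object@blockSize^2 / object@measurements,
    object@seed))
})

setMethod("show", "CompressedImage", function(object) {
  cfg <- object@config
  nb <- (cfg@resizeTo %/% cfg@blockSize)^2
  cat(sprintf(
    "CompressedImage: %dx%d, %d channel(s), %d blocks x %d measurements (CR=%.3g), seed=%d\n",
    cfg@resizeTo, cfg@resizeTo, object@channels, nb, cfg@measurements,
    cfg@blockSize^2 / cfg@measurements, cfg@seed))
})

setMethod("show", "OMPResult", function(object) {
  cat(sprintf(
    "OMPResult: %d atom(s) selected, residual norm %.3e\n",
    object@iterations, object@residualNorm))
})

setMethod("show", "LabeledDataset", function(object) {
  cat(sprintf("LabeledDataset: %d image(s), %d class(es)\n",
              length(object@images), length(object@classes)))
  if (length(object@labels)) print(table(object@labels))
})

setMethod("show", "TrainedModel", function(object) {
  h <- object@history
  cat(sprintf(
    "TrainedModel (%s, input %dx%d, %d classes): %d epoch(s)\n",
    object@arch@preset, object@arch@inputSize, object@arch@inputSize,
    object@arch@numClasses, nrow(h)))
  if (nrow(h)) {
    last <- h[nrow(h), ]
    cat(sprintf("  final train acc %.3f, loss %.3f", last$train_acc, last$train_loss))
    if (!is.na(last$val_acc))
      cat(sprintf("; val acc %.3f, loss %.3f", last$val_acc, last$val_loss))
    cat("\n")
  }
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix (%d classes, %d items; rows = true):\n",
              length(object@classes), sum(object@counts)))
  m <- object@counts
  dimnames(m) <- list(true = object@classes, predicted = object@classes)
  print(m)
})
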