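#' @include AllClasses.R
NULL

#' Stratified dataset split
#'
#' Splits a labelled dataset into train / validation / test subsets,
#' stratified by class: within every class the items are shuffled with the
#' given seed and allocated according to \code{fractions} (largest-remainder
#' rounding, so per-class proportions are preserved within one item). The
#' three subsets are disjoint and their union is the input.
#'
#' @param ds a \linkS4class{LabeledDataset}
#' @param fractions length-3 numeric (train, validation, test); all strictly
#'   positive, summing to 1 within 1e-9
#' @param seed integer shuffle seed
#' @return named list of three \linkS4class{LabeledDataset}s:
#'   \code{train}, \code{validation}, \code{test}
#' @examples
#' ds <- generateDataset(FixtureSpec(imagesPerClass = 10L, imageSize = 16L))
#' sp <- splitDataset(ds, c(0.7, 0.1, 0.2), seed = 1)
#' vapply(sp, length, integer(1))  # 28 / 4 / 8
#' @export
splitDataset <- function(ds, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(is(ds, "LabeledDataset"))
  if (length(fractions) != 3L) stop("fractions must have length 3")
  if (any(fractions <= 0)) stop("all three fractions must be strictly positive")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  idx <- split(seq_along(ds@labels), ds@labels)
  take <- list(integer(0), integer(0), integer(0))
  withSeed(as.integer(seed), {
    for (cls in names(idx)) {
      ii <- idx[[cls]]
      n <- length(ii)
      if (n < 3L)
        stop(sprintf("class '%s' has %d item(s), fewer than the 3 splits", cls, n))
      ii <- ii[sample.int(n)]
      base <- floor(fractions * n)
      rem <- n - sum(base)
      if (rem > 0) {
        extra <- order(fractions * n - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
      }
      while (any(base == 0L)) {    # extreme fractions: keep every split nonempty
        base[which.max(base)] <- base[which.max(base)] - 1L
        base[which(base == 0L)[1L]] <- 1L
      }
      ends <- cumsum(base)
      starts <- c(1L, ends[-3L] + 1L)
      for (k in 1:3)
        take[[k]] <- c(take[[k]], ii[starts[k]:ends[k]])
    }
  })
  subsetOf <- function(keep) {
    new("LabeledDataset",
        images = ds@images[keep],
        labels = factor(as.character(ds@labels[keep]), levels = ds@classes),
        classes = ds@classes)
  }
  list(train = subsetOf(take[[1L]]),
       validation = subsetOf(take[[2L]]),
       test = subsetOf(take[[3L]]))
}

# layer lists for the two presets
.smallLayers <- function(numClasses, dropout) {
  list(
    list(type = "conv", filters = 8L, kernel = 3L, stride = 1L, pad = 1L),
    list(type = "relu"),
    list(type = "pool", size = 2L, stride = 2L),
    list(type = "conv", filters = 16L, kernel = 3L, stride = 1L, pad = 1L),
    list(type = "relu"),
    list(type = "pool", size = 2L, stride = 2L),
    list(type = "conv", filters = 32L, kernel = 3L, stride = 1L, pad = 1L),
    list(type = "relu"),
    list(type = "pool", size = 2L, stride = 2L),
    list(type = "flatten"),
    list(type = "dense", units = 64L),
    list(type = "relu"),
    list(type = "dropout", rate = dropout),
    list(type = "dense", units = as.integer(numClasses))
  )
}

.alexnetLayers <- function(numClasses, dropout) {
  list(
    list(type = "conv", filters = 96L, kernel = 11L, stride = 4L, pad = 0L),
    list(type = "relu"),
    list(type = "pool", size = 3L, stride = 2L),
    list(type = "conv", filters = 256L, kernel = 5L, stride = 1L, pad = 2L),
    list(type = "relu"),
    list(type = "pool", size = 3L, stride = 2L),
    list(type = "conv", filters = 384L, kernel = 3L, stride = 1L, pad = 1L),
    list(type = "relu"),
    list(type = "conv", filters = 384L, kernel = 3L, stride = 1L, pad = 1L),
    list(type = "relu"),
    list(type = "conv", filters = 256L, kernel = 3L, stride = 1L, pad = 1L),
    list(type = "relu"),
    list(type = "pool", size = 3L, stride = 2L),
    list(type = "flatten"),
    list(type = "dense", units = 4096L),
    list(type = "relu"),
    list(type = "dropout", rate = dropout),
    list(type = "dense", units = 4096L),
    list(type = "relu"),
    list(type = "dropout", rate = dropout),
    list(type = "dense", units = as.integer(numClasses))
  )
}

#' Build a convolutional classifier architecture
#'
#' Two presets are provided. \code{"alexnet"} is the classic five-stage
#' convolutional stack (96/256/384/384/256 filters, overlapping 3x2 pooling)
#' with two 4096-unit fully connected layers, dropout on both, and a softmax
#' output; its native input is 227 x 227. \code{"small"} is a scaled-down
#' three-stage variant (8/16/32 filters, one 64-unit hidden dense layer,
#' dropout on it) with a 64 x 64 native input, intended for desk-scale
#' experiments. With \code{dropout = 0} the dropout layers are inert and the
#' architecture is otherwise unchanged.
#'
#' @param numClasses softmax width, >= 2
#' @param dropout dropout rate on the hidden dense layers (default 0.4)
#' @param preset \code{"small"} (default) or \code{"alexnet"}
#' @param inputSize input side in pixels; defaults to the preset's native
#'   size (64 for small, 227 for alexnet). The small preset requires a
#'   multiple of 8 (three halvings by pooling).
#' @return a \linkS4class{ModelArch}
#' @export
buildModel <- function(numClasses, dropout = 0.4,
                       preset = c("small", "alexnet"), inputSize = NULL) {
  preset <- match.arg(preset)
  numClasses <- as.integer(numClasses)
  if (numClasses < 2L) stop("numClasses must be >= 2")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (is.null(inputSize)) inputSize <- if (preset == "small") 64L else 227L
  inputSize <- as.integer(inputSize)
  if (preset == "small") {
    if (inputSize < 8L || inputSize %% 8L != 0L)
      stop("small preset requires inputSize to be a multiple of 8")
    layers <- .smallLayers(numClasses, dropout)
  } else {
    if (inputSize < 67L) stop("alexnet preset requires inputSize >= 67")
    layers <- .alexnetLayers(numClasses, dropout)
  }
  new("ModelArch",
    preset = preset, inputSize = inputSize, channels = 3L,
    numClasses = numClasses, dropout = dropout, layers = layers)
}

# spec list consumed by the C++ engine, optionally overriding dropout rates
.archSpec <- function(arch, dropout = NULL) {
  layers <- arch@layers
  if (!is.null(dropout)) {
    layers <- lapply(layers, function(l) {
      if (identical(l$type, "dropout")) l$rate <- dropout
      l
    })
  }
  list(inputSize = arch@inputSize, channels = arch@channels,
       numClasses = arch@numClasses, layers = layers)
}

# images (list of H x W x 3 arrays, [0, 255]) -> (size^2 * 3) x n matrix,
# resized to the network input and scaled to [-0.5, 0.5]
.imagesToMatrix <- function(images, inputSize) {
  cols <- lapply(images, function(im) {
    if (is.matrix(im)) im <- array(rep(im, 3L), c(dim(im), 3L))
    if (!all(dim(im)[1:2] == inputSize)) {
      img <- EBImage::Image(im / 255, colormode = "Color")
      im <- EBImage::imageData(
        EBImage::resize(img, w = inputSize, h = inputSize)) * 255
    }
    as.numeric(im) / 255 - 0.5
  })
  n <- length(cols)
  matrix(unlist(cols, use.names = FALSE), ncol = n)
}

.labelsToInt <- function(labels, classes) {
  ii <- match(as.character(labels), classes)
  if (anyNA(ii)) stop("label outside the model's class set: ",
                      paste(unique(as.character(labels)[is.na(ii)]),
                            collapse = ", "))
  as.integer(ii) - 1L
}

#' Train a convolutional classifier
#'
#' Minimizes categorical cross-entropy by minibatch stochastic gradient
#' descent with momentum, using the architecture's layer stack and the
#' training configuration's epochs / batch size / learning rate / dropout.
#' Images are resized to the network input at this boundary. Weight
#' initialization, shuffling and dropout are all driven by
#' \code{config@seed}, so identical inputs and seed reproduce the run
#' exactly. Per-epoch train and validation accuracy and loss are recorded.
#'
#' @param arch a \linkS4class{ModelArch} from \code{\link{buildModel}}
#' @param train a nonempty \linkS4class{LabeledDataset}
#' @param validation optional \linkS4class{LabeledDataset} evaluated after
#'   each epoch
#' @param config a \linkS4class{TrainConfig}
#' @return a \linkS4class{TrainedModel}
#' @export
trainModel <- function(arch, train, validation = NULL,
                       config = TrainConfig()) {
  stopifnot(is(arch, "ModelArch"), is(train, "LabeledDataset"),
            is(config, "TrainConfig"))
  validObject(config)
  if (length(train) == 0L) stop("training set is empty")
  classes <- train@classes
  if (length(classes) != arch@numClasses)
    stop(sprintf("dataset has %d classes but the model expects %d",
                 length(classes), arch@numClasses))
  spec <- .archSpec(arch, dropout = config@dropout)
  X <- .imagesToMatrix(train@images, arch@inputSize)
  y <- .labelsToInt(train@labels, classes)
  if (!is.null(validation) && length(validation) > 0L) {
    Xv <- .imagesToMatrix(validation@images, arch@inputSize)
    yv <- .labelsToInt(validation@labels, classes)
  } else {
    Xv <- matrix(numeric(0), nrow(X), 0L)
    yv <- integer(0)
  }
  params <- .cpp_cnn_init(spec, config@seed)
  fit <- .cpp_cnn_train(spec, params, X, y, Xv, yv,
                        config@epochs, config@batchSize,
                        config@learningRate, config@momentum, config@seed)
  h <- fit$history
  history <- data.frame(
    epoch = seq_len(nrow(h)),
    train_loss = h[, 1L], train_acc = h[, 2L],
    val_loss = h[, 3L], val_acc = h[, 4L])
  new("TrainedModel", arch = arch, params = fit$params, history = history,
      classes = classes)
}

.newdataImages <- function(newdata) {
  if (is(newdata, "LabeledDataset")) return(newdata@images)
  if (is.array(newdata) && length(dim(newdata)) == 3L) return(list(newdata))
  if (is.list(newdata)) return(newdata)
  stop("newdata must be a LabeledDataset, an image array, or a list of them")
}

#' Class probabilities and predicted labels
#'
#' \code{predictProb} runs the softmax forward pass (dropout inactive) and
#' returns one row of class probabilities per image; \code{predictLabels}
#' returns the argmax label. Both preserve input order and are
#' deterministic.
#'
#' @param model a \linkS4class{TrainedModel}
#' @param newdata a \linkS4class{LabeledDataset}, one H x W x 3 array, or a
#'   list of arrays (values in [0, 255])
#' @return \code{predictProb}: an n x C numeric matrix with rows summing to
#'   1; \code{predictLabels}: a factor of length n over the model's classes
#' @export
predictProb <- function(model, newdata) {
  stopifnot(is(model, "TrainedModel"))
  images <- .newdataImages(newdata)
  if (length(images) == 0L) {
    p <- matrix(numeric(0), 0L, length(model@classes))
    colnames(p) <- model@classes
    return(p)
  }
  X <- .imagesToMatrix(images, model@arch@inputSize)
  pr <- t(.cpp_cnn_predict(.archSpec(model@arch), model@params, X))
  colnames(pr) <- model@classes
  pr
}

#' @rdname predictProb
#' @export
predictLabels <- function(model, newdata) {
  pr <- predictProb(model, newdata)
  factor(model@classes[max.col(pr, ties.method = "first")],
         levels = model@classes)
}

#' Save / load a trained model
#'
#' Serialized with R's native RDS format.
#'
#' @param model a \linkS4class{TrainedModel}
#' @param path file path
#' @return \code{loadModel} returns the \linkS4class{TrainedModel};
#'   \code{saveModel} returns \code{path} invisibly
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "TrainedModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  m <- readRDS(path)
  stopifnot(is(m, "TrainedModel"))
  m
}

#' Export the training history as CSV
#'
#' Columns: epoch, train_acc, val_acc, train_loss, val_loss.
#'
#' @param model a \linkS4class{TrainedModel}
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
exportHistory <- function(model, path) {
  h <- trainingHistory(model)
  utils::write.csv(
    h[, c("epoch", "train_acc", "val_acc", "train_loss", "val_loss")],
    path, row.names = FALSE)
  invisible(path)
}

#' Evaluate a model on a labelled dataset
#'
#' Predicts every item, tabulates the confusion matrix, and reports
#' per-class precision / recall / F1, their macro averages, overall
#' accuracy, and the mean categorical cross-entropy.
#'
#' @param model a \linkS4class{TrainedModel}
#' @param ds a nonempty \linkS4class{LabeledDataset} over the same classes
#' @return list with elements \code{confusion}
#'   (\linkS4class{ConfusionMatrix}), \code{perClass} (data.frame),
#'   \code{macro} (named numeric), \code{accuracy}, \code{loss}
#' @export
evaluateModel <- function(model, ds) {
  stopifnot(is(model, "TrainedModel"), is(ds, "LabeledDataset"))
  if (length(ds) == 0L) stop("cannot evaluate on an empty dataset")
  pr <- predictProb(model, ds)
  pred <- model@classes[max.col(pr, ties.method = "first")]
  cm <- confusionMatrix(as.character(ds@labels), pred, classes = model@classes)
  yi <- .labelsToInt(ds@labels, model@classes)
  loss <- -mean(log(pmax(pr[cbind(seq_len(nrow(pr)), yi + 1L)], 1e-12)))
  per <- perClassMetrics(cm)
  list(confusion = cm, perClass = per, macro = macroAverage(per),
       accuracy = overallAccuracy(cm), loss = loss)
}
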