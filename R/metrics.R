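#' @include AllClasses.R
NULL

#' Build a confusion matrix
#'
#' Counts[i, j] is the number of items with true class i predicted as class
#' j. Labels outside \code{classes} raise an error; empty inputs yield an
#' all-zero matrix with a warning.
#'
#' @param true,predicted equal-length label vectors (character or factor)
#' @param classes ordered class labels; defaults to the sorted union of the
#'   observed labels
#' @return a \linkS4class{ConfusionMatrix}
#' @export
confusionMatrix <- function(true, predicted, classes = NULL) {
  true <- as.character(true)
  predicted <- as.character(predicted)
  if (length(true) != length(predicted))
    stop("true and predicted must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(true, predicted)))
  bad <- setdiff(unique(c(true, predicted)), classes)
  if (length(bad))
    stop("label(s) outside the class set: ", paste(bad, collapse = ", "))
  C <- length(classes)
  cm <- matrix(0L, C, C)
  if (length(true) == 0L) {
    warning("empty label vectors: returning an all-zero confusion matrix")
  } else {
    ti <- match(true, classes)
    pj <- match(predicted, classes)
    for (k in seq_along(ti)) cm[ti[k], pj[k]] <- cm[ti[k], pj[k]] + 1L
  }
  new("ConfusionMatrix", counts = cm, classes = classes)
}

# one-vs-rest TP / FP / FN for one class index
.ovr <- function(cm, i) {
  list(tp = cm[i, i], fp = sum(cm[, i]) - cm[i, i],
       fn = sum(cm[i, ]) - cm[i, i])
}

.safeRatio <- function(num, den, what, cls) {
  if (den == 0) {
    warning(sprintf("%s undefined for class '%s' (zero denominator); returning 0",
                    what, cls))
    return(0)
  }
  num / den
}

#' Per-class precision, recall and F1
#'
#' One-vs-rest on the confusion matrix: precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 = 2PR/(P+R). A zero denominator yields 0 with a warning,
#' so sweeps on degenerate small sets run to completion.
#'
#' @param cm a \linkS4class{ConfusionMatrix}
#' @param class optional single class name; default all classes
#' @return data.frame with columns class, precision, recall, f1
#' @examples
#' cm <- confusionMatrix(c("a", "a", "b"), c("a", "b", "b"))
#' perClassMetrics(cm)
#' @export
perClassMetrics <- function(cm, class = NULL) {
  stopifnot(is(cm, "ConfusionMatrix"))
  cls <- if (is.null(class)) cm@classes else class
  if (!all(cls %in% cm@classes))
    stop("class not in the confusion matrix: ",
         paste(setdiff(cls, cm@classes), collapse = ", "))
  rows <- lapply(cls, function(cc) {
    i <- match(cc, cm@classes)
    o <- .ovr(cm@counts, i)
    p <- .safeRatio(o$tp, o$tp + o$fp, "precision", cc)
    r <- .safeRatio(o$tp, o$tp + o$fn, "recall", cc)
    f1 <- if (p + r == 0) {
      warning(sprintf("F1 undefined for class '%s' (P + R = 0); returning 0", cc))
      0
    } else 2 * p * r / (p + r)
    data.frame(class = cc, precision = p, recall = r, f1 = f1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' F1 score from precision and recall
#'
#' The harmonic mean 2PR/(P+R); 0 when both are 0.
#'
#' @param precision,recall values in [0, 1] (or percentages, consistently)
#' @return F1 on the same scale as the inputs
#' @export
f1Score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Overall classification accuracy
#'
#' The multiclass reduction of (TP+TN)/(TP+TN+FP+FN): the fraction of items
#' on the confusion-matrix diagonal, trace/total.
#'
#' @param cm a \linkS4class{ConfusionMatrix} with at least one counted item
#' @return accuracy in [0, 1]
#' @export
overallAccuracy <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  tot <- sum(cm@counts)
  if (tot == 0) stop("cannot compute accuracy of an empty confusion matrix")
  sum(diag(cm@counts)) / tot
}

#' Macro-averaged precision, recall and F1
#'
#' Unweighted arithmetic mean of the per-class metrics.
#'
#' @param metrics a data.frame from \code{\link{perClassMetrics}}, or a
#'   \linkS4class{ConfusionMatrix} (metrics computed first)
#' @return named numeric vector (precision, recall, f1)
#' @export
macroAverage <- function(metrics) {
  if (is(metrics, "ConfusionMatrix")) metrics <- perClassMetrics(metrics)
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 1L)
  c(precision = mean(metrics$precision),
    recall = mean(metrics$recall),
    f1 = mean(metrics$f1))
}

#' Compression ratio of a codec setting
#'
#' CR = uncompressed size / compressed size = B^2 / M per block: L = B^2
#' coefficients are represented by M measurements.
#'
#' @param x a \linkS4class{CodecConfig}, or the measurement count M
#' @param blockSize block side B when \code{x} is numeric (default 8)
#' @return CR >= 1
#' @examples
#' compressionRatio(32)         # 2
#' compressionRatio(CodecConfig(measurements = 4L))  # 16
#' @export
compressionRatio <- function(x, blockSize = 8L) {
  if (is(x, "CodecConfig")) {
    M <- x@measurements; B <- x@blockSize
  } else {
    M <- as.numeric(x); B <- as.numeric(blockSize)
  }
  if (length(M) != 1L || M < 1) stop("M must be a scalar >= 1")
  if (M > B * B) stop(sprintf("M (%g) exceeds B^2 (%g)", M, B * B))
  B * B / M
}

#' Round half away from zero
#'
#' Presentation rounding for report tables (R's \code{round} rounds halves
#' to even).
#'
#' @param x numeric
#' @param digits decimal places (default 2)
#' @return rounded numeric
#' @export
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  # pre-round far below the presentation precision so that values which are
  # exactly half in decimal but sit just under it in binary round upward
  sign(x) * floor(round(abs(x) * p, 6) + 0.5) / p
}

#' Export a per-class metrics report as CSV
#'
#' Columns class, precision, recall, f1, values rounded half-up to 2
#' decimals.
#'
#' @param cm a \linkS4class{ConfusionMatrix}
#' @param path output CSV path
#' @return the written data.frame, invisibly
#' @export
writeMetricsCSV <- function(cm, path) {
  m <- perClassMetrics(cm)
  m$precision <- roundHalfUp(m$precision)
  m$recall <- roundHalfUp(m$recall)
  m$f1 <- roundHalfUp(m$f1)
  utils::write.csv(m, path, row.names = FALSE)
  invisible(m)
}
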