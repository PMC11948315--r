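#' Confusion matrix
#'
#' Tally of true versus predicted class labels: `cm[i, j]` is the number of
#' samples with true class `i` predicted as class `j`. The matrix total always
#' equals the number of samples.
#'
#' @param truth integer vector of true labels in `1..nClasses`.
#' @param predicted integer vector of predicted labels, same length.
#' @param nClasses number of classes `K`; defaults to the largest label seen.
#' @return a `K x K` integer matrix, rows = truth, columns = prediction.
#' @examples
#' confusionMatrix(c(1, 1, 2, 2), c(1, 2, 2, 2), 2)
#' @export
confusionMatrix <- function(truth, predicted, nClasses = max(truth, predicted)) {
  if (length(truth) != length(predicted)) stop("label vectors differ in length", call. = FALSE)
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (any(truth < 1L | truth > nClasses) || any(predicted < 1L | predicted > nClasses))
    stop("labels out of range 1..", nClasses, call. = FALSE)
  cm <- matrix(tabulate((truth - 1L) * nClasses + predicted, nbins = nClasses^2),
               nrow = nClasses, byrow = TRUE)
  dimnames(cm) <- list(truth = seq_len(nClasses), predicted = seq_len(nClasses))
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy plus precision, recall and F1 averaged over classes. Per class,
#' precision is the diagonal over the column sum (0 when the class is never
#' predicted), recall the diagonal over the row sum, and F1 their harmonic
#' mean. `averaging = "macro"` is the unweighted class mean;
#' `"weighted"` (the default) weights by class support (row sums), under which
#' recall is identically the accuracy.
#'
#' @param cm confusion matrix from [confusionMatrix()].
#' @param averaging `"weighted"` or `"macro"`.
#' @return list with `accuracy`, `precision`, `recall`, `f1`, `averaging`,
#'   `support` and `perClass` (a data frame of per-class values).
#' @examples
#' m <- classificationMetrics(confusionMatrix(c(1, 1, 2, 2), c(1, 2, 2, 2)))
#' m$accuracy  # 0.75
#' @export
classificationMetrics <- function(cm, averaging = c("weighted", "macro")) {
  averaging <- match.arg(averaging)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  d <- diag(cm); rs <- rowSums(cm); cs <- colSums(cm)
  prec <- ifelse(cs > 0, d / cs, 0)
  rec  <- ifelse(rs > 0, d / rs, 0)
  f1   <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- if (averaging == "weighted") rs / total else rep(1 / nrow(cm), nrow(cm))
  list(accuracy = sum(d) / total,
       precision = sum(w * prec), recall = sum(w * rec), f1 = sum(w * f1),
       averaging = averaging, support = rs,
       perClass = data.frame(class = seq_len(nrow(cm)), precision = prec,
                             recall = rec, f1 = f1, support = rs))
}

#' Mean categorical cross-entropy
#'
#' Mean over samples of the negative log probability assigned to the true
#' class, in nats. Predicted probabilities are clipped to `[eps, 1]` before the
#' log so that a zero on the true class yields a large finite loss.
#'
#' @param probs `n x K` matrix of predicted class distributions (each row sums
#'   to 1 within `1e-6`).
#' @param truth integer vector of true labels in `1..K`, or an `n x K` one-hot
#'   matrix.
#' @param eps clipping floor for the log, default `1e-7`.
#' @return non-negative numeric scalar.
#' @examples
#' categoricalCrossentropy(matrix(0.25, 2, 4), c(1, 3))  # log(4)
#' @export
categoricalCrossentropy <- function(probs, truth, eps = 1e-7) {
  probs <- as.matrix(probs)
  if (is.matrix(truth)) {
    if (!identical(dim(truth), dim(probs))) stop("one-hot shape mismatch", call. = FALSE)
    truth <- max.col(truth, ties.method = "first")
  }
  if (length(truth) != nrow(probs)) stop("label/probability shape mismatch", call. = FALSE)
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("predicted distributions must sum to 1", call. = FALSE)
  p <- probs[cbind(seq_len(nrow(probs)), as.integer(truth))]
  -mean(log(pmin(pmax(p, eps), 1)))
}
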