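# Embedding-quality diagnostics (alignment, uniformity) and the
# classification metric suite (accuracy, precision, recall, F1, AUC), all
# reported in percent for the classification metrics to match the reporting
# convention of the DR literature.

#' Alignment of positive-pair embeddings
#'
#' Mean squared Euclidean distance between the two embeddings of each
#' positive pair drawn from the positive-pair distribution. On the unit
#' hypersphere this equals \eqn{2 - 2\cos\theta}; lower is better (0 means
#' every pair coincides).
#'
#' @param x,y Matrices of paired unit-norm embeddings, one pair per row.
#' @return Nonnegative scalar.
#' @export
alignment <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) == 0L) stop("empty pair set")
  if (!all(dim(x) == dim(y))) stop("'x' and 'y' must have the same shape")
  mean(rowSums((x - y)^2))
}

#' Uniformity of embeddings on the hypersphere
#'
#' Log of the mean Gaussian kernel \eqn{e^{-2\|x-y\|^2}} over all ordered
#' i.i.d. pairs of the embedding set (self-pairs included, matching the
#' i.i.d. expectation). Bounded above by 0; more negative means the points
#' are better spread over the sphere.
#'
#' @param x Matrix of M >= 2 unit-norm embeddings.
#' @return Scalar <= 0.
#' @export
uniformity <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("uniformity needs at least 2 embeddings")
  sq <- rowSums(x^2)
  d2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(x), 0)
  log(mean(exp(-2 * d2)))
}

#' One-vs-rest confusion tallies
#'
#' Per-class true/false positive/negative counts for multiclass predictions,
#' treating each class in turn as the positive one.
#'
#' @param predicted,truth Integer label vectors (0-based), equal length.
#' @param n_classes Number of classes; labels must lie in
#'   \code{0:(n_classes-1)}.
#' @return Data frame with columns \code{class}, \code{tp}, \code{fp},
#'   \code{fn}, \code{tn}.
#' @export
confusion_tally <- function(predicted, truth, n_classes = max(truth, predicted) + 1L) {
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (length(truth) == 0L) stop("no samples")
  if (any(c(predicted, truth) < 0L) || any(c(predicted, truth) >= n_classes)) {
    stop("labels out of range")
  }
  n <- length(truth)
  cls <- 0:(n_classes - 1L)
  tp <- vapply(cls, function(k) sum(predicted == k & truth == k), integer(1))
  fp <- vapply(cls, function(k) sum(predicted == k & truth != k), integer(1))
  fn <- vapply(cls, function(k) sum(predicted != k & truth == k), integer(1))
  data.frame(class = cls, tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn)
}

#' Precision, recall and F1 from a confusion tally
#'
#' Binary mode applies the textbook formulas to the positive class (class
#' 1); macro mode takes the unweighted mean of per-class one-vs-rest values.
#' A class with an empty denominator (no predicted positives, or no true
#' members) contributes 0 with a warning, which keeps macro averages finite
#' on sparse label sets.
#'
#' @param tally Output of [confusion_tally()].
#' @param mode \code{"binary"} or \code{"macro"}.
#' @return Named numeric vector \code{c(precision, recall, f1)} in percent.
#' @export
precision_recall_f1 <- function(tally, mode = c("binary", "macro")) {
  mode <- match.arg(mode)
  if (sum(tally$tp + tally$fn) == 0L) stop("no samples")
  safe_div <- function(num, den, what, k) {
    if (den == 0) {
      warning(sprintf("%s undefined for class %d (zero denominator); using 0", what, k))
      0
    } else num / den
  }
  per_class <- lapply(seq_len(nrow(tally)), function(r) {
    k <- tally$class[r]
    prec <- safe_div(tally$tp[r], tally$tp[r] + tally$fp[r], "precision", k)
    rec  <- safe_div(tally$tp[r], tally$tp[r] + tally$fn[r], "recall", k)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1)
  })
  out <- if (mode == "binary") {
    r <- which(tally$class == 1L)
    if (length(r) != 1L) stop("binary mode expects a class-1 row in the tally")
    per_class[[r]]
  } else {
    colMeans(do.call(rbind, per_class))
  }
  100 * out
}

#' Classification accuracy in percent
#'
#' @param predicted,truth Equal-length label vectors.
#' @return Scalar in \code{[0, 100]}.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (length(truth) == 0L) stop("no samples")
  100 * mean(predicted == truth)
}

#' Area under the ROC curve, in percent
#'
#' Rank-based (Mann-Whitney) estimator with midranks for ties, so the value
#' is invariant under strictly monotone transformations of the scores. In
#' macro mode, \code{scores} is a matrix with one column per class and the
#' result is the unweighted mean of the one-vs-rest AUCs; classes absent
#' from \code{truth} are skipped with a warning.
#'
#' @param scores Positive-class score vector (binary) or samples-by-classes
#'   score matrix (macro one-vs-rest).
#' @param truth Integer labels (binary: 0/1).
#' @param mode \code{"binary"} or \code{"macro_ovr"}.
#' @return Scalar in \code{[0, 100]}.
#' @export
auc <- function(scores, truth, mode = c("binary", "macro_ovr")) {
  mode <- match.arg(mode)
  truth <- as.integer(truth)
  if (mode == "binary") {
    scores <- as.numeric(scores)
    if (length(scores) != length(truth)) stop("length mismatch")
    100 * .auc_rank(scores, truth == 1L)
  } else {
    scores <- as.matrix(scores)
    if (nrow(scores) != length(truth)) stop("length mismatch")
    vals <- numeric(0)
    for (k in seq_len(ncol(scores))) {
      pos <- truth == (k - 1L)
      if (!any(pos) || all(pos)) {
        warning(sprintf("class %d absent from truth (or its complement); skipped", k - 1L))
        next
      }
      vals <- c(vals, .auc_rank(scores[, k], pos))
    }
    if (length(vals) == 0L) {
      warning("no class with both positives and negatives; AUC undefined")
      return(NA_real_)
    }
    100 * mean(vals)
  }
}

# Mann-Whitney AUC with midranks; pos is logical
.auc_rank <- function(scores, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both positives and negatives")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bundle the five classification metrics
#'
#' Computes accuracy, precision, recall, F1 and AUC (all in percent) from
#' predicted labels, class scores and ground truth, using binary formulas or
#' macro averaging with one-vs-rest AUC depending on the task.
#'
#' @param scores Positive-class scores (binary task) or samples-by-classes
#'   score matrix (multiclass).
#' @param predicted Predicted integer labels.
#' @param truth True integer labels.
#' @param task \code{"binary"} or \code{"multiclass"}.
#' @return An object of class \code{"am_report"}: a list with the five
#'   metrics, the averaging \code{mode} tag, and the per-class tally.
#' @export
classification_report <- function(scores, predicted, truth,
                                  task = c("binary", "multiclass")) {
  task <- match.arg(task)
  n_classes <- if (task == "binary") 2L else max(truth, predicted) + 1L
  tally <- confusion_tally(predicted, truth, n_classes)
  if (task == "binary") {
    prf <- precision_recall_f1(tally, "binary")
    a <- auc(scores, truth, "binary")
    mode <- "binary"
  } else {
    prf <- precision_recall_f1(tally, "macro")
    a <- auc(scores, truth, "macro_ovr")
    mode <- "macro"
  }
  structure(
    list(accuracy = accuracy(predicted, truth),
         precision = unname(prf["precision"]), recall = unname(prf["recall"]),
         f1 = unname(prf["f1"]), auc = a, mode = mode, tally = tally),
    class = "am_report"
  )
}

#' @export
print.am_report <- function(x, ...) {
  cat(sprintf(
    "<classification report, %s averaging>\n  accuracy %6.2f  precision %6.2f  recall %6.2f  F1 %6.2f  AUC %6.2f\n",
    x$mode, x$accuracy, x$precision, x$recall, x$f1, x$auc))
  invisible(x)
}

#' Serialize a classification report to JSON
#'
#' Writes the five percent-scale metrics, the averaging mode and the
#' per-class confusion tallies to a JSON document.
#'
#' @param report An \code{"am_report"} object.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "am_report"))
  obj <- list(accuracy = report$accuracy, precision = report$precision,
              recall = report$recall, f1 = report$f1, auc = report$auc,
              mode = report$mode, per_class = report$tally)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
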