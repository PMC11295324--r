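#' Binary classification metrics from predicted and true labels
#'
#' Accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and F1 (harmonic mean of precision and
#' recall).  Ratios with a zero denominator are reported as `NaN`,
#' never silently as 0.
#'
#' @param y_true,y_pred binary vectors (logical, 0/1, or a common
#'   two-level factor/character coding with `positive` naming the
#'   positive class).
#' @param positive value treated as the positive class for non-logical
#'   input (default `1`/`TRUE`).
#' @return object of class `metrics_report`: list with the four counts
#'   and the five metrics.
#' @export
classification_metrics <- function(y_true, y_pred, positive = NULL) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    stop("y_true and y_pred must have equal positive length", call. = FALSE)
  }
  to_bin <- function(y) {
    if (is.logical(y)) return(y)
    if (is.numeric(y)) {
      if (!all(y %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
      return(y == 1)
    }
    if (is.null(positive)) stop("supply `positive` for non-numeric labels",
                                call. = FALSE)
    y == positive
  }
  t <- to_bin(y_true); p <- to_bin(y_pred)
  tp <- sum(t & p); fp <- sum(!t & p); tn <- sum(!t & !p); fn <- sum(t & !p)
  div <- function(a, b) if (b == 0) NaN else a / b
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0) {
    NaN
  } else 2 * precision * recall / (precision + recall)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 accuracy = (tp + tn) / length(t),
                 precision = precision, recall = recall,
                 specificity = div(tn, tn + fp), f1 = f1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("accuracy=%.4f precision=%.4f recall=%.4f specificity=%.4f f1=%.4f\n",
              x$accuracy, x$precision, x$recall, x$specificity, x$f1))
  invisible(x)
}

#' Area under the ROC curve (rank statistic)
#'
#' The probability that a random positive scores above a random
#' negative, ties counted 1/2 — the normalized Mann-Whitney U.
#'
#' @param scores numeric scores, higher means more positive.
#' @param y_true binary labels (both classes present).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, y_true) {
  stopifnot(length(scores) == length(y_true))
  pos <- y_true == 1 | y_true == TRUE
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged one-vs-rest metrics for multi-class labels
#' @param y_true,y_pred label vectors over the same class set.
#' @return list of per-class `metrics_report`s plus `macro` averages.
#' @export
macro_metrics <- function(y_true, y_pred) {
  classes <- sort(unique(c(y_true, y_pred)))
  per <- lapply(classes, function(cl) {
    classification_metrics(y_true == cl, y_pred == cl)
  })
  names(per) <- as.character(classes)
  pick <- function(f) {
    v <- vapply(per, `[[`, 0, f)
    mean(v[!is.nan(v)])
  }
  list(per_class = per,
       macro = list(accuracy = pick("accuracy"), precision = pick("precision"),
                    recall = pick("recall"), specificity = pick("specificity"),
                    f1 = pick("f1")))
}

#' k-nearest-neighbour label agreement in an embedding
#'
#' Fraction of points whose majority label among their k nearest
#' embedding neighbours (self excluded; ties broken by the nearest
#' neighbour) equals their own label.  The standard gauge of whether an
#' embedding preserved cluster structure.
#'
#' @param Y embedding coordinates.
#' @param labels per-point labels.
#' @param k neighbourhood size (default 5).
#' @return agreement fraction in \[0, 1\].
#' @export
knn_agreement <- function(Y, labels, k = 5L) {
  n <- nrow(Y)
  stopifnot(length(labels) == n, k < n)
  D <- as.matrix(stats::dist(Y))
  hits <- 0L
  for (i in seq_len(n)) {
    nb <- order(D[i, -i])[seq_len(k)]
    nb_idx <- seq_len(n)[-i][nb]
    tab <- table(labels[nb_idx])
    top <- names(tab)[tab == max(tab)]
    pred <- if (length(top) == 1L) top else as.character(labels[nb_idx[1L]])
    if (pred == as.character(labels[i])) hits <- hits + 1L
  }
  hits / n
}
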