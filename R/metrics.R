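# Clinical evaluation metrics: accuracy, precision, sensitivity,
# specificity and the Youden index, with one-vs-rest counts per class and
# macro (unweighted) aggregation across classes. Per-class metrics with a
# zero denominator are undefined and excluded from macro means.

#' One-vs-rest confusion counts
#'
#' @param y_true,y_pred integer label vectors (0-based grades).
#' @param num_classes number of classes; defaults to the label range.
#' @return object of class `"confusion_counts"`: the full confusion
#'   matrix (`table`, rows = truth), a per-class data frame of TP/FP/TN/FN,
#'   total `N` and total correct `Nc`.
#' @export
confusion <- function(y_true, y_pred, num_classes = NULL) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (is.null(num_classes)) num_classes <- max(y_true, y_pred) + 1L
  if (any(y_true < 0L | y_true >= num_classes) ||
      any(y_pred < 0L | y_pred >= num_classes))
    stop("label out of range [0, num_classes)")
  tab <- matrix(0L, num_classes, num_classes,
                dimnames = list(true = 0:(num_classes - 1L),
                                pred = 0:(num_classes - 1L)))
  for (i in seq_along(y_true))
    tab[y_true[i] + 1L, y_pred[i] + 1L] <- tab[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  N <- length(y_true)
  per <- data.frame(class = 0:(num_classes - 1L), TP = 0L, FP = 0L,
                    TN = 0L, FN = 0L)
  for (k in seq_len(num_classes)) {
    per$TP[k] <- tab[k, k]
    per$FP[k] <- sum(tab[-k, k])
    per$FN[k] <- sum(tab[k, -k])
    per$TN[k] <- N - per$TP[k] - per$FP[k] - per$FN[k]
  }
  structure(list(table = tab, per_class = per, N = N, Nc = sum(diag(tab))),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  print(x$table)
  cat(sprintf("N = %d, correct = %d, accuracy = %.4f\n", x$N, x$Nc,
              x$Nc / x$N))
  invisible(x)
}

#' Overall accuracy: correct / total
#' @param c a [confusion()] object.
#' @export
accuracy <- function(c) {
  if (c$N == 0L) stop("undefined metric: no samples")
  c$Nc / c$N
}

ovr_ratio <- function(c, num, den1, den2, class) {
  p <- c$per_class
  vals <- p[[num]] / (p[[den1]] + p[[den2]])
  if (!is.null(class)) {
    v <- vals[p$class == class]
    if (!is.finite(v)) stop("undefined metric for class ", class)
    return(v)
  }
  ok <- is.finite(vals)
  if (!any(ok)) stop("metric undefined for every class")
  mean(vals[ok])
}

#' Per-class or macro precision (TP / (TP + FP))
#' @param c a [confusion()] object.
#' @param class 0-based class index, or `NULL` for the macro mean over
#'   classes with a defined value.
#' @export
precision <- function(c, class = NULL) ovr_ratio(c, "TP", "TP", "FP", class)

#' Per-class or macro sensitivity (TP / (TP + FN))
#' @inheritParams precision
#' @export
sensitivity <- function(c, class = NULL) ovr_ratio(c, "TP", "TP", "FN", class)

#' Per-class or macro specificity (TN / (TN + FP))
#' @inheritParams precision
#' @export
specificity <- function(c, class = NULL) ovr_ratio(c, "TN", "TN", "FP", class)

#' Youden index: sensitivity + specificity - 1
#'
#' @param se,sp sensitivity and specificity in \[0, 1\].
#' @return value in \[-1, 1\]; 0 on the chance line.
#' @export
youden_index <- function(se, sp) {
  stopifnot(all(se >= 0 & se <= 1), all(sp >= 0 & sp <= 1))
  se + sp - 1
}

#' Full evaluation report for predicted grades
#'
#' @inheritParams confusion
#' @return list with the confusion object, per-class metrics, and macro
#'   metrics (accuracy, precision, sensitivity, specificity, Youden
#'   index computed from the macro sensitivity/specificity).
#' @export
evaluate_predictions <- function(y_true, y_pred, num_classes = NULL) {
  cc <- confusion(y_true, y_pred, num_classes)
  p <- cc$per_class
  per <- data.frame(
    class = p$class,
    precision = p$TP / (p$TP + p$FP),
    sensitivity = p$TP / (p$TP + p$FN),
    specificity = p$TN / (p$TN + p$FP)
  )
  se <- sensitivity(cc); sp <- specificity(cc)
  list(confusion = cc, per_class = per,
       macro = list(accuracy = accuracy(cc), precision = precision(cc),
                    sensitivity = se, specificity = sp,
                    youden = youden_index(se, sp)))
}
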