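# Classification metrics: confusion matrix and one-vs-rest per-class /
# macro-averaged accuracy, precision, recall and specificity.
#
# Convention note (important): the headline "accuracy" reported for this
# task is the macro average of per-class one-vs-rest accuracies, which
# for K > 2 exceeds the pooled accuracy trace/total whenever any
# off-diagonal mass exists. Both are reported.

#' Confusion matrix
#'
#' @param y_true,y_pred equal-length label vectors: integers in
#'   `[0, K)`, or factors/characters over `classes`
#' @param classes class names in order (default Normal/ODE/PPE); for
#'   integer input, length defines `K`
#' @return a `wha_confusion` matrix, rows = true class, columns =
#'   predicted class
#' @export
confusion_matrix <- function(y_true, y_pred,
                             classes = c("Normal", "ODE", "PPE")) {
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length")
  to_idx <- function(y) {
    if (is.numeric(y)) {
      if (any(y < 0 | y >= length(classes) | y != floor(y)))
        stop("labels out of range [0, K)")
      as.integer(y) + 1L
    } else {
      i <- match(as.character(y), classes)
      if (anyNA(i)) stop("labels outside the class set")
      i
    }
  }
  ti <- to_idx(y_true); pi <- to_idx(y_pred)
  K <- length(classes)
  cm <- matrix(0L, K, K, dimnames = list(true = classes, pred = classes))
  for (i in seq_along(ti)) cm[ti[i], pi[i]] <- cm[ti[i], pi[i]] + 1L
  structure(cm, class = c("wha_confusion", "matrix", "array"))
}

#' One-vs-rest classification metrics
#'
#' Per class `c`: `TP = cm[c,c]`, `FP` = column sum minus TP, `FN` = row
#' sum minus TP, `TN` = remainder; then
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`. Macro values are unweighted
#' means over classes (classes with zero support are excluded from the
#' macro mean and flagged); pooled accuracy is `trace/total`.
#' Division-by-zero cells are reported as `NA` with an `undefined` flag.
#' `macro_printed` additionally averages the per-class values after
#' rounding them to 4 decimal places, the convention of published
#' result tables (it can differ from the exact macro in the last digit).
#'
#' @param cm a confusion matrix (`wha_confusion` or plain square matrix)
#' @return an object of class `wha_metrics`: list with `per_class`
#'   tibble, `macro` named vector, `pooled_accuracy`, `n`
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(cm)
  if (is.null(dim(cm)) || nrow(cm) != ncol(cm) || sum(cm) == 0)
    stop("cm must be a non-empty square matrix")
  K <- nrow(cm)
  classes <- rownames(cm) %||% paste0("class", seq_len(K) - 1)
  total <- sum(cm)
  res <- lapply(seq_len(K), function(c) {
    tp <- cm[c, c]
    fp <- sum(cm[, c]) - tp
    fn <- sum(cm[c, ]) - tp
    tn <- total - tp - fp - fn
    div <- function(a, b) if (b == 0) NA_real_ else a / b
    tibble::tibble(
      class = classes[c], support = tp + fn,
      tp = tp, fp = fp, fn = fn, tn = tn,
      accuracy = div(tp + tn, total),
      precision = div(tp, tp + fp),
      recall = div(tp, tp + fn),
      specificity = div(tn, tn + fp)
    )
  })
  per_class <- do.call(rbind, res)
  keep <- per_class$support > 0
  cols <- c("accuracy", "precision", "recall", "specificity")
  macro <- colMeans(per_class[keep, cols], na.rm = FALSE)
  # published tables round per-class values to 4 dp before averaging;
  # kept alongside the exact macro so printed averages can be reproduced
  macro_printed <- colMeans(round(per_class[keep, cols], 4), na.rm = FALSE)
  structure(list(
    per_class = per_class,
    macro = macro,
    macro_printed = macro_printed,
    pooled_accuracy = sum(diag(cm)) / total,
    n = total,
    undefined = per_class$class[!stats::complete.cases(
      per_class[c("accuracy", "precision", "recall", "specificity")])],
    excluded_from_macro = per_class$class[!keep]
  ), class = "wha_metrics")
}

#' @export
print.wha_metrics <- function(x, ...) {
  df <- as.data.frame(x$per_class[c("class", "support", "accuracy",
                                    "precision", "recall", "specificity")])
  df[3:6] <- lapply(df[3:6], round, 4)
  print(df, row.names = FALSE)
  cat(sprintf("macro:  acc %.4f  prec %.4f  rec %.4f  spec %.4f\n",
              x$macro["accuracy"], x$macro["precision"],
              x$macro["recall"], x$macro["specificity"]))
  cat(sprintf("pooled accuracy: %.4f  (n = %d)\n", x$pooled_accuracy, x$n))
  if (length(x$undefined))
    cat("undefined (division by zero) for:",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a metrics report
#'
#' @param x a `wha_metrics`
#' @param ... unused
#' @return tibble with one row per class plus a `macro` row
#' @export
tidy.wha_metrics <- function(x, ...) {
  pc <- x$per_class[c("class", "support", "accuracy", "precision",
                      "recall", "specificity")]
  rbind(pc, tibble::tibble(class = "macro", support = x$n,
                           accuracy = x$macro[["accuracy"]],
                           precision = x$macro[["precision"]],
                           recall = x$macro[["recall"]],
                           specificity = x$macro[["specificity"]]))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance.wha_metrics <- function(object, ...) {
  tibble::tibble(
    macro_accuracy = object$macro[["accuracy"]],
    macro_precision = object$macro[["precision"]],
    macro_recall = object$macro[["recall"]],
    macro_specificity = object$macro[["specificity"]],
    pooled_accuracy = object$pooled_accuracy,
    n = object$n
  )
}
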