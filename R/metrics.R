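#' Confusion matrix
#'
#' Counts of true class (rows) against predicted class (columns) over a
#' fixed class vocabulary.
#'
#' @param y_true,y_pred Vectors of labels (coerced to character).
#' @param classes Ordered class vocabulary; defaults to the union of
#'   observed labels.
#' @return A `gait_confusion`: integer K x K matrix with class dimnames.
#' @export
confusion <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    abort("y_true and y_pred must have equal length")
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  if (!all(c(y_true, y_pred) %in% classes))
    abort("labels outside the class vocabulary")
  k <- length(classes)
  cm <- matrix(0L, k, k, dimnames = list(true = classes, pred = classes))
  for (i in seq_along(y_true))
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  class(cm) <- c("gait_confusion", class(cm))
  cm
}

#' Classification scores from a confusion matrix
#'
#' Per-class one-vs-rest precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)` and accuracy `(TP+TN)/total`, plus an unweighted
#' (`macro`) and a support-weighted (`weighted`) summary row. Degenerate
#' 0/0 ratios are defined as 0.
#'
#' @param cm A [confusion()] matrix.
#' @param average Summary rows to append: any of `"macro"`, `"weighted"`.
#' @return Tibble with columns `class`, `n`, `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
scores <- function(cm, average = c("macro", "weighted")) {
  stopifnot(inherits(cm, "gait_confusion"))
  total <- sum(cm)
  if (total == 0) abort("empty confusion matrix")
  classes <- rownames(cm)
  tp <- unname(diag(unclass(cm)))
  fp <- unname(colSums(cm)) - tp
  fn <- unname(rowSums(cm)) - tp
  tn <- total - tp - fp - fn
  div0 <- function(a, b) ifelse(b == 0, 0, a / b)
  precision <- div0(tp, tp + fp)
  recall <- div0(tp, tp + fn)
  f1 <- div0(2 * precision * recall, precision + recall)
  acc <- (tp + tn) / total
  out <- tibble::tibble(class = classes, n = as.integer(rowSums(cm)),
                        accuracy = acc, precision = precision,
                        recall = recall, f1 = f1)
  if ("macro" %in% average)
    out <- dplyr::bind_rows(out, tibble::tibble(
      class = "macro", n = as.integer(total),
      accuracy = mean(acc), precision = mean(precision),
      recall = mean(recall), f1 = mean(f1)))
  if ("weighted" %in% average) {
    wts <- rowSums(cm) / total
    out <- dplyr::bind_rows(out, tibble::tibble(
      class = "weighted", n = as.integer(total),
      accuracy = sum(wts * acc), precision = sum(wts * precision),
      recall = sum(wts * recall), f1 = sum(wts * f1)))
  }
  out
}

#' Overall accuracy of a confusion matrix
#' @param cm A [confusion()] matrix.
#' @return Scalar in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) sum(diag(unclass(cm))) / sum(cm)

#' Macro F1 convenience
#' @param y_true,y_pred Label vectors.
#' @param classes Class vocabulary.
#' @return Scalar macro-averaged F1.
#' @export
macro_f1 <- function(y_true, y_pred, classes = NULL) {
  sc <- scores(confusion(y_true, y_pred, classes), average = "macro")
  sc$f1[sc$class == "macro"]
}

#' @export
print.gait_confusion <- function(x, ...) {
  cat("<confusion matrix> rows = true, cols = predicted\n")
  print(unclass(x))
  invisible(x)
}
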