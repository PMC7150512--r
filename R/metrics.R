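# Evaluation metrics.  The ranking metric throughout is the mean
# sensitivity S = (1/C) * sum_i TP_i / (TP_i + FN_i): the unweighted average
# of per-class recalls, robust to class imbalance.

#' Mean sensitivity (balanced multi-class recall)
#'
#' Predictions given as a probability matrix are reduced by argmax (ties
#' broken toward the lowest class index).  Classes absent from the truth are
#' excluded from the average with a warning, since their recall is
#' undefined.
#'
#' @param truth integer true labels in `0..C_cls-1`.
#' @param pred predicted labels (same coding) or an `n x C_cls` probability
#'   matrix.
#' @param C_cls number of classes; defaults to the number of probability
#'   columns, or `max label + 1`.
#' @return S in \[0, 1\].
#' @export
mean_sensitivity <- function(truth, pred, C_cls = NULL) {
  abort_if(length(truth) == 0, "empty input")
  if (is.matrix(pred)) {
    if (is.null(C_cls)) C_cls <- ncol(pred)
    pred <- max.col(pred, ties.method = "first") - 1L
  }
  if (is.null(C_cls)) C_cls <- max(truth, pred) + 1L
  abort_if(length(pred) != length(truth), "truth and predictions differ in length")
  abort_if(any(truth < 0 | truth >= C_cls), "labels out of range")
  recalls <- vapply(0:(C_cls - 1L), function(k) {
    in_k <- truth == k
    if (!any(in_k)) return(NA_real_)
    mean(pred[in_k] == k)
  }, numeric(1))
  if (anyNA(recalls))
    warning(sprintf("%d class(es) absent from the truth excluded from S",
                    sum(is.na(recalls))), call. = FALSE)
  mean(recalls, na.rm = TRUE)
}

#' Per-class metrics report
#'
#' For each class (one vs rest): AUC; partial AUC restricted to sensitivity
#' above 0.8, normalized by its maximal area 0.2 so it also lies in
#' \[0, 1\]; and argmax-based sensitivity and specificity.  AUCs are
#' computed with `pROC`; a class absent from the truth (or filling it
#' entirely) gets `NA` AUCs.
#'
#' @param truth integer true labels in `0..C-1`.
#' @param probs `n x C` probability (or score) matrix.
#' @return data.frame with one row per class: `class`, `n`, `auc`, `auc_s`,
#'   `sensitivity`, `specificity`; the mean sensitivity is attached as the
#'   `"mean_sensitivity"` attribute.
#' @export
per_class_report <- function(truth, probs) {
  abort_if(!is.matrix(probs), "probs must be a matrix")
  C <- ncol(probs)
  pred <- max.col(probs, ties.method = "first") - 1L
  cls_names <- if (C == 9) isic_classes() else paste0("class", 0:(C - 1))
  rows <- lapply(0:(C - 1L), function(k) {
    is_k <- truth == k
    n_k <- sum(is_k)
    sens <- if (n_k > 0) mean(pred[is_k] == k) else NA_real_
    spec <- if (any(!is_k)) mean(pred[!is_k] != k) else NA_real_
    if (n_k == 0 || n_k == length(truth)) {
      auc <- NA_real_; auc_s <- NA_real_
    } else {
      r <- pROC::roc(response = as.integer(is_k), predictor = probs[, k + 1L],
                     levels = c(0, 1), direction = "<", quiet = TRUE)
      auc <- as.numeric(pROC::auc(r))
      auc_s <- as.numeric(pROC::auc(r, partial.auc = c(0.8, 1),
                                    partial.auc.focus = "sensitivity",
                                    partial.auc.correct = FALSE)) / 0.2
    }
    data.frame(class = cls_names[k + 1L], n = n_k, auc = auc, auc_s = auc_s,
               sensitivity = sens, specificity = spec)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_sensitivity") <- mean(out$sensitivity, na.rm = TRUE)
  out
}
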