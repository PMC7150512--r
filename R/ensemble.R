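# Ensemble subset selection over cross-validation predictions.
#
# Each configuration (a backbone / input-strategy / resolution combination)
# contributes m cross-validated models; their held-out predictions form a
# configurations x folds tensor.  An exhaustive search over all nonempty
# subsets picks C* whose averaged predictions maximize the mean sensitivity
# on the pooled held-out folds; by construction S(C*) is at least the score
# of the full-ensemble average and of every single configuration.

#' Per-configuration, per-fold prediction tensor
#'
#' @param preds nested list: `preds[[i]][[j]]` is the row-stochastic
#'   `n_j x C` matrix of configuration `i`'s predictions on fold `j`'s
#'   held-out images.  All configurations must share fold shapes.
#' @param labels list of integer label vectors, one per fold, aligned with
#'   prediction rows.
#' @param config_names optional configuration names.
#' @return object of class `prediction_tensor`.
#' @export
prediction_tensor <- function(preds, labels,
                              config_names = paste0("cfg", seq_along(preds))) {
  abort_if(length(preds) == 0, "need at least one configuration")
  m <- length(labels)
  for (i in seq_along(preds)) {
    abort_if(length(preds[[i]]) != m, "every configuration needs one block per fold")
    for (j in seq_len(m)) {
      p <- preds[[i]][[j]]
      abort_if(!is.matrix(p), "prediction blocks must be matrices")
      abort_if(nrow(p) != length(labels[[j]]),
               sprintf("fold %d: %d rows vs %d labels", j, nrow(p), length(labels[[j]])))
      abort_if(any(p < -1e-12) || any(abs(rowSums(p) - 1) > 1e-6),
               "prediction rows must be probability vectors")
      abort_if(!identical(dim(p), dim(preds[[1]][[j]])),
               "configurations disagree on fold shapes")
    }
  }
  structure(list(preds = preds, labels = labels,
                 config_names = config_names,
                 n_configs = length(preds), n_folds = m,
                 n_classes = ncol(preds[[1]][[1]])),
            class = "prediction_tensor")
}

#' @export
print.prediction_tensor <- function(x, ...) {
  cat(sprintf("<prediction_tensor  %d configs x %d folds, %d classes, %d images>\n",
              x$n_configs, x$n_folds, x$n_classes,
              sum(lengths(x$labels))))
  invisible(x)
}

#' Average a prediction tensor over a subset of configurations
#'
#' Per fold, the subset configurations' predictions for that fold's held-out
#' images are averaged; rows stay on the probability simplex.
#'
#' @param tensor a [prediction_tensor()].
#' @param subset nonempty integer vector of configuration indices.
#' @return list of per-fold averaged probability matrices.
#' @export
ensemble_average <- function(tensor, subset) {
  abort_if(length(subset) == 0, "subset must be nonempty")
  abort_if(any(!(subset %in% seq_len(tensor$n_configs))), "subset index out of range")
  lapply(seq_len(tensor$n_folds), function(j) {
    acc <- 0
    for (i in subset) acc <- acc + tensor$preds[[i]][[j]]
    acc / length(subset)
  })
}

# Pooled-CV mean sensitivity of per-fold prediction matrices.
pooled_cv_S <- function(fold_preds, labels, C_cls) {
  pred <- unlist(lapply(fold_preds, function(p) max.col(p, ties.method = "first") - 1L))
  truth <- unlist(labels)
  mean_sensitivity(truth, pred, C_cls = C_cls)
}

per_fold_S <- function(fold_preds, labels, C_cls) {
  vapply(seq_along(fold_preds), function(j)
    suppressWarnings(mean_sensitivity(labels[[j]], fold_preds[[j]], C_cls = C_cls)),
    numeric(1))
}

#' Exhaustive ensemble subset search
#'
#' Evaluates all `2^n - 1` nonempty subsets of configurations and returns
#' the one whose averaged predictions maximize the mean sensitivity on the
#' pooled held-out folds.  Deterministic tie-break: smaller subsets first,
#' then lexicographic order.  Per-fold S values of the winner are also
#' reported (mean and standard deviation over folds), alongside the full
#' search log.
#'
#' @param tensor a [prediction_tensor()] built from best-checkpoint
#'   predictions.
#' @param max_configs guard on the search size (default 16, i.e. at most
#'   65535 subsets); raise explicitly for larger searches.
#' @return object of class `ensemble_selection`: `subset` (indices of C*),
#'   `config_names`, `S_star` (pooled CV S), `per_fold_S`, `y_star`
#'   (per-fold averaged predictions), and `search_log` (a data.frame with
#'   one row per evaluated subset).
#' @export
exhaustive_subset_search <- function(tensor, max_configs = 16L) {
  n <- tensor$n_configs
  abort_if(n > max_configs,
           sprintf("%d configurations exceed max_configs = %d; pass a larger max_configs to search anyway",
                   n, max_configs))
  absent <- setdiff(0:(tensor$n_classes - 1L), unique(unlist(tensor$labels)))
  if (length(absent) > 0)
    warning(sprintf("%d class(es) absent from the held-out labels are excluded from S",
                    length(absent)), call. = FALSE)
  subsets <- lapply(seq_len(2^n - 1L), function(bits) which(bitwAnd(bits, 2^(0:(n - 1))) > 0))
  scores <- vapply(subsets, function(ss)
    suppressWarnings(pooled_cv_S(ensemble_average(tensor, ss), tensor$labels,
                                 tensor$n_classes)),
    numeric(1))
  sizes <- lengths(subsets)
  ord <- order(-scores, sizes, vapply(subsets, paste, "", collapse = ","))
  winner <- subsets[[ord[1]]]
  y_star <- ensemble_average(tensor, winner)
  pf <- suppressWarnings(per_fold_S(y_star, tensor$labels, tensor$n_classes))
  structure(list(subset = winner,
                 config_names = tensor$config_names[winner],
                 S_star = scores[ord[1]],
                 per_fold_S = pf,
                 y_star = y_star,
                 search_log = data.frame(
                   subset = vapply(subsets, paste, "", collapse = "+"),
                   size = sizes, S = scores)),
            class = "ensemble_selection")
}

#' @export
print.ensemble_selection <- function(x, ...) {
  cat(sprintf("<ensemble_selection  C* = {%s}  S = %.4f (per-fold %.4f +/- %.4f)>\n",
              paste(x$config_names, collapse = ", "), x$S_star,
              mean(x$per_fold_S), stats::sd(x$per_fold_S)))
  invisible(x)
}

#' Pool best and last checkpoints of the selected subset
#'
#' The subset search runs on best-checkpoint predictions only; the final
#' ensemble additionally averages in the last-checkpoint predictions of the
#' selected configurations for more variability.
#'
#' @param selection an [exhaustive_subset_search()] result.
#' @param best_tensor the [prediction_tensor()] the search ran on.
#' @param last_tensor an aligned tensor of last-checkpoint predictions.
#' @return list with `y_final` (per-fold averaged probability matrices over
#'   the `2 * |C*| * m` prediction blocks) and `S` (its pooled CV mean
#'   sensitivity).
#' @export
pool_best_last <- function(selection, best_tensor, last_tensor) {
  abort_if(!inherits(selection, "ensemble_selection"), "selection required")
  abort_if(best_tensor$n_configs != last_tensor$n_configs ||
             best_tensor$n_folds != last_tensor$n_folds ||
             !identical(lapply(best_tensor$preds[[1]], dim),
                        lapply(last_tensor$preds[[1]], dim)) ||
             !identical(best_tensor$labels, last_tensor$labels),
           "best and last tensors are misaligned")
  yb <- ensemble_average(best_tensor, selection$subset)
  yl <- ensemble_average(last_tensor, selection$subset)
  y_final <- Map(function(a, b) (a + b) / 2, yb, yl)
  list(y_final = y_final,
       S = pooled_cv_S(y_final, best_tensor$labels, best_tensor$n_classes))
}
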