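# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each quantity from first principles and never
# call the code paths they verify.

# Mean of per-class recalls via explicit per-class loops.
oracle_mean_sensitivity <- function(truth, pred_labels) {
  classes <- sort(unique(truth))
  mean(vapply(classes, function(k)
    sum(pred_labels == k & truth == k) / sum(truth == k), numeric(1)))
}

# Pair-counting (rank-statistic) AUC for a binary response.
oracle_auc <- function(response01, scores) {
  pos <- scores[response01 == 1]
  neg <- scores[response01 == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Per-sample weighted cross-entropy, no matrix algebra.
oracle_weighted_ce <- function(logits, labels, w) {
  losses <- vapply(seq_len(nrow(logits)), function(i) {
    z <- logits[i, ]
    p <- exp(z - max(z)) / sum(exp(z - max(z)))
    w[labels[i] + 1] * (-log(p[labels[i] + 1]))
  }, numeric(1))
  mean(losses)
}

# Nested mean over configurations and folds, explicit loops.
oracle_ensemble_average <- function(preds, subset, fold) {
  acc <- 0 * preds[[subset[1]]][[fold]]
  for (i in subset) acc <- acc + preds[[i]][[fold]]
  acc / length(subset)
}

# Exact pixel mask of a rotated ellipse, for bounding-box containment checks.
rasterize_ellipse <- function(h, w, cx, cy, a, b, theta) {
  xg <- matrix(rep(0:(w - 1), each = h), h, w)
  yg <- matrix(rep(0:(h - 1), times = w), h, w)
  xr <- (xg - cx) * cos(theta) + (yg - cy) * sin(theta)
  yr <- -(xg - cx) * sin(theta) + (yg - cy) * cos(theta)
  m <- matrix(0L, h, w)
  m[(xr / a)^2 + (yr / b)^2 <= 1] <- 1L
  m
}

# Inverse of encode_metadata for complete records (round-trip checks).
decode_metadata <- function(v) {
  site_block <- v[1:8]; sex_block <- v[9:10]
  meta_record(
    age = if (v[11] == -5) NA else v[11],
    site = if (sum(site_block) == 0) NA else isic_sites()[which(site_block == 1)],
    sex = if (sum(sex_block) == 0) NA else c("female", "male")[which(sex_block == 1)])
}
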