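#' Stratified group k-fold assignment
#'
#' All recordings sharing a group (participant) ID land in the same fold, so
#' no voice leaks between training and validation. Groups are assigned
#' greedily, largest first, each to the fold where adding it best preserves
#' the global class balance (then the smallest fold, then the lowest index).
#' The assignment depends only on the multiset of groups, not on recording
#' order; `seed` breaks ties among equally sized groups.
#'
#' @param labels binary labels (0/1), one per recording.
#' @param groups group ID per recording.
#' @param k number of folds (default 5).
#' @param seed integer seed for the tie-breaking permutation.
#' @return Integer vector of fold indices in `1..k`, one per recording.
#' @export
stratified_group_kfold <- function(labels, groups, k = 5, seed = 1) {
  labels <- as.integer(labels)
  groups <- as.character(groups)
  stopifnot(length(labels) == length(groups), k >= 2)
  ug <- sort(unique(groups))
  if (length(ug) < k) stop("fewer distinct groups than folds")
  g_size <- vapply(ug, function(g) sum(groups == g), integer(1))
  g_pos <- vapply(ug, function(g) sum(labels[groups == g] == 1L), integer(1))
  g_neg <- g_size - g_pos
  # largest first; equal sizes ordered by a seeded permutation of sorted IDs
  perm <- withr::with_seed(seed, sample.int(length(ug)))
  ord <- order(-g_size, perm)
  fold_pos <- numeric(k); fold_neg <- numeric(k)
  g_fold <- integer(length(ug))
  for (i in ord) {
    # placing the group in each candidate fold, prefer the assignment that
    # keeps per-class counts most even across folds
    cost <- vapply(seq_len(k), function(f) {
      fp <- fold_pos; fn <- fold_neg
      fp[f] <- fp[f] + g_pos[i]
      fn[f] <- fn[f] + g_neg[i]
      stats::sd(fp) + stats::sd(fn)
    }, numeric(1))
    best <- which(cost <= min(cost) + 1e-12)
    if (length(best) > 1L) {
      tot <- fold_pos[best] + fold_neg[best]
      best <- best[tot == min(tot)]
    }
    f <- best[1L]
    g_fold[i] <- f
    fold_pos[f] <- fold_pos[f] + g_pos[i]
    fold_neg[f] <- fold_neg[f] + g_neg[i]
  }
  g_fold[match(groups, ug)]
}

#' Balanced accuracy
#'
#' Mean of sensitivity (accuracy on the fake class, label 1) and specificity
#' (accuracy on the authentic class, label 0).
#'
#' @param y_true,y_pred binary vectors of equal length; `y_true` must contain
#'   both classes.
#' @return A proportion in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1L)
  if (length(unique(y_true)) < 2L)
    stop("balanced accuracy undefined: y_true has a single class")
  sens <- mean(y_pred[y_true == 1L] == 1L)
  spec <- mean(y_pred[y_true == 0L] == 0L)
  (sens + spec) / 2
}

# Per-class metrics for one validation fold (fake = positive class).
fold_metrics <- function(y_true, y_pred) {
  sens <- if (any(y_true == 1L)) mean(y_pred[y_true == 1L] == 1L) else NA_real_
  spec <- if (any(y_true == 0L)) mean(y_pred[y_true == 0L] == 0L) else NA_real_
  tp <- sum(y_pred == 1L & y_true == 1L)
  fp <- sum(y_pred == 1L & y_true == 0L)
  fn <- sum(y_pred == 0L & y_true == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(sens) && precision + sens > 0) {
    2 * precision * sens / (precision + sens)
  } else NA_real_
  c(sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2, precision = precision, f1 = f1)
}
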