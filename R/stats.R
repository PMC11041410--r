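#' Mann–Whitney U test
#'
#' Rank-sum U statistic with midrank ties. The two-sided p-value is exact
#' (full permutation distribution) when `n1 * n2 <= 400` and the pooled
#' sample is tie-free; otherwise the normal approximation with tie and
#' continuity correction is used. A pooled sample with no variation returns
#' `U = n1 * n2 / 2` and `p = 1`.
#'
#' @param x,y numeric samples (non-empty).
#' @return List with `U` (the U statistic for `x`), `p_value`, and `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples contain NA")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(U = n1 * n2 / 2, p_value = 1, method = "degenerate"))
  ties <- anyDuplicated(pooled) > 0L
  exact <- (n1 * n2 <= 400) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  list(U = unname(wt$statistic), p_value = min(p, 1),
       method = if (exact) "exact" else "normal_approx")
}

#' Format a p-value in report style
#'
#' Three decimals without the leading zero; values below 0.001 render as
#' `"<.001"`.
#'
#' @param p numeric p-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.3f", p)))
}

#' Compare pause features between authentic and fake recordings
#'
#' For each of the five pause-profile features, reports the class means and
#' SDs, the Mann–Whitney U statistic (for the authentic sample) and the
#' two-sided p-value, with significance at `alpha`.
#'
#' @param features data frame containing the five pause-feature columns (see
#'   [pause_feature_names()]).
#' @param labels binary vector (0 = authentic, 1 = fake), one per row.
#' @param alpha significance level (default 0.05).
#' @return Data frame of class `feature_comparison`: one row per feature with
#'   `mean_authentic`, `sd_authentic`, `mean_fake`, `sd_fake`, `U`, `p_value`,
#'   `p_formatted`, `significant`.
#' @export
compare_features <- function(features, labels, alpha = 0.05) {
  feats <- pause_feature_names()
  if (!all(feats %in% names(features)))
    stop("feature table must contain the five pause features")
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) stop("labels/feature length mismatch")
  if (length(unique(labels)) < 2L)
    stop("both classes required to compare features")
  rows <- lapply(feats, function(f) {
    xa <- features[[f]][labels == 0L]
    xf <- features[[f]][labels == 1L]
    mw <- mann_whitney_u(xa, xf)
    data.frame(feature = f,
               mean_authentic = mean(xa), sd_authentic = stats::sd(xa),
               mean_fake = mean(xf), sd_fake = stats::sd(xf),
               U = mw$U, p_value = mw$p_value,
               p_formatted = format_p(mw$p_value),
               significant = mw$p_value < alpha)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("feature_comparison", "data.frame")
  out
}
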