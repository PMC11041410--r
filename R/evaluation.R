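#' Rank-statistic AUC
#'
#' Area under the ROC curve computed from the Mann–Whitney rank statistic
#' with midrank ties: the probability that a random fake scores above a
#' random authentic recording (ties counted half).
#'
#' @param scores continuous fake scores (higher = more fake-like).
#' @param labels binary labels (0 authentic, 1 fake); both classes required.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' @param scores continuous fake scores.
#' @param labels binary labels (0/1).
#' @return Data frame with `threshold`, `fpr`, `tpr`, ordered from (0,0) to
#'   (1,1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0,
                numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

subgroup_axes <- function() {
  list(
    paragraph_group = c("trained_paragraph", "naive_paragraph"),
    participant_group = c("model_trained_participant",
                          "model_naive_participant", "pregenerated_tts"),
    generator_group = c("authentic", "model_trained_generator",
                        "model_naive_generator")
  )
}

make_subgroup_report <- function(rows, scores = NULL, labels = NULL) {
  needed <- c("paragraph_group", "participant_group", "generator_group",
              "truth", "n_pred_authentic", "n_pred_fake")
  stopifnot(all(needed %in% names(rows)))
  rows$n <- rows$n_pred_authentic + rows$n_pred_fake
  rows$n_correct <- ifelse(rows$truth == "authentic", rows$n_pred_authentic,
                           rows$n_pred_fake)
  rows$accuracy <- ifelse(rows$n > 0, rows$n_correct / rows$n, NA_real_)
  structure(list(rows = rows, scores = scores, labels = labels),
            class = "subgroup_report")
}

#' Evaluate the final detector on the test partition by subgroup
#'
#' Applies the detector to every test recording and bins the predictions into
#' the model-naive subgroup layout: one block per paragraph axis (trained vs
#' naive paragraph), rows by participant axis crossed with generator axis.
#' Each row is a 2-cell confusion count (predicted authentic / predicted
#' fake) with its accuracy.
#'
#' @param model a `pause_detector` from [fit_final_model()].
#' @param test_features feature table of the test recordings.
#' @param test_meta their `recording_meta` rows.
#' @param config the [split_config()] used for the train/test partition.
#' @return A `subgroup_report`: `rows` (confusion rows), plus per-recording
#'   `scores` and true `labels` for AUC.
#' @export
evaluate_subgroups <- function(model, test_features, test_meta, config) {
  stopifnot(nrow(test_features) == nrow(test_meta))
  tags <- assign_subgroups(test_meta, config)
  pred <- predict(model, test_features)
  scores <- detector_score(model, test_features)
  truth <- ifelse(test_meta$label == 1L, "fake", "authentic")
  ax <- subgroup_axes()
  rows <- list()
  for (pb in ax$paragraph_group) {
    for (pg in ax$participant_group) {
      for (gg in ax$generator_group) {
        sel <- tags$paragraph_group == pb & tags$participant_group == pg &
          tags$generator_group == gg
        if (!any(sel)) next
        rows[[length(rows) + 1L]] <- data.frame(
          paragraph_group = pb, participant_group = pg, generator_group = gg,
          truth = if (gg == "authentic") "authentic" else "fake",
          n_pred_authentic = sum(pred[sel] == 0L),
          n_pred_fake = sum(pred[sel] == 1L))
      }
    }
  }
  make_subgroup_report(do.call(rbind, rows), scores = scores,
                       labels = test_meta$label)
}

#' Compile a subgroup report into overall accuracy and AUC
#'
#' Overall accuracy pools correct counts over every confusion row; AUC is the
#' rank statistic over the pooled per-recording scores (`NA` when the report
#' carries no scores, e.g. one rebuilt from printed counts).
#'
#' @param report a `subgroup_report`.
#' @return List with `overall_accuracy`, `auc`, `n`, and `per_block` (overall
#'   accuracy per paragraph block and participant group).
#' @export
compile_report <- function(report) {
  stopifnot(inherits(report, "subgroup_report"))
  rows <- report$rows
  if (nrow(rows) == 0L) stop("empty subgroup report")
  overall <- sum(rows$n_correct) / sum(rows$n)
  auc <- if (!is.null(report$scores) && !is.null(report$labels)) {
    auc_rank(report$scores, report$labels)
  } else NA_real_
  agg <- stats::aggregate(cbind(n_correct, n) ~ paragraph_group +
                            participant_group, data = rows, FUN = sum)
  agg$accuracy <- agg$n_correct / agg$n
  list(overall_accuracy = overall, auc = auc, n = sum(rows$n),
       per_block = agg)
}

#' Pooled accuracy over a subset of subgroup rows
#'
#' Filters the report's confusion rows on any combination of the three axes
#' and pools correct counts over what remains — e.g. all model-naive-generator
#' rows across both paragraph blocks.
#'
#' @param report a `subgroup_report`.
#' @param paragraph_group,participant_group,generator_group optional filter
#'   values (character vectors).
#' @return List with `accuracy`, `n_correct`, `n`.
#' @export
pooled_accuracy <- function(report, paragraph_group = NULL,
                            participant_group = NULL, generator_group = NULL) {
  rows <- report$rows
  if (!is.null(paragraph_group))
    rows <- rows[rows$paragraph_group %in% paragraph_group, ]
  if (!is.null(participant_group))
    rows <- rows[rows$participant_group %in% participant_group, ]
  if (!is.null(generator_group))
    rows <- rows[rows$generator_group %in% generator_group, ]
  if (nrow(rows) == 0L) stop("no rows match the requested subgroups")
  list(accuracy = sum(rows$n_correct) / sum(rows$n),
       n_correct = sum(rows$n_correct), n = sum(rows$n))
}

#' Bundled reference test report
#'
#' Loads the confusion-matrix counts of a reference evaluation of a
#' pause-pattern deepfake detector on a 257-recording held-out set (bundled
#' as plain CSV under `inst/extdata/`). Useful for validating the reporting
#' arithmetic and as a worked example; it carries counts only, so its AUC is
#' `NA`.
#'
#' @return A `subgroup_report`.
#' @export
reference_test_report <- function() {
  path <- system.file("extdata", "reference_test_counts.csv",
                      package = "pausefake", mustWork = TRUE)
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  make_subgroup_report(rows)
}
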