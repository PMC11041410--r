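test_that("rank AUC matches trapezoidal ROC integration and pROC", {
  withr::with_seed(6, {
    for (i in 1:5) {
      labels <- stats::rbinom(40, 1, 0.5)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      scores <- stats::rnorm(40) + labels
      a_rank <- auc_rank(scores, labels)
      roc <- roc_points(scores, labels)
      a_trap <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                       utils::tail(roc$tpr, -1)) / 2)
      expect_equal(a_rank, a_trap, tolerance = 1e-12)
      if (requireNamespace("pROC", quietly = TRUE)) {
        a_proc <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                 quiet = TRUE,
                                                 direction = "<")))
        expect_equal(a_rank, a_proc, tolerance = 1e-12)
      }
    }
  })
})

test_that("degenerate score sets give chance or perfect AUC", {
  labels <- c(0, 0, 1, 1)
  expect_equal(auc_rank(rep(1, 4), labels), 0.5)
  expect_equal(auc_rank(c(0, 0, 5, 5), labels), 1)
  expect_error(auc_rank(1:3, c(1, 1, 1)), "both classes")
})

test_that("the bundled reference report reproduces every printed accuracy", {
  rep_ <- reference_test_report()
  rows <- rep_$rows
  acc <- function(pb, pg, gg) {
    r <- rows[rows$paragraph_group == pb & rows$participant_group == pg &
                rows$generator_group == gg, ]
    round(r$accuracy, 3)
  }
  # trained-paragraph block
  expect_equal(acc("trained_paragraph", "model_trained_participant",
                   "model_naive_generator"), 0.773)
  expect_equal(acc("trained_paragraph", "model_naive_participant",
                   "authentic"), 0.962)
  expect_equal(acc("trained_paragraph", "model_naive_participant",
                   "model_trained_generator"), 0.769)
  expect_equal(acc("trained_paragraph", "model_naive_participant",
                   "model_naive_generator"), 0.875)
  expect_equal(acc("trained_paragraph", "pregenerated_tts",
                   "model_trained_generator"), 0.646)
  expect_equal(acc("trained_paragraph", "pregenerated_tts",
                   "model_naive_generator"), 1)
  # naive-paragraph block
  expect_equal(acc("naive_paragraph", "model_trained_participant",
                   "authentic"), 0.704)
  expect_equal(acc("naive_paragraph", "model_trained_participant",
                   "model_trained_generator"), 0.806)
  expect_equal(acc("naive_paragraph", "model_trained_participant",
                   "model_naive_generator"), 1)
  expect_equal(acc("naive_paragraph", "model_naive_participant",
                   "authentic"), 0.727)
  expect_equal(acc("naive_paragraph", "model_naive_participant",
                   "model_trained_generator"), 0.875)
  expect_equal(acc("naive_paragraph", "model_naive_participant",
                   "model_naive_generator"), 0.667)
  expect_equal(acc("naive_paragraph", "pregenerated_tts",
                   "model_trained_generator"), 0.875)
  expect_equal(acc("naive_paragraph", "pregenerated_tts",
                   "model_naive_generator"), 1)
})

test_that("block overall accuracies and the compiled total match the printed report", {
  rep_ <- reference_test_report()
  comp <- compile_report(rep_)
  expect_equal(comp$n, 257)
  expect_equal(comp$overall_accuracy, 204 / 257)
  expect_equal(round(comp$overall_accuracy, 2), 0.79)
  expect_true(is.na(comp$auc)) # counts only, no scores
  blk <- function(pb, pg) {
    b <- comp$per_block
    round(b$accuracy[b$paragraph_group == pb & b$participant_group == pg], 3)
  }
  expect_equal(blk("trained_paragraph", "model_trained_participant"), 0.773)
  expect_equal(blk("trained_paragraph", "model_naive_participant"), 0.894)
  expect_equal(blk("trained_paragraph", "pregenerated_tts"), 0.673)
  expect_equal(blk("naive_paragraph", "model_trained_participant"), 0.805)
  expect_equal(blk("naive_paragraph", "model_naive_participant"), 0.758)
  expect_equal(blk("naive_paragraph", "pregenerated_tts"), 0.885)
})

test_that("an always-fake detector zeroes authentic rows and aces fake rows", {
  meta <- reference_cohort()
  cfg <- default_split_config(meta)
  split <- assign_split(meta, cfg)
  test_meta <- meta[split == "test", ]
  idx <- unique(round(seq(1, nrow(test_meta), length.out = 60)))
  cohort <- generate_cohort(test_meta[idx, ], master_seed = 2)
  feats <- cohort_features(cohort)
  all_fake <- fit_final_model(feats, rep(1L, nrow(feats)), "ADA",
                              list(n_estimators = 1, learning_rate = 1))
  rep_ <- evaluate_subgroups(all_fake, feats, cohort$meta, cfg)
  auth_rows <- rep_$rows[rep_$rows$truth == "authentic", ]
  fake_rows <- rep_$rows[rep_$rows$truth == "fake", ]
  expect_true(all(auth_rows$accuracy == 0))
  expect_true(all(fake_rows$accuracy == 1))
  comp <- compile_report(rep_)
  expect_equal(comp$overall_accuracy, mean(cohort$meta$label == 1L))
  expect_equal(comp$auc, 0.5) # constant score
})

test_that("pooled subgroup accuracies recombine the confusion rows", {
  rep_ <- reference_test_report()
  naive_gen <- pooled_accuracy(rep_, generator_group = "model_naive_generator")
  expect_equal(naive_gen$n_correct, 46)
  expect_equal(naive_gen$n, 53)
  all_rows <- pooled_accuracy(rep_)
  expect_equal(all_rows$n, 257)
  expect_error(pooled_accuracy(rep_, paragraph_group = "nonexistent"),
               "no rows")
})
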