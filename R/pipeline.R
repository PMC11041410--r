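#' Run the full detection pipeline on a synthetic cohort
#'
#' End-to-end workflow: generate (or accept) a cohort, compute pause-profile
#' features, split train/test, compare features between classes on the
#' training partition, cross-validate the five model families, refit the
#' winner, and evaluate it on the held-out partition by model-naive subgroup.
#'
#' @param cohort a `synthetic_cohort`; by default one is generated from
#'   [reference_cohort()] with `seed`.
#' @param seed master seed driving cohort generation, fold assignment and
#'   stochastic learners.
#' @param n_training_participants participants used in cross-validation.
#' @param grids hyperparameter grids (see [default_model_grids()]).
#' @param k number of cross-validation folds.
#' @return List of class `pause_pipeline` with `features`, `config`, `split`,
#'   `comparison`, `cv`, `best_family`, `model`, `report`, `summary`.
#' @export
run_detection_pipeline <- function(cohort = NULL, seed = 1,
                                   n_training_participants = 30,
                                   grids = default_model_grids(), k = 5) {
  if (is.null(cohort)) cohort <- generate_cohort(master_seed = seed)
  features <- cohort_features(cohort)
  config <- default_split_config(cohort$meta, n_training_participants)
  split <- assign_split(cohort$meta, config)
  tr <- split == "train"
  comparison <- compare_features(features[tr, ], features$label[tr])
  cv <- cross_validate_models(features[tr, ], features$label[tr],
                              features$group_id[tr], grids = grids, k = k,
                              seed = seed)
  best_family <- cv$summary$family[1L]
  model <- fit_final_model(features[tr, ], features$label[tr], best_family,
                           cv$best_params[[best_family]], seed = seed)
  report <- evaluate_subgroups(model, features[!tr, ], cohort$meta[!tr, ],
                               config)
  structure(list(features = features, config = config, split = split,
                 comparison = comparison, cv = cv, best_family = best_family,
                 model = model, report = report,
                 summary = compile_report(report)),
            class = "pause_pipeline")
}

#' @export
print.pause_pipeline <- function(x, ...) {
  cat(sprintf("Pause-pattern detection pipeline: %d train / %d test recordings\n",
              sum(x$split == "train"), sum(x$split == "test")))
  cat(sprintf("Best family: %s (CV balanced accuracy %.2f)\n", x$best_family,
              x$cv$summary$balanced_accuracy_mean[1L]))
  cat(sprintf("Test overall accuracy %.2f, AUC %.2f (n = %d)\n",
              x$summary$overall_accuracy, x$summary$auc, x$summary$n))
  invisible(x)
}
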