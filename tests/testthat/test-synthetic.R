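test_that("timelines are reproducible from their seed", {
  p <- timeline_params("authentic")
  t1 <- sample_timeline(p, rng_seed = 42)
  t2 <- sample_timeline(p, rng_seed = 42)
  expect_identical(t1, t2)
  t3 <- sample_timeline(p, rng_seed = 43)
  expect_false(identical(t1, t3))
})

test_that("every generated gap is at least the micropause floor", {
  for (seed in 1:10) {
    tl <- sample_timeline(timeline_params("cloned"), rng_seed = seed)
    if (nrow(tl) > 1) {
      gaps <- tl$start[-1] - tl$end[-nrow(tl)]
      expect_gte(min(gaps), 0.1)
    }
    expect_gte(tl$end[nrow(tl)], 90) # runs through the target duration
  }
})

test_that("authentic-class Monte Carlo recovers the generator targets", {
  profs <- do.call(rbind, lapply(1:200, function(i) {
    compute_profile(sample_timeline(timeline_params("authentic"), i))
  }))
  expect_lt(abs(mean(profs$SpeechAV) - 2.93) / 2.93, 0.10)
  expect_lt(abs(mean(profs$MiRate) - 11.72) / 11.72, 0.15)
})

test_that("class differences point the observed way on a large draw", {
  pa <- do.call(rbind, lapply(1:150, function(i) {
    compute_profile(sample_timeline(timeline_params("authentic"), i))
  }))
  pf <- do.call(rbind, lapply(1:150, function(i) {
    compute_profile(sample_timeline(timeline_params("cloned"), 5000 + i))
  }))
  expect_gt(mean(pf$SpeechAV), mean(pa$SpeechAV))   # clones speak longer
  expect_lt(mean(pf$SpeechSD), mean(pa$SpeechSD))   # with less variation
  expect_gt(mean(pf$SpeechProp), mean(pa$SpeechProp))
  expect_lt(mean(pf$MiRate), mean(pa$MiRate))
  expect_lt(mean(pf$MaRate), mean(pa$MaRate))
})

test_that("infeasible pause rates fall back to a single segment with warning", {
  p <- timeline_params("authentic", mi_rate = 1e-4, ma_rate = 1e-4,
                       target_duration = 10)
  expect_warning(tl <- sample_timeline(p, rng_seed = 1), "single-segment")
  expect_equal(nrow(tl), 1)
  expect_equal(compute_profile(tl)$SpeechProp, 1)
})

test_that("rendered audio has the requested envelope and tail", {
  tl <- speech_segments(c(0, 1.5), c(1, 2.2))
  w <- render_audio(tl, rng_seed = 3)
  expect_equal(wave_duration(w), 2.7, tolerance = 1e-3)
  expect_error(render_audio(tl, sample_rate = 4000), "8000")
  silent <- render_audio(speech_segments(numeric(0), numeric(0)), rng_seed = 4)
  expect_equal(wave_duration(silent), 0.5, tolerance = 1e-3)
  expect_equal(nrow(detect_speech_segments(silent)), 0)
})

test_that("cohorts are deterministic and participant effects correlate recordings", {
  meta <- small_cohort_meta(4)
  c1 <- generate_cohort(meta, master_seed = 9)
  c2 <- generate_cohort(meta, master_seed = 9)
  expect_equal(cohort_features(c1), cohort_features(c2))
  c3 <- generate_cohort(meta, master_seed = 10)
  expect_false(identical(cohort_features(c1), cohort_features(c3)))
  # with a shared multiplicative effect, between-participant variance of the
  # mean segment length exceeds what independent draws would give
  feats <- cohort_features(generate_cohort(small_cohort_meta(12),
                                           master_seed = 5))
  auth <- feats[feats$source == "authentic", ]
  fit <- stats::aov(SpeechAV ~ participant_id, data = auth)
  expect_lt(summary(fit)[[1]][["Pr(>F)"]][1], 0.05)
})

test_that("a minimal cohort runs the full pipeline end to end", {
  meta <- small_cohort_meta(6)
  cohort <- generate_cohort(meta, master_seed = 3)
  feats <- cohort_features(cohort)
  expect_equal(nrow(feats), nrow(meta))
  cfg <- split_config(c("q01", "q02", "q03", "q04"))
  split <- assign_split(meta, cfg)
  grids <- list(DT = data.frame(maxdepth = 3), LR = data.frame(lambda = 1))
  cv <- suppressWarnings(cross_validate_models(
    feats[split == "train", ], feats$label[split == "train"],
    feats$group_id[split == "train"], grids = grids, k = 2, seed = 3))
  fam <- cv$summary$family[1]
  model <- fit_final_model(feats[split == "train", ],
                           feats$label[split == "train"], fam,
                           cv$best_params[[fam]])
  rep_ <- evaluate_subgroups(model, feats[split == "test", ],
                             meta[split == "test", ], cfg)
  comp <- compile_report(rep_)
  expect_equal(comp$n, sum(split == "test"))
  expect_true(comp$overall_accuracy >= 0 && comp$overall_accuracy <= 1)
})

test_that("parameter recovery error stays small in a large sample", {
  profs <- do.call(rbind, lapply(1:600, function(i) {
    compute_profile(sample_timeline(timeline_params("authentic"), 20000 + i))
  }))
  targets <- c(SpeechAV = 2.93, SpeechSD = 1.51, SpeechProp = 0.87,
               MiRate = 11.72, MaRate = 7.04)
  got <- vapply(names(targets), function(f) mean(profs[[f]]), numeric(1))
  mare <- mean(abs(got - targets) / targets)
  expect_lt(mare, 0.05)
})
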