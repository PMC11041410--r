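#' Generative parameters for one class of speech timelines
#'
#' Defaults are the observed class-level feature statistics of authentic and
#' cloned recordings: authentic speech segments average 2.93 s (SD 1.51) with
#' 11.72 micropauses and 7.04 macropauses per minute; clones average 3.49 s
#' (SD 1.22) with 9.47 and 5.78. Segment lengths are drawn from a
#' moment-matched log-normal; macro gaps are 0.5 s plus an exponential excess
#' (mean `macro_mean_excess`); micro gaps are uniform on `[0.1, 0.5)`.
#' `target_duration` of 90 s approximates one read paragraph.
#'
#' @param class `"authentic"` or `"cloned"` (sets the defaults).
#' @param seg_mean,seg_sd mean and SD of speech-segment length (s).
#' @param mi_rate,ma_rate micro-/macropauses per trimmed minute.
#' @param macro_mean_excess mean macro-gap length above the 0.5 s floor (s).
#' @param participant_sd SD of the per-participant multiplicative log-normal
#'   random effect on `seg_mean` and both rates.
#' @param target_duration timeline length to generate (s).
#' @return A list of class `timeline_params`.
#' @export
timeline_params <- function(class = c("authentic", "cloned"),
                            seg_mean = NULL, seg_sd = NULL, mi_rate = NULL,
                            ma_rate = NULL, macro_mean_excess = 0.3,
                            participant_sd = 0.15, target_duration = 90) {
  class <- match.arg(class)
  defaults <- if (class == "authentic") {
    list(seg_mean = 2.93, seg_sd = 1.51, mi_rate = 11.72, ma_rate = 7.04)
  } else {
    list(seg_mean = 3.49, seg_sd = 1.22, mi_rate = 9.47, ma_rate = 5.78)
  }
  p <- list(class = class,
            seg_mean = seg_mean %||% defaults$seg_mean,
            seg_sd = seg_sd %||% defaults$seg_sd,
            mi_rate = mi_rate %||% defaults$mi_rate,
            ma_rate = ma_rate %||% defaults$ma_rate,
            macro_mean_excess = macro_mean_excess,
            participant_sd = participant_sd,
            target_duration = target_duration)
  nums <- p[c("seg_mean", "seg_sd", "mi_rate", "ma_rate", "macro_mean_excess",
              "participant_sd", "target_duration")]
  if (any(vapply(nums, function(x) !is.numeric(x) || x <= 0, logical(1))))
    stop("all timeline parameters must be positive")
  if (p$seg_sd >= 2 * p$seg_mean)
    stop("seg_sd too large relative to seg_mean")
  class(p) <- "timeline_params"
  p
}

# log-normal parameters matching a target mean m and SD s
lnorm_match <- function(m, s) {
  sigma2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Sample one speech/pause timeline
#'
#' Alternates log-normal speech segments with gaps: each gap is a macropause
#' with probability `ma_rate / (mi_rate + ma_rate)` (0.5 s plus exponential
#' excess), otherwise a micropause uniform on `[0.1, 0.5)`. Generation stops
#' with the first segment whose end reaches `target_duration`, so a timeline
#' always starts and ends with speech and every gap is at least 0.1 s.
#'
#' @param p a [timeline_params()].
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @return A `speech_segments` data frame.
#' @export
sample_timeline <- function(p, rng_seed = NULL) {
  stopifnot(inherits(p, "timeline_params"))
  if (!is.null(rng_seed))
    return(withr::with_seed(as.integer(rng_seed), sample_timeline(p, NULL)))
  ln <- lnorm_match(p$seg_mean, p$seg_sd)
  expected_gaps <- (p$mi_rate + p$ma_rate) * p$target_duration / 60
  if (expected_gaps < 1) {
    warning("expected fewer than one pause in target_duration; returning a single-segment timeline")
    len <- stats::rlnorm(1, ln$meanlog, ln$sdlog)
    return(speech_segments(0, len))
  }
  p_macro <- p$ma_rate / (p$mi_rate + p$ma_rate)
  starts <- numeric(0); ends <- numeric(0)
  t <- 0
  repeat {
    len <- stats::rlnorm(1, ln$meanlog, ln$sdlog)
    starts <- c(starts, t)
    ends <- c(ends, t + len)
    t <- t + len
    if (t >= p$target_duration) break
    gap <- if (stats::runif(1) < p_macro) {
      0.5 + stats::rexp(1, rate = 1 / p$macro_mean_excess)
    } else {
      stats::runif(1, 0.1, 0.5)
    }
    t <- t + gap
  }
  speech_segments(starts, ends)
}

#' Render a timeline as audio
#'
#' Fills speech intervals with band-limited (300–3400 Hz) noise at RMS 0.2,
#' shaped by 10 ms raised-cosine onset/offset ramps, over a noise floor at
#' RMS 0.002, with a 0.5 s tail after the last segment. Intended for
#' exercising the voice activity detector end to end, not for listening.
#'
#' @param segments a `speech_segments` data frame (may be empty).
#' @param sample_rate output rate in Hz (>= 8000).
#' @param rng_seed integer seed; `NULL` uses the current RNG stream.
#' @param speech_rms,floor_rms RMS levels of speech and floor noise.
#' @return A [waveform()].
#' @export
render_audio <- function(segments, sample_rate = 16000, rng_seed = NULL,
                         speech_rms = 0.2, floor_rms = 0.002) {
  if (sample_rate < 8000) stop("sample_rate must be at least 8000 Hz")
  if (!is.null(rng_seed))
    return(withr::with_seed(as.integer(rng_seed),
                            render_audio(segments, sample_rate, NULL,
                                         speech_rms, floor_rms)))
  validate_segments(segments)
  dur <- if (nrow(segments) > 0L) segments$end[nrow(segments)] + 0.5 else 0.5
  n <- as.integer(round(dur * sample_rate))
  noise <- stats::rnorm(n)
  bf <- signal::butter(4, c(300, 3400) / (sample_rate / 2), type = "pass")
  noise <- signal::filtfilt(bf, noise)
  noise <- noise / sqrt(mean(noise^2))
  env <- rep(floor_rms, n)
  ramp_n <- as.integer(round(0.010 * sample_rate))
  ramp <- (1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2
  for (i in seq_len(nrow(segments))) {
    i0 <- as.integer(round(segments$start[i] * sample_rate)) + 1L
    i1 <- min(as.integer(round(segments$end[i] * sample_rate)), n)
    if (i1 <= i0) next
    seg_env <- rep(1, i1 - i0 + 1L)
    m <- length(seg_env)
    r <- min(ramp_n, m %/% 2L)
    if (r > 0L) {
      seg_env[seq_len(r)] <- ramp[seq_len(r)]
      seg_env[m - seq_len(r) + 1L] <- ramp[seq_len(r)]
    }
    env[i0:i1] <- pmax(env[i0:i1], floor_rms + (speech_rms - floor_rms) * seg_env)
  }
  waveform(pmin(1, pmax(-1, noise * env)), sample_rate)
}

#' Generate a full synthetic cohort
#'
#' Attaches a sampled timeline to every recording of a cohort. Each human
#' participant receives one multiplicative log-normal random effect (scale
#' `participant_sd`) applied to the segment-length mean and both pause rates
#' of both of their classes, so recordings from one voice are correlated and
#' participant-grouped cross-validation is consequential. Pregenerated TTS
#' voices draw from the cloned parameters without participant effects.
#'
#' @param meta a `recording_meta` data frame (default: [reference_cohort()]).
#' @param authentic_params,cloned_params class [timeline_params()].
#' @param master_seed integer seed; the whole cohort is reproducible from it.
#' @return List of class `synthetic_cohort` with `meta` and `timelines`
#'   (named list of `speech_segments`).
#' @export
generate_cohort <- function(meta = reference_cohort(),
                            authentic_params = timeline_params("authentic"),
                            cloned_params = timeline_params("cloned"),
                            master_seed = 1) {
  validate_meta(meta)
  if (length(unique(meta$participant_id[!is.na(meta$participant_id)])) < 2L)
    stop("need at least 2 participants")
  withr::with_seed(as.integer(master_seed), {
    parts <- sort(unique(meta$participant_id[!is.na(meta$participant_id)]))
    eff <- stats::setNames(
      exp(stats::rnorm(length(parts), 0, authentic_params$participant_sd)),
      parts)
    timelines <- vector("list", nrow(meta))
    names(timelines) <- meta$recording_id
    for (i in seq_len(nrow(meta))) {
      base <- if (meta$source[i] == "authentic") authentic_params else cloned_params
      e <- if (meta$source[i] == "pregenerated") 1 else eff[[meta$participant_id[i]]]
      p <- timeline_params(
        class = base$class, seg_mean = base$seg_mean * e,
        seg_sd = base$seg_sd, mi_rate = base$mi_rate * e,
        ma_rate = base$ma_rate * e,
        macro_mean_excess = base$macro_mean_excess,
        participant_sd = base$participant_sd,
        target_duration = base$target_duration)
      timelines[[i]] <- suppressWarnings(sample_timeline(p, NULL))
    }
    structure(list(meta = meta, timelines = timelines,
                   master_seed = as.integer(master_seed)),
              class = "synthetic_cohort")
  })
}

#' Feature table of a synthetic cohort
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @return The [profile_table()] of its timelines.
#' @export
cohort_features <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  profile_table(cohort$timelines, cohort$meta)
}
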