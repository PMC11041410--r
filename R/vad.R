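#' Parameters for the energy-based voice activity detector
#'
#' Defaults: 25 ms frames with a 10 ms hop, speech threshold at 4x the noise
#' floor (10th percentile of frame RMS), voiced runs shorter than 50 ms
#' dropped, silent runs shorter than 50 ms absorbed into speech. The
#' `min_silence` bound must stay below 0.1 s so the detector can never erase a
#' micropause by construction.
#'
#' @param frame_length analysis frame length in seconds.
#' @param hop_length hop between frame starts in seconds (`<= frame_length`).
#' @param energy_threshold_factor multiplier over the noise-floor RMS.
#' @param min_speech minimum voiced-run duration in seconds; shorter runs are
#'   discarded.
#' @param min_silence maximum silent-run duration in seconds that is absorbed
#'   into surrounding speech; must be `< 0.1`.
#' @param absolute_floor absolute RMS level used only for recordings with no
#'   internal dynamic range (e.g. a noise burst spanning the whole file),
#'   where a relative threshold is undefined.
#' @return A list of class `vad_params`.
#' @export
vad_params <- function(frame_length = 0.025, hop_length = 0.010,
                       energy_threshold_factor = 4, min_speech = 0.05,
                       min_silence = 0.05, absolute_floor = 0.01) {
  p <- list(frame_length = frame_length, hop_length = hop_length,
            energy_threshold_factor = energy_threshold_factor,
            min_speech = min_speech, min_silence = min_silence,
            absolute_floor = absolute_floor)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1L || x <= 0,
                 logical(1))))
    stop("all vad_params must be single positive numbers")
  if (p$hop_length > p$frame_length) stop("hop_length must be <= frame_length")
  if (p$min_silence >= 0.1)
    stop("min_silence must be < 0.1 s so micropauses cannot be absorbed")
  class(p) <- "vad_params"
  p
}

# Frame RMS via cumulative sum of squares; frame i covers samples
# [starts[i], starts[i] + frame_n).
frame_rms <- function(samples, frame_n, hop_n) {
  n <- length(samples)
  if (n <= frame_n) return(list(rms = sqrt(mean(samples^2)), starts = 0L))
  starts <- seq.int(0L, n - frame_n, by = hop_n)
  cs <- c(0, cumsum(samples^2))
  energy <- cs[starts + frame_n + 1L] - cs[starts + 1L]
  list(rms = sqrt(energy / frame_n), starts = starts)
}

# Earliest (mode = "first") or latest (mode = "last") time in [t_lo, t_hi]
# where the short-window RMS reaches `threshold`. Used to refine the coarse
# frame-level boundary to sample accuracy.
refine_boundary <- function(samples, sr, t_lo, t_hi, threshold, win_s, mode) {
  win <- max(2L, as.integer(round(win_s * sr)))
  n <- length(samples)
  i_lo <- max(0L, as.integer(floor(t_lo * sr)))
  i_hi <- min(n - win, as.integer(ceiling(t_hi * sr)))
  if (i_hi < i_lo) return(NA_real_)
  cs <- c(0, cumsum(samples^2))
  idx <- i_lo:i_hi
  rms <- sqrt((cs[idx + win + 1L] - cs[idx + 1L]) / win)
  hit <- which(rms >= threshold)
  if (length(hit) == 0L) return(NA_real_)
  if (mode == "first") idx[hit[1L]] / sr else (idx[hit[length(hit)]] + win) / sr
}

#' Detect speech segments with a deterministic energy VAD
#'
#' Frames whose RMS energy exceeds the noise floor (10th percentile of frame
#' RMS) times `energy_threshold_factor` are voiced. Silent runs shorter than
#' `min_silence` are absorbed into speech, voiced runs shorter than
#' `min_speech` are dropped, and each remaining boundary is refined to sample
#' accuracy with a 5 ms energy window searched within one frame of the coarse
#' boundary. The threshold is relative to the recording's own noise floor, so
#' segmentation is invariant to overall amplitude scaling.
#'
#' @param w a [waveform()].
#' @param p a [vad_params()].
#' @return A data frame of class `speech_segments` with columns `start` and
#'   `end` (seconds, half-open intervals, sorted, non-overlapping). Zero rows
#'   for an all-silent recording.
#' @export
detect_speech_segments <- function(w, p = vad_params()) {
  stopifnot(inherits(w, "waveform"), inherits(p, "vad_params"))
  if (anyNA(w$samples)) stop("waveform contains NaN/NA samples")
  if (length(w$samples) == 0L) stop("empty waveform")
  sr <- w$sample_rate
  dur <- wave_duration(w)
  frame_n <- max(2L, as.integer(round(p$frame_length * sr)))
  hop_n <- max(1L, as.integer(round(p$hop_length * sr)))
  fr <- frame_rms(w$samples, frame_n, hop_n)
  rms <- fr$rms
  t_frame <- fr$starts / sr

  noise_floor <- stats::quantile(rms, 0.10, names = FALSE, type = 7)
  threshold <- noise_floor * p$energy_threshold_factor
  if (max(rms) <= threshold) {
    # No internal dynamic range (all speech or all silence): fall back to an
    # absolute floor to separate a full-file burst from digital silence.
    threshold <- p$absolute_floor
  }
  voiced <- rms > threshold
  if (!any(voiced)) return(empty_segments())

  # Absorb sub-min_silence silent runs, then drop sub-min_speech voiced runs.
  r <- rle(voiced)
  interior <- seq_along(r$values)
  for (j in interior) {
    if (!r$values[j] && j > 1L && j < length(r$values) &&
        r$lengths[j] * p$hop_length < p$min_silence) {
      r$values[j] <- TRUE
    }
  }
  voiced <- inverse.rle(r)
  r <- rle(voiced)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  segs <- list()
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    span <- (r$lengths[j] - 1L) * p$hop_length + p$frame_length
    if (span < p$min_speech) next
    cs <- t_frame[starts_idx[j]]
    ce <- min(t_frame[ends_idx[j]] + p$frame_length, dur)
    segs[[length(segs) + 1L]] <- c(cs, ce)
  }
  if (length(segs) == 0L) return(empty_segments())
  m <- do.call(rbind, segs)

  # Boundary refinement keeps each refined edge inside the neighbouring gap.
  out <- m
  for (i in seq_len(nrow(m))) {
    lo_s <- if (i == 1L) 0 else m[i - 1L, 2L]
    hi_e <- if (i == nrow(m)) dur else m[i + 1L, 1L]
    rs <- refine_boundary(w$samples, sr, max(lo_s, m[i, 1L] - p$frame_length),
                          m[i, 1L] + p$frame_length, threshold, 0.005, "first")
    re <- refine_boundary(w$samples, sr, m[i, 2L] - p$frame_length,
                          min(hi_e, m[i, 2L] + p$frame_length), threshold,
                          0.005, "last")
    if (!is.na(rs)) out[i, 1L] <- rs
    if (!is.na(re)) out[i, 2L] <- min(re, dur)
    if (out[i, 2L] <= out[i, 1L]) out[i, ] <- m[i, ] # refinement degenerate
  }
  # Enforce non-overlap after refinement (adjacent search windows can touch).
  for (i in seq_len(nrow(out))[-1]) {
    if (out[i, 1L] < out[i - 1L, 2L]) out[i, 1L] <- out[i - 1L, 2L]
  }
  speech_segments(out[, 1L], out[, 2L])
}

empty_segments <- function() {
  speech_segments(numeric(0), numeric(0))
}

#' Construct and validate a speech-segment table
#'
#' @param start,end segment boundaries in seconds; half-open `[start, end)`.
#' @return A `speech_segments` data frame.
#' @export
speech_segments <- function(start, end) {
  df <- data.frame(start = as.numeric(start), end = as.numeric(end))
  class(df) <- c("speech_segments", "data.frame")
  validate_segments(df)
  df
}

#' Validate the speech-segment contract
#'
#' Checks the invariants every segmenter must satisfy: numeric `start`/`end`
#' columns, `end > start`, sorted by `start`, non-overlapping, and (if
#' `duration` is given) `end <= duration`.
#'
#' @param segments a data frame with `start` and `end` columns.
#' @param duration optional recording duration in seconds.
#' @return `segments`, invisibly; errors on contract violation.
#' @export
validate_segments <- function(segments, duration = NULL) {
  if (!is.data.frame(segments) || !all(c("start", "end") %in% names(segments)))
    stop("segmenter contract violation: need a data frame with start/end")
  s <- segments$start; e <- segments$end
  if (anyNA(s) || anyNA(e)) stop("segmenter contract violation: NA boundary")
  if (any(s < 0)) stop("segmenter contract violation: negative start")
  if (any(e <= s)) stop("segmenter contract violation: end <= start")
  if (is.unsorted(s, strictly = FALSE))
    stop("segmenter contract violation: segments not sorted by start")
  if (nrow(segments) > 1L && any(s[-1] < e[-nrow(segments)]))
    stop("segmenter contract violation: overlapping segments")
  if (!is.null(duration) && any(e > duration + 1e-9))
    stop("segmenter contract violation: segment past end of recording")
  invisible(segments)
}

.segmenter_env <- new.env(parent = emptyenv())

#' Register or reset the active segmenter
#'
#' Downstream feature extraction depends only on the segmenter contract
#' (`function(waveform) -> speech_segments`), so an external neural VAD can be
#' substituted for the built-in energy detector. Passing `NULL` restores the
#' default ([detect_speech_segments()] with default [vad_params()]).
#'
#' @param fun a segmenter function, or `NULL` to reset.
#' @return The previously registered segmenter, invisibly.
#' @export
set_segmenter <- function(fun = NULL) {
  if (!is.null(fun) && !is.function(fun)) stop("segmenter must be a function")
  old <- .segmenter_env$segmenter
  .segmenter_env$segmenter <- fun
  invisible(old)
}

#' Segment a recording through the registered segmenter
#'
#' Applies the active segmenter (default: the energy VAD) and validates its
#' output against the segment contract before returning it.
#'
#' @param w a [waveform()].
#' @param segmenter optional one-off segmenter overriding the registered one.
#' @return A validated `speech_segments` data frame.
#' @export
segment_speech <- function(w, segmenter = NULL) {
  fn <- segmenter %||% .segmenter_env$segmenter %||%
    function(w) detect_speech_segments(w, vad_params())
  out <- fn(w)
  validate_segments(out, duration = wave_duration(w) + 1e-9)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
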