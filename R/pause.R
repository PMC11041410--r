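#' Classify an inter-segment gap
#'
#' Gaps of at least 0.1 s and under 0.5 s are micropauses; gaps of 0.5 s or
#' more are macropauses. Shorter gaps ("intra" gaps) are below the resolution
#' at which a pause is counted: they still separate segments and contribute to
#' the trimmed recording length, but to neither pause rate.
#'
#' @param gap gap length(s) in seconds; must be non-negative.
#' @param micro_floor lower bound of a micropause (default 0.1 s).
#' @param macro_floor lower bound of a macropause (default 0.5 s).
#' @return A factor with levels `intra`, `micro`, `macro`.
#' @export
classify_gap <- function(gap, micro_floor = 0.1, macro_floor = 0.5) {
  if (any(!is.finite(gap))) stop("gap must be finite")
  if (any(gap < 0)) stop("negative gap implies overlapping segments")
  stopifnot(micro_floor > 0, macro_floor > micro_floor)
  cls <- ifelse(gap >= macro_floor, "macro",
                ifelse(gap >= micro_floor, "micro", "intra"))
  factor(cls, levels = c("intra", "micro", "macro"))
}

#' Trimmed span of a segment list
#'
#' The analysis window runs from the start of the first speech segment to the
#' end of the last one; leading and trailing silence are discarded.
#'
#' @param segments a `speech_segments` data frame (at least one row).
#' @return Named numeric vector `c(start, end)`.
#' @export
trim_span <- function(segments) {
  validate_segments(segments)
  if (nrow(segments) == 0L) stop("no speech segments: cannot trim")
  c(start = segments$start[1L], end = segments$end[nrow(segments)])
}

#' Pause-profile features of one recording
#'
#' Computes the five amplitude-agnostic features summarizing the speech/pause
#' pattern of a segmented recording:
#' \describe{
#'   \item{SpeechAV}{mean speech-segment length (s).}
#'   \item{SpeechSD}{sample SD of segment lengths (s); 0 for one segment.}
#'   \item{SpeechProp}{total speech time over the trimmed recording length.}
#'   \item{MiRate}{micropauses per minute of trimmed recording.}
#'   \item{MaRate}{macropauses per minute of trimmed recording.}
#' }
#'
#' @param segments a `speech_segments` data frame, sorted and non-overlapping,
#'   with at least one row.
#' @param micro_floor,macro_floor gap-class thresholds in seconds, passed to
#'   [classify_gap()].
#' @return One-row data frame with the five features plus `n_segments` and
#'   `trimmed_length`.
#' @export
compute_profile <- function(segments, micro_floor = 0.1, macro_floor = 0.5) {
  validate_segments(segments)
  if (nrow(segments) == 0L) stop("no speech segments: cannot compute profile")
  len <- segments$end - segments$start
  if (any(len <= 0)) stop("zero-length speech segment")
  span <- trim_span(segments)
  trimmed <- unname(span["end"] - span["start"])
  if (trimmed <= 0) stop("degenerate recording: trimmed length is zero")
  gaps <- if (nrow(segments) > 1L) {
    segments$start[-1L] - segments$end[-nrow(segments)]
  } else numeric(0)
  if (any(gaps < 0)) stop("overlapping segments")
  gap_class <- classify_gap(gaps, micro_floor, macro_floor)
  minutes <- trimmed / 60
  data.frame(
    SpeechAV = mean(len),
    SpeechSD = if (length(len) > 1L) stats::sd(len) else 0,
    SpeechProp = sum(len) / trimmed,
    MiRate = sum(gap_class == "micro") / minutes,
    MaRate = sum(gap_class == "macro") / minutes,
    n_segments = nrow(segments),
    trimmed_length = trimmed
  )
}

#' Names of the five pause-profile features, in canonical order
#' @return Character vector.
#' @export
pause_feature_names <- function() {
  c("SpeechAV", "SpeechSD", "SpeechProp", "MiRate", "MaRate")
}

#' Feature table for a set of segmented recordings
#'
#' Binds per-recording pause profiles to their metadata, producing the feature
#' table consumed by the comparison, training and evaluation stages.
#'
#' @param timelines named list of `speech_segments`, names = recording IDs.
#' @param meta recording metadata ([recording_meta()] data frame) whose
#'   `recording_id` values match `names(timelines)`.
#' @return Data frame: metadata columns followed by the five features,
#'   `n_segments` and `trimmed_length`.
#' @export
profile_table <- function(timelines, meta) {
  stopifnot(is.list(timelines), !is.null(names(timelines)))
  if (!all(meta$recording_id %in% names(timelines)))
    stop("missing timeline for some recordings")
  profs <- do.call(rbind, lapply(meta$recording_id, function(id) {
    compute_profile(timelines[[id]])
  }))
  cbind(meta, profs, row.names = NULL)
}
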