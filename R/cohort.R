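#' Recording metadata table
#'
#' One row per recording. `source` is `authentic` (a participant reading a
#' paragraph), `cloned` (a voice-clone model trained on that participant,
#' reading the same paragraph) or `pregenerated` (a stock text-to-speech voice
#' shipped with a cloning platform; no human participant). `label` is 0 for
#' authentic, 1 for fake (cloned or pregenerated). `group_id` is the
#' cross-validation grouping unit: the participant for human-derived audio, a
#' synthetic per-voice ID for pregenerated TTS.
#'
#' @param recording_id unique recording identifiers.
#' @param participant_id participant identifiers; `NA` for pregenerated TTS.
#' @param source one of `authentic`, `cloned`, `pregenerated`.
#' @param generator one of `ElevenLabs`, `Podcastle`, `Descript`, `none`.
#' @param paragraph one of `P1`, `P2`, `P3`.
#' @param voice_id optional TTS voice identifier (pregenerated rows only).
#' @return A validated data frame of class `recording_meta`.
#' @export
recording_meta <- function(recording_id, participant_id, source, generator,
                           paragraph, voice_id = NA_character_) {
  df <- data.frame(
    recording_id = as.character(recording_id),
    participant_id = as.character(participant_id),
    source = as.character(source),
    generator = as.character(generator),
    paragraph = as.character(paragraph),
    stringsAsFactors = FALSE
  )
  voice_id <- rep_len(as.character(voice_id), nrow(df))
  df$label <- ifelse(df$source == "authentic", 0L, 1L)
  df$group_id <- ifelse(df$source == "pregenerated",
                        paste0("tts_", df$generator, "_", voice_id),
                        df$participant_id)
  class(df) <- c("recording_meta", "data.frame")
  validate_meta(df)
  df
}

#' Validate recording metadata invariants
#' @param meta a `recording_meta` data frame.
#' @return `meta`, invisibly; errors on violation.
#' @export
validate_meta <- function(meta) {
  stopifnot(is.data.frame(meta))
  if (anyDuplicated(meta$recording_id)) stop("duplicate recording_id")
  if (!all(meta$source %in% c("authentic", "cloned", "pregenerated")))
    stop("invalid source")
  if (!all(meta$generator %in% c("ElevenLabs", "Podcastle", "Descript", "none")))
    stop("invalid generator")
  if (!all(meta$paragraph %in% c("P1", "P2", "P3"))) stop("invalid paragraph")
  auth <- meta$source == "authentic"
  if (any(auth & meta$generator != "none"))
    stop("authentic recordings must have generator = none")
  if (any(auth & is.na(meta$participant_id)))
    stop("authentic recordings need a participant_id")
  if (any(meta$source == "pregenerated" & !is.na(meta$participant_id)))
    stop("pregenerated TTS recordings have no participant")
  if (any(meta$source != "authentic" & meta$generator == "none"))
    stop("fake recordings need a generator")
  if (!identical(meta$label, ifelse(auth, 0L, 1L)))
    stop("label must be 0 iff source is authentic")
  invisible(meta)
}

#' Train/test split configuration
#'
#' The default mirrors the study design: paragraphs P1 and P2, the ElevenLabs
#' and Podcastle generators, and a designated subset of participants are used
#' for training; everything else — including all pregenerated TTS voices and
#' the Descript generator — is held out for testing.
#'
#' @param training_participants character vector of participant IDs.
#' @param training_paragraphs paragraphs used in training (default P1, P2).
#' @param training_generators clone generators used in training (default
#'   ElevenLabs and Podcastle).
#' @return A list of class `split_config`.
#' @export
split_config <- function(training_participants,
                         training_paragraphs = c("P1", "P2"),
                         training_generators = c("ElevenLabs", "Podcastle")) {
  if (length(training_participants) == 0L) stop("no training participants")
  if (length(training_paragraphs) == 0L) stop("no training paragraphs")
  if (length(training_generators) == 0L) stop("no training generators")
  structure(list(training_participants = as.character(training_participants),
                 training_paragraphs = as.character(training_paragraphs),
                 training_generators = as.character(training_generators)),
            class = "split_config")
}

#' Default training-participant subset
#'
#' The first `n` participants by sorted ID (about 60 percent of a 49-person
#' cohort when `n = 30`).
#'
#' @param meta a `recording_meta` data frame.
#' @param n number of training participants.
#' @return Character vector of participant IDs.
#' @export
default_training_participants <- function(meta, n = 30) {
  ids <- sort(unique(meta$participant_id[!is.na(meta$participant_id)]))
  utils::head(ids, n)
}

#' Assign each recording to the training or testing partition
#'
#' A recording trains the model iff its participant, paragraph and (for
#' clones) generator are all in the training configuration; pregenerated TTS
#' recordings are always test.
#'
#' @param meta a `recording_meta` data frame.
#' @param config a [split_config()].
#' @return Character vector, `"train"` or `"test"`, one per row of `meta`.
#' @export
assign_split <- function(meta, config) {
  validate_meta(meta)
  stopifnot(inherits(config, "split_config"))
  in_part <- !is.na(meta$participant_id) &
    meta$participant_id %in% config$training_participants
  in_para <- meta$paragraph %in% config$training_paragraphs
  src_ok <- meta$source == "authentic" |
    (meta$source == "cloned" & meta$generator %in% config$training_generators)
  ifelse(in_part & in_para & src_ok, "train", "test")
}

#' Model-naive subgroup tags for test recordings
#'
#' Every test recording receives exactly one tag per axis:
#' participant axis (`model_trained_participant`, `model_naive_participant`,
#' `pregenerated_tts`), paragraph axis (`trained_paragraph`,
#' `naive_paragraph`) and generator axis (`authentic`,
#' `model_trained_generator`, `model_naive_generator`).
#'
#' @param meta a `recording_meta` data frame of test recordings only.
#' @param config a [split_config()].
#' @return Data frame with columns `participant_group`, `paragraph_group`,
#'   `generator_group`.
#' @export
assign_subgroups <- function(meta, config) {
  split <- assign_split(meta, config)
  if (any(split == "train"))
    stop("assign_subgroups called on training recordings")
  participant_group <- ifelse(
    meta$source == "pregenerated", "pregenerated_tts",
    ifelse(meta$participant_id %in% config$training_participants,
           "model_trained_participant", "model_naive_participant"))
  paragraph_group <- ifelse(meta$paragraph %in% config$training_paragraphs,
                            "trained_paragraph", "naive_paragraph")
  generator_group <- ifelse(
    meta$source == "authentic", "authentic",
    ifelse(meta$generator %in% config$training_generators,
           "model_trained_generator", "model_naive_generator"))
  data.frame(participant_group = participant_group,
             paragraph_group = paragraph_group,
             generator_group = generator_group)
}

#' Cohort ledger: recording counts by generator, split and paragraph
#'
#' Tabulates collected/generated recordings in the study's bookkeeping layout:
#' one block per generator (pretrained/cloned/total rows), an authentic block,
#' and a grand-total row, each split into training and testing columns with
#' per-paragraph breakdowns.
#'
#' @param meta a `recording_meta` data frame.
#' @param config a [split_config()].
#' @return Data frame with columns `section`, `row`, `train_n`, `train_P1`,
#'   `train_P2`, `test_n`, `test_P1`, `test_P2`, `test_P3`, `total_n`,
#'   `total_P1`, `total_P2`, `total_P3`.
#' @export
tabulate_ledger <- function(meta, config) {
  if (nrow(meta) > 0L) validate_meta(meta)
  split <- if (nrow(meta) > 0L) assign_split(meta, config) else character(0)
  count <- function(keep) {
    n_cell <- function(sp, para) sum(keep & split == sp & meta$paragraph == para)
    c(train_n = sum(keep & split == "train"),
      train_P1 = n_cell("train", "P1"), train_P2 = n_cell("train", "P2"),
      test_n = sum(keep & split == "test"),
      test_P1 = n_cell("test", "P1"), test_P2 = n_cell("test", "P2"),
      test_P3 = n_cell("test", "P3"),
      total_n = sum(keep),
      total_P1 = sum(keep & meta$paragraph == "P1"),
      total_P2 = sum(keep & meta$paragraph == "P2"),
      total_P3 = sum(keep & meta$paragraph == "P3"))
  }
  keep_all <- rep(TRUE, nrow(meta))
  rows <- list(c(section = "All", row = "all_recordings", count(keep_all)))
  for (gen in c("ElevenLabs", "Podcastle", "Descript")) {
    g <- meta$generator == gen
    rows <- c(rows, list(
      c(section = gen, row = "pretrained", count(g & meta$source == "pregenerated")),
      c(section = gen, row = "cloned", count(g & meta$source == "cloned")),
      c(section = gen, row = "total", count(g))
    ))
  }
  rows <- c(rows, list(c(section = "Authentic", row = "total",
                         count(meta$source == "authentic"))))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  num_cols <- setdiff(names(out), c("section", "row"))
  out[num_cols] <- lapply(out[num_cols], as.integer)
  out
}

# Deterministic incidence helper: participant ids p01..p49.
.pid <- function(i) sprintf("p%02d", i)

#' Reference cohort metadata
#'
#' A deterministic 384-recording cohort of 49 participants reproducing the
#' study's recording multiplicities cell by cell: 130 authentic recordings,
#' 176 clones across three generators, and 78 pregenerated TTS recordings,
#' yielding 127 training and 257 testing recordings under the default split
#' (30 training participants, paragraphs P1/P2, ElevenLabs + Podcastle).
#' Which individual participants miss which recordings is not public; the
#' pattern used here is a fixed, documented choice that (a) reproduces every
#' aggregate count, (b) gives all 30 training participants at least one
#' training recording, and (c) populates every model-naive subgroup cell.
#'
#' @return A `recording_meta` data frame of 384 rows.
#' @export
reference_cohort <- function() {
  rows <- list()
  add <- function(pids, source, generator, paragraph) {
    for (p in pids) {
      rows[[length(rows) + 1L]] <<- data.frame(
        participant_id = p, source = source, generator = generator,
        paragraph = paragraph, voice_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  add_tts <- function(generator, paragraph, voices) {
    for (v in voices) {
      rows[[length(rows) + 1L]] <<- data.frame(
        participant_id = NA_character_, source = "pregenerated",
        generator = generator, paragraph = paragraph,
        voice_id = sprintf("v%02d", v), stringsAsFactors = FALSE)
    }
  }
  # Authentic: 41 / 40 / 49 per paragraph.
  add(.pid(c(1:28, 31:43)), "authentic", "none", "P1")
  add(.pid(c(3:29, 31:43)), "authentic", "none", "P2")
  add(.pid(1:49), "authentic", "none", "P3")
  # ElevenLabs clones: 26 / 23 / 24.
  add(.pid(c(1:22, 31:34)), "cloned", "ElevenLabs", "P1")
  add(.pid(8:30), "cloned", "ElevenLabs", "P2")
  add(.pid(c(1:18, 31:36)), "cloned", "ElevenLabs", "P3")
  # Podcastle clones: 19 / 18 / 20.
  add(.pid(c(1:13, 31:36)), "cloned", "Podcastle", "P1")
  add(.pid(c(17:30, 31:34)), "cloned", "Podcastle", "P2")
  add(.pid(c(1:16, 31:34)), "cloned", "Podcastle", "P3")
  # Descript clones (held-out generator): 13 / 16 / 17.
  add(.pid(c(1:9, 31:34)), "cloned", "Descript", "P1")
  add(.pid(c(1:12, 31:34)), "cloned", "Descript", "P2")
  add(.pid(c(1:13, 31:34)), "cloned", "Descript", "P3")
  # Pregenerated TTS voices: ElevenLabs 7/5/7, Podcastle 18/18/17,
  # Descript 2/2/2.
  add_tts("ElevenLabs", "P1", 1:7)
  add_tts("ElevenLabs", "P2", 1:5)
  add_tts("ElevenLabs", "P3", 1:7)
  add_tts("Podcastle", "P1", 1:18)
  add_tts("Podcastle", "P2", 1:18)
  add_tts("Podcastle", "P3", 1:17)
  add_tts("Descript", "P1", 1:2)
  add_tts("Descript", "P2", 1:2)
  add_tts("Descript", "P3", 1:2)

  df <- do.call(rbind, rows)
  recording_meta(
    recording_id = sprintf("r%03d", seq_len(nrow(df))),
    participant_id = df$participant_id,
    source = df$source,
    generator = df$generator,
    paragraph = df$paragraph,
    voice_id = df$voice_id
  )
}

#' Default split configuration for a cohort
#'
#' @param meta a `recording_meta` data frame.
#' @param n_training_participants how many participants train the model.
#' @return A [split_config()].
#' @export
default_split_config <- function(meta, n_training_participants = 30) {
  split_config(default_training_participants(meta, n_training_participants))
}
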