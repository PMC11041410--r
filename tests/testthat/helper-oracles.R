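# Independent straight-line oracles, kept deliberately naive and separate
# from the package implementation paths they check.

# Recompute all five pause features from first principles.
oracle_profile <- function(start, end) {
  L <- end - start
  n <- length(L)
  gaps <- if (n > 1) start[-1] - end[-n] else numeric(0)
  trimmed <- end[n] - start[1]
  mu <- sum(L) / n
  list(
    SpeechAV = mu,
    SpeechSD = if (n > 1) sqrt(sum((L - mu)^2) / (n - 1)) else 0,
    SpeechProp = sum(L) / trimmed,
    MiRate = sum(gaps >= 0.1 & gaps < 0.5) / (trimmed / 60),
    MaRate = sum(gaps >= 0.5) / (trimmed / 60)
  )
}

# Exact Mann-Whitney two-sided p by enumeration of all C(n1+n2, n1)
# relabelings; U uses midrank tie handling via the pairwise definition.
oracle_mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n1 + n2, n1), 2, u_of)
  mu <- n1 * n2 / 2
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# Random timeline honouring the segmenter round-trip preconditions:
# segments >= 0.3 s, gaps >= 0.1 s.
random_recoverable_timeline <- function(n_segments, seed) {
  withr::with_seed(seed, {
    lens <- pmax(0.35, stats::rlnorm(n_segments, log(1.2), 0.5))
    gaps <- 0.1 + stats::rexp(n_segments - 1, rate = 3)
    starts <- cumsum(c(0.4, lens[-n_segments] + gaps))
    speech_segments(starts, starts + lens)
  })
}

# Small deterministic cohort for fast end-to-end tests: n participants, all
# three paragraphs, authentic + one clone per generator requested.
small_cohort_meta <- function(n_participants = 4,
                              generators = c("ElevenLabs", "Podcastle")) {
  rows <- list()
  for (i in seq_len(n_participants)) {
    pid <- sprintf("q%02d", i)
    for (para in c("P1", "P2", "P3")) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, source = "authentic", generator = "none",
        paragraph = para)
      for (g in generators) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, source = "cloned", generator = g,
          paragraph = para)
      }
    }
  }
  df <- do.call(rbind, rows)
  recording_meta(sprintf("s%03d", seq_len(nrow(df))), df$participant_id,
                 df$source, df$generator, df$paragraph)
}

# Write a small PCM WAV by hand (supports stereo and chosen bit depth) so
# load_waveform can be checked against an independent byte layout.
write_raw_wav <- function(path, channels, sample_rate, bits = 16) {
  stopifnot(is.matrix(channels)) # one column per channel, integer samples
  nch <- ncol(channels)
  interleaved <- as.integer(t(channels))
  bytes_per <- bits / 8
  n_bytes <- length(interleaved) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * nch * bytes_per), con, size = 4,
           endian = "little")
  writeBin(as.integer(nch * bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(interleaved, con, size = bytes_per, endian = "little")
  path
}
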