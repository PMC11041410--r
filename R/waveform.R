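#' Mono waveform container
#'
#' A `waveform` holds mono audio samples in `[-1, 1]` together with the
#' sampling rate in Hz. All audio entering the pause-pattern pipeline is
#' normalized to this representation (see [load_waveform()]).
#'
#' @param samples numeric vector of amplitudes, nominally in `[-1, 1]`.
#' @param sample_rate sampling rate in Hz (positive integer).
#' @return An object of class `waveform` with elements `samples` and
#'   `sample_rate`.
#' @seealso [load_waveform()], [write_waveform()], [wave_duration()]
#' @export
waveform <- function(samples, sample_rate) {
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (length(samples) == 0L) stop("empty waveform: no samples")
  if (anyNA(samples)) stop("waveform contains NA samples")
  sample_rate <- as.numeric(sample_rate)
  if (length(sample_rate) != 1L || !is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(
    list(samples = as.numeric(samples), sample_rate = as.integer(round(sample_rate))),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %.3f s @ %d Hz, %d samples, peak %.3f>\n",
              wave_duration(x), x$sample_rate, length(x$samples),
              max(abs(x$samples))))
  invisible(x)
}

#' Duration of a waveform in seconds
#'
#' @param w a [waveform()].
#' @return Duration in seconds (`n_samples / sample_rate`).
#' @export
wave_duration <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$sample_rate
}

# Linear-interpolation resampler. Deterministic; adequate for energy-based
# segmentation (we never analyse spectral content above the envelope scale).
resample_linear <- function(samples, from_rate, to_rate) {
  if (from_rate == to_rate) return(samples)
  n_in <- length(samples)
  n_out <- max(1L, as.integer(round(n_in * to_rate / from_rate)))
  t_in <- (seq_len(n_in) - 1) / from_rate
  t_out <- (seq_len(n_out) - 1) / to_rate
  stats::approx(t_in, samples, xout = t_out, rule = 2)$y
}

#' Read a PCM WAV file as a mono waveform
#'
#' Reads RIFF/WAVE files containing 8/16/24/32-bit integer PCM or 32-bit IEEE
#' float samples. Multichannel audio is averaged to mono; integer samples are
#' rescaled to `[-1, 1]`. By default the signal is resampled to the package's
#' canonical 16 kHz rate so frame-based segmentation has fixed semantics.
#'
#' @param path path to a `.wav` file.
#' @param target_rate canonical rate in Hz to resample to on load; `NULL`
#'   keeps the file's native rate. Default 16000.
#' @return A [waveform()].
#' @export
load_waveform <- function(path, target_rate = 16000) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  size <- file.info(path)$size
  if (is.na(size) || size < 44) stop(sprintf("not a WAV file (too short): %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  raw4 <- function() rawToChar(readBin(con, "raw", 4L))
  u32 <- function() readBin(con, "integer", 1L, size = 4L, endian = "little")
  u16 <- function() readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")

  if (!identical(raw4(), "RIFF")) stop(sprintf("not a RIFF/WAV file: %s", path))
  u32() # riff size, unused
  if (!identical(raw4(), "WAVE")) stop(sprintf("not a WAVE file: %s", path))

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4L)
    if (length(id_raw) < 4L) break
    id <- rawToChar(id_raw)
    len <- u32()
    if (length(len) == 0L || is.na(len) || len < 0) break
    if (id == "fmt ") {
      fmt <- list(
        audio_format = u16(), n_channels = u16(), sample_rate = u32(),
        byte_rate = u32(), block_align = u16(), bits = u16()
      )
      extra <- len - 16L
      if (fmt$audio_format == 65534L && extra >= 10L) {
        # WAVE_FORMAT_EXTENSIBLE: cbSize, valid bits, channel mask, subformat
        u16(); u16(); u32()
        sub <- u16()
        fmt$audio_format <- sub
        extra <- extra - 10L
      }
      if (extra > 0) readBin(con, "raw", extra)
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", len)
      if (len %% 2L == 1L) readBin(con, "raw", 1L)
    } else {
      skip <- len + (len %% 2L)
      seek(con, skip, origin = "current")
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop(sprintf("corrupt WAV (no fmt chunk): %s", path))
  if (is.null(data_raw) || length(data_raw) == 0L)
    stop(sprintf("empty WAV (no audio data): %s", path))
  if (!fmt$audio_format %in% c(1L, 3L))
    stop(sprintf("unsupported WAV encoding (format tag %d): %s", fmt$audio_format, path))

  samples <- decode_pcm(data_raw, fmt$bits, fmt$audio_format)
  nch <- fmt$n_channels
  if (nch > 1L) {
    usable <- (length(samples) %/% nch) * nch
    samples <- rowMeans(matrix(samples[seq_len(usable)], ncol = nch, byrow = TRUE))
  }
  if (length(samples) == 0L) stop(sprintf("empty WAV (zero-length audio): %s", path))
  if (!is.null(target_rate)) {
    samples <- resample_linear(samples, fmt$sample_rate, target_rate)
    return(waveform(samples, target_rate))
  }
  waveform(samples, fmt$sample_rate)
}

decode_pcm <- function(data_raw, bits, audio_format) {
  if (audio_format == 3L) {
    if (bits != 32L) stop("float WAV must be 32-bit")
    return(readBin(data_raw, "double", length(data_raw) %/% 4L, size = 4L,
                   endian = "little"))
  }
  switch(as.character(bits),
    "8" = {
      x <- as.integer(data_raw) # unsigned bytes
      (x - 128) / 128
    },
    "16" = {
      x <- readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2L,
                   signed = TRUE, endian = "little")
      x / 32768
    },
    "24" = {
      n <- length(data_raw) %/% 3L
      b <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
      x <- b[1L, ] + 256 * b[2L, ] + 65536 * b[3L, ]
      x <- ifelse(x >= 8388608, x - 16777216, x)
      x / 8388608
    },
    "32" = {
      x <- readBin(data_raw, "integer", length(data_raw) %/% 4L, size = 4L,
                   endian = "little")
      x / 2147483648
    },
    stop(sprintf("unsupported PCM bit depth: %d", bits))
  )
}

#' Write a waveform as 16-bit PCM mono WAV
#'
#' Samples outside `[-1, 1]` are clipped with a warning (the synthetic
#' renderer can overshoot slightly after filtering). Quantization is
#' round-to-nearest so a load/write round trip reproduces every sample within
#' one quantization step (1/32768) and is idempotent thereafter.
#'
#' @param w a [waveform()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  s <- w$samples
  if (length(s) == 0L) stop("cannot write empty waveform")
  if (any(s > 1 | s < -1)) {
    warning("samples outside [-1, 1] clipped on write")
    s <- pmin(1, pmax(-1, s))
  }
  q <- as.integer(pmin(32767, pmax(-32768, round(s * 32768))))
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")                  # PCM
  writeBin(1L, con, size = 2L, endian = "little")                  # mono
  writeBin(as.integer(w$sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(w$sample_rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")                  # block align
  writeBin(16L, con, size = 2L, endian = "little")                 # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4L, endian = "little")
  writeBin(q, con, size = 2L, endian = "little")
  invisible(path)
}
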