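# Audio rendering of tone streams and a minimal PCM WAV writer.

#' Render a token sequence to an audio waveform
#'
#' Pure sinusoids of 150 ms with 5 ms raised-cosine rise and fall, placed
#' at the sequence onsets; inter-stimulus intervals and the 20 ms blanks
#' are silent. Total duration is padded to the full timing grid (for
#' STAT/RDM, `n_cycles * 0.545 s`).
#'
#' @param seq A `token_sequence`.
#' @param sample_rate Sampling rate in Hz; must exceed twice the highest
#'   tone frequency (default 96 kHz).
#' @param reference_a Tuning reference for A, Hz.
#' @param amplitude Peak amplitude of the plateau, in [0, 1].
#' @return List of class `waveform`: `samples` (numeric vector in [-1, 1]),
#'   `sample_rate`, `duration`.
#' @export
render_audio <- function(seq, sample_rate = 96000, reference_a = 440,
                         amplitude = 0.9) {
  stopifnot(inherits(seq, "token_sequence"))
  freqs <- tone_frequencies(reference_a)
  if (sample_rate < 2 * max(freqs))
    stop_invalid("sample_rate %.0f Hz is below the Nyquist limit for the tone set",
                 sample_rate)
  g <- seq$grid
  n_tok <- length(seq$tokens)
  if (seq$stream_type %in% c("STAT", "RDM")) {
    duration <- ceiling(n_tok / 3) * g$cycle_period
  } else {
    duration <- n_tok * g$tone_onset_interval
  }
  n <- round(duration * sample_rate)
  samples <- numeric(n)
  env <- tone_envelope(g$tone_duration, g$ramp, sample_rate)
  L <- length(env)
  t_rel <- (seq_len(L) - 1L) / sample_rate
  for (i in seq_len(n_tok)) {
    i0 <- round(seq$onsets[i] * sample_rate) + 1L
    idx <- i0:(i0 + L - 1L)
    keep <- idx <= n
    tone <- amplitude * env * sin(2 * pi * freqs[[seq$tokens[i]]] * t_rel)
    samples[idx[keep]] <- samples[idx[keep]] + tone[keep]
  }
  structure(list(samples = samples, sample_rate = sample_rate,
                 duration = duration),
            class = "waveform")
}

#' Raised-cosine (Hann-flank) tone envelope
#'
#' Plateau of 1 with cosine ramps of `ramp` seconds at both ends.
#'
#' @param duration Tone duration, s.
#' @param ramp Rise/fall time, s.
#' @param sample_rate Hz.
#' @return Numeric vector of `round(duration * sample_rate)` samples.
#' @keywords internal
tone_envelope <- function(duration, ramp, sample_rate) {
  n <- round(duration * sample_rate)
  nr <- round(ramp * sample_rate)
  env <- rep(1, n)
  if (nr > 0) {
    up <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    env[seq_len(nr)] <- up
    env[n + 1L - seq_len(nr)] <- up
  }
  env
}

#' Write a waveform to a 16-bit PCM WAV file
#'
#' Minimal mono RIFF/WAVE writer. Samples are clipped to [-1, 1] and
#' scaled to the signed 16-bit range; identical input yields a
#' byte-identical file.
#'
#' @param wav A `waveform` (or list with `samples` and `sample_rate`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wav, path) {
  x <- pmin(1, pmax(-1, wav$samples))
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(wav$sample_rate)
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")       # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")   # byte rate
  writeBin(2L, con, size = 2, endian = "little")        # block align
  writeBin(16L, con, size = 2, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
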