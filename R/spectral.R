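# Epoching, phase-locked averaging, Hann-taper FFT power spectra,
# combined-gradiometer power, and neighbour-bin SNR spectra.

#' Extract a trigger-locked epoch
#'
#' The epoch starts at the trigger following `skip_tones` tones (12 by
#' default, discarding onset transients) and spans exactly `n_cycles`
#' tritone cycles (0.545 s each), so that the frequencies of interest
#' fall on exact DFT bins.
#'
#' @param rec A `meg_recording`.
#' @param n_cycles Number of tritone cycles to span.
#' @param skip_tones Tones to skip before the epoch starts (multiple of 3).
#' @return An `epoch`: list with `data` (channels x samples), `fs`,
#'   `duration`, `n_cycles`, `channels`, `array`.
#' @export
extract_epoch <- function(rec, n_cycles, skip_tones = 12) {
  stopifnot(inherits(rec, "meg_recording"))
  if (skip_tones %% 3 != 0)
    stop_invalid("skip_tones must be a multiple of 3 (triggers come every 3 tones)")
  k <- skip_tones %/% 3 + 1L
  if (k > length(rec$trigger_samples))
    stop_invalid("insufficient data: no trigger after the skipped tones")
  start <- rec$trigger_samples[k]
  cycle_samples <- 0.545 * rec$fs
  len <- round(n_cycles * cycle_samples)
  if (start + len - 1L > ncol(rec$data))
    stop_invalid(paste0("insufficient data: need %d cycles after the skip ",
                        "but only %.1f are available"),
                 n_cycles, (ncol(rec$data) - start + 1) / cycle_samples)
  structure(list(
    data = rec$data[, start:(start + len - 1L), drop = FALSE],
    fs = rec$fs, duration = len / rec$fs, n_cycles = n_cycles,
    channels = rec$channels, array = rec$array
  ), class = "epoch")
}

#' Average epochs in the time domain
#'
#' Pointwise mean of phase-locked epochs: signal components locked to the
#' triggers are conserved while non-phase-locked noise power shrinks by
#' about the number of epochs.
#'
#' @param epochs List of `epoch`s with identical shape and sampling rate.
#' @return An `epoch`.
#' @export
average_epochs <- function(epochs) {
  stopifnot(length(epochs) >= 1)
  e1 <- epochs[[1]]
  for (e in epochs[-1]) {
    if (!identical(dim(e$data), dim(e1$data)) || e$fs != e1$fs)
      stop_invalid("epochs must have identical shape and sampling rate")
  }
  if (length(epochs) == 1) return(e1)
  e1$data <- Reduce(`+`, lapply(epochs, `[[`, "data")) / length(epochs)
  e1
}

#' Hann-taper FFT power spectrum
#'
#' Per-channel power `|X|^2 / N` of the Hann-windowed DFT, cropped to the
#' analysis band. Frequency resolution is the reciprocal of the epoch
#' duration. The normalization is uncritical for the downstream SNR
#' (a ratio), and a rectangular window is available for energy checks.
#'
#' @param ep An `epoch`.
#' @param band Frequency band `c(lo, hi)` in Hz to keep (default
#'   1.5-12 Hz, covering both frequencies of interest and their first
#'   harmonics).
#' @param window `"hann"` (default) or `"none"`.
#' @return A `power_spectrum`: list with `freqs`, `power`
#'   (channels x bins), `resolution`, `channels`, `array`, `kind`
#'   (`"single"`, channel-level).
#' @export
power_spectrum <- function(ep, band = c(1.5, 12), window = c("hann", "none")) {
  stopifnot(inherits(ep, "epoch"))
  window <- match.arg(window)
  n <- ncol(ep$data)
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n) else rep(1, n)
  X <- stats::mvfft(t(ep$data * rep(w, each = nrow(ep$data))))
  pw <- (Mod(X)^2) / n
  freqs <- (seq_len(n) - 1) * ep$fs / n
  keep <- freqs >= band[1] & freqs <= band[2] & freqs <= ep$fs / 2
  structure(list(
    freqs = freqs[keep],
    power = t(pw[keep, , drop = FALSE]),
    resolution = ep$fs / n,
    channels = ep$channels, array = ep$array,
    kind = "single", window = window
  ), class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum %s> %d ch x %d bins, %.1f-%.1f Hz @ %.4g Hz\n",
              x$kind, nrow(x$power), length(x$freqs),
              min(x$freqs), max(x$freqs), x$resolution))
  invisible(x)
}

#' Combine gradiometer pairs into per-chipset power
#'
#' Sums the power of the two orthogonal planar gradiometers of each
#' chipset (orientation-invariant), dropping magnetometers: 102 combined
#' channels out.
#'
#' @param ps A channel-level `power_spectrum`.
#' @return A `power_spectrum` with `kind = "combined"` and one row per
#'   chipset.
#' @export
combine_gradiometers <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum"), ps$kind == "single")
  ch <- ps$channels[ps$channels$type %in% c("grad1", "grad2"), , drop = FALSE]
  present <- intersect(ch$channel, rownames(ps$power))
  ch <- ch[ch$channel %in% present, , drop = FALSE]
  counts <- table(ch$chipset)
  if (any(counts != 2))
    stop_invalid("unpaired gradiometer channels for chipset(s): %s",
                 paste(names(counts)[counts != 2], collapse = ", "))
  chips <- sort(unique(ch$chipset))
  comb <- matrix(0, length(chips), length(ps$freqs),
                 dimnames = list(sprintf("CH%03d", chips), NULL))
  for (j in seq_along(chips)) {
    rows <- ch$channel[ch$chipset == chips[j]]
    comb[j, ] <- colSums(ps$power[rows, , drop = FALSE])
  }
  out <- ps
  out$power <- comb
  out$kind <- "combined"
  out
}

#' Neighbour-bin SNR spectrum
#'
#' For every frequency bin, the ratio of its power to the mean power of
#' `n_neighbors` flanking bins (`n_neighbors/2` per side), skipping the
#' `n_skip` closest bins on each side to guard against spectral leakage.
#' Under a flat (no-response) spectrum the expected SNR is 1. Bins whose
#' neighbourhood is truncated by the band edge use the available bins,
#' re-balanced, and are flagged in `edge`.
#'
#' @param ps A `power_spectrum` (any kind).
#' @param n_neighbors Total neighbour count (even; 200 for 5-min epochs,
#'   40 for 1-min windows).
#' @param n_skip Closest bins skipped per side.
#' @return An `snr_spectrum`: list with `freqs`, `snr` (channels x bins),
#'   `edge` (logical per bin), `n_neighbors`, `n_skip`, plus the parent
#'   spectrum metadata.
#' @export
snr_spectrum <- function(ps, n_neighbors = 200, n_skip = 2) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (n_neighbors %% 2 != 0 || n_neighbors < 2)
    stop_invalid("n_neighbors must be a positive even count")
  half <- n_neighbors %/% 2
  nb <- length(ps$freqs)
  if (nb < n_skip + 2)
    stop_invalid("band too narrow for the requested neighbourhood")
  pw <- ps$power
  # cumulative sums along frequency for O(1) window means
  cs <- cbind(0, t(apply(pw, 1, cumsum)))
  win_sum <- function(lo, hi) {
    # inclusive bin range, clipped; returns rowSums of pw[, lo:hi]
    lo <- max(lo, 1L); hi <- min(hi, nb)
    if (lo > hi) return(list(s = numeric(nrow(pw)), k = 0L))
    list(s = cs[, hi + 1L] - cs[, lo], k = hi - lo + 1L)
  }
  snr <- matrix(NA_real_, nrow(pw), nb, dimnames = dimnames(pw))
  edge <- logical(nb)
  for (i in seq_len(nb)) {
    left <- win_sum(i - n_skip - half, i - n_skip - 1L)
    right <- win_sum(i + n_skip + 1L, i + n_skip + half)
    k <- left$k + right$k
    edge[i] <- k < n_neighbors
    if (k == 0L) { snr[, i] <- NA_real_; next }
    snr[, i] <- pw[, i] / ((left$s + right$s) / k)
  }
  structure(list(freqs = ps$freqs, snr = snr, edge = edge,
                 n_neighbors = n_neighbors, n_skip = n_skip,
                 resolution = ps$resolution, channels = ps$channels,
                 array = ps$array, kind = ps$kind),
            class = "snr_spectrum")
}

#' Locate the DFT bin of a frequency of interest
#'
#' The nearest bin to `foi`; errors when the nearest bin is further than
#' half a resolution step away (which signals an epoch length that does
#' not span an integer number of cycles) or when `foi` lies outside the
#' band.
#'
#' @param ps A `power_spectrum` or `snr_spectrum`.
#' @param foi Frequency of interest, Hz.
#' @return Integer bin index into `ps$freqs`.
#' @export
foi_bin <- function(ps, foi) {
  freqs <- ps$freqs
  if (foi < min(freqs) - ps$resolution / 2 || foi > max(freqs) + ps$resolution / 2)
    stop_invalid("frequency %.4g Hz is outside the analysis band", foi)
  i <- which.min(abs(freqs - foi))
  if (abs(freqs[i] - foi) > ps$resolution / 2 + 1e-9)
    stop_invalid("no exact bin for %.4g Hz (nearest %.4g Hz, resolution %.4g)",
                 foi, freqs[i], ps$resolution)
  i
}

#' Per-channel SNR summary at the frequencies of interest
#'
#' Reads the SNR at each FOI (and optionally their first harmonics) for
#' every channel of an SNR spectrum, as a tidy table; optionally written
#' as JSON alongside a long-format TSV of the full spectrum.
#'
#' @param sn An `snr_spectrum`.
#' @param fois Named FOIs, Hz.
#' @param harmonics Include first harmonics that fall inside the band?
#' @param path Optional JSON output path.
#' @return Data frame with columns `channel`, `foi`, `freq`, `snr`.
#' @export
foi_snr_summary <- function(sn, fois = foi_frequencies(),
                            harmonics = TRUE, path = NULL) {
  probe <- as.list(fois)
  if (harmonics) {
    for (fn in names(fois)) {
      h <- harmonic_of(fois[[fn]], 1)
      if (h <= max(sn$freqs)) probe[[paste0(fn, "_h1")]] <- h
    }
  }
  rows <- lapply(names(probe), function(fn) {
    b <- foi_bin(sn, probe[[fn]])
    data.frame(channel = rownames(sn$snr) %||% seq_len(nrow(sn$snr)),
               foi = fn, freq = sn$freqs[b], snr = sn$snr[, b])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  out
}

#' Export an SNR spectrum as long-format TSV
#'
#' Columns: `channel`, `freq`, `snr`, `edge`.
#'
#' @param sn An `snr_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snr_spectrum <- function(sn, path) {
  long <- data.frame(
    channel = rep(rownames(sn$snr) %||% seq_len(nrow(sn$snr)),
                  times = ncol(sn$snr)),
    freq = rep(sn$freqs, each = nrow(sn$snr)),
    snr = as.vector(sn$snr),
    edge = rep(sn$edge, each = nrow(sn$snr)))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Harmonics of a tagged frequency
#'
#' Uses the convention of steady-state analyses where the "first
#' harmonic" is twice the fundamental: `harmonic_of(f, k) = (k + 1) * f`,
#' and order 0 returns the fundamental.
#'
#' @param foi Fundamental frequency, Hz.
#' @param k Harmonic order (>= 0).
#' @return Frequency in Hz.
#' @examples
#' harmonic_of(1.835, 1)  # 3.67
#' @export
harmonic_of <- function(foi, k) {
  stopifnot(k >= 0)
  (k + 1) * foi
}
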