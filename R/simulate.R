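# Synthetic 306-channel MEG recordings with phase-locked tagged responses.
#
# Signal model: every tone evokes a fixed kernel (damped sinusoid), giving
# a train that is exactly periodic at the tone rate (5.505 Hz); when the
# triplet (tritone) structure is "detected", triple-initial tones carry an
# extra kernel, adding spectral lines at the tritone rate (1.835 Hz) and
# its harmonics. Background is 1/f noise (optionally boosted below 2 Hz to
# emulate the NREM sleep spectrum) plus white sensor noise. Kernel trains
# are evaluated at continuous onset times so that periodicity is exact
# regardless of the sampling rate.

#' Simulation configuration
#'
#' @param fs Sampling rate, Hz.
#' @param tone_amp Amplitude of the per-tone evoked kernel (arbitrary
#'   units; the analysis is ratio-based so units are free).
#' @param tritone_amp Amplitude of the extra kernel on triple-initial
#'   tones; 0 means no segmentation response (no 1.835 Hz line).
#' @param tone_topo,tritone_topo Per-chipset gain maps (length 102);
#'   `NULL` uses the bilateral temporal defaults of
#'   [bilateral_topography()] (tritone map left-dominant).
#' @param noise_exponent Spectral slope beta of the 1/f^beta background.
#' @param sleep_boost Multiplicative power gain applied below 2 Hz
#'   (1 = wake-like; > 1 emulates the increased low-frequency power of
#'   NREM sleep).
#' @param pink_noise_sd Standard deviation of the shaped background noise.
#' @param white_noise_sd Standard deviation of the additive white noise.
#' @param tritone_ramp Length-2 multiplier applied linearly from the start
#'   to the end of the recording to the tritone kernel amplitude
#'   (`c(1, 1)` = constant; `c(0.5, 1.5)` = response building up over the
#'   exposure).
#' @param mag_gain Gain of the magnetometer channel relative to the
#'   chipset signal.
#' @param state_label `"wake"` or `"sleep"` (metadata).
#' @param seed Seed for the noise draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(fs = 1000, tone_amp = 1, tritone_amp = 0,
                       tone_topo = NULL, tritone_topo = NULL,
                       noise_exponent = 1, sleep_boost = 1,
                       pink_noise_sd = 1, white_noise_sd = 0.3,
                       tritone_ramp = c(1, 1), mag_gain = 1,
                       state_label = "wake", seed = NULL) {
  stopifnot(fs > 24, tone_amp >= 0, tritone_amp >= 0, sleep_boost > 0,
            pink_noise_sd >= 0, white_noise_sd >= 0,
            length(tritone_ramp) == 2, all(tritone_ramp >= 0))
  structure(list(fs = fs, tone_amp = tone_amp, tritone_amp = tritone_amp,
                 tone_topo = tone_topo, tritone_topo = tritone_topo,
                 noise_exponent = noise_exponent, sleep_boost = sleep_boost,
                 pink_noise_sd = pink_noise_sd,
                 white_noise_sd = white_noise_sd,
                 tritone_ramp = tritone_ramp, mag_gain = mag_gain,
                 state_label = state_label, seed = seed),
            class = "sim_config")
}

#' Damped-sinusoid evoked kernel
#'
#' `sin(2 pi carrier t) * exp(-t / decay)` for `t >= 0`; any kernel works
#' for frequency tagging (only the train's periodicity matters), this one
#' loosely resembles an auditory evoked field.
#'
#' @param t Time from onset, s (values < 0 give 0).
#' @param carrier Carrier frequency, Hz.
#' @param decay Exponential decay constant, s.
#' @return Kernel values.
#' @export
evoked_kernel <- function(t, carrier = 10, decay = 0.08) {
  ifelse(t >= 0, sin(2 * pi * carrier * t) * exp(-t / decay), 0)
}

# Sum of kernels at continuous onset times, sampled on 1..n_samples/fs.
# amps: one amplitude per onset.
kernel_train <- function(onsets, amps, n_samples, fs,
                         carrier = 10, decay = 0.08, support = 0.4) {
  train <- numeric(n_samples)
  L <- ceiling(support * fs)
  for (i in seq_along(onsets)) {
    i0 <- floor(onsets[i] * fs) + 1L
    idx <- i0:min(i0 + L, n_samples)
    if (idx[1] > n_samples) next
    t_rel <- (idx - 1) / fs - onsets[i]
    train[idx] <- train[idx] + amps[i] * evoked_kernel(t_rel, carrier, decay)
  }
  train
}

# Continuous-time Fourier transform of the damped-sinusoid kernel
kernel_ctft <- function(f, carrier = 10, decay = 0.08) {
  a <- 1 / decay
  (1 / 2i) * (1 / (a + 2i * pi * (f - carrier)) -
                1 / (a + 2i * pi * (f + carrier)))
}

# Steady-state periodic kernel train, synthesized in the frequency domain
# as the exact Fourier series of the periodic kernel summation (Poisson:
# c_k = H(k/period)/period), truncated strictly below Nyquist. Being
# band-limited, the sampled train carries power at exact multiples of
# 1/period only -- in particular, a tone train at period 0.545/3 s has no
# energy at the tritone rate or its non-tone harmonics, however the
# sampling rate divides the cycle. The DC coefficient is dropped
# (recordings are high-pass filtered in the design this emulates).
periodic_kernel_train <- function(n_samples, fs, period,
                                  carrier = 10, decay = 0.08) {
  t <- (seq_len(n_samples) - 1) / fs
  K <- floor(period * fs / 2 - 1e-9)
  x <- numeric(n_samples)
  for (k in seq_len(K)) {
    fk <- k / period
    ck <- kernel_ctft(fk, carrier, decay) / period
    x <- x + 2 * Re(ck * exp(2i * pi * fk * t))
  }
  x
}

#' Background sensor noise: 1/f^beta plus white, shaped spectrally
#'
#' One spectral draw covers both components: the power profile is
#' `pink_sd^2 * P1f(f) + white_sd^2`, where `P1f` is the normalized
#' `f^(-beta)` profile (clamped below `f_floor`). The sleep-like
#' low-frequency boost multiplies `P1f` by a smooth logistic ramp from
#' `sleep_boost` (low frequencies) to 1 (above `boost_below` Hz); the
#' ramp is smooth because a spectral step would bias the neighbour-ratio
#' SNR of nearby bins, which no physiological spectrum would. The 1/f
#' profile is normalized before boosting, so the boost adds
#' low-frequency power without changing the noise level elsewhere
#' (as in the wake-to-NREM transition it emulates).
#'
#' @param n_samples,n_channels Output dimensions.
#' @param fs Sampling rate, Hz.
#' @param beta Spectral exponent.
#' @param sleep_boost Power gain well below `boost_below` Hz.
#' @param pink_sd,white_sd Standard deviations of the two components
#'   (without boost).
#' @param boost_below Centre of the logistic boost roll-off, Hz.
#' @param boost_width Logistic scale of the roll-off, Hz.
#' @param f_floor Low-frequency clamp of the 1/f profile, Hz.
#' @return `n_channels x n_samples` matrix.
#' @keywords internal
shaped_noise <- function(n_samples, n_channels, fs, beta = 1,
                         sleep_boost = 1, pink_sd = 1, white_sd = 0,
                         boost_below = 2, boost_width = 0.25,
                         f_floor = 0.1) {
  # even, FFT-friendly length (the Hermitian construction needs m %% 2 == 0)
  m <- 2L * stats::nextn(ceiling(max(n_samples, 4) / 2), c(2, 3, 5))
  f <- (0:(m - 1)) * fs / m
  f_eff <- pmin(f, fs - f)
  p1f <- pmax(f_eff, f_floor)^(-beta)
  p1f <- p1f / mean(p1f)
  boost_gain <- 1 + (sleep_boost - 1) /
    (1 + exp((f_eff - boost_below) / boost_width))
  amp <- sqrt(pink_sd^2 * p1f * boost_gain + white_sd^2)
  amp[1] <- 0
  # Hermitian-symmetric complex spectrum -> a single inverse FFT yields
  # real noise with unit variance before scaling
  m2 <- m %/% 2
  re <- matrix(stats::rnorm((m2 + 1) * n_channels), m2 + 1, n_channels)
  im <- matrix(stats::rnorm((m2 - 1) * n_channels), m2 - 1, n_channels)
  Z <- matrix(0 + 0i, m, n_channels)
  Z[m2 + 1, ] <- re[m2 + 1, ]
  Z[2:m2, ] <- (re[2:m2, , drop = FALSE] + 1i * im) / sqrt(2)
  Z[m:(m2 + 2), ] <- Conj(Z[2:m2, , drop = FALSE])
  x <- Re(stats::mvfft(Z * amp, inverse = TRUE)) / sqrt(m)
  t(x[seq_len(n_samples), , drop = FALSE])
}

#' Simulate a tagged multichannel recording
#'
#' @param cfg A [sim_config()].
#' @param seq A `token_sequence` of type STAT or RDM on the blanked
#'   timing grid.
#' @param array A `sensor_array` (defaults to [make_sensor_array()]).
#' @return A `meg_recording`: list with `data` (306 x samples matrix),
#'   `fs`, `trigger_samples`, `channels` (channel table), `array`,
#'   `state_label`, `n_cycles`.
#' @export
simulate_recording <- function(cfg, seq, array = make_sensor_array()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(seq, "token_sequence"))
  if (!seq$stream_type %in% c("STAT", "RDM"))
    stop_invalid("recordings are simulated for STAT/RDM streams, not %s",
                 seq$stream_type)
  fs <- cfg$fs
  n_cycles <- length(seq$trigger_onsets)
  duration <- n_cycles * seq$grid$cycle_period
  n <- round(duration * fs)
  n_chip <- nrow(array$pos)

  tone_train <- periodic_kernel_train(n, fs, seq$grid$cycle_period / 3)
  tri_onsets <- seq$trigger_onsets
  ramp <- cfg$tritone_ramp[1] +
    (cfg$tritone_ramp[2] - cfg$tritone_ramp[1]) * tri_onsets / duration
  tri_train <- if (cfg$tritone_amp > 0)
    kernel_train(tri_onsets, ramp, n, fs, carrier = 6, decay = 0.12)
  else numeric(n)

  topo_tone <- cfg$tone_topo %||% bilateral_topography(array)
  topo_tri <- cfg$tritone_topo %||%
    bilateral_topography(array, left_gain = 1, right_gain = 0.6)
  stopifnot(length(topo_tone) == n_chip, length(topo_tri) == n_chip)

  # per-channel gains: mag, then the two gradiometer orientations
  orient <- cbind(cfg$mag_gain, cos(array$grad_angle), sin(array$grad_angle))
  g_tone <- as.vector(t(orient * (cfg$tone_amp * topo_tone)))
  g_tri <- as.vector(t(orient * (cfg$tritone_amp * topo_tri)))

  data <- with_seed(cfg$seed, {
    if (cfg$pink_noise_sd > 0 || cfg$white_noise_sd > 0)
      shaped_noise(n, 3L * n_chip, fs, cfg$noise_exponent,
                   cfg$sleep_boost, pink_sd = cfg$pink_noise_sd,
                   white_sd = cfg$white_noise_sd)
    else matrix(0, 3L * n_chip, n)
  })
  data <- data + outer(g_tone, tone_train)
  if (cfg$tritone_amp > 0) data <- data + outer(g_tri, tri_train)
  rownames(data) <- array$channels$channel

  structure(list(
    data = data, fs = fs,
    trigger_samples = round(seq$trigger_onsets * fs) + 1L,
    channels = array$channels, array = array,
    state_label = cfg$state_label, n_cycles = n_cycles,
    stream_type = seq$stream_type
  ), class = "meg_recording")
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf("<meg_recording %s/%s> %d ch x %d samples @ %g Hz, %d triggers\n",
              x$stream_type, x$state_label, nrow(x$data), ncol(x$data),
              x$fs, length(x$trigger_samples)))
  invisible(x)
}

#' Simulate a cohort of tagged recordings
#'
#' Builds the per-subject simulation plan for one of the two study-like
#' scenarios:
#' \describe{
#'   \item{`sleep_null`}{no segmentation response in either stream
#'     (`tritone_amp = 0`), sleep-like background (low-frequency power
#'     boosted 4x).}
#'   \item{`wake_effect`}{segmentation response in STAT streams only
#'     (RDM never carries a 1.835 Hz component), amplitude ramping up
#'     linearly over the exposure; wake-like background.}
#' }
#' Each subject gets an independently jittered topography and independent
#' noise; each run gets a freshly generated stream. Recordings are
#' materialized on demand with [subject_recordings()] to keep memory
#' bounded.
#'
#' @param scenario `"sleep_null"` or `"wake_effect"`.
#' @param n_subjects Number of subjects (>= 1).
#' @param runs_per_stream 5-minute-equivalent runs per stream type.
#' @param seed Master seed; per-subject and per-run seeds are derived by
#'   the counter scheme of [derive_seeds()].
#' @param fs Sampling rate for the simulated cohort, Hz.
#' @param n_cycles Tritone cycles per run (564+ allows a 12-tone skip
#'   followed by a full 560-cycle epoch).
#' @param tone_amp,tritone_amp,pink_noise_sd,white_noise_sd Study-condition
#'   amplitudes; defaults reproduce the magnitudes of responses the
#'   pipeline is designed to recover (see the package vignette).
#' @param array A `sensor_array` shared by the cohort.
#' @return A `cohort` object (plan + per-subject configs).
#' @export
simulate_cohort <- function(scenario = c("sleep_null", "wake_effect"),
                            n_subjects, runs_per_stream = 2, seed = 1,
                            fs = 200, n_cycles = 566,
                            tone_amp = 1, tritone_amp = 0.6,
                            pink_noise_sd = 1, white_noise_sd = 0.3,
                            array = make_sensor_array()) {
  scenario <- match.arg(scenario)
  if (n_subjects < 1) stop_invalid("n_subjects must be >= 1")
  sleep <- scenario == "sleep_null"
  subj_seeds <- derive_seeds(seed, n_subjects)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    ss <- derive_seeds(subj_seeds[i], 1 + 4 * runs_per_stream)
    seed_at <- function(block, r) ss[1 + (block - 1) * runs_per_stream + r]
    jit <- with_seed(ss[1], c(centre = stats::rnorm(1, 0.65, 0.03),
                              gain = exp(stats::rnorm(1, 0, 0.1)),
                              right = stats::rnorm(1, 0.6, 0.05)))
    topo_tone <- bilateral_topography(array, centre = jit["centre"]) * jit["gain"]
    topo_tri <- bilateral_topography(array, centre = jit["centre"],
                                     left_gain = 1,
                                     right_gain = max(jit["right"], 0.1)) * jit["gain"]
    mk_cfg <- function(stream, run_seed) {
      amp <- if (!sleep && stream == "STAT") tritone_amp else 0
      sim_config(fs = fs, tone_amp = tone_amp, tritone_amp = amp,
                 tone_topo = topo_tone, tritone_topo = topo_tri,
                 noise_exponent = 1, sleep_boost = if (sleep) 4 else 1,
                 pink_noise_sd = pink_noise_sd,
                 white_noise_sd = white_noise_sd,
                 tritone_ramp = if (!sleep && stream == "STAT") c(0.5, 1.5)
                                else c(1, 1),
                 state_label = if (sleep) "sleep" else "wake",
                 seed = run_seed)
    }
    rr <- seq_len(runs_per_stream)
    subjects[[i]] <- list(
      id = i,
      stat = list(seq_seeds = seed_at(1, rr),
                  cfgs = lapply(seed_at(2, rr),
                                function(s) mk_cfg("STAT", s))),
      rdm = list(seq_seeds = seed_at(3, rr),
                 cfgs = lapply(seed_at(4, rr),
                               function(s) mk_cfg("RDM", s)))
    )
  }
  structure(list(scenario = scenario, n_subjects = n_subjects,
                 runs_per_stream = runs_per_stream, fs = fs,
                 n_cycles = n_cycles, array = array, subjects = subjects,
                 seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort %s> %d subjects x %d runs/stream, %d cycles @ %g Hz\n",
              x$scenario, x$n_subjects, x$runs_per_stream, x$n_cycles, x$fs))
  invisible(x)
}

#' Materialize the recordings of one cohort subject
#'
#' @param cohort A [simulate_cohort()] plan.
#' @param i Subject index.
#' @param stream `"STAT"` or `"RDM"`.
#' @return List of `meg_recording`s, one per run.
#' @export
subject_recordings <- function(cohort, i, stream = c("STAT", "RDM")) {
  stream <- match.arg(stream)
  s <- cohort$subjects[[i]]
  n_tones <- cohort$n_cycles * 3L
  lapply(seq_len(cohort$runs_per_stream), function(r) {
    if (stream == "STAT") {
      sq <- generate_stat_sequence(cohort$n_cycles, seed = s$stat$seq_seeds[r])
      simulate_recording(s$stat$cfgs[[r]], sq, cohort$array)
    } else {
      sq <- generate_rdm_sequence(n_tones, seed = s$rdm$seq_seeds[r])
      simulate_recording(s$rdm$cfgs[[r]], sq, cohort$array)
    }
  })
}

#' Save / load a recording as flat binary + JSON sidecar
#'
#' The container is a raw little-endian float64 array (channels x samples,
#' column-major) next to a JSON sidecar holding the sampling rate, channel
#' table, trigger samples and state label.
#'
#' @param rec A `meg_recording`.
#' @param stem Path stem; writes `<stem>.bin` and `<stem>.json`.
#' @return `stem`, invisibly.
#' @export
save_recording <- function(rec, stem) {
  con <- file(paste0(stem, ".bin"), "wb")
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  close(con)
  side <- list(fs = rec$fs, n_channels = nrow(rec$data),
               n_samples = ncol(rec$data),
               trigger_samples = rec$trigger_samples,
               channels = rec$channels, state_label = rec$state_label,
               stream_type = rec$stream_type, n_cycles = rec$n_cycles)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname save_recording
#' @param array Sensor array to attach on load.
#' @export
load_recording <- function(stem, array = make_sensor_array()) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  con <- file(paste0(stem, ".bin"), "rb")
  x <- readBin(con, "double", side$n_channels * side$n_samples,
               size = 8, endian = "little")
  close(con)
  data <- matrix(x, side$n_channels, side$n_samples)
  rownames(data) <- side$channels$channel
  structure(list(data = data, fs = side$fs,
                 trigger_samples = side$trigger_samples,
                 channels = side$channels, array = array,
                 state_label = side$state_label, n_cycles = side$n_cycles,
                 stream_type = side$stream_type),
            class = "meg_recording")
}
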