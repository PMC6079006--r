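fois <- foi_frequencies()

# short noiseless recording reused across spectral tests
spec_rec <- simulate_recording(
  sim_config(fs = 200, tone_amp = 1, tritone_amp = 0.3,
             pink_noise_sd = 0, white_noise_sd = 0, seed = 1),
  generate_stat_sequence(120, seed = 55), test_array())

test_that("epoch geometry: durations, resolutions, and the insufficient-data error", {
  ep112 <- extract_epoch(spec_rec, 112)
  expect_equal(ep112$duration, 61.04)
  expect_equal(ep112$n_cycles, 112)
  ps112 <- power_spectrum(ep112)
  expect_equal(round(ps112$resolution, 4), 0.0164)
  # the canonical 5-minute epoch: 560 cycles = 305.20 s at 0.0033 Hz
  expect_equal(round(560 * 0.545, 2), 305.20)
  expect_equal(round(1 / (560 * 0.545), 4), 0.0033)
  expect_error(extract_epoch(spec_rec, 560), "insufficient")
  expect_error(extract_epoch(spec_rec, 112, skip_tones = 7), "multiple of 3")
  # epoch starts at the trigger after the skipped tones
  expect_equal(ep112$data[1, 1],
               spec_rec$data[1, spec_rec$trigger_samples[5]])
})

test_that("FOIs fall on exact bins of integer-cycle epochs", {
  ps <- power_spectrum(extract_epoch(spec_rec, 112))
  bt <- foi_bin(ps, 1.835)   # rounded FOI still lands on the exact bin
  bn <- foi_bin(ps, 5.505)
  expect_equal(ps$freqs[bt], 112 / 61.04, tolerance = 1e-9)
  # tone bin sits at three times the tritone frequency offset
  expect_equal(ps$freqs[bn], 3 * ps$freqs[bt], tolerance = 1e-9)
  expect_error(foi_bin(ps, 20), "outside")
  # a frequency within half a bin of the FOI resolves to the same bin
  expect_equal(foi_bin(ps, 1.835 + ps$resolution / 3), bt)
})

test_that("a pure sinusoid peaks at its own bin", {
  ep <- extract_epoch(spec_rec, 112)
  t <- (seq_len(ncol(ep$data)) - 1) / ep$fs
  ep$data <- matrix(sin(2 * pi * fois["tone"] * t), 1)
  ps <- power_spectrum(ep)
  expect_equal(which.max(ps$power[1, ]), foi_bin(ps, fois["tone"]))
})

test_that("power spectrum satisfies Parseval within the band (rectangular window)", {
  ep <- extract_epoch(spec_rec, 112)
  n <- ncol(ep$data)
  t <- (seq_len(n) - 1) / ep$fs
  # band-limited input: sum of sinusoids inside 1.5-12 Hz
  x <- 0.7 * sin(2 * pi * 2.2 * t) + 0.4 * cos(2 * pi * 7.5 * t)
  ep$data <- matrix(x, 1)
  ps <- power_spectrum(ep, band = c(0, 100), window = "none")
  # the kept half-spectrum carries half the energy of a real signal
  # (DC and Nyquist are negligible for this band-limited input)
  expect_equal(2 * sum(ps$power[1, ]), sum(x^2), tolerance = 1e-5)
})

test_that("combined gradiometers sum pair power and drop magnetometers", {
  ps <- power_spectrum(extract_epoch(spec_rec, 112))
  comb <- combine_gradiometers(ps)
  expect_equal(nrow(comb$power), 102)
  g1 <- ps$power[ps$channels$type == "grad1", , drop = FALSE]
  g2 <- ps$power[ps$channels$type == "grad2", , drop = FALSE]
  expect_equal(comb$power, g1 + g2, ignore_attr = TRUE)
  expect_true(all(comb$power >= g1) && all(comb$power >= g2))
  # signal entirely on one gradiometer: combined equals that one
  ps1 <- ps
  ps1$power[ps1$channels$type == "grad2", ] <- 0
  comb1 <- combine_gradiometers(ps1)
  expect_equal(comb1$power,
               ps1$power[ps1$channels$type == "grad1", , drop = FALSE],
               ignore_attr = TRUE)
  # unpaired channels are refused
  bad <- ps
  bad$power <- ps$power[-2, ]   # drops one gradiometer row
  expect_error(combine_gradiometers(bad), "unpaired")
})

test_that("SNR is 1 on flat spectra and equals the hand ratio for one line", {
  flat <- toy_power_spectrum(rep(3.7, 64), freqs = seq(2, 8, length.out = 64))
  sn <- snr_spectrum(flat, n_neighbors = 20, n_skip = 2)
  expect_equal(unname(sn$snr[1, !sn$edge]),
               rep(1, sum(!sn$edge)))
  # one line of power 100 on a flat background of 1: SNR = 100 at the line
  p <- rep(1, 101); p[51] <- 100
  line <- toy_power_spectrum(p, freqs = seq(1, 2, length.out = 101))
  sn2 <- snr_spectrum(line, n_neighbors = 40, n_skip = 2)
  expect_equal(sn2$snr[1, 51], 100)
  # neighbours skip the 2 closest bins: moving the line into the skip zone
  # of a probe bin leaves that probe's SNR untouched
  p3 <- rep(1, 101); p3[53] <- 100
  sn3 <- snr_spectrum(toy_power_spectrum(p3, seq(1, 2, length.out = 101)),
                      n_neighbors = 40, n_skip = 2)
  expect_equal(sn3$snr[1, 51], 1)
  expect_error(snr_spectrum(flat, n_neighbors = 21), "even")
})

test_that("SNR implementation matches the brute-force loop oracle bin for bin", {
  set.seed(404)
  for (case in 1:5) {
    nb <- sample(24:64, 1)
    nch <- sample(1:4, 1)
    pw <- matrix(rexp(nb * nch) + 0.05, nch, nb)
    ps <- toy_power_spectrum(pw, freqs = seq(1.5, 12, length.out = nb))
    nn <- sample(c(4, 8, 10), 1)
    sn <- snr_spectrum(ps, n_neighbors = nn, n_skip = 2)
    expect_equal(unname(sn$snr), snr_oracle(pw, nn, 2), tolerance = 1e-12)
  }
})

test_that("mean SNR at the tritone bin of noise-only epochs is about 1", {
  vals <- vapply(1:6, function(s) {
    rec <- simulate_recording(
      sim_config(fs = 200, tone_amp = 1, tritone_amp = 0,
                 pink_noise_sd = 1, white_noise_sd = 0.3, seed = s),
      generate_stat_sequence(120, seed = 200 + s), test_array())
    sn <- snr_spectrum(combine_gradiometers(power_spectrum(
      extract_epoch(rec, 112))), n_neighbors = 40)
    mean(sn$snr[, foi_bin(sn, fois["tritone"])])
  }, 0)
  expect_equal(mean(vals), 1, tolerance = 0.1)
})

test_that("harmonics follow the steady-state convention", {
  expect_equal(harmonic_of(1.835, 1), 3.67)
  expect_equal(harmonic_of(5.505, 1), 11.01)
  expect_lt(harmonic_of(5.505, 1), 12)  # inside the analysis band
  expect_equal(harmonic_of(2.5, 0), 2.5)
})

test_that("FOI summary and long-format export reflect the SNR matrix", {
  p <- matrix(1, 2, 101); p[, 51] <- 9
  sn <- snr_spectrum(toy_power_spectrum(p, seq(1.5, 2.5, length.out = 101)),
                     n_neighbors = 20, n_skip = 2)
  fois <- c(line = 2.0)
  summ <- foi_snr_summary(sn, fois, harmonics = FALSE)
  expect_equal(nrow(summ), 2)
  expect_equal(summ$snr, c(9, 9))
  expect_equal(summ$freq, c(2, 2))
  # harmonic rows appear only when inside the band
  summ2 <- foi_snr_summary(sn, c(low = 1.6), harmonics = TRUE)
  expect_false(any(summ2$foi == "low_h1"))  # 3.2 Hz > band max -> skipped
  expect_false(any(summ2$freq > max(sn$freqs)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_snr_spectrum(sn, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 2 * 101)
  expect_equal(back$snr[back$freq == 2], c(9, 9))
})
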