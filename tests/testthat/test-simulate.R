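# Simulator tests run at a reduced scale (short streams, fs = 200 Hz);
# the tagged rates are far below Nyquist at any of these rates and the
# SNR analysis is sampling-rate-free.

sim_seq <- generate_stat_sequence(120, seed = 101)

test_that("recordings carry the trigger grid and finite data", {
  cfg <- sim_config(fs = 200, pink_noise_sd = 0.5, white_noise_sd = 0.2,
                    seed = 1)
  rec <- simulate_recording(cfg, sim_seq, test_array())
  expect_equal(nrow(rec$data), 306)
  expect_equal(ncol(rec$data), round(120 * 0.545 * 200))
  expect_true(all(is.finite(rec$data)))
  spacing <- diff(rec$trigger_samples)
  expect_true(all(abs(spacing - 0.545 * 200) <= 1))
  expect_error(simulate_recording(cfg, generate_hab_sequence(5, seed = 1)),
               "STAT/RDM")
})

test_that("a pure tone response has spectral lines only at tone harmonics", {
  cfg <- sim_config(fs = 200, tone_amp = 1, tritone_amp = 0,
                    pink_noise_sd = 0, white_noise_sd = 0, seed = 1)
  rec <- simulate_recording(cfg, sim_seq, test_array())
  ps <- combine_gradiometers(power_spectrum(extract_epoch(rec, 112)))
  fois <- foi_frequencies()
  ch <- which.max(rowMeans(ps$power))
  p_tone <- ps$power[ch, foi_bin(ps, fois["tone"])]
  p_tri <- ps$power[ch, foi_bin(ps, fois["tritone"])]
  p_tri2 <- ps$power[ch, foi_bin(ps, 2 * fois["tritone"])]
  expect_gt(p_tone, 1e-6)
  expect_lt(p_tri / p_tone, 1e-12)
  expect_lt(p_tri2 / p_tone, 1e-12)
})

test_that("a tritone response adds lines at 1.835 Hz and its first harmonic", {
  cfg <- sim_config(fs = 200, tone_amp = 1, tritone_amp = 0.5,
                    pink_noise_sd = 0, white_noise_sd = 0, seed = 1)
  rec <- simulate_recording(cfg, sim_seq, test_array())
  ps <- combine_gradiometers(power_spectrum(extract_epoch(rec, 112)))
  fois <- foi_frequencies()
  ch <- which.max(rowMeans(ps$power))
  expect_gt(ps$power[ch, foi_bin(ps, fois["tritone"])], 1e-4)
  expect_gt(ps$power[ch, foi_bin(ps, harmonic_of(fois["tritone"], 1))], 1e-4)
  # off-bin background stays at numerical zero
  expect_lt(ps$power[ch, foi_bin(ps, fois["tritone"]) + 3] /
              ps$power[ch, foi_bin(ps, fois["tritone"])], 1e-6)
})

test_that("white-only noise gives a flat expected spectrum and SNR near 1", {
  cfg <- sim_config(fs = 200, tone_amp = 0, tritone_amp = 0,
                    pink_noise_sd = 0, white_noise_sd = 1, seed = 3)
  rec <- simulate_recording(cfg, sim_seq, test_array())
  ps <- combine_gradiometers(power_spectrum(extract_epoch(rec, 112)))
  sn <- snr_spectrum(ps, n_neighbors = 40)
  interior <- !sn$edge
  expect_equal(mean(sn$snr[, interior]), 1, tolerance = 0.05)
  # flatness: band-third mean powers agree within a factor
  thirds <- cut(seq_along(ps$freqs), 3)
  m <- tapply(colMeans(ps$power), thirds, mean)
  expect_lt(max(m) / min(m), 1.3)
})

test_that("phase-locked averaging conserves tagged power, shrinks noise ~ k-fold", {
  k <- 4
  mk <- function(s) simulate_recording(
    sim_config(fs = 200, tone_amp = 2, pink_noise_sd = 1,
               white_noise_sd = 0.3, seed = s), sim_seq, test_array())
  eps <- lapply(1:k, function(s) extract_epoch(mk(s), 112))
  avg <- average_epochs(eps)
  ps1 <- combine_gradiometers(power_spectrum(eps[[1]]))
  psk <- combine_gradiometers(power_spectrum(avg))
  fois <- foi_frequencies()
  bt <- foi_bin(ps1, fois["tone"])
  # tagged line conserved (measured where the response lives, so the
  # residual noise share of the bin is negligible)
  tc <- temporal_chipsets(test_array())$all
  expect_equal(mean(psk$power[tc, bt]) / mean(ps1$power[tc, bt]), 1,
               tolerance = 0.1)
  # noise bins shrink by about k
  null_bins <- setdiff(seq_along(ps1$freqs), bt + (-3:3))
  ratio <- mean(ps1$power[, null_bins]) / mean(psk$power[, null_bins])
  expect_equal(ratio, k, tolerance = 0.25 * k)
  # identity and single-epoch cases
  expect_identical(average_epochs(list(eps[[1]])), eps[[1]])
  same <- average_epochs(list(eps[[1]], eps[[1]]))
  expect_equal(same$data, eps[[1]]$data)
  bad <- eps[[2]]; bad$data <- bad$data[, -1]
  expect_error(average_epochs(list(eps[[1]], bad)), "identical shape")
})

test_that("tritone SNR grows monotonically with tritone amplitude", {
  fois <- foi_frequencies()
  snr_at <- function(amp) {
    cfg <- sim_config(fs = 200, tone_amp = 1, tritone_amp = amp,
                      pink_noise_sd = 0.8, white_noise_sd = 0.3, seed = 7)
    rec <- simulate_recording(cfg, sim_seq, test_array())
    sn <- snr_spectrum(combine_gradiometers(power_spectrum(
      extract_epoch(rec, 112))), n_neighbors = 40)
    tc <- temporal_chipsets(test_array())$all
    mean(sn$snr[tc, foi_bin(sn, fois["tritone"])])
  }
  vals <- vapply(c(0, 0.4, 0.8, 1.6), snr_at, 0)
  expect_equal(cor(vals, 1:4, method = "spearman"), 1)
})

test_that("cohort plans honour the scenario amplitude rules", {
  co_wake <- simulate_cohort("wake_effect", n_subjects = 3, seed = 5)
  co_sleep <- simulate_cohort("sleep_null", n_subjects = 3, seed = 5)
  for (i in 1:3) {
    expect_gt(co_wake$subjects[[i]]$stat$cfgs[[1]]$tritone_amp, 0)
    expect_equal(co_wake$subjects[[i]]$rdm$cfgs[[1]]$tritone_amp, 0)
    expect_equal(co_sleep$subjects[[i]]$stat$cfgs[[1]]$tritone_amp, 0)
    expect_equal(co_sleep$subjects[[i]]$rdm$cfgs[[1]]$tritone_amp, 0)
    expect_equal(co_sleep$subjects[[i]]$stat$cfgs[[1]]$sleep_boost, 4)
    expect_equal(co_wake$subjects[[i]]$stat$cfgs[[1]]$sleep_boost, 1)
  }
  # per-subject seeds differ, so do recordings
  s1 <- co_wake$subjects[[1]]$stat$cfgs[[1]]$seed
  s2 <- co_wake$subjects[[2]]$stat$cfgs[[1]]$seed
  expect_false(identical(s1, s2))
  expect_error(simulate_cohort("wake_effect", n_subjects = 0), "n_subjects")
})

test_that("recordings round-trip through the binary + JSON container", {
  cfg <- sim_config(fs = 200, pink_noise_sd = 0.5, white_noise_sd = 0.1,
                    seed = 2)
  rec <- simulate_recording(cfg, generate_stat_sequence(20, seed = 8),
                            test_array())
  stem <- withr::local_tempfile()
  save_recording(rec, stem)
  back <- load_recording(stem, test_array())
  expect_equal(back$data, rec$data, ignore_attr = TRUE)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$trigger_samples, rec$trigger_samples)
  expect_equal(back$stream_type, rec$stream_type)
})
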