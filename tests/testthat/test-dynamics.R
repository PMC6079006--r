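test_that("minute windows span 61.04 s and give four minute-pair rows", {
  rec <- simulate_recording(
    sim_config(fs = 200, tone_amp = 1, tritone_amp = 0,
               pink_noise_sd = 0.8, white_noise_sd = 0.3, seed = 2),
    generate_stat_sequence(566, seed = 17), test_array())
  tc <- temporal_chipsets(test_array())$all
  mw <- minute_windows(rec, tc, foi_frequencies()["tone"])
  expect_equal(nrow(mw), 4)
  expect_equal(mw$window, c("1-2", "2-3", "3-4", "4-5"))
  expect_true(all(mw$snr > 5))   # strong tone response in each window
  # each 1-minute window spans 112 cycles = 61.04 s
  ep <- extract_epoch(rec, 112)
  expect_equal(ep$duration, 61.04)
  # a recording too short for five windows errors out
  short <- simulate_recording(
    sim_config(fs = 200, pink_noise_sd = 0.3, seed = 1),
    generate_stat_sequence(120, seed = 1), test_array())
  expect_error(minute_windows(short, tc, 5.505), "insufficient")
})

test_that("a constant (tiled) response gives identical window values", {
  # tile one 112-cycle segment (signal + frozen noise) five times: every
  # minute window then sees the same samples, so SNR must not vary
  seg_rec <- simulate_recording(
    sim_config(fs = 200, tone_amp = 1, tritone_amp = 0.4,
               pink_noise_sd = 0.5, white_noise_sd = 0.2, seed = 3),
    generate_stat_sequence(116, seed = 19), test_array())
  seg <- seg_rec$data[, seg_rec$trigger_samples[5] +
                        seq_len(112 * 109) - 1L]
  lead <- seg_rec$data[, seq_len(4 * 109)]
  data <- cbind(lead, seg, seg, seg, seg, seg)
  rec <- seg_rec
  rec$data <- data
  rec$trigger_samples <- seq(1L, ncol(data) - 108L, by = 109L)
  rec$n_cycles <- length(rec$trigger_samples)
  tc <- temporal_chipsets(test_array())$all
  mw <- minute_windows(rec, tc, foi_frequencies()["tritone"])
  expect_equal(diff(range(mw$snr)) / mean(mw$snr), 0, tolerance = 1e-9)
})

test_that("candidate random structures are the four stated combinations", {
  rs <- candidate_random_structures()
  expect_length(rs, 4)
  expect_true(all(grepl("1", rs, fixed = TRUE)))   # intercept everywhere
  expect_false(any(duplicated(names(rs))))
  expect_true(any(grepl("minutes", rs)) && any(grepl("stream", rs)))
})

test_that("candidate fixed models cover the design space without mixing encodings", {
  sleep <- candidate_fixed_models("sleep")
  expect_true("1" %in% sleep)                       # intercept-only
  expect_true("stream" %in% sleep)                  # SNR ~ STREAM
  expect_true("minutes" %in% sleep)                 # SNR ~ MINUTES (continuous)
  expect_equal(length(sleep), 11)
  # no formula contains two MINUTES encodings at once
  enc_count <- grepl("factor\\(minutes\\)", sleep) +
    grepl("poly\\(minutes, 2\\)", sleep) +
    grepl("(^| )minutes( |$|:)", sleep)
  expect_true(all(enc_count <= 1))
  wake <- candidate_fixed_models("wake")
  expect_gt(length(wake), length(sleep))
  expect_true(any(grepl("group", wake)))
  # hierarchy: any formula with an interaction also has both mains
  with_ix <- wake[grepl(":", wake)]
  for (f in with_ix) {
    vars <- all.vars(stats::as.formula(paste("~", f)))
    for (v in setdiff(vars, "2")) {
      mains <- strsplit(f, " \\+ ")[[1]]
      expect_true(any(grepl(v, mains[!grepl(":", mains)], fixed = TRUE)))
    }
  }
  expect_false(any(duplicated(sleep)))
  expect_false(any(duplicated(wake)))
})

test_that("AICc equals AIC plus the small-sample correction", {
  ll <- structure(-10, df = 3, nobs = 20, class = "logLik")
  expect_equal(aicc(ll), (-2 * -10 + 2 * 3) + 24 / 16)
  # blows up to Inf when n <= k + 1
  ll2 <- structure(-10, df = 10, nobs = 11, class = "logLik")
  expect_equal(aicc(ll2), Inf)
})

# table-level generator for selection tests: 4 minute-pairs x 2 streams
sim_dynamics_table <- function(n_subjects, slope = 0, subj_sd = 0.2,
                               resid_sd = 0.1, intercept = 1, seed = 1) {
  set.seed(seed)
  g <- expand.grid(subject = factor(seq_len(n_subjects)), minutes = 1:4,
                   stream = factor(c("RDM", "STAT"), levels = c("RDM", "STAT")))
  b0 <- rnorm(n_subjects, 0, subj_sd)
  g$snr <- intercept + slope * g$minutes + b0[as.integer(g$subject)] +
    rnorm(nrow(g), 0, resid_sd)
  g
}

test_that("selection recovers a pure linear MINUTES effect with accurate slope", {
  slopes <- rep(NA_real_, 100)
  has_minutes <- logical(100)
  for (r in 1:100) {
    tab <- sim_dynamics_table(11, slope = 0.15, seed = 7000 + r)
    sel <- suppressWarnings(select_lmm(tab, "sleep"))
    has_minutes[r] <- grepl("minutes", sel$selected_fixed)
    co <- sel$coefficients
    if ("minutes" %in% co$term) slopes[r] <- co$estimate[co$term == "minutes"]
  }
  expect_gt(mean(has_minutes), 0.8)
  expect_lt(abs(mean(slopes, na.rm = TRUE) - 0.15), 0.05)
  # individual estimates are also close on average
  expect_lt(mean(abs(slopes - 0.15), na.rm = TRUE), 0.05)
})

test_that("null data selects the intercept-only fixed model most often", {
  # with 10 competitors each gaining ~ a chi-square(1) of log-likelihood,
  # AICc retains the true (intercept-only) model as the modal choice at a
  # rate a little under 2/3 -- the computed behaviour of the procedure
  picks <- vapply(1:100, function(r) {
    tab <- sim_dynamics_table(11, slope = 0, seed = 8000 + r)
    suppressWarnings(select_lmm(tab, "sleep"))$selected_fixed
  }, "")
  expect_gte(mean(picks == "intercept_only"), 0.5)
  expect_equal(names(which.max(table(picks))), "intercept_only")
})

test_that("selection is invariant to row order and subject relabeling", {
  tab <- sim_dynamics_table(9, slope = 0.12, seed = 99)
  sel1 <- suppressWarnings(select_lmm(tab, "sleep"))
  perm <- sample(nrow(tab))
  sel2 <- suppressWarnings(select_lmm(tab[perm, ], "sleep"))
  expect_equal(sel1$selected_fixed, sel2$selected_fixed)
  expect_equal(sel1$selected_random, sel2$selected_random)
  expect_equal(sel1$fixed_aicc, sel2$fixed_aicc, tolerance = 1e-6)
  # relabel subjects
  tab3 <- tab
  tab3$subject <- factor(paste0("S", as.integer(tab3$subject)))
  sel3 <- suppressWarnings(select_lmm(tab3, "sleep"))
  expect_equal(sel1$selected_fixed, sel3$selected_fixed)
})

test_that("wake-session selection uses GROUP and reports Satterthwaite p-values", {
  tab <- sim_dynamics_table(10, slope = 0.1, seed = 123)
  tab$group <- factor(rep(c("exposure", "no_exposure"),
                          length.out = nrow(tab))[order(tab$subject)])
  # consistent group per subject
  tab$group <- factor(ifelse(as.integer(tab$subject) <= 5,
                             "exposure", "no_exposure"))
  sel <- suppressWarnings(select_lmm(tab, "wake"))
  expect_true(all(c("estimate", "se", "df", "p") %in% names(sel$coefficients)))
  expect_true(all(sel$coefficients$p >= 0 & sel$coefficients$p <= 1))
  expect_error(select_lmm(tab[, setdiff(names(tab), "group")], "wake"),
               "group")
})
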