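# End-to-end orchestration: simulate cohorts -> spectral analysis ->
# cluster statistics -> temporal dynamics -> behaviour -> report bundle.

#' Full spectral analysis of a simulated cohort
#'
#' One pass over the cohort: for every subject and stream the runs are
#' materialized once, and both analysis stages are computed from them:
#' \enumerate{
#'   \item the whole-exposure topographies -- runs averaged in the time
#'     domain (phase-locked averaging), Hann-taper power spectrum,
#'     combined gradiometers, neighbour-bin SNR, read at each FOI;
#'   \item (optionally) the minute-wise topographies -- the first run
#'     cropped into five 1-minute windows, power averaged over the four
#'     overlapping minute pairs, SNR with the minute-wise neighbour
#'     count, read at each FOI per chipset.
#' }
#' Recordings are discarded after each subject, keeping memory flat.
#'
#' @param cohort A [simulate_cohort()] plan.
#' @param epoch_cycles Tritone cycles per analysis epoch (560 = the
#'   canonical 5-minute epoch).
#' @param skip_tones Tones skipped before the epoch.
#' @param n_neighbors Neighbour bins for the whole-exposure SNR.
#' @param n_neighbors_minute Neighbour bins for minute-pair SNR.
#' @param cycles_per_window Cycles per 1-minute window.
#' @param fois Named frequencies of interest, Hz.
#' @param minute_pairs Compute the minute-pair stage?
#' @return A `cohort_analysis` list: `topo[[stream]][[foi]]` =
#'   subjects x chipsets SNR matrices; `minute[[stream]][[foi]]` =
#'   subjects x 4 pairs x chipsets arrays (when `minute_pairs`);
#'   `example_snr[[stream]]` = the SNR spectrum of subject 1; `fois`.
#' @export
analyze_cohort <- function(cohort, epoch_cycles = 560, skip_tones = 12,
                           n_neighbors = 200, n_neighbors_minute = 40,
                           cycles_per_window = 112,
                           fois = foi_frequencies(), minute_pairs = TRUE) {
  n_chip <- nrow(cohort$array$pos)
  topo <- list(); minute <- list(); example_snr <- list()
  pair_list <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 5))
  for (stream in c("STAT", "RDM")) {
    topo[[stream]] <- lapply(fois, function(f)
      matrix(NA_real_, cohort$n_subjects, n_chip))
    if (minute_pairs)
      minute[[stream]] <- lapply(fois, function(f)
        array(NA_real_, c(cohort$n_subjects, 4, n_chip)))
    for (i in seq_len(cohort$n_subjects)) {
      recs <- subject_recordings(cohort, i, stream)
      eps <- lapply(recs, extract_epoch, n_cycles = epoch_cycles,
                    skip_tones = skip_tones)
      avg <- average_epochs(eps)
      rm(eps)
      sn <- snr_spectrum(combine_gradiometers(power_spectrum(avg)),
                         n_neighbors = n_neighbors)
      rm(avg)
      for (fn in names(fois))
        topo[[stream]][[fn]][i, ] <- sn$snr[, foi_bin(sn, fois[[fn]])]
      if (i == 1L) example_snr[[stream]] <- sn
      if (minute_pairs) {
        wins <- lapply(1:5, function(w) {
          ep <- extract_epoch(recs[[1]], cycles_per_window,
                              skip_tones = skip_tones +
                                3L * cycles_per_window * (w - 1L))
          combine_gradiometers(power_spectrum(ep))
        })
        for (p in seq_along(pair_list)) {
          pr <- pair_list[[p]]
          avgw <- wins[[pr[1]]]
          avgw$power <- (wins[[pr[1]]]$power + wins[[pr[2]]]$power) / 2
          snw <- snr_spectrum(avgw, n_neighbors = n_neighbors_minute)
          for (fn in names(fois))
            minute[[stream]][[fn]][i, p, ] <- snw$snr[, foi_bin(snw, fois[[fn]])]
        }
        rm(wins)
      }
      rm(recs)
    }
  }
  structure(list(topo = topo, minute = minute, example_snr = example_snr,
                 fois = fois, scenario = cohort$scenario,
                 n_subjects = cohort$n_subjects),
            class = "cohort_analysis")
}

#' Group-level SNR topographies of a cohort
#'
#' Whole-exposure stage of [analyze_cohort()] only.
#'
#' @inheritParams analyze_cohort
#' @return A `cohort_analysis` without the minute-pair stage.
#' @export
cohort_topographies <- function(cohort, epoch_cycles = 560, skip_tones = 12,
                                n_neighbors = 200,
                                fois = foi_frequencies()) {
  analyze_cohort(cohort, epoch_cycles = epoch_cycles,
                 skip_tones = skip_tones, n_neighbors = n_neighbors,
                 fois = fois, minute_pairs = FALSE)
}

#' Minute-pair SNR topography of one recording
#'
#' Per-chipset SNR at a FOI for one pair of 1-minute windows (power
#' averaged over the two windows), used by the SOI threshold rules
#' ("tone SNR during minutes 1-2 of RDM streams").
#'
#' @param rec A `meg_recording`.
#' @param foi Frequency of interest, Hz.
#' @param pair Two consecutive window indices (1..5).
#' @param n_neighbors Neighbour bins (40 for minute windows).
#' @param cycles_per_window,skip_tones Window geometry.
#' @return Numeric vector of SNR per chipset.
#' @export
minute_pair_topography <- function(rec, foi, pair = c(1, 2),
                                   n_neighbors = 40,
                                   cycles_per_window = 112,
                                   skip_tones = 12) {
  specs <- lapply(pair, function(w) {
    ep <- extract_epoch(rec, cycles_per_window,
                        skip_tones = skip_tones +
                          3L * cycles_per_window * (w - 1L))
    combine_gradiometers(power_spectrum(ep))
  })
  avg <- specs[[1]]
  avg$power <- (specs[[1]]$power + specs[[2]]$power) / 2
  sn <- snr_spectrum(avg, n_neighbors = n_neighbors)
  sn$snr[, foi_bin(sn, foi)]
}

#' Build a validated run configuration
#'
#' All analysis thresholds of the emulated design are configuration
#' defaults, not constants: permutation count, cluster alphas, SOI
#' thresholds, neighbour counts, tone skip.
#'
#' @param scenario `"sleep_null"`, `"wake_effect"`, or `"custom"`.
#' @param n_subjects,runs_per_stream,n_cycles,fs Cohort geometry.
#' @param tone_amp,tritone_amp,pink_noise_sd,white_noise_sd Simulation
#'   amplitudes (see [simulate_cohort()]).
#' @param epoch_cycles,skip_tones,n_neighbors,n_neighbors_minute Spectral
#'   knobs.
#' @param n_perm,cluster_alpha,soi_alpha Statistical knobs.
#' @param soi_tone_threshold SNR threshold of the tone SOI rule (5 at
#'   wake, 2 in sleep).
#' @param soi_tritone_threshold SNR threshold of the tritone shortcut rule.
#' @param seed Master seed.
#' @param out_dir Output directory of the artifact tree.
#' @return A validated `run_config` list.
#' @export
run_config <- function(scenario = c("sleep_null", "wake_effect", "custom"),
                       n_subjects = 10, runs_per_stream = 2,
                       n_cycles = 566, fs = 200,
                       tone_amp = 1, tritone_amp = 0.6,
                       pink_noise_sd = 1, white_noise_sd = 0.3,
                       epoch_cycles = 560, skip_tones = 12,
                       n_neighbors = 200, n_neighbors_minute = 40,
                       n_perm = 10000, cluster_alpha = 0.05,
                       soi_alpha = 0.05,
                       soi_tone_threshold = NULL,
                       soi_tritone_threshold = 1.25,
                       seed = 1, out_dir = "freqtag_run") {
  scenario <- match.arg(scenario)
  sleep <- scenario == "sleep_null"
  soi_tone_threshold <- soi_tone_threshold %||% (if (sleep) 2 else 5)
  cfg <- list(scenario = scenario, n_subjects = n_subjects,
              runs_per_stream = runs_per_stream, n_cycles = n_cycles,
              fs = fs, tone_amp = tone_amp, tritone_amp = tritone_amp,
              pink_noise_sd = pink_noise_sd,
              white_noise_sd = white_noise_sd,
              epoch_cycles = epoch_cycles, skip_tones = skip_tones,
              n_neighbors = n_neighbors,
              n_neighbors_minute = n_neighbors_minute,
              n_perm = n_perm, cluster_alpha = cluster_alpha,
              soi_alpha = soi_alpha,
              soi_tone_threshold = soi_tone_threshold,
              soi_tritone_threshold = soi_tritone_threshold,
              seed = seed, out_dir = out_dir)
  stopifnot(n_subjects >= 1, runs_per_stream >= 1, fs > 24,
            n_perm >= 1, cluster_alpha > 0, cluster_alpha < 1,
            soi_alpha > 0, soi_alpha < 1)
  if (epoch_cycles + skip_tones / 3 > n_cycles)
    stop_invalid("n_cycles (%d) too short for skip %d tones + %d epoch cycles",
                 n_cycles, skip_tones, epoch_cycles)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML or JSON file
#'
#' The file holds any subset of [run_config()]'s arguments; missing
#' fields take the defaults and everything is validated on construction.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  fields <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_invalid("reading YAML configs needs the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  fields$config_hash <- NULL
  known <- names(formals(run_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown))
    stop_invalid("unknown config field(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, fields)
}

config_hash <- function(cfg) {
  # hash of the scientific configuration; the output location is not part
  # of provenance
  x <- unclass(cfg)
  x$out_dir <- NULL
  fnv1a32(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
}

write_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full simulated experiment
#'
#' Deterministic end-to-end pipeline producing an artifact tree under
#' `cfg$out_dir`:
#' `streams/` (example event tables), `spectra/` (group-mean SNR
#' topographies and example SNR spectra), `stats/` (cluster tests and SOI
#' masks), `dynamics/` (dynamics table and LMM selection), `behaviour/`
#' (simulated 2AFC scores and tests), and `report.json` (headline
#' numbers). Every table carries the configuration hash in a header
#' line; any stage failure halts with a stage-tagged error, preserving
#' the outputs already written.
#'
#' @param cfg A [run_config()].
#' @param stages Subset of stages to run (in canonical order).
#' @return Invisibly, a list with the in-memory results of the stages run.
#' @export
run_experiment <- function(cfg, stages = c("streams", "spectra", "stats",
                                           "dynamics", "behaviour")) {
  stopifnot(inherits(cfg, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  hash <- config_hash(cfg)
  out <- cfg$out_dir
  for (d in c("", "streams", "spectra", "stats", "dynamics", "behaviour"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(c(unclass(cfg), list(config_hash = hash)),
                       file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res <- list(config = cfg, hash = hash)
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop_invalid("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  seeds <- derive_seeds(cfg$seed, 8)
  scen <- if (cfg$scenario == "custom") "wake_effect" else cfg$scenario
  cohort <- simulate_cohort(scen, cfg$n_subjects, cfg$runs_per_stream,
                            seed = seeds[1], fs = cfg$fs,
                            n_cycles = cfg$n_cycles,
                            tone_amp = cfg$tone_amp,
                            tritone_amp = cfg$tritone_amp,
                            pink_noise_sd = cfg$pink_noise_sd,
                            white_noise_sd = cfg$white_noise_sd)
  res$cohort <- cohort
  fois <- foi_frequencies()

  if ("streams" %in% stages) run_stage("streams", function() {
    st <- generate_stat_sequence(min(cfg$n_cycles, 200), seed = seeds[2])
    rd <- generate_rdm_sequence(3 * min(cfg$n_cycles, 200), seed = seeds[3])
    write_tsv(sequence_events(st), file.path(out, "streams", "stat_events.tsv"), hash)
    write_tsv(sequence_events(rd), file.path(out, "streams", "rdm_events.tsv"), hash)
    write_tsv(as.data.frame(empirical_tp_matrix(st)$probs),
              file.path(out, "streams", "stat_tp_matrix.tsv"), hash)
    write_tsv(as.data.frame(empirical_tp_matrix(rd)$probs),
              file.path(out, "streams", "rdm_tp_matrix.tsv"), hash)
    NULL
  })

  spectra <- NULL
  if (any(c("spectra", "stats", "dynamics") %in% stages)) {
    need_minutes <- any(c("stats", "dynamics") %in% stages)
    spectra <- run_stage("spectra", function()
      analyze_cohort(cohort, epoch_cycles = cfg$epoch_cycles,
                     skip_tones = cfg$skip_tones,
                     n_neighbors = cfg$n_neighbors,
                     n_neighbors_minute = cfg$n_neighbors_minute,
                     fois = fois, minute_pairs = need_minutes))
    res$spectra <- spectra
  }
  if ("spectra" %in% stages) run_stage("spectra", function() {
    for (stream in c("STAT", "RDM")) {
      gm <- data.frame(chipset = rownames(cohort$array$pos),
                       x = cohort$array$pos[, 1], y = cohort$array$pos[, 2],
                       tone_snr = colMeans(spectra$topo[[stream]]$tone),
                       tritone_snr = colMeans(spectra$topo[[stream]]$tritone))
      write_tsv(gm, file.path(out, "spectra",
                              sprintf("%s_group_mean_topography.tsv",
                                      tolower(stream))), hash)
      ex <- spectra$example_snr[[stream]]
      peak <- which.max(rowMeans(ex$snr))
      write_tsv(data.frame(freq = ex$freqs, snr = ex$snr[peak, ]),
                file.path(out, "spectra",
                          sprintf("%s_example_snr_spectrum.tsv",
                                  tolower(stream))), hash)
    }
    NULL
  })

  stats_res <- NULL
  if (any(c("stats", "dynamics") %in% stages)) {
    stats_res <- run_stage("stats", function() {
      cl_tone <- paired_cluster_test(spectra$topo$STAT$tone,
                                     spectra$topo$RDM$tone, cohort$array,
                                     n_perm = cfg$n_perm,
                                     cluster_alpha = cfg$cluster_alpha,
                                     seed = seeds[4])
      cl_tri <- paired_cluster_test(spectra$topo$STAT$tritone,
                                    spectra$topo$RDM$tritone, cohort$array,
                                    n_perm = cfg$n_perm,
                                    cluster_alpha = cfg$cluster_alpha,
                                    seed = seeds[5])
      soi_tri <- one_sample_soi_test(spectra$topo$STAT$tritone,
                                     baseline = 1, n_perm = cfg$n_perm,
                                     alpha = cfg$soi_alpha, seed = seeds[6])
      # tone SOI: group-mean tone SNR in minutes 1-2 of the first RDM run
      tone_12 <- spectra$minute$RDM$tone[, 1, ]
      soi_tone <- threshold_soi(colMeans(tone_12), cfg$soi_tone_threshold)
      list(cl_tone = cl_tone, cl_tri = cl_tri, soi_tri = soi_tri,
           soi_tone = soi_tone, tone_12 = tone_12)
    })
    res$stats <- stats_res
  }
  if ("stats" %in% stages) run_stage("stats", function() {
    write_cluster_result(stats_res$cl_tone,
                         file.path(out, "stats", "cluster_tone.json"))
    write_cluster_result(stats_res$cl_tri,
                         file.path(out, "stats", "cluster_tritone.json"))
    write_tsv(data.frame(chipset = rownames(cohort$array$pos),
                         soi_tone = as.integer(stats_res$soi_tone),
                         soi_tritone = as.integer(stats_res$soi_tri$mask),
                         tritone_p = stats_res$soi_tri$p),
              file.path(out, "stats", "soi_masks.tsv"), hash)
    NULL
  })

  if ("dynamics" %in% stages) {
    dyn <- run_stage("dynamics", function() {
      soi <- if (any(stats_res$soi_tri$mask)) which(stats_res$soi_tri$mask)
             else temporal_chipsets(cohort$array)$all
      tab <- cohort_dynamics(cohort, soi, fois[["tritone"]],
                             analysis = spectra)
      # a single simulated cohort has one group, so the GROUP-free
      # candidate set applies regardless of scenario
      sel <- select_lmm(tab, session = "sleep")
      list(table = tab, lmm = sel, soi = soi)
    })
    res$dynamics <- dyn
    write_tsv(dyn$table, file.path(out, "dynamics", "dynamics_table.tsv"), hash)
    write_lmm_result(dyn$lmm, file.path(out, "dynamics", "lmm_selection.json"))
  }

  if ("behaviour" %in% stages) {
    beh <- run_stage("behaviour", function() {
      key <- build_2afc_test(seed = seeds[7])
      half <- ceiling(cfg$n_subjects / 2)
      groups <- rep(c("exposure", "no_exposure"),
                    c(half, cfg$n_subjects - half))
      results <- simulate_2afc_cohort(key, cfg$n_subjects, p_correct = 0.5,
                                      seed = seeds[8])
      scores <- vapply(results, `[[`, 0, "percent")
      wil <- wilcoxon_vs_chance(scores)
      bf <- jzs_bf_one_sample(scores)
      grp <- if (cfg$n_subjects >= 4 && length(unique(groups)) == 2) {
        a <- scores[groups == "exposure"]; b <- scores[groups == "no_exposure"]
        list(mw = mann_whitney_groups(a, b), bf = jzs_bf_independent(a, b))
      } else NULL
      list(key = key, scores = scores, groups = groups, wilcoxon = wil,
           bf = bf, group_tests = grp)
    })
    res$behaviour <- beh
    write_tsv(data.frame(subject = seq_along(beh$scores),
                         group = beh$groups, percent = beh$scores),
              file.path(out, "behaviour", "afc_scores.tsv"), hash)
    beh_json <- list(
      mean_percent = mean(beh$scores), sd_percent = stats::sd(beh$scores),
      wilcoxon_V = beh$wilcoxon$V, wilcoxon_p = beh$wilcoxon$p,
      bf10_vs_chance = beh$bf$bf10, verdict = beh$bf$verdict)
    if (!is.null(beh$group_tests))
      beh_json <- c(beh_json, list(
        mann_whitney_W = beh$group_tests$mw$W,
        mann_whitney_p = beh$group_tests$mw$p,
        bf10_groups = beh$group_tests$bf$bf10))
    jsonlite::write_json(beh_json, file.path(out, "behaviour", "tests.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  report <- list(config_hash = hash, scenario = cfg$scenario)
  if (!is.null(res$spectra)) {
    tc <- temporal_chipsets(cohort$array)$all
    report$mean_tone_snr_temporal_stat <-
      mean(colMeans(res$spectra$topo$STAT$tone)[tc])
    report$mean_tritone_snr_stat <- mean(res$spectra$topo$STAT$tritone)
    report$mean_tritone_snr_rdm <- mean(res$spectra$topo$RDM$tritone)
  }
  if (!is.null(res$stats)) {
    sig <- significant_clusters(res$stats$cl_tri, 0.05)
    report$n_significant_tritone_clusters <- length(sig)
    report$min_tritone_cluster_p <- if (length(res$stats$cl_tri$clusters))
      min(vapply(res$stats$cl_tri$clusters, `[[`, 0, "p")) else NA
  }
  if (!is.null(res$dynamics))
    report$lmm_selected_fixed <- res$dynamics$lmm$selected_fixed
  if (!is.null(res$behaviour))
    report$behaviour_mean_percent <- mean(res$behaviour$scores)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$report <- report
  invisible(res)
}
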