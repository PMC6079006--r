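#!/usr/bin/env Rscript
# Topography and SNR-spectrum figures from the cohort artifact trees.
#
# Reads the group-mean tables written by 02_sleep_null.R and
# 03_wake_effect.R and draws layout heatmaps (cluster sensors ringed)
# and example SNR spectra. PNGs land in results/figures/.

suppressMessages(library(freqtag))
out <- "results/figures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
arr <- make_sensor_array()

for (scen in c("sleep_null", "wake_effect")) {
  base <- file.path("results", scen)
  if (!dir.exists(base)) {
    cat("skipping", scen, "- run its analysis script first\n")
    next
  }
  cl <- jsonlite::read_json(file.path(base, "stats", "cluster_tritone.json"),
                            simplifyVector = FALSE)
  sig05 <- unlist(lapply(cl$clusters,
                         function(x) if (x$p <= 0.05) x$chipsets))
  sig025 <- unlist(lapply(cl$clusters,
                          function(x) if (x$p <= 0.025) x$chipsets))
  for (stream in c("stat", "rdm")) {
    gm <- read.delim(file.path(base, "spectra",
                               paste0(stream, "_group_mean_topography.tsv")),
                     comment.char = "#")
    png(file.path(out, sprintf("%s_%s_topographies.png", scen, stream)),
        900, 480, res = 96)
    op <- par(mfrow = c(1, 2), mar = c(1, 1, 3, 1))
    plot_topography(arr, gm$tone_snr, main = sprintf("%s %s: tone 5.505 Hz",
                                                     scen, toupper(stream)))
    plot_topography(arr, gm$tritone_snr,
                    mark = if (stream == "stat") sig025,
                    mark2 = if (stream == "stat") setdiff(sig05, sig025),
                    main = sprintf("%s %s: tritone 1.835 Hz",
                                   scen, toupper(stream)))
    par(op); dev.off()
  }
  sn <- read.delim(file.path(base, "spectra", "stat_example_snr_spectrum.tsv"),
                   comment.char = "#")
  png(file.path(out, sprintf("%s_snr_spectrum.png", scen)), 900, 420, res = 96)
  plot(sn$freq, sn$snr, type = "l", xlab = "frequency (Hz)", ylab = "SNR",
       main = sprintf("%s: example SNR spectrum (peak chipset, STAT)", scen))
  abline(v = c(1.835, 3.67, 5.505, 11.01), lty = 3, col = "grey50")
  dev.off()
  cat("figures written for", scen, "\n")
}
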