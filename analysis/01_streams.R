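#!/usr/bin/env Rscript
# Stream construction and design statistics.
#
# Builds the three stream types at study-like lengths, verifies their
# transitional-probability structure empirically, and writes the design
# tables under results/streams/. Expected outcome: within-triple TPs of
# exactly 1, triple-to-triple TPs near 1/3, RDM tone TPs near 1/11
# (9%), and about 30% repeated ascents in the habituation stream.

suppressMessages(library(freqtag))
out <- "results/streams"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20180806

g <- timing_grid()
cat(sprintf("Timing grid: tone rate %.3f Hz, tritone rate %.3f Hz, cycle %.3f s\n",
            g$tone_rate, g$tritone_rate, g$cycle_period))

## STAT stream: 560 tritones = one canonical 5-minute block
st <- generate_stat_sequence(560, seed = seed)
sequence_events(st, file.path(out, "stat_events.tsv"))
stream_manifest(st, file.path(out, "stat_manifest.json"), seed = seed)

## empirical TPs on a long stream
st_long <- generate_stat_sequence(30000, seed = seed + 1)
tp <- empirical_tp_matrix(st_long)$probs
write.table(round(tp, 4), file.path(out, "stat_tp_matrix.tsv"),
            sep = "\t", quote = FALSE)
ttp <- empirical_triple_tp_matrix(st_long)$probs
cat(sprintf("STAT: mean within-triple TP = %.3f, mean triple TP = %.3f\n",
            mean(tp[tp > 0.5]), mean(ttp[row(ttp) != col(ttp)])))

rd_long <- generate_rdm_sequence(1e5, seed = seed + 2)
rtp <- empirical_tp_matrix(rd_long)$probs
write.table(round(rtp, 4), file.path(out, "rdm_tp_matrix.tsv"),
            sep = "\t", quote = FALSE)
cat(sprintf("RDM: mean off-diagonal TP = %.4f (design 1/11 = %.4f)\n",
            mean(rtp[row(rtp) != col(rtp)]), 1 / 11))

hab <- generate_hab_sequence(1e4, repeat_prob = 0.3, seed = seed + 3)
cat(sprintf("HAB: repeated ascents %.1f%% of %d scales\n",
            100 * length(hab$repeat_marks) / 1e4, 1e4))

## 2AFC test key
key <- build_2afc_test(seed = seed + 4)
write.table(as.data.frame(key), file.path(out, "afc_key.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("2AFC: %d trials, every tritone 4x, %d STAT-first\n",
            nrow(key), sum(key$stat_first)))

## short rendered audio demo (kept small; full streams render the same way)
wav <- render_audio(generate_stat_sequence(8, seed = seed), sample_rate = 44100)
write_wav(wav, file.path(out, "stat_demo_8cycles.wav"))
cat("Wrote", file.path(out, "stat_demo_8cycles.wav"),
    sprintf("(%.2f s)\n", wav$duration))
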