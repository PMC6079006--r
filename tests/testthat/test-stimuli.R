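test_that("equal-temperament frequencies are anchored at A = 440", {
  f <- tone_frequencies()
  expect_equal(unname(f["A"]), 440)
  expect_equal(unname(f["C"]), 261.63, tolerance = 1e-4)
  expect_equal(names(f)[1], "C")
  expect_true(all(diff(f) > 0))           # C lowest, B highest
  expect_equal(length(unique(names(f))), 12)
  # scale invariance of the reference
  expect_equal(unname(tone_frequencies(220)), unname(f) / 2)
  expect_error(tone_frequencies(-1), "positive")
})

test_that("timing grid yields the tagged rates and exact cycle period", {
  g <- timing_grid()
  expect_equal(round(g$tone_rate, 3), 5.505)
  expect_equal(round(g$tritone_rate, 3), 1.835)
  expect_equal(g$cycle_period, 0.545)
  expect_equal(g$tone_rate, 1 / (0.175 + 0.020 / 3))
  expect_equal(g$tritone_rate, g$tone_rate / 3)
  # HAB grid has no blank
  expect_equal(timing_grid(blank = FALSE)$blank_every_3, 0)
})

test_that("printed tritone sets satisfy the construction constraints", {
  expect_silent(validate_tritone_set(stat_tritone_set()))
  expect_silent(validate_tritone_set(test_tritone_set()))
  # no shared within-triple bigram across the two sets
  bg <- function(set) unlist(lapply(set$triples,
                                    function(t) paste(t[-3], t[-1], sep = ">")))
  expect_length(intersect(bg(stat_tritone_set()), bg(test_tritone_set())), 0)
  # a corrupted set is rejected
  bad <- stat_tritone_set()
  bad$triples[[1]][1] <- "A"   # duplicates A, drops G#
  expect_error(validate_tritone_set(bad), "exactly once")
})

test_that("constrained search yields fresh valid sets avoiding a given set", {
  s <- generate_tritone_set(seed = 7, avoid = stat_tritone_set())
  expect_s3_class(s, "tritone_set")
  bg <- function(set) unlist(lapply(set$triples,
                                    function(t) paste(t[-3], t[-1], sep = ">")))
  expect_length(intersect(bg(s), bg(stat_tritone_set())), 0)
  expect_identical(generate_tritone_set(seed = 7, avoid = stat_tritone_set()),
                   s)
})

test_that("STAT streams factor into tritones with uniform non-repeating succession", {
  sq <- generate_stat_sequence(1000, seed = 41)
  expect_length(sq$tokens, 3000)
  # tokens factor exactly into triples of the set
  set <- stat_tritone_set()
  for (k in seq(1, 2998, by = 3)) {
    id <- sq$triplet_id[k]
    expect_identical(sq$tokens[k:(k + 2)], set$triples[[id]])
  }
  ids <- sq$triplet_id[seq(1, 3000, by = 3)]
  expect_true(all(diff(ids) != 0))        # no immediate repetition
  # within-triple TPs are exactly 1
  tp <- empirical_tp_matrix(sq)$probs
  for (tr in set$triples) {
    expect_equal(tp[tr[1], tr[2]], 1)
    expect_equal(tp[tr[2], tr[3]], 1)
  }
  # triple-to-triple TPs approach 1/3
  ttp <- empirical_triple_tp_matrix(sq)$probs
  expect_true(all(abs(ttp[row(ttp) != col(ttp)] - 1 / 3) < 0.05))
  expect_true(all(diag(ttp) == 0))
  # single triple degenerate case
  one <- generate_stat_sequence(1, seed = 1)
  expect_length(one$tokens, 3)
  expect_error(generate_stat_sequence(0), "n_triples")
})

test_that("STAT onsets sit on the blanked grid with triggers every 3 tones", {
  sq <- generate_stat_sequence(5, seed = 3)
  expect_equal(sq$onsets[1:4], c(0, 0.175, 0.35, 0.545))
  expect_equal(diff(sq$trigger_onsets), rep(0.545, 4))
  expect_true(all(diff(sq$onsets) > 0))
  expect_equal(sq$trigger_onsets, sq$onsets[seq(1, 15, by = 3)])
})

test_that("RDM streams avoid immediate repetition and approach 9% TPs", {
  sq <- generate_rdm_sequence(50000, seed = 88)
  expect_true(all(sq$tokens[-1] != sq$tokens[-length(sq$tokens)]))
  tp <- empirical_tp_matrix(sq)
  expect_true(all(diag(tp$probs) == 0))
  off <- tp$probs[row(tp$probs) != col(tp$probs)]
  expect_true(all(abs(off - 1 / 11) < 0.01))
  # blank grid identical to STAT
  expect_equal(sq$onsets[4] - sq$onsets[3], 0.175 + 0.020)
  expect_error(generate_rdm_sequence(0), "n_tones")
})

test_that("reproducibility: identical seed gives identical sequences", {
  expect_identical(generate_stat_sequence(50, seed = 5),
                   generate_stat_sequence(50, seed = 5))
  expect_identical(generate_rdm_sequence(100, seed = 5),
                   generate_rdm_sequence(100, seed = 5))
  expect_false(identical(generate_rdm_sequence(100, seed = 5)$tokens,
                         generate_rdm_sequence(100, seed = 6)$tokens))
})

test_that("HAB streams alternate scales and repeat ascents at the set rate", {
  sq <- generate_hab_sequence(10000, repeat_prob = 0.3, seed = 21)
  frac <- length(sq$repeat_marks) / 10000
  expect_lt(abs(frac - 0.30), 0.02)
  expect_identical(sq$tokens[1:12], tone_names())  # ascending scale first
  # degenerate probabilities
  expect_length(generate_hab_sequence(50, 0, seed = 1)$repeat_marks, 0)
  expect_length(generate_hab_sequence(50, 1, seed = 1)$repeat_marks, 50)
  expect_error(generate_hab_sequence(10, 1.5), "repeat_prob")
  # plain 175 ms grid, no blank
  expect_equal(diff(sq$onsets[1:13]), rep(0.175, 12))
})

test_that("empirical TP matrix row-normalizes counts", {
  tp <- empirical_tp_matrix(c("C", "D", "C", "D"))
  expect_equal(tp$probs["C", "D"], 1)
  expect_equal(tp$probs["D", "C"], 1)
  expect_equal(tp$counts["C", "D"], 2)
  rs <- rowSums(tp$probs)
  expect_true(all(rs[rowSums(tp$counts) > 0] == 1))
  expect_error(empirical_tp_matrix(c("C")), "2 tokens")
})

test_that("TP convergence: empirical matrices approach the design in sup norm", {
  # design for RDM: 1/11 off-diagonal, 0 diagonal
  sq <- generate_rdm_sequence(1e5, seed = 25)
  probs <- empirical_tp_matrix(sq)$probs
  design <- matrix(1 / 11, 12, 12); diag(design) <- 0
  expect_lt(max(abs(probs - design)), 0.01)
  # design for STAT: 1 within triples, 1/3 across triple boundaries
  st <- generate_stat_sequence(33334, seed = 25)
  stp <- empirical_tp_matrix(st)$probs
  set <- stat_tritone_set()
  design_stat <- matrix(0, 12, 12, dimnames = dimnames(stp))
  for (tr in set$triples) {
    design_stat[tr[1], tr[2]] <- 1
    design_stat[tr[2], tr[3]] <- 1
  }
  lasts <- vapply(set$triples, `[`, "", 3)
  firsts <- vapply(set$triples, `[`, "", 1)
  for (i in 1:4) for (j in 1:4) if (i != j)
    design_stat[lasts[i], firsts[j]] <- 1 / 3
  expect_lt(max(abs(stp - design_stat)), 0.01)
})

test_that("2AFC construction pairs every tritone four times, counterbalanced", {
  key <- build_2afc_test(seed = 13)
  expect_equal(nrow(key), 16)
  expect_equal(as.integer(table(key$stat_idx)), rep(4L, 4))
  expect_equal(as.integer(table(key$test_idx)), rep(4L, 4))
  # every STAT x TEST combination unique
  expect_equal(nrow(unique(key[, c("stat_idx", "test_idx")])), 16)
  expect_equal(sum(key$stat_first), 8)
  # each tritone first in half of its trials
  for (i in 1:4) {
    expect_equal(sum(key$stat_first[key$stat_idx == i]), 2)
    expect_equal(sum(!key$stat_first[key$test_idx == i]), 2)
  }
  # seeds change order only, not the pairing multiset
  key2 <- build_2afc_test(seed = 14)
  k1 <- key[order(key$stat_idx, key$test_idx), c("stat_idx", "test_idx")]
  k2 <- key2[order(key2$stat_idx, key2$test_idx), c("stat_idx", "test_idx")]
  rownames(k1) <- rownames(k2) <- NULL
  expect_identical(k1, k2)
  expect_false(identical(key$stat_idx, key2$stat_idx))
})

test_that("event export carries onsets, triplet ids and trigger flags", {
  sq <- generate_stat_sequence(4, seed = 2)
  ev <- sequence_events(sq)
  expect_equal(nrow(ev), 12)
  expect_equal(ev$trigger_flag, rep(c(1L, 0L, 0L), 4))
  expect_equal(ev$triplet_id, sq$triplet_id)
  path <- withr::local_tempfile(fileext = ".tsv")
  sequence_events(sq, path)
  back <- read.delim(path)
  expect_equal(back$onset_s, ev$onset_s)
})
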