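# ---------------------------------------------------------------------------
# Tone set and timing grid
# ---------------------------------------------------------------------------

#' Pitch-class names of the twelve-tone set
#'
#' Half tones from C to B in English musical notation, a single octave.
#'
#' @return Character vector of length 12.
#' @export
tone_names <- function() {
  c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")
}

#' Equal-temperament tone frequencies
#'
#' Frequencies for the twelve half tones C..B in the single octave that
#' contains the reference A (A4 = 440 Hz by default, so the register is
#' C4-B4). `f(name) = reference_a * 2^((k - 9)/12)` where `k` is the
#' semitone index from C.
#'
#' @param reference_a Frequency of A, in Hz. Must be positive.
#' @return Named numeric vector of 12 frequencies in Hz, C lowest, B highest.
#' @examples
#' tone_frequencies()["A"]   # 440
#' tone_frequencies()["C"]   # 261.63
#' @export
tone_frequencies <- function(reference_a = 440) {
  if (!is.numeric(reference_a) || length(reference_a) != 1L || reference_a <= 0)
    stop_invalid("reference_a must be a single positive number")
  k <- 0:11
  stats::setNames(reference_a * 2^((k - 9) / 12), tone_names())
}

#' Timing grid of the tagged streams
#'
#' Tones last 150 ms (5 ms raised-cosine rise/fall) and are separated by a
#' 25 ms inter-stimulus interval; STAT and RDM streams insert an extra
#' 20 ms blank every three tones. The effective tone rate is therefore
#' 1/(0.175 + 0.020/3) = 5.505 Hz and the tritone (triplet) rate is a third
#' of it, 1.835 Hz; one tritone cycle is exactly 0.545 s.
#'
#' @param blank Logical; whether the 20 ms blank every three tones is
#'   present (`TRUE` for STAT/RDM, `FALSE` for HAB streams).
#' @return List with fields `tone_duration`, `ramp`, `isi`,
#'   `tone_onset_interval`, `blank_every_3`, `cycle_period`, `tone_rate`,
#'   `tritone_rate`.
#' @export
timing_grid <- function(blank = TRUE) {
  toi <- 0.150 + 0.025
  b <- if (blank) 0.020 else 0
  list(
    tone_duration = 0.150,
    ramp = 0.005,
    isi = 0.025,
    tone_onset_interval = toi,
    blank_every_3 = b,
    cycle_period = 3 * toi + b,
    tone_rate = 1 / (toi + b / 3),
    tritone_rate = 1 / (3 * toi + b)
  )
}

#' Frequencies of interest for the tagged analysis
#'
#' @return Named numeric vector: `tone` = 5.505 Hz, `tritone` = 1.835 Hz
#'   (unrounded values from the timing grid).
#' @export
foi_frequencies <- function() {
  g <- timing_grid()
  c(tone = g$tone_rate, tritone = g$tritone_rate)
}

# ---------------------------------------------------------------------------
# Tritone sets
# ---------------------------------------------------------------------------

new_tritone_set <- function(triples, label) {
  stopifnot(length(triples) == 4L)
  x <- structure(list(triples = triples, label = label),
                 class = "tritone_set")
  validate_tritone_set(x)
  x
}

#' Validate a tritone set
#'
#' Checks the construction constraints: the 12 slots cover all 12 pitch
#' classes exactly once, no two triples share a first or last tone, and no
#' ordered within-triple bigram is duplicated.
#'
#' @param x A `tritone_set`.
#' @return `x`, invisibly; errors if a constraint is violated.
#' @export
validate_tritone_set <- function(x) {
  tr <- x$triples
  if (!all(vapply(tr, length, 1L) == 3L))
    stop_invalid("each tritone must have exactly 3 tones")
  slots <- unlist(tr)
  if (!setequal(slots, tone_names()) || anyDuplicated(slots))
    stop_invalid("the 12 slots must cover all 12 pitch classes exactly once")
  firsts <- vapply(tr, `[`, "", 1L)
  lasts <- vapply(tr, `[`, "", 3L)
  if (anyDuplicated(firsts) || anyDuplicated(lasts))
    stop_invalid("no two tritones may start or end with the same tone")
  bg <- unlist(lapply(tr, function(t) paste(t[-3], t[-1], sep = ">")))
  if (anyDuplicated(bg))
    stop_invalid("within-triple bigrams must be unique")
  invisible(x)
}

#' The exposed (STAT) tritone set
#'
#' The four tritones used in the statistical streams: G#CD, AC#G, FA#D#
#' and EF#B.
#'
#' @return A `tritone_set` labelled `"STAT"`.
#' @export
stat_tritone_set <- function() {
  new_tritone_set(list(c("G#", "C", "D"), c("A", "C#", "G"),
                       c("F", "A#", "D#"), c("E", "F#", "B")), "STAT")
}

#' The foil (TEST) tritone set for the 2AFC task
#'
#' The concurrent set DG#F, D#A#A, BC#F# and GCE, built under the same
#' constraints as the STAT set and sharing no transitional pair with it.
#'
#' @return A `tritone_set` labelled `"TEST"`.
#' @export
test_tritone_set <- function() {
  new_tritone_set(list(c("D", "G#", "F"), c("D#", "A#", "A"),
                       c("B", "C#", "F#"), c("G", "C", "E")), "TEST")
}

#' Search for a fresh tritone set under the construction constraints
#'
#' Rejection sampling over random partitions of the 12 pitch classes into
#' 4 ordered triples, accepting the first partition that satisfies the
#' set constraints and (optionally) shares no within-triple bigram and no
#' first/last tone with `avoid`.
#'
#' @param seed Integer seed.
#' @param avoid Optional `tritone_set` whose bigrams and boundary tones the
#'   new set must not reuse (as when building a foil set).
#' @param max_tries Give up after this many rejections.
#' @param label Label for the returned set.
#' @return A `tritone_set`.
#' @export
generate_tritone_set <- function(seed = NULL, avoid = NULL,
                                 max_tries = 10000, label = "SEARCH") {
  avoid_bg <- character(0); avoid_first <- character(0); avoid_last <- character(0)
  if (!is.null(avoid)) {
    avoid_bg <- unlist(lapply(avoid$triples,
                              function(t) paste(t[-3], t[-1], sep = ">")))
    avoid_first <- vapply(avoid$triples, `[`, "", 1L)
    avoid_last <- vapply(avoid$triples, `[`, "", 3L)
  }
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      perm <- sample(tone_names())
      tr <- split(perm, rep(1:4, each = 3))
      names(tr) <- NULL
      ok <- tryCatch({
        x <- new_tritone_set(tr, label)
        bg <- unlist(lapply(tr, function(t) paste(t[-3], t[-1], sep = ">")))
        !any(bg %in% avoid_bg) &&
          !any(vapply(tr, `[`, "", 1L) %in% avoid_first) &&
          !any(vapply(tr, `[`, "", 3L) %in% avoid_last)
      }, error = function(e) FALSE)
      if (isTRUE(ok)) return(new_tritone_set(tr, label))
    }
    stop_invalid("no admissible tritone set found in %d tries", max_tries)
  })
}

#' @export
print.tritone_set <- function(x, ...) {
  cat(sprintf("<tritone_set %s> %s\n", x$label,
              paste(vapply(x$triples, paste, "", collapse = ""),
                    collapse = " / ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Token sequences
# ---------------------------------------------------------------------------

token_onsets <- function(n_tokens, blank = TRUE) {
  g <- timing_grid(blank)
  j <- seq_len(n_tokens) - 1L
  if (blank) (j %/% 3L) * g$cycle_period + (j %% 3L) * g$tone_onset_interval
  else j * g$tone_onset_interval
}

new_token_sequence <- function(tokens, stream_type, triplet_id = NULL,
                               repeat_marks = numeric(0)) {
  blank <- stream_type %in% c("STAT", "RDM")
  onsets <- token_onsets(length(tokens), blank)
  structure(list(
    tokens = tokens,
    onsets = onsets,
    triplet_id = triplet_id,
    trigger_onsets = onsets[seq(1L, length(tokens), by = 3L)],
    stream_type = stream_type,
    repeat_marks = repeat_marks,
    grid = timing_grid(blank)
  ), class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("<token_sequence %s> %d tokens, %.2f s, %d triggers\n",
              x$stream_type, length(x$tokens),
              max(x$onsets) + x$grid$tone_onset_interval,
              length(x$trigger_onsets)))
  invisible(x)
}

#' Generate a statistical (STAT) stream
#'
#' Concatenates `n_triples` tritones drawn from the set, with immediate
#' repetition of the same tritone proscribed: each successor is drawn
#' uniformly from the other three, giving within-triple transitional
#' probability 1 and triple-to-triple transitional probability 1/3.
#'
#' @param n_triples Number of tritones (>= 1).
#' @param set A `tritone_set` (defaults to the exposed STAT set).
#' @param seed Integer seed for reproducibility.
#' @return A `token_sequence` with `triplet_id` marking the tritone index
#'   (into `set$triples`) of every token.
#' @export
generate_stat_sequence <- function(n_triples, set = stat_tritone_set(),
                                   seed = NULL) {
  if (!is.numeric(n_triples) || n_triples < 1)
    stop_invalid("n_triples must be >= 1")
  n_triples <- as.integer(n_triples)
  validate_tritone_set(set)
  idx <- with_seed(seed, {
    out <- integer(n_triples)
    out[1L] <- sample.int(4L, 1L)
    for (i in seq_len(n_triples - 1L))
      out[i + 1L] <- sample(setdiff(1:4, out[i]), 1L)
    out
  })
  tokens <- unlist(set$triples[idx], use.names = FALSE)
  new_token_sequence(tokens, "STAT", triplet_id = rep(idx, each = 3L))
}

#' Generate a random (RDM) stream
#'
#' The same twelve tones in random order, the only constraint being that a
#' tone is never repeated twice in a row (uniform over the 11 other tones),
#' so tone-to-tone transitional probabilities are 1/11, about 9%. The
#' 20 ms blank every three tones is kept, as in the STAT streams.
#'
#' @param n_tones Number of tones (>= 1).
#' @param seed Integer seed.
#' @return A `token_sequence`.
#' @export
generate_rdm_sequence <- function(n_tones, seed = NULL) {
  if (!is.numeric(n_tones) || n_tones < 1)
    stop_invalid("n_tones must be >= 1")
  n_tones <- as.integer(n_tones)
  nm <- tone_names()
  tok <- with_seed(seed, {
    out <- integer(n_tones)
    out[1L] <- sample.int(12L, 1L)
    if (n_tones > 1L) {
      # draw uniformly over the 11 non-identical successors
      r <- sample.int(11L, n_tones - 1L, replace = TRUE)
      for (i in seq_len(n_tones - 1L))
        out[i + 1L] <- if (r[i] >= out[i]) r[i] + 1L else r[i]
    }
    out
  })
  new_token_sequence(nm[tok], "RDM")
}

#' Generate a habituation (HAB) stream
#'
#' Ascending then descending musical scales over the twelve tones; each
#' ascending scale is independently repeated with probability
#' `repeat_prob` (30% in the study), and the onsets of repeated ascents
#' are recorded in `repeat_marks` (the events participants respond to).
#' HAB streams run on the plain 175 ms grid, without the 20 ms blank.
#'
#' @param n_scales Number of ascending scales (>= 1).
#' @param repeat_prob Probability that an ascending scale is repeated.
#' @param seed Integer seed.
#' @return A `token_sequence` with `stream_type = "HAB"`.
#' @export
generate_hab_sequence <- function(n_scales, repeat_prob = 0.3, seed = NULL) {
  if (!is.numeric(n_scales) || n_scales < 1)
    stop_invalid("n_scales must be >= 1")
  if (!is.numeric(repeat_prob) || repeat_prob < 0 || repeat_prob > 1)
    stop_invalid("repeat_prob must be in [0, 1]")
  n_scales <- as.integer(n_scales)
  asc <- tone_names()
  desc <- rev(asc)
  rep_flags <- with_seed(seed,
                         stats::runif(n_scales) < repeat_prob)
  units <- vector("list", 3L * n_scales)
  unit_is_repeat <- logical(3L * n_scales)
  k <- 0L
  for (i in seq_len(n_scales)) {
    k <- k + 1L; units[[k]] <- asc
    if (rep_flags[i]) {
      k <- k + 1L; units[[k]] <- asc; unit_is_repeat[k] <- TRUE
    }
    k <- k + 1L; units[[k]] <- desc
  }
  units <- units[seq_len(k)]
  unit_is_repeat <- unit_is_repeat[seq_len(k)]
  tokens <- unlist(units, use.names = FALSE)
  onset0 <- token_onsets(length(tokens), blank = FALSE)
  unit_start <- cumsum(c(0L, vapply(units, length, 1L)))[seq_along(units)] + 1L
  marks <- onset0[unit_start[unit_is_repeat]]
  seq <- new_token_sequence(tokens, "HAB", repeat_marks = marks)
  attr(seq, "repeat_flags") <- rep_flags
  seq
}

# ---------------------------------------------------------------------------
# Empirical transition statistics
# ---------------------------------------------------------------------------

#' Empirical tone-to-tone transitional probability matrix
#'
#' Counts ordered bigrams in a token sequence and row-normalizes them.
#'
#' @param seq A `token_sequence` (or a plain character vector of tone
#'   names) with at least 2 tokens.
#' @return A `tp_matrix`: list with `counts` and `probs`, both 12 x 12
#'   matrices over the tone set (rows = antecedent, columns = successor);
#'   rows with zero counts have `probs` of 0.
#' @export
empirical_tp_matrix <- function(seq) {
  tokens <- if (inherits(seq, "token_sequence")) seq$tokens else seq
  if (length(tokens) < 2L) stop_invalid("need at least 2 tokens")
  nm <- tone_names()
  from <- factor(tokens[-length(tokens)], levels = nm)
  to <- factor(tokens[-1L], levels = nm)
  counts <- table(from, to)
  counts <- matrix(as.integer(counts), 12, 12, dimnames = list(nm, nm))
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, probs = probs), class = "tp_matrix")
}

#' Empirical tritone-to-tritone transition matrix of a STAT stream
#'
#' @param seq A `token_sequence` of type STAT with `triplet_id`.
#' @return List with 4 x 4 `counts` and row-normalized `probs` over the
#'   tritone indices of the generating set.
#' @export
empirical_triple_tp_matrix <- function(seq) {
  stopifnot(inherits(seq, "token_sequence"), seq$stream_type == "STAT")
  idx <- seq$triplet_id[seq(1L, length(seq$tokens), by = 3L)]
  if (length(idx) < 2L) stop_invalid("need at least 2 triples")
  from <- factor(idx[-length(idx)], levels = 1:4)
  to <- factor(idx[-1L], levels = 1:4)
  counts <- matrix(as.integer(table(from, to)), 4, 4)
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, probs = probs)
}

# ---------------------------------------------------------------------------
# 2AFC test construction
# ---------------------------------------------------------------------------

#' Build the two-alternative forced-choice recognition test
#'
#' Pairs each of the 4 exposed (STAT) tritones with each of the 4 foil
#' (TEST) tritones exactly once, giving 16 unique trials in which every
#' tritone occurs 4 times. Presentation order within the pair is
#' counterbalanced: the STAT member comes first in 8 of the 16 trials, and
#' each tritone is first in exactly half of its trials. Trial order is
#' shuffled under the seed; the pairing multiset never changes.
#'
#' @param stat,test `tritone_set`s of 4 triples each.
#' @param seed Integer seed for the trial-order shuffle.
#' @param isi Interstimulus interval within a pair, seconds.
#' @return An `afc_test`: data frame with columns `trial`, `stat_idx`,
#'   `test_idx`, `stat_first` plus attributes `stat_set`, `test_set`, `isi`.
#' @export
build_2afc_test <- function(stat = stat_tritone_set(),
                            test = test_tritone_set(),
                            seed = NULL, isi = 1.0) {
  validate_tritone_set(stat); validate_tritone_set(test)
  grid <- expand.grid(stat_idx = 1:4, test_idx = 1:4)
  # (i + j) parity puts each tritone first in exactly 2 of its 4 trials
  grid$stat_first <- (grid$stat_idx + grid$test_idx) %% 2L == 0L
  ord <- with_seed(seed, sample.int(nrow(grid)))
  grid <- grid[ord, , drop = FALSE]
  grid$trial <- seq_len(nrow(grid))
  rownames(grid) <- NULL
  structure(grid[, c("trial", "stat_idx", "test_idx", "stat_first")],
            class = c("afc_test", "data.frame"),
            stat_set = stat, test_set = test, isi = isi)
}

# ---------------------------------------------------------------------------
# Event export
# ---------------------------------------------------------------------------

#' Export a token sequence as a tab-separated event table
#'
#' Columns: `onset_s`, `token`, `triplet_id` (NA outside STAT streams),
#' `trigger_flag` (1 on every third tone, where a trigger is sent to the
#' recording).
#'
#' @param seq A `token_sequence`.
#' @param path Optional file path; when given, the table is written as TSV.
#' @return The event data frame, invisibly when `path` is given.
#' @export
sequence_events <- function(seq, path = NULL) {
  stopifnot(inherits(seq, "token_sequence"))
  n <- length(seq$tokens)
  ev <- data.frame(
    onset_s = seq$onsets,
    token = seq$tokens,
    triplet_id = if (is.null(seq$triplet_id)) rep(NA_integer_, n) else seq$triplet_id,
    trigger_flag = as.integer(seq_len(n) %% 3L == 1L)
  )
  if (!is.null(path)) {
    utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(ev))
  }
  ev
}

#' Write a JSON manifest describing a generated stream
#'
#' @param seq A `token_sequence`.
#' @param path Output path.
#' @param seed The seed the stream was generated with (recorded verbatim).
#' @return The manifest list, invisibly.
#' @export
stream_manifest <- function(seq, path = NULL, seed = NULL) {
  m <- list(
    stream_type = seq$stream_type,
    n_tokens = length(seq$tokens),
    seed = seed,
    timing = seq$grid,
    n_triggers = length(seq$trigger_onsets),
    duration_s = length(seq$trigger_onsets) * seq$grid$cycle_period
  )
  if (!is.null(path))
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(m)
}
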