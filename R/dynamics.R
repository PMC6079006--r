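# Minute-wise SNR time courses in sensors of interest and two-step
# AICc-based linear mixed-model selection of their temporal evolution.

#' Minute-wise SOI-averaged SNR of one recording
#'
#' Crops the recording into five 1-minute windows (112 tritone cycles,
#' 61.04 s each, starting after the usual 12-tone skip), computes the
#' Hann-taper power spectrum per window, averages power over the four
#' overlapping minute pairs (1-2, 2-3, 3-4, 4-5) to increase statistical
#' power, forms the SNR with 40 neighbouring bins (skipping the two
#' closest per side), and averages the FOI SNR over the sensors of
#' interest.
#'
#' @param rec A `meg_recording` with at least 12 tones + 560 cycles.
#' @param soi_mask Logical mask (or integer indices) of SOI chipsets.
#' @param foi Frequency of interest, Hz.
#' @param n_neighbors Neighbour count for the minute-wise SNR (default 40).
#' @param cycles_per_window Cycles per 1-minute window (default 112).
#' @param skip_tones Tones skipped before the first window.
#' @return Data frame with columns `window` (`"1-2"` .. `"4-5"`) and `snr`.
#' @export
minute_windows <- function(rec, soi_mask, foi, n_neighbors = 40,
                           cycles_per_window = 112, skip_tones = 12) {
  n_windows <- 5L
  specs <- vector("list", n_windows)
  for (w in seq_len(n_windows)) {
    ep <- extract_epoch(rec, cycles_per_window,
                        skip_tones = skip_tones +
                          3L * cycles_per_window * (w - 1L))
    specs[[w]] <- combine_gradiometers(power_spectrum(ep))
  }
  pairs <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 5))
  snr_vals <- vapply(pairs, function(pr) {
    avg <- specs[[pr[1]]]
    avg$power <- (specs[[pr[1]]]$power + specs[[pr[2]]]$power) / 2
    sn <- snr_spectrum(avg, n_neighbors = n_neighbors)
    mean(sn$snr[soi_mask, foi_bin(sn, foi)])
  }, 0)
  data.frame(window = c("1-2", "2-3", "3-4", "4-5"),
             minutes = 1:4, snr = snr_vals)
}

#' Assemble the dynamics table of a cohort
#'
#' One row per subject x minute-pair window x stream: SOI-averaged SNR at
#' the given FOI, computed on the first run of each stream (the first
#' continuous 5 minutes, as in the temporal-evolution analysis).
#'
#' @param cohort A [simulate_cohort()] plan.
#' @param soi_mask SOI chipset mask or indices.
#' @param foi Frequency of interest, Hz (must be one of the FOIs of
#'   `analysis` when that is supplied).
#' @param group Group label to attach (`"exposure"`/`"no_exposure"`), or
#'   `NA` for single-group designs.
#' @param analysis Optional precomputed [analyze_cohort()] result with
#'   minute pairs; avoids re-simulating the cohort.
#' @param ... Passed to [minute_windows()] when recomputing from scratch.
#' @return A `DynamicsTable` data frame: `subject`, `window`, `minutes`,
#'   `stream`, `group`, `snr`.
#' @export
cohort_dynamics <- function(cohort, soi_mask, foi, group = NA_character_,
                            analysis = NULL, ...) {
  rows <- list()
  if (!is.null(analysis)) {
    if (!length(analysis$minute))
      stop_invalid("analysis was computed without minute pairs")
    fn <- names(analysis$fois)[which.min(abs(analysis$fois - foi))]
    if (abs(analysis$fois[[fn]] - foi) > 1e-6)
      stop_invalid("FOI %.4g Hz not present in the precomputed analysis", foi)
    for (i in seq_len(cohort$n_subjects)) {
      for (stream in c("STAT", "RDM")) {
        vals <- analysis$minute[[stream]][[fn]][i, , , drop = FALSE]
        snr <- vapply(1:4, function(p)
          mean(vals[1, p, soi_mask]), 0)
        rows[[length(rows) + 1L]] <-
          data.frame(window = c("1-2", "2-3", "3-4", "4-5"), minutes = 1:4,
                     snr = snr, subject = i, stream = stream, group = group)
      }
    }
  } else {
    for (i in seq_len(cohort$n_subjects)) {
      for (stream in c("STAT", "RDM")) {
        rec <- subject_recordings(cohort, i, stream)[[1]]
        mw <- minute_windows(rec, soi_mask, foi, ...)
        mw$subject <- i; mw$stream <- stream; mw$group <- group
        rows[[length(rows) + 1L]] <- mw
        rm(rec)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$subject <- factor(out$subject)
  out$stream <- factor(out$stream, levels = c("RDM", "STAT"))
  rownames(out) <- NULL
  out[, c("subject", "window", "minutes", "stream", "group", "snr")]
}

#' Candidate random-effect structures
#'
#' All stated combinations: random intercepts per subject, optionally
#' with a random slope of the MINUTES and/or STREAM predictor.
#'
#' @return Named character vector of random-effect formula fragments.
#' @export
candidate_random_structures <- function() {
  c(intercept = "(1 | subject)",
    minutes_slope = "(1 + minutes | subject)",
    stream_slope = "(1 + stream | subject)",
    both_slopes = "(1 + minutes + stream | subject)")
}

#' Candidate fixed-effect models
#'
#' All well-formed fixed-effect formulas over STREAM, MINUTES (categorical,
#' continuous, or quadratic encoding), and - for the wake session - the
#' between-subjects GROUP predictor, plus the intercept-only model.
#' Interactions imply their main effects (hierarchy), and a formula never
#' mixes two MINUTES encodings.
#'
#' @param session `"sleep"` (STREAM, MINUTES) or `"wake"` (adds GROUP).
#' @return Named character vector of right-hand sides (without random
#'   effects).
#' @export
candidate_fixed_models <- function(session = c("sleep", "wake")) {
  session <- match.arg(session)
  minutes_terms <- c(categorical = "factor(minutes)",
                     continuous = "minutes",
                     quadratic = "poly(minutes, 2)")
  out <- c(intercept_only = "1")
  preds <- c("stream", if (session == "wake") "group")
  # main-effect sets: any subset of {stream, group}, with or without one
  # MINUTES encoding
  main_sets <- list(character(0))
  for (p in preds)
    main_sets <- c(main_sets, lapply(main_sets, function(s) c(s, p)))
  for (mains in main_sets) {
    for (enc in c(NA, names(minutes_terms))) {
      labels <- c(mains, if (!is.na(enc)) paste0("minutes_", enc))
      terms <- c(mains, if (!is.na(enc)) minutes_terms[[enc]])
      if (!length(terms)) next
      base_label <- paste(labels, collapse = "+")
      # hierarchy-closed interaction subsets: any set of 2-way
      # interactions, plus the 3-way when all its 2-ways are present
      m <- length(terms)
      two_way <- if (m >= 2) utils::combn(m, 2, simplify = FALSE) else list()
      int_sets <- list(integer(0))
      for (k in seq_along(two_way))
        int_sets <- c(int_sets, lapply(int_sets, function(s) c(s, k)))
      for (is2 in int_sets) {
        variants <- list(list(two = is2, three = FALSE))
        if (m == 3 && length(is2) == 3)
          variants <- c(variants, list(list(two = is2, three = TRUE)))
        for (v in variants) {
          ints <- vapply(two_way[v$two], function(ix)
            paste(terms[ix], collapse = ":"), "")
          if (v$three) ints <- c(ints, paste(terms, collapse = ":"))
          rhs <- paste(c(terms, ints), collapse = " + ")
          lbl <- if (length(v$two) || v$three)
            paste0(base_label, "_ix",
                   paste(v$two, collapse = ""), if (v$three) "x3")
          else base_label
          out[lbl] <- rhs
        }
      }
    }
  }
  out
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = AIC + 2k(k+1)/(n - k - 1)` with `k` the number of estimated
#' parameters (fixed effects + variance components) and `n` the number of
#' observations.
#'
#' @param fit A fitted model with `logLik` and `nobs` methods, or a
#'   `logLik` object.
#' @param k,n Optional overrides for the parameter and observation counts.
#' @return AICc value.
#' @export
aicc <- function(fit, k = NULL, n = NULL) {
  ll <- if (inherits(fit, "logLik")) fit else stats::logLik(fit)
  k <- k %||% attr(ll, "df")
  n <- n %||% tryCatch(stats::nobs(fit), error = function(e) attr(ll, "nobs"))
  if (is.null(n)) stop_invalid("cannot determine the number of observations")
  if (n - k - 1 <= 0) return(Inf)
  as.numeric(-2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1))
}

fit_lmm <- function(fixed_rhs, random, data, reml) {
  f <- stats::as.formula(paste("snr ~", fixed_rhs, "+", random))
  withCallingHandlers(
    lme4::lmer(f, data = data, REML = reml,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage")
  )
}

#' Two-step AICc model selection for temporal dynamics
#'
#' Step 1 selects the covariance (random-effect) structure: the saturated
#' fixed model (all categorical predictors and their interactions) is fit
#' under REML for each candidate random structure, and the structure with
#' the smallest AICc wins. Step 2 fixes that structure, fits every
#' candidate fixed-effect model under ML, and selects the smallest AICc.
#' Candidates that fail to converge are dropped with a warning; singular
#' fits are flagged. The selected model is refit with lmerTest to obtain
#' Satterthwaite p-values for its fixed effects.
#'
#' @param table A dynamics table from [cohort_dynamics()] (columns
#'   `subject`, `minutes`, `stream`, `snr`, and `group` for wake).
#' @param session `"sleep"` or `"wake"`.
#' @return An `lmm_result`: list with `selected_random`, `selected_fixed`
#'   (labels), `random_aicc` and `fixed_aicc` tables, `coefficients`
#'   (estimate, SE, df, t, p), `model` (the lmerTest fit), `singular`.
#' @export
select_lmm <- function(table, session = c("sleep", "wake")) {
  session <- match.arg(session)
  stopifnot(all(c("subject", "minutes", "stream", "snr") %in% names(table)))
  if (session == "wake" && !"group" %in% names(table))
    stop_invalid("wake-session selection needs a 'group' column")
  table$subject <- factor(table$subject)
  saturated <- if (session == "wake")
    "stream * factor(minutes) * group" else "stream * factor(minutes)"

  rand <- candidate_random_structures()
  rand_aicc <- rep(NA_real_, length(rand)); names(rand_aicc) <- names(rand)
  for (r in names(rand)) {
    fit <- tryCatch(fit_lmm(saturated, rand[[r]], table, reml = TRUE),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("random structure '%s' failed to converge; dropped", r))
      next
    }
    rand_aicc[r] <- aicc(fit)
  }
  if (all(is.na(rand_aicc))) stop_invalid("no random structure converged")
  selected_random <- names(which.min(rand_aicc))

  fixed <- candidate_fixed_models(session)
  fixed_aicc <- rep(NA_real_, length(fixed)); names(fixed_aicc) <- names(fixed)
  for (f in names(fixed)) {
    fit <- tryCatch(fit_lmm(fixed[[f]], rand[[selected_random]], table,
                            reml = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("fixed model '%s' failed to converge; dropped", f))
      next
    }
    fixed_aicc[f] <- aicc(fit)
  }
  if (all(is.na(fixed_aicc))) stop_invalid("no fixed-effect model converged")
  selected_fixed <- names(which.min(fixed_aicc))

  final <- withCallingHandlers(
    lmerTest::lmer(stats::as.formula(paste("snr ~", fixed[[selected_fixed]],
                                           "+", rand[[selected_random]])),
                   data = table, REML = FALSE),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage"))
  co <- stats::coef(summary(final))
  coefs <- data.frame(term = rownames(co),
                      estimate = co[, "Estimate"],
                      se = co[, "Std. Error"],
                      df = co[, "df"],
                      t = co[, "t value"],
                      p = co[, "Pr(>|t|)"],
                      row.names = NULL)
  structure(list(selected_random = selected_random,
                 selected_fixed = selected_fixed,
                 random_aicc = rand_aicc, fixed_aicc = fixed_aicc,
                 coefficients = coefs, model = final,
                 singular = lme4::isSingular(final)),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("<lmm_result> random: %s | fixed: %s%s\n",
              x$selected_random, x$selected_fixed,
              if (x$singular) " (singular fit)" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Export an LMM selection result as JSON
#'
#' @param x An `lmm_result`.
#' @param path Output path.
#' @return The list written, invisibly.
#' @export
write_lmm_result <- function(x, path) {
  out <- list(selected_random = x$selected_random,
              selected_fixed = x$selected_fixed,
              random_aicc = as.list(x$random_aicc),
              fixed_aicc = as.list(x$fixed_aicc),
              coefficients = x$coefficients,
              singular = x$singular)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
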