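# Scoring of the 2AFC recognition test and the frequentist and Bayesian
# analyses against chance level.

#' Score a 2AFC response sheet
#'
#' A correct response is the recognition of the tritone belonging to the
#' exposed (STAT) set. Responses are given as the chosen interval per
#' trial (1 = first tritone of the pair, 2 = second); the key's
#' `stat_first` flag determines correctness.
#'
#' @param responses Integer vector of 1/2, one per trial, in the key's
#'   trial order.
#' @param key An `afc_test` from [build_2afc_test()].
#' @param subject,group Optional identifiers carried into the result.
#' @return An `afc_result`: list with `n_correct`, `n_trials`, `percent`,
#'   `correct` (per-trial logical), `subject`, `group`.
#' @export
score_2afc <- function(responses, key, subject = NA, group = NA) {
  stopifnot(inherits(key, "afc_test"))
  if (length(responses) != nrow(key))
    stop_invalid("expected %d responses, got %d", nrow(key), length(responses))
  if (!all(responses %in% c(1L, 2L)))
    stop_invalid("responses must be 1 (first) or 2 (second)")
  correct <- (responses == 1L) == key$stat_first
  n <- nrow(key)
  structure(list(n_correct = sum(correct), n_trials = n,
                 percent = sum(correct) / n * 100,
                 correct = correct, subject = subject, group = group),
            class = "afc_result")
}

#' @export
print.afc_result <- function(x, ...) {
  cat(sprintf("<afc_result> %d/%d correct = %.1f%%\n",
              x$n_correct, x$n_trials, x$percent))
  invisible(x)
}

#' One-sample Wilcoxon signed-rank test against chance
#'
#' Tests recognition percentages against the 50% chance level with the
#' one-sample signed-rank test (scores exactly at 50 drop out, per the
#' signed-rank convention); `V` is the sum of positive ranks.
#'
#' @param scores Percent scores.
#' @param mu Chance level (50).
#' @param ... Passed to [stats::wilcox.test()] (e.g. `alternative`).
#' @return List with `V`, `p`, and the underlying `htest`.
#' @export
wilcoxon_vs_chance <- function(scores, mu = 50, ...) {
  if (!length(scores)) stop_invalid("no scores")
  if (all(scores == mu))
    stop_invalid("all scores equal chance level: the signed-rank test is undefined")
  ht <- suppressWarnings(stats::wilcox.test(scores, mu = mu, ...))
  list(V = unname(ht$statistic), p = ht$p.value, htest = ht)
}

#' Independent two-group Wilcoxon (Mann-Whitney) test
#'
#' Rank-sum comparison of recognition scores between two groups, ties
#' mid-ranked.
#'
#' @param a,b Percent scores of the two groups.
#' @param ... Passed to [stats::wilcox.test()].
#' @return List with `W`, `p`, and the underlying `htest`.
#' @export
mann_whitney_groups <- function(a, b, ...) {
  if (!length(a) || !length(b)) stop_invalid("both groups must be non-empty")
  ht <- suppressWarnings(stats::wilcox.test(a, b, ...))
  list(W = unname(ht$statistic), p = ht$p.value, htest = ht)
}

# JZS integrand: marginal likelihood of the data under a Cauchy(0, r)
# prior on the standardized effect size, expressed through the
# noncentral-t density of the observed t statistic.
jzs_bf10_t <- function(t, n, r, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  df <- n - 1
  h1 <- function(delta)
    stats::dt(t, df, ncp = delta * sqrt(n)) * stats::dcauchy(delta, 0, r)
  # noncentral-t tail warnings ('full precision...') are benign here
  num <- suppressWarnings(
    if (alternative == "two.sided")
      stats::integrate(h1, -Inf, Inf, rel.tol = 1e-9,
                       stop.on.error = FALSE)$value
    else  # one-sided: prior truncated to delta > 0 (doubled half-Cauchy)
      2 * stats::integrate(h1, 0, Inf, rel.tol = 1e-9,
                           stop.on.error = FALSE)$value)
  num / stats::dt(t, df)
}

#' JZS Bayes factor for a one-sample t-test
#'
#' Jeffreys-Zellner-Siow Bayes factor comparing H1 (standardized effect
#' size delta ~ Cauchy(0, `prior_scale`)) against H0 (delta = 0), by
#' numerical integration of the noncentral-t marginal likelihood. The
#' default prior scale is the conventional sqrt(2)/2 of common Bayesian
#' t-test software. The verdict uses the conventional thresholds: BF10 > 3
#' substantial evidence for H1, BF10 < 1/3 substantial evidence for H0,
#' in between inconclusive.
#'
#' @param scores Sample values (e.g. percent scores).
#' @param null_value Value under H0 (50 for chance level).
#' @param prior_scale Cauchy prior scale r.
#' @param alternative `"greater"` (one-sided, effect above the null value;
#'   default, matching a directional learning hypothesis) or
#'   `"two.sided"`.
#' @return A `bayes_report`: list with `bf10`, `t`, `n`, `prior_scale`,
#'   `alternative`, `verdict`.
#' @export
jzs_bf_one_sample <- function(scores, null_value = 50,
                              prior_scale = sqrt(2) / 2,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(scores)
  if (n < 2) stop_invalid("need at least 2 observations")
  if (stats::sd(scores) < .Machine$double.eps)
    stop_invalid("degenerate (zero-variance) scores")
  t <- (mean(scores) - null_value) / (stats::sd(scores) / sqrt(n))
  bf10 <- jzs_bf10_t(t, n, prior_scale, alternative)
  structure(list(bf10 = bf10, t = t, n = n, prior_scale = prior_scale,
                 alternative = alternative, verdict = bf_verdict(bf10)),
            class = "bayes_report")
}

#' JZS Bayes factor for an independent-samples t-test
#'
#' Same construction as [jzs_bf_one_sample()] with the two-sample t
#' statistic (pooled variance) and effective sample size
#' `n1 n2 / (n1 + n2)`.
#'
#' @param a,b The two samples.
#' @param prior_scale Cauchy prior scale r.
#' @param alternative `"two.sided"` (default for group differences) or
#'   `"greater"` (a above b).
#' @return A `bayes_report`.
#' @export
jzs_bf_independent <- function(a, b, prior_scale = sqrt(2) / 2,
                               alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop_invalid("need at least 2 observations per group")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  if (sp2 < .Machine$double.eps) stop_invalid("degenerate variance")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  neff <- n1 * n2 / (n1 + n2)
  h1 <- function(delta)
    stats::dt(t, df, ncp = delta * sqrt(neff)) *
      stats::dcauchy(delta, 0, prior_scale)
  num <- suppressWarnings(
    if (alternative == "two.sided")
      stats::integrate(h1, -Inf, Inf, rel.tol = 1e-9,
                       stop.on.error = FALSE)$value
    else 2 * stats::integrate(h1, 0, Inf, rel.tol = 1e-9,
                              stop.on.error = FALSE)$value)
  bf10 <- num / stats::dt(t, df)
  structure(list(bf10 = bf10, t = t, n = c(n1, n2),
                 prior_scale = prior_scale, alternative = alternative,
                 verdict = bf_verdict(bf10)),
            class = "bayes_report")
}

#' Evidence verdict from a Bayes factor
#'
#' @param bf10 Bayes factor for H1 over H0.
#' @return `"supports H1"` (BF10 > 3), `"supports H0"` (BF10 < 1/3), or
#'   `"inconclusive"`.
#' @export
bf_verdict <- function(bf10) {
  stopifnot(bf10 > 0)
  if (bf10 > 3) "supports H1"
  else if (bf10 < 1 / 3) "supports H0"
  else "inconclusive"
}

#' @export
print.bayes_report <- function(x, ...) {
  cat(sprintf("<bayes_report> BF10 = %.3g (t = %.2f, r = %.3f, %s): %s\n",
              x$bf10, x$t, x$prior_scale, x$alternative, x$verdict))
  invisible(x)
}

#' Simulate 2AFC responders
#'
#' Draws per-trial choices with a fixed probability of choosing the STAT
#' member (0.5 = chance-level responder) and scores them against the key.
#'
#' @param key An `afc_test`.
#' @param n_subjects Number of simulated responders.
#' @param p_correct Probability of choosing the STAT tritone on a trial.
#' @param seed Seed.
#' @param group Group label attached to each result.
#' @return List of `afc_result`s.
#' @export
simulate_2afc_cohort <- function(key, n_subjects, p_correct = 0.5,
                                 seed = NULL, group = NA) {
  seeds <- derive_seeds(seed %||% stats::runif(1, 1, 1e6), n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    resp <- with_seed(seeds[i], {
      pick_stat <- stats::runif(nrow(key)) < p_correct
      ifelse(pick_stat == key$stat_first, 1L, 2L)
    })
    score_2afc(resp, key, subject = i, group = group)
  })
}
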