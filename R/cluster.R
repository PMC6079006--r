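# Nonparametric Monte-Carlo cluster-based permutation tests over sensor
# topographies, and sensor-of-interest (SOI) selection rules.

# paired t statistics for all sign-flip assignments at once.
# d: subjects x chipsets matrix; signs: n_perm x subjects (+/-1).
# Sign flips leave sum(d^2) untouched, so t can be vectorized:
# t = mean / (sd/sqrt(n)),  sd^2 = (q - mean^2) * n/(n-1),  q = mean(d^2).
flip_t_matrix <- function(d, signs) {
  n <- nrow(d)
  m <- (signs %*% d) / n
  q <- matrix(colMeans(d^2), nrow(signs), ncol(d), byrow = TRUE)
  v <- (q - m^2) * n / (n - 1)
  v[v < .Machine$double.eps] <- NA_real_
  m / sqrt(v / n)
}

# connected components of the suprathreshold set under an adjacency list;
# returns a list of integer vectors (chipset indices)
supra_clusters <- function(supra, adj_list) {
  idx <- which(supra)
  if (!length(idx)) return(list())
  seen <- logical(length(supra))
  out <- list()
  for (s in idx) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- adj_list[[v]]
      nb <- nb[supra[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

max_cluster_mass <- function(tvals, thresh, adj_list, mass = c("maxsum", "size")) {
  mass <- match.arg(mass)
  supra <- !is.na(tvals) & tvals >= thresh
  cl <- supra_clusters(supra, adj_list)
  if (!length(cl)) return(0)
  max(vapply(cl, function(ix)
    if (mass == "maxsum") sum(tvals[ix]) else length(ix), 0))
}

#' Paired cluster-based permutation test on sensor topographies
#'
#' The Maris-Oostenveld construction: a paired t statistic per chipset
#' (condition A minus B), suprathreshold chipsets (one-sided t above the
#' `cluster_alpha` quantile of t with n-1 degrees of freedom) grouped by
#' spatial adjacency, cluster mass summed over the cluster, and a
#' Monte-Carlo null from random within-subject condition swaps
#' (sign flips). The direction is one-sided, A greater than B (in the
#' study design, STAT greater than RDM). The plus-one estimator keeps
#' p strictly positive.
#'
#' @param topoA,topoB Subjects x chipsets matrices of per-subject
#'   topographies under the two conditions (same subject order).
#' @param array A `sensor_array` providing the neighbour graph.
#' @param n_perm Number of Monte-Carlo permutations.
#' @param cluster_alpha One-sided cluster-forming alpha.
#' @param mass Cluster statistic: `"maxsum"` (sum of t, default) or
#'   `"size"` (chipset count).
#' @param seed Seed for the permutation draw.
#' @return A `cluster_result`: list with `clusters` (each with `chipsets`,
#'   `mass`, `p`), `t`, `threshold`, `n_perm`, `cluster_alpha`,
#'   `null_max_mass`.
#' @export
paired_cluster_test <- function(topoA, topoB, array, n_perm = 10000,
                                cluster_alpha = 0.05,
                                mass = c("maxsum", "size"), seed = NULL) {
  mass <- match.arg(mass)
  stopifnot(is.matrix(topoA), is.matrix(topoB))
  if (!identical(dim(topoA), dim(topoB)))
    stop_invalid("condition matrices must share subjects and chipsets")
  n <- nrow(topoA)
  if (n < 2) stop_invalid("need at least 2 subjects")
  d <- topoA - topoB
  sds <- apply(d, 2, stats::sd)
  if (all(sds < .Machine$double.eps))
    return(structure(list(clusters = list(), t = rep(0, ncol(d)),
                          threshold = stats::qt(1 - cluster_alpha, n - 1),
                          n_perm = n_perm, cluster_alpha = cluster_alpha,
                          null_max_mass = rep(0, n_perm), mass = mass),
                     class = "cluster_result"))
  thresh <- stats::qt(1 - cluster_alpha, n - 1)
  adj_list <- apply(array$neighbours, 1, which, simplify = FALSE)
  tobs <- as.vector(flip_t_matrix(d, matrix(1, 1, n)))
  obs_cl <- supra_clusters(!is.na(tobs) & tobs >= thresh, adj_list)
  obs_mass <- vapply(obs_cl, function(ix)
    if (mass == "maxsum") sum(tobs[ix]) else length(ix), 0)

  signs <- with_seed(seed,
                     matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                            n_perm, n))
  tp <- flip_t_matrix(d, signs)
  null_max <- vapply(seq_len(n_perm), function(k)
    max_cluster_mass(tp[k, ], thresh, adj_list, mass), 0)

  clusters <- lapply(seq_along(obs_cl), function(j) {
    list(chipsets = obs_cl[[j]], mass = obs_mass[j],
         p = (1 + sum(null_max >= obs_mass[j])) / (1 + n_perm))
  })
  ord <- order(vapply(clusters, `[[`, 0, "mass"), decreasing = TRUE)
  structure(list(clusters = clusters[ord], t = tobs, threshold = thresh,
                 n_perm = n_perm, cluster_alpha = cluster_alpha,
                 null_max_mass = null_max, mass = mass),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), threshold t >= %.3f, %d permutations\n",
              length(x$clusters), x$threshold, x$n_perm))
  for (cl in x$clusters)
    cat(sprintf("  %2d chipsets, mass %.2f, p = %.4f\n",
                length(cl$chipsets), cl$mass, cl$p))
  invisible(x)
}

#' Significant clusters of a cluster test
#'
#' @param x A `cluster_result`.
#' @param alpha Significance level on the Monte-Carlo cluster p.
#' @return The subset of clusters with `p <= alpha`.
#' @export
significant_clusters <- function(x, alpha = 0.05) {
  Filter(function(cl) cl$p <= alpha, x$clusters)
}

#' One-sample permutation test against baseline per chipset (SOI rule)
#'
#' Per-chipset sign-flip permutation test of mean(SNR - baseline) > 0,
#' uncorrected, as used to select sensors of interest: sensors whose
#' tritone SNR is significantly above the no-response baseline of 1.
#'
#' @param topos Subjects x chipsets matrix of SNR topographies.
#' @param baseline Baseline value (1 for SNR).
#' @param n_perm Number of permutations.
#' @param alpha Uncorrected alpha.
#' @param seed Seed.
#' @return List: `mask` (logical per chipset), `p` (per chipset),
#'   `mean` (group-mean topography).
#' @export
one_sample_soi_test <- function(topos, baseline = 1, n_perm = 10000,
                                alpha = 0.05, seed = NULL) {
  stopifnot(is.matrix(topos), nrow(topos) >= 2)
  d <- topos - baseline
  n <- nrow(d)
  obs <- colMeans(d)
  signs <- with_seed(seed,
                     matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                            n_perm, n))
  perm_means <- (signs %*% d) / n
  p <- (1 + colSums(perm_means >= matrix(obs, n_perm, ncol(d), byrow = TRUE))) /
    (1 + n_perm)
  list(mask = p <= alpha, p = p, mean = colMeans(topos))
}

#' Threshold rule for sensors of interest
#'
#' `values > threshold` on a group-mean topography, e.g. tone SNR above 5
#' (wake) or 2 (sleep) during the first minutes of random streams, or the
#' tritone SNR above 1.25 shortcut.
#'
#' @param values Group-mean topography (numeric per chipset).
#' @param threshold SNR threshold.
#' @return Logical mask per chipset.
#' @export
threshold_soi <- function(values, threshold) {
  as.vector(values > threshold)
}

#' Export a cluster result as JSON
#'
#' @param x A `cluster_result`.
#' @param path Output path.
#' @return The list written, invisibly.
#' @export
write_cluster_result <- function(x, path) {
  out <- list(
    n_perm = x$n_perm, cluster_alpha = x$cluster_alpha,
    threshold = x$threshold, mass = x$mass,
    clusters = lapply(x$clusters, function(cl)
      list(chipsets = cl$chipsets, mass = cl$mass, p = cl$p))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
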