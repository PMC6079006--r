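# Shared fixtures, built in code at test time.

# A bare power_spectrum object with prescribed power values, for testing
# spectral operators against hand-computable inputs.
toy_power_spectrum <- function(power, freqs, resolution = diff(freqs[1:2]),
                               kind = "combined") {
  if (is.null(dim(power))) power <- matrix(power, 1)
  structure(list(freqs = freqs, power = power, resolution = resolution,
                 channels = NULL, array = NULL, kind = kind,
                 window = "none"),
            class = "power_spectrum")
}

# Brute-force SNR oracle: literal loop over bins and neighbours,
# independent of the package's cumulative-sum implementation.
snr_oracle <- function(power, n_neighbors, n_skip) {
  half <- n_neighbors / 2
  nb <- ncol(power)
  out <- matrix(NA_real_, nrow(power), nb)
  for (i in seq_len(nb)) {
    idx <- c(seq(i - n_skip - half, i - n_skip - 1),
             seq(i + n_skip + 1, i + n_skip + half))
    idx <- idx[idx >= 1 & idx <= nb]
    if (!length(idx)) next
    for (ch in seq_len(nrow(power)))
      out[ch, i] <- power[ch, i] / mean(power[ch, idx])
  }
  out
}

# Exhaustive sign-flip enumeration of the paired cluster test null for
# small n: returns the max-cluster-mass distribution over all 2^n flips.
exhaustive_max_masses <- function(d, array, cluster_alpha = 0.05) {
  n <- nrow(d)
  thresh <- qt(1 - cluster_alpha, n - 1)
  adj_list <- apply(array$neighbours, 1, which, simplify = FALSE)
  masses <- numeric(2^n)
  for (code in 0:(2^n - 1)) {
    signs <- ifelse(bitwAnd(code, 2^(0:(n - 1))) > 0, 1, -1)
    ds <- d * signs
    m <- colMeans(ds)
    s <- apply(ds, 2, sd)
    t <- m / (s / sqrt(n))
    t[!is.finite(t)] <- NA
    supra <- !is.na(t) & t >= thresh
    cl <- freqtag:::supra_clusters(supra, adj_list)
    masses[code + 1] <-
      if (length(cl)) max(vapply(cl, function(ix) sum(t[ix]), 0)) else 0
  }
  masses
}

# A tiny cached sensor array shared across test files.
test_array <- local({
  arr <- NULL
  function() {
    if (is.null(arr)) arr <<- make_sensor_array()
    arr
  }
})
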