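#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers do not disturb
#' the caller's RNG stream. Used by every generator in the package.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive per-unit child seeds from a master seed
#'
#' Counter scheme: the master seed seeds R's RNG once, and `n` child seeds
#' are drawn as integers below 2^31. Deterministic and extensible: the
#' first `k` children do not change when `n` grows.
#'
#' @param master Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max, n))
}

#' 32-bit FNV-1a hash of a character string
#'
#' Lightweight provenance tag written into output-file headers so that
#' mixed-provenance result bundles are detectable. Not cryptographic.
#'
#' @param x Character scalar.
#' @return Hex string of 8 characters.
#' @keywords internal
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 0x811c9dc5
  for (b in bytes) {
    # xor only touches the low byte (b < 256); done in doubles since h
    # can exceed the signed 32-bit range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit multiply by FNV prime 16777619, split into 16-bit halves so
    # every intermediate stays exactly representable in a double
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
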