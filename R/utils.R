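## Internal helpers shared across modules.

#' Derive a reproducible substream seed from a global seed and a stage label
#'
#' A single global seed is expanded into named substreams so that each
#' simulation stage (manifest, sample design, noise, ...) and each pipeline
#' stage draws from its own stream. The result always fits in a 32-bit
#' integer.
#' @noRd
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647L)
}

#' Dirichlet sampler via normalized gamma variates
#' @param n number of draws
#' @param alpha concentration vector
#' @return n x length(alpha) matrix, rows sum to 1
#' @noRd
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Stop unless a condition holds, with a formatted message
#' @noRd
check_that <- function(ok, ...) {
  if (!ok) abort(sprintf(...))
  invisible(TRUE)
}

#' Percentage helper used by rate reporters; returns NA_real_ (the
#' "undefined" marker) on a zero denominator rather than 0.
#' @noRd
pct_of <- function(k, n) {
  out <- 100 * k / n
  out[rep_len(!(n > 0), length(out))] <- NA_real_
  out
}
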