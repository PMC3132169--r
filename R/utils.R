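# Internal helpers shared across modules.

#' Round half-up to a fixed number of decimals
#'
#' Percentages in reports are rounded half-up (5 rounds away from zero),
#' i.e. the convention of printed tables, not base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Derive a reproducible sub-seed from a global seed and a tag
#'
#' All stochastic generators in the package draw their RNG state from one
#' global seed; each stage uses a tagged sub-seed so that adding a stage
#' never perturbs the streams of the others.
#'
#' @param seed integer global seed.
#' @param tag character tag naming the consumer.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

# Truncated-normal sampling by inverse-CDF (deterministic given RNG state).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (lower > upper) stop("lower bound exceeds upper bound")
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  pa <- pnorm(lower, mean, sd)
  pb <- pnorm(upper, mean, sd)
  qnorm(runif(n, pa, pb), mean, sd)
}

# Reverse-complement of a plain character string (ACGTN).
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a 4-vector of base frequencies (A, C, G, T order).
check_base_freqs <- function(base_freqs) {
  if (length(base_freqs) != 4 || any(base_freqs < 0) ||
      abs(sum(base_freqs) - 1) > 1e-9) {
    stop("base_freqs must be 4 non-negative probabilities summing to 1")
  }
  invisible(base_freqs)
}
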