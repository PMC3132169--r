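# Library coverage mathematics: the Clarke-Carbon equation, recovery
# probability, fold coverage with contamination accounting, and exact
# binomial contamination rates.

#' Clarke-Carbon clone count
#'
#' Number of clones `N = ln(1-P) / ln(1 - I/GS)` required to recover any
#' given locus with probability `P` from a library of random inserts of
#' size `I` drawn from a genome of size `GS`.
#'
#' @param P target recovery probability, in `(0, 1)`.
#' @param I mean insert size (bp).
#' @param GS genome size (bp).
#' @return the (real-valued) clone count `N`.
#' @examples
#' clarke_carbon_clones(0.99, 135e3, 740e6)
#' @export
clarke_carbon_clones <- function(P, I, GS) {
  if (!(P > 0 && P < 1)) stop("P must be in (0, 1)")
  if (!(I > 0 && I < GS)) stop("require 0 < I < GS")
  log(1 - P) / log(1 - I / GS)
}

#' Probability of recovering a locus from a clone library
#'
#' Inverse of the Clarke-Carbon relation: `P = 1 - (1 - I/GS)^N`.
#'
#' @param N clone count (>= 0).
#' @param I mean insert size (bp).
#' @param GS genome size (bp).
#' @return recovery probability in `[0, 1)`.
#' @export
recovery_probability <- function(N, I, GS) {
  if (N < 0) stop("N must be >= 0")
  if (!(I > 0 && I < GS)) stop("require 0 < I < GS")
  # log1p keeps full precision when I/GS is tiny
  -expm1(N * log1p(-I / GS))
}

#' Parameters of a clone library
#'
#' @param N clone count.
#' @param I mean insert size (bp).
#' @param GS genome size (bp).
#' @param empty_fraction fraction of clones without insert.
#' @param organelle_fraction fraction of clones carrying organelle DNA.
#' @return an object of class `"library_params"`.
#' @export
library_params <- function(N, I, GS, empty_fraction = 0,
                           organelle_fraction = 0) {
  stopifnot(N >= 0, I > 0, I < GS,
            empty_fraction >= 0, empty_fraction <= 1,
            organelle_fraction >= 0, organelle_fraction <= 1)
  structure(list(N = N, I = I, GS = GS,
                 empty_fraction = empty_fraction,
                 organelle_fraction = organelle_fraction),
            class = "library_params")
}

#' Effective fold coverage (genome equivalents) of a library
#'
#' Empty and organelle clones contribute no nuclear coverage, so the
#' effective clone count is discounted by both fractions before dividing
#' the cloned bases by the genome size:
#' `N * (1 - empty) * (1 - organelle) * I / GS`.
#'
#' @param params a [library_params()].
#' @return fold coverage (real).
#' @export
coverage_depth <- function(params) {
  stopifnot(inherits(params, "library_params"))
  if (params$GS == 0) stop("genome size must be positive")
  params$N * (1 - params$empty_fraction) *
    (1 - params$organelle_fraction) * params$I / params$GS
}

#' Contamination rate with exact binomial confidence interval
#'
#' Point estimate `100 * positives / screened` (half-up rounded to 1
#' decimal) with a Clopper-Pearson 95% interval.
#'
#' @param positives positive clones in the screen.
#' @param screened clones screened.
#' @param conf_level confidence level (default 0.95).
#' @return a list: `percent`, `ci_lower`, `ci_upper` (all percentages),
#'   `positives`, `screened`.
#' @examples
#' contamination_rate(22, 984)  # 2.2%
#' @export
contamination_rate <- function(positives, screened, conf_level = 0.95) {
  if (screened <= 0) stop("no clones screened: rate undefined")
  stopifnot(positives >= 0, positives <= screened)
  ci <- binom.test(positives, screened, conf.level = conf_level)$conf.int
  list(percent = round_half_up(100 * positives / screened, 1),
       ci_lower = 100 * ci[1], ci_upper = 100 * ci[2],
       positives = positives, screened = screened)
}
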