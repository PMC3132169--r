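# Mate-pair microsynteny classification against a reference genome.
#
# Category hierarchy (each implies the previous):
#   no_hit < single_end < paired_end < colocalized < {gapped | non_gapped}
#   and non_gapped splits into {collinear | rearranged}.

SYNTENY_CATEGORIES <- c("no_hit", "single_end", "paired_end",
                        "colocalized", "gapped", "non_gapped",
                        "collinear", "rearranged")

#' Microsynteny span bounds
#'
#' @param min_span minimum mate-pair span on the reference (bp, default
#'   15000).
#' @param max_span maximum span (bp, default 250000). Bounds are
#'   inclusive.
#' @return an object of class `"synteny_params"`.
#' @export
synteny_params <- function(min_span = 15000, max_span = 250000) {
  stopifnot(min_span > 0, min_span < max_span)
  structure(list(min_span = min_span, max_span = max_span),
            class = "synteny_params")
}

#' Are two mate hits correctly oriented?
#'
#' BAC end reads face inward, so a pair maps consistently iff the two
#' hits are on opposite strands and the plus-strand hit lies 5' (lower
#' reference coordinate) of the minus-strand hit.
#'
#' @param hit_f,hit_r one-row hit tables (forward/reverse read hits) on
#'   the same target sequence.
#' @return `TRUE` or `FALSE`.
#' @export
orientation_consistent <- function(hit_f, hit_r) {
  if (hit_f$subject_id != hit_r$subject_id) {
    stop("hits are on different target sequences")
  }
  if (hit_f$subject_strand == hit_r$subject_strand) return(FALSE)
  plus <- if (hit_f$subject_strand == "+") hit_f else hit_r
  minus <- if (hit_f$subject_strand == "-") hit_f else hit_r
  plus$s_start < minus$s_start
}

#' Classify one BES mate pair against a reference hit table
#'
#' Rules, applied in order: both hit lists empty gives `no_hit`; exactly
#' one non-empty gives `single_end`; both non-empty gives at least
#' `paired_end`; if any (forward, reverse) combination lies on the same
#' target sequence the pair is `colocalized`; among colocalized
#' combinations, if any has span within `[min_span, max_span]` the pair
#' is `non_gapped` (else `gapped`); a non-gapped pair is `collinear` if
#' its best in-range combination is orientation-consistent, else
#' `rearranged`. Span is `max(end coordinates) - min(start coordinates)`
#' over the two hits; the best combination maximizes summed hit lengths
#' (ties broken by lowest target coordinate).
#'
#' @param hits_f,hits_r hit tables for the forward and reverse read
#'   (pre-filtered by E-value and window rule as appropriate).
#' @param params a [synteny_params()].
#' @return a list of class `"pair_classification"`: `category`, and for
#'   colocalized pairs `target`, `span`, plus the best combination's row
#'   indices `best_f`, `best_r` when in range.
#' @export
classify_pair <- function(hits_f, hits_r, params = synteny_params()) {
  nf <- if (is.null(hits_f)) 0 else nrow(hits_f)
  nr <- if (is.null(hits_r)) 0 else nrow(hits_r)
  res <- list(category = NA_character_, target = NA_character_,
              span = NA_real_, best_f = NA_integer_, best_r = NA_integer_)
  class(res) <- "pair_classification"
  if (nf == 0 && nr == 0) { res$category <- "no_hit"; return(res) }
  if (nf == 0 || nr == 0) { res$category <- "single_end"; return(res) }
  combos <- expand.grid(f = seq_len(nf), r = seq_len(nr))
  same <- hits_f$subject_id[combos$f] == hits_r$subject_id[combos$r]
  if (!any(same)) { res$category <- "paired_end"; return(res) }
  combos <- combos[same, , drop = FALSE]
  span <- pmax(hits_f$s_end[combos$f], hits_r$s_end[combos$r]) -
    pmin(hits_f$s_start[combos$f], hits_r$s_start[combos$r])
  in_range <- span >= params$min_span & span <= params$max_span
  if (!any(in_range)) {
    res$category <- "gapped"
    res$target <- hits_f$subject_id[combos$f[1]]
    res$span <- span[1]
    return(res)
  }
  cand <- which(in_range)
  len_sum <- (hits_f$q_end[combos$f[cand]] -
                hits_f$q_start[combos$f[cand]] + 1) +
    (hits_r$q_end[combos$r[cand]] - hits_r$q_start[combos$r[cand]] + 1)
  low_coord <- pmin(hits_f$s_start[combos$f[cand]],
                    hits_r$s_start[combos$r[cand]])
  best <- cand[order(-len_sum, low_coord)][1]
  f_row <- combos$f[best]; r_row <- combos$r[best]
  ok <- orientation_consistent(hits_f[f_row, , drop = FALSE],
                               hits_r[r_row, , drop = FALSE])
  res$category <- if (ok) "collinear" else "rearranged"
  res$target <- hits_f$subject_id[f_row]
  res$span <- span[best]
  res$best_f <- f_row; res$best_r <- r_row
  res
}

#' Classify every mate pair of a dataset
#'
#' @param pairs a `"mate_pair_set"` from [pair_reads()].
#' @param hits a hit table covering the paired reads' query ids
#'   (pre-filtered).
#' @param params a [synteny_params()].
#' @return a list of class `"synteny_summary"` with `per_pair` (a
#'   data.frame: `clone_id`, `category`, `target`, `span`) and `counts`
#'   (named vector over categories; `colocalized`, `non_gapped` and
#'   `paired_end` are cumulative, i.e. `colocalized == gapped +
#'   non_gapped` and `non_gapped == collinear + rearranged`).
#' @export
classify_dataset <- function(pairs, hits, params = synteny_params()) {
  pr <- pairs$pairs
  n <- nrow(pr)
  per_pair <- data.frame(clone_id = pr$clone_id,
                         category = character(n),
                         target = NA_character_, span = NA_real_,
                         stringsAsFactors = FALSE)
  by_query <- if (nrow(hits) > 0) split(seq_len(nrow(hits)),
                                        hits$query_id) else list()
  for (i in seq_len(n)) {
    hf <- hits[by_query[[pr$forward_id[i]]] %||% integer(), , drop = FALSE]
    hr <- hits[by_query[[pr$reverse_id[i]]] %||% integer(), , drop = FALSE]
    cl <- classify_pair(hf, hr, params)
    per_pair$category[i] <- cl$category
    per_pair$target[i] <- cl$target
    per_pair$span[i] <- cl$span
  }
  leaf <- table(factor(per_pair$category, levels = SYNTENY_CATEGORIES))
  counts <- c(
    no_hit = unname(leaf["no_hit"]),
    single_end = unname(leaf["single_end"]),
    paired_end = unname(leaf["paired_end"]) + unname(leaf["gapped"]) +
      unname(leaf["non_gapped"]) + unname(leaf["collinear"]) +
      unname(leaf["rearranged"]) + unname(leaf["colocalized"]),
    colocalized = unname(leaf["gapped"]) + unname(leaf["non_gapped"]) +
      unname(leaf["collinear"]) + unname(leaf["rearranged"]) +
      unname(leaf["colocalized"]),
    gapped = unname(leaf["gapped"]),
    non_gapped = unname(leaf["non_gapped"]) + unname(leaf["collinear"]) +
      unname(leaf["rearranged"]),
    collinear = unname(leaf["collinear"]),
    rearranged = unname(leaf["rearranged"]))
  structure(list(per_pair = per_pair, counts = counts),
            class = "synteny_summary")
}
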