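# Repeat statistics: the binomial null model for self-comparison matches,
# repeat density accounting, novel-repeat candidate selection, family
# clustering and genome copy-number extrapolation.

#' Per-pair null match probability
#'
#' Under an i.i.d. background model, the probability that a given pair of
#' reads shows a `w`-column window with at least
#' `k = ceiling(min_identity * w)` matching positions is approximated by
#' the independence model `p0 = (sum(freq^2))^k`: the per-position match
#' probability raised to the required number of matching positions.
#'
#' @param base_freqs base frequencies (must sum to 1); uniform frequencies
#'   give a per-position match probability of 1/4.
#' @param w window length (default 100).
#' @param min_identity required window identity (default 0.90).
#' @return the null probability `p0` (evaluated in log space).
#' @examples
#' null_match_probability(rep(0.25, 4))  # 0.25^90 = 6.5e-55
#' @export
null_match_probability <- function(base_freqs, w = 100,
                                   min_identity = 0.90) {
  check_base_freqs(base_freqs)
  if (!(min_identity > 0 && min_identity <= 1)) {
    stop("min_identity must be in (0, 1]")
  }
  k <- ceiling(min_identity * w)
  p_match <- sum(base_freqs^2)
  exp(k * log(p_match))
}

#' Null model for repeat calling
#'
#' Bundles the binomial null model used to decide how many self-comparison
#' matches make a read significantly repetitive.
#'
#' @inheritParams null_match_probability
#' @param n_trials number of pairwise comparisons per read (one against
#'   each other read; `n_reads - 1`).
#' @param alpha Type-I error bound (default 0.05).
#' @return a list of class `"null_model"` with `base_freqs`, `w`, `k`,
#'   `p0`, `n_trials`, `alpha`, and the match-count threshold `T`.
#' @export
null_model <- function(base_freqs, n_trials, w = 100, min_identity = 0.90,
                       alpha = 0.05) {
  p0 <- null_match_probability(base_freqs, w, min_identity)
  T <- match_count_threshold(p0, n_trials, alpha)
  structure(list(base_freqs = base_freqs, w = w,
                 k = as.integer(ceiling(min_identity * w)), p0 = p0,
                 n_trials = as.integer(n_trials), alpha = alpha,
                 threshold = T),
            class = "null_model")
}

#' Match-count threshold for significant repetitiveness
#'
#' Smallest integer `T` such that `P(X >= T) <= alpha` for
#' `X ~ Binomial(n_trials, p0)`. When `n_trials * p0 < 1e-3` the Poisson
#' tail is used (numerically identical at that scale and cheaper).
#'
#' @param p0 per-comparison match probability.
#' @param n_trials number of comparisons.
#' @param alpha Type-I error bound.
#' @return integer threshold `T >= 1`.
#' @examples
#' match_count_threshold(6.5e-55, 19999, 0.05)  # 1: any match is significant
#' match_count_threshold(0.001, 1000, 0.05)     # 4
#' @export
match_count_threshold <- function(p0, n_trials, alpha) {
  stopifnot(p0 >= 0, p0 <= 1, n_trials >= 1, alpha > 0, alpha < 1)
  if (p0 == 0) return(1L)
  upper_tail <- if (n_trials * p0 < 1e-3) {
    function(t) ppois(t - 1, n_trials * p0, lower.tail = FALSE)
  } else {
    function(t) pbinom(t - 1, n_trials, p0, lower.tail = FALSE)
  }
  t <- 1L
  while (upper_tail(t) > alpha) {
    t <- t + 1L
    if (t > n_trials) break
  }
  t
}

#' Repeat density of a sequence set
#'
#' Percentage of nucleotides annotated as repetitive.
#'
#' @param masked_bp repeat-annotated base count.
#' @param total_bp total base count.
#' @return percentage, rounded half-up to 2 decimals.
#' @examples
#' repeat_density(706119, 12018238)  # 5.88
#' @export
repeat_density <- function(masked_bp, total_bp) {
  if (total_bp <= 0) stop("total_bp must be positive")
  stopifnot(masked_bp >= 0, masked_bp <= total_bp)
  round_half_up(100 * masked_bp / total_bp, 2)
}

#' Select novel-repeat candidate reads
#'
#' Reads matching at least `min_matches` distinct other reads (after known
#' repeats have been masked) are candidate members of novel repeat
#' families.
#'
#' @param counts a `"match_counts"` object from [self_match_counts()].
#' @param min_matches candidate threshold (default 6).
#' @return character vector of candidate read ids.
#' @export
candidate_repeats <- function(counts, min_matches = 6) {
  cts <- if (inherits(counts, "match_counts")) counts$counts else counts
  names(cts)[cts >= min_matches]
}

#' Cluster candidate reads into repeat families
#'
#' Single-linkage clustering: candidate reads are nodes, window-passing
#' matches between candidates are edges, families are connected
#' components. Per family, the covered bases are the union of passing-hit
#' spans over member reads (when hit coordinates are available).
#'
#' @param candidates character vector of candidate read ids.
#' @param pairs data.frame of matching pairs (`id_a`, `id_b`), e.g. the
#'   `pairs` element of [self_match_counts()].
#' @param hits optional hit table with `query_id`, `subject_id`,
#'   `q_start`, `q_end`, used to compute per-family covered bp.
#' @return a data.frame of class `"repeat_families"`: `family_id`, `size`
#'   (member reads), `covered_bp` (NA without `hits`), plus a `members`
#'   list-column of read ids. Sorted by decreasing size.
#' @export
cluster_families <- function(candidates, pairs, hits = NULL) {
  out <- data.frame(family_id = character(), size = integer(),
                    covered_bp = integer(), stringsAsFactors = FALSE)
  out$members <- list()
  if (length(candidates) == 0) {
    class(out) <- c("repeat_families", "data.frame")
    return(out)
  }
  keep <- pairs$id_a %in% candidates & pairs$id_b %in% candidates
  g <- igraph::graph_from_data_frame(pairs[keep, , drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = candidates))
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  # drop singleton components (a candidate whose partners were all
  # non-candidates forms no family evidence on its own)
  members <- members[lengths(members) >= 2]
  if (!length(members)) {
    class(out) <- c("repeat_families", "data.frame")
    return(out)
  }
  members <- members[order(-lengths(members))]
  covered <- rep(NA_integer_, length(members))
  if (!is.null(hits)) {
    for (i in seq_along(members)) {
      m <- members[[i]]
      h <- hits[hits$query_id %in% m & hits$subject_id %in% m, ,
                drop = FALSE]
      if (nrow(h) == 0) { covered[i] <- 0L; next }
      spans <- IRanges::IRanges(h$q_start, h$q_end)
      by_read <- split(spans, h$query_id)
      covered[i] <- sum(vapply(by_read, function(x)
        sum(IRanges::width(IRanges::reduce(x))), numeric(1)))
    }
  }
  out <- data.frame(family_id = sprintf("family%03d", seq_along(members)),
                    size = lengths(members), covered_bp = covered,
                    stringsAsFactors = FALSE)
  out$members <- unname(members)
  rownames(out) <- NULL
  class(out) <- c("repeat_families", "data.frame")
  out
}

#' Extrapolate BES repeat copies to the whole genome
#'
#' A family observed `bes_copies` times in a BES sample of `total_bes_bp`
#' bases scales to `round(bes_copies * genome_size_bp / total_bes_bp)`
#' copies genome-wide.
#'
#' @param bes_copies copies observed in the BES set.
#' @param genome_size_bp genome size (bp).
#' @param total_bes_bp total BES base count.
#' @return integer genome copy estimate.
#' @examples
#' extrapolate_copies(119, 740e6, 12018238)  # 7327
#' @export
extrapolate_copies <- function(bes_copies, genome_size_bp, total_bes_bp) {
  if (total_bes_bp <= 0) stop("total_bes_bp must be positive")
  round(bes_copies * genome_size_bp / total_bes_bp)
}

#' Combine known and novel repeat densities
#'
#' @param known_density known-repeat density (percent).
#' @param novel_density novel-repeat density (percent), over the same
#'   denominator.
#' @return a list of class `"repeat_density_report"`: `known_density`,
#'   `novel_density`, `total_density`.
#' @examples
#' total_repeat_accounting(5.88, 3.06)  # total 8.94
#' @export
total_repeat_accounting <- function(known_density, novel_density) {
  if (known_density < 0 || novel_density < 0) {
    stop("densities must be non-negative")
  }
  structure(list(known_density = known_density,
                 novel_density = novel_density,
                 total_density = known_density + novel_density),
            class = "repeat_density_report")
}

#' Window-passing hits among a set of reads
#'
#' Aligns all pairs within `members` with the built-in aligner (ungapped
#' extension) and keeps hits passing the sliding-window rule, for
#' per-family coverage accounting in [cluster_families()]. Hits are
#' returned in both query/subject orientations so per-read coverage
#' unions are complete.
#'
#' @param reads a `"bes_reads"` data.frame.
#' @param members character vector of read ids.
#' @param params an [align_params()].
#' @param w,min_identity sliding-window rule parameters.
#' @return a hit table (possibly empty).
#' @export
within_family_hits <- function(reads, members, params = align_params(),
                               w = 100, min_identity = 0.90) {
  idx <- match(members, reads$read_id)
  idx <- idx[!is.na(idx)]
  out <- list()
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (a >= b) next
      i <- idx[a]; j <- idx[b]
      h <- local_align(reads$sequence[i], reads$sequence[j],
                       params = params, query_id = reads$read_id[i],
                       subject_id = reads$read_id[j], gapped = FALSE)
      if (nrow(h) == 0) next
      pass <- vapply(h$match_vector, function(mv)
        .cpp_window_pass(mv, as.integer(w),
                         as.integer(ceiling(min_identity * w))),
        logical(1))
      h <- h[pass, , drop = FALSE]
      if (nrow(h) == 0) next
      rev <- h
      rev$query_id <- h$subject_id; rev$subject_id <- h$query_id
      rev$q_start <- h$s_start; rev$q_end <- h$s_end
      rev$s_start <- h$q_start; rev$s_end <- h$q_end
      out[[length(out) + 1]] <- rbind(h, rev)
    }
  }
  if (!length(out)) return(empty_hits())
  do.call(rbind, out)
}

#' Read RepeatMasker .out annotations as mask intervals
#'
#' Parses the whitespace-delimited RepeatMasker `.out` format (3 header
#' lines, then one row per annotated interval) into the mask format used
#' by [self_match_counts()].
#'
#' @param path path to a RepeatMasker `.out` file.
#' @return a data.frame: `read_id`, `start`, `end`, `repeat_name`,
#'   `repeat_class`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  lines <- lines[-seq_len(min(3, length(lines)))]
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (!length(lines)) {
    return(data.frame(read_id = character(), start = integer(),
                      end = integer(), repeat_name = character(),
                      repeat_class = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\\s+")
  data.frame(read_id = vapply(fields, `[[`, character(1), 5),
             start = as.integer(vapply(fields, `[[`, character(1), 6)),
             end = as.integer(vapply(fields, `[[`, character(1), 7)),
             repeat_name = vapply(fields, `[[`, character(1), 10),
             repeat_class = vapply(fields, `[[`, character(1), 11),
             stringsAsFactors = FALSE)
}
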