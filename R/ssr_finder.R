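# Perfect microsatellite (SSR) detection: maximal perfect tandem repeats
# with primitive motifs of period 1-6, canonical motif classes, and
# summary statistics.

#' SSR detection parameters
#'
#' Defaults follow the classical survey parameterization for perfect
#' repeats: minimum locus spans of 16 bp for di- and tetranucleotide
#' motifs, 15 bp for tri- and pentanucleotide motifs and 18 bp for
#' hexanucleotide motifs; no imperfections allowed. Mononucleotide runs
#' are detected (they block spurious higher-period calls) but excluded
#' from period 2-6 statistics.
#'
#' @param min_span named vector of minimum locus spans (bp) by period
#'   `"1"`..`"6"`.
#' @param report_mono include mononucleotide loci in the output (default
#'   `FALSE`).
#' @return an object of class `"ssr_params"`.
#' @export
ssr_params <- function(min_span = c("1" = 10, "2" = 16, "3" = 15,
                                    "4" = 16, "5" = 15, "6" = 18),
                       report_mono = FALSE) {
  stopifnot(all(min_span > 0),
            all(as.character(1:6) %in% names(min_span)))
  structure(list(min_span = min_span, report_mono = report_mono),
            class = "ssr_params")
}

#' Find perfect SSRs in a sequence
#'
#' Reports every maximal perfect tandem repetition with a primitive motif
#' of period 1-6 whose span meets the per-period minimum. The trailing
#' copy may be partial (`copies` can be fractional). Runs are broken at
#' `N`. A locus lying entirely inside a locus of smaller period is
#' suppressed, so each position is reported under its smallest period.
#'
#' @param sequence a character string over `{A,C,G,T,N}` (case
#'   insensitive).
#' @param params an [ssr_params()].
#' @param seq_id identifier recorded in the output.
#' @return a data.frame: `seq_id`, `start`, `end` (1-based inclusive),
#'   `period`, `motif`, `canonical_class`, `span`, `copies`.
#' @examples
#' find_perfect_ssrs(strrep("AT", 8))   # one dinucleotide locus
#' find_perfect_ssrs(strrep("AT", 7))   # none: 14 bp is below threshold
#' @export
find_perfect_ssrs <- function(sequence, params = ssr_params(),
                              seq_id = "seq") {
  x <- strsplit(toupper(sequence), "")[[1]]
  n <- length(x)
  loci <- list()
  for (p in 1:6) {
    if (n < p + 1) break
    eq <- x[seq_len(n - p)] == x[seq_len(n - p) + p] &
      x[seq_len(n - p)] != "N" & x[seq_len(n - p) + p] != "N"
    r <- rle(eq)
    ends_eq <- cumsum(r$lengths)
    starts_eq <- ends_eq - r$lengths + 1L
    run_idx <- which(r$values)
    for (k in run_idx) {
      start <- starts_eq[k]
      span <- r$lengths[k] + p
      end <- start + span - 1L
      if (span < params$min_span[[as.character(p)]]) next
      motif <- paste(x[start:(start + p - 1L)], collapse = "")
      if (grepl("N", motif, fixed = TRUE)) next
      if (!is_primitive_motif(motif)) next
      loci[[length(loci) + 1]] <- list(start = start, end = end,
                                       period = p, motif = motif,
                                       span = span)
    }
  }
  if (!length(loci)) return(empty_ssr_table())
  df <- do.call(rbind, lapply(loci, as.data.frame,
                              stringsAsFactors = FALSE))
  # suppress loci fully inside a smaller-period locus
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    inside <- df$period < df$period[i] &
      df$start <= df$start[i] & df$end >= df$end[i]
    if (any(inside)) keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  if (!params$report_mono) df <- df[df$period > 1, , drop = FALSE]
  if (nrow(df) == 0) return(empty_ssr_table())
  out <- data.frame(seq_id = seq_id, start = df$start, end = df$end,
                    period = df$period, motif = df$motif,
                    canonical_class = vapply(df$motif, canonical_class,
                                             character(1)),
                    span = df$span, copies = df$span / df$period,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_ssr_table <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             period = integer(), motif = character(),
             canonical_class = character(), span = integer(),
             copies = numeric(), stringsAsFactors = FALSE)
}

#' Find perfect SSRs in a set of reads
#'
#' @param reads a `"bes_reads"` data.frame (or any data.frame with
#'   `read_id` and `sequence` columns).
#' @param params an [ssr_params()].
#' @return a combined SSR table (see [find_perfect_ssrs()]).
#' @export
find_ssrs_in_reads <- function(reads, params = ssr_params()) {
  res <- lapply(seq_len(nrow(reads)), function(i) {
    find_perfect_ssrs(reads$sequence[i], params,
                      seq_id = reads$read_id[i])
  })
  out <- do.call(rbind, res)
  if (is.null(out)) empty_ssr_table() else out
}

#' Canonical class of an SSR motif
#'
#' The lexicographically smallest string among all rotations of the motif
#' and all rotations of its reverse complement; e.g. `GA`, `TC` and `CT`
#' all canonicalize to `AG`, while `AT` is its own (self-complementary)
#' class.
#'
#' @param motif motif string over `{A,C,G,T}`.
#' @return the canonical class label.
#' @examples
#' canonical_class("TC")   # "AG"
#' canonical_class("GGC")  # "CCG"
#' @export
canonical_class <- function(motif) {
  motif <- toupper(motif)
  if (!nzchar(motif) || grepl("[^ACGT]", motif)) {
    stop("motif must be non-empty over {A,C,G,T}")
  }
  p <- nchar(motif)
  rot <- function(m) {
    vapply(seq_len(p), function(i)
      paste0(substr(m, i, p), substr(m, 1, i - 1)), character(1))
  }
  min(c(rot(motif), rot(revcomp_chr(motif))))
}

#' Summarize an SSR table
#'
#' @param loci an SSR table from [find_perfect_ssrs()] /
#'   [find_ssrs_in_reads()]; only periods 2-6 are summarized.
#' @param total_bp total searched base count.
#' @return a list of class `"ssr_summary"`: `n_ssr`, `by_period` (counts
#'   and percentage by period), `by_class` (counts and within-period
#'   percentage by canonical class), `kb_per_ssr` (total_bp / count in
#'   kb), `per_100kb` (count per 100 kb). Frequencies are `NA` when no
#'   loci are present.
#' @export
ssr_summary <- function(loci, total_bp) {
  if (total_bp <= 0) stop("total_bp must be positive")
  loci <- loci[loci$period >= 2 & loci$period <= 6, , drop = FALSE]
  n <- nrow(loci)
  by_period <- data.frame(period = 2:6,
                          count = vapply(2:6, function(p)
                            sum(loci$period == p), integer(1)))
  by_period$pct <- if (n > 0) {
    round_half_up(100 * by_period$count / n, 2)
  } else NA_real_
  by_class <- if (n > 0) {
    agg <- as.data.frame(table(period = loci$period,
                               class = loci$canonical_class),
                         stringsAsFactors = FALSE)
    agg <- agg[agg$Freq > 0, , drop = FALSE]
    agg$period <- as.integer(agg$period)
    names(agg)[3] <- "count"
    per_count <- by_period$count[match(agg$period, by_period$period)]
    agg$pct_within_period <- round_half_up(100 * agg$count / per_count, 2)
    rownames(agg) <- NULL
    agg
  } else {
    data.frame(period = integer(), class = character(), count = integer(),
               pct_within_period = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(n_ssr = n, by_period = by_period, by_class = by_class,
                 kb_per_ssr = if (n > 0) total_bp / n / 1000 else NA_real_,
                 per_100kb = if (n > 0) n * 1e5 / total_bp else NA_real_,
                 total_bp = total_bp),
            class = "ssr_summary")
}
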