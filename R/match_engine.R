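# Pairwise local alignment: a built-in desk-scale seed-and-extend aligner,
# a reader for 12-column tabular hits from external search tools, the
# 100-bp/90%-identity sliding-window rule, and all-vs-all self-comparison.

#' Alignment parameters for the built-in aligner
#'
#' @param word exact-word seed size (default 11).
#' @param match match score (default +1).
#' @param mismatch mismatch score (default -2).
#' @param gap_open gap opening score (default -5); a gap of length L costs
#'   `|gap_open| + L * |gap_extend|`.
#' @param gap_extend gap extension score (default -2).
#' @param xdrop x-drop bound for ungapped seed extension (default 20).
#' @param min_score minimum reported alignment score (default 28).
#' @return an object of class `"align_params"`.
#' @export
align_params <- function(word = 11, match = 1, mismatch = -2,
                         gap_open = -5, gap_extend = -2,
                         xdrop = 20, min_score = 28) {
  stopifnot(word >= 4, match > 0, mismatch < 0, gap_open <= 0,
            gap_extend <= 0, xdrop > 0, min_score > 0)
  structure(list(word = as.integer(word), match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(abs(gap_open)),
                 gap_extend = as.integer(abs(gap_extend)),
                 xdrop = as.integer(xdrop),
                 min_score = as.integer(min_score)),
            class = "align_params")
}

empty_hits <- function() {
  out <- data.frame(query_id = character(), subject_id = character(),
                    q_start = integer(), q_end = integer(),
                    s_start = integer(), s_end = integer(),
                    subject_strand = character(), n_columns = integer(),
                    identity = numeric(), score = numeric(),
                    evalue = numeric(), stringsAsFactors = FALSE)
  out$match_vector <- list()
  out
}

#' Local alignment of two sequences
#'
#' Seed-gated local alignment: exact shared words of `params$word` bases
#' gate each subject orientation; gated orientations are aligned either by
#' an exact affine-gap local DP (`gapped = TRUE`, default) or by ungapped
#' x-drop extension of every seed. Hits below `params$min_score` are
#' dropped. Reverse-strand hits are reported with `s_start <= s_end` on
#' the original subject and `subject_strand == "-"`.
#'
#' @param query,subject sequences (character strings over `{A,C,G,T,N}`).
#' @param params an [align_params()].
#' @param query_id,subject_id identifiers recorded in the hit table.
#' @param max_hits maximum hits per orientation (default 5).
#' @param gapped use the exact affine-gap DP (default) or ungapped
#'   extension only.
#' @return a hit table: one row per hit with columns `query_id`,
#'   `subject_id`, `q_start`, `q_end`, `s_start`, `s_end`,
#'   `subject_strand`, `n_columns`, `identity`, `score`, `evalue` (NA for
#'   built-in hits) and a `match_vector` list-column of per-column logicals
#'   (gap columns are `FALSE`). Sorted by decreasing score.
#' @export
local_align <- function(query, subject, params = align_params(),
                        query_id = "query", subject_id = "subject",
                        max_hits = 5, gapped = TRUE) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  query <- toupper(query); subject <- toupper(subject)
  slen <- nchar(subject)
  rows <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") subject else revcomp_chr(subject)
    hits <- .cpp_align_one_strand(query, subj, params$word, params$match,
                                  params$mismatch, params$gap_open,
                                  params$gap_extend, params$xdrop,
                                  params$min_score, max_hits, gapped)
    for (h in hits) {
      ss <- h$s_start; se <- h$s_end
      if (strand == "-") {
        tmp <- ss
        ss <- slen - se + 1L
        se <- slen - tmp + 1L
      }
      mv <- h$match_vector
      rows[[length(rows) + 1]] <- list(
        query_id = query_id, subject_id = subject_id,
        q_start = h$q_start, q_end = h$q_end,
        s_start = ss, s_end = se, subject_strand = strand,
        n_columns = length(mv), identity = mean(mv),
        score = h$score, evalue = NA_real_, match_vector = list(mv))
    }
  }
  if (!length(rows)) return(empty_hits())
  out <- do.call(rbind, lapply(rows, function(r) {
    d <- data.frame(r[setdiff(names(r), "match_vector")],
                    stringsAsFactors = FALSE)
    d$match_vector <- r$match_vector
    d
  }))
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a 12-column tabular hit file
#'
#' Reads the tab-separated pairwise-search dialect
#' `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`. Subject coordinates with `sstart > send` denote
#' reverse-strand hits and are canonicalized to `s_start <= s_end` with
#' `subject_strand == "-"`.
#'
#' @param path path to the TSV (no header).
#' @param approximate_match_vector if `TRUE`, reconstruct a per-column
#'   match vector from `pident`/`length` with the non-identical columns
#'   spread uniformly; required if window filtering is to be applied to
#'   external hits. Default `FALSE` (match vectors absent).
#' @return a hit table as in [local_align()]; `match_vector` entries are
#'   `NULL` unless reconstructed.
#' @export
read_tabular_hits <- function(path, approximate_match_vector = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hits())
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf != 12)) {
    stop("expected 12 tab-separated columns, got ", nf[nf != 12][1],
         " at line ", which(nf != 12)[1])
  }
  dt <- data.table::fread(text = lines, sep = "\t", header = FALSE,
    col.names = c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore"))
  minus <- dt$sstart > dt$send
  s_start <- ifelse(minus, dt$send, dt$sstart)
  s_end <- ifelse(minus, dt$sstart, dt$send)
  out <- data.frame(query_id = dt$qseqid, subject_id = dt$sseqid,
                    q_start = dt$qstart, q_end = dt$qend,
                    s_start = s_start, s_end = s_end,
                    subject_strand = ifelse(minus, "-", "+"),
                    n_columns = dt$length,
                    identity = dt$pident / 100,
                    score = dt$bitscore, evalue = dt$evalue,
                    stringsAsFactors = FALSE)
  out$match_vector <- if (approximate_match_vector) {
    lapply(seq_len(nrow(out)), function(i) {
      n <- out$n_columns[i]
      n_mismatch <- n - round(out$identity[i] * n)
      mv <- rep(TRUE, n)
      if (n_mismatch > 0) {
        # spread non-identical columns evenly across the alignment
        pos <- unique(round(seq(1, n, length.out = n_mismatch + 2)))
        pos <- pos[-c(1, length(pos))]
        extra <- n_mismatch - length(pos)
        if (extra > 0) pos <- unique(c(pos, seq_len(n)[-pos][seq_len(extra)]))
        mv[pos[seq_len(min(n_mismatch, length(pos)))]] <- FALSE
      }
      mv
    })
  } else {
    vector("list", nrow(out))
  }
  out
}

#' Write a hit table in the 12-column tabular dialect
#'
#' @param hits a hit table ([local_align()] / [read_tabular_hits()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  n <- nrow(hits)
  n_match <- round(hits$identity * hits$n_columns)
  minus <- hits$subject_strand == "-"
  dt <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = round(100 * hits$identity, 2), length = hits$n_columns,
    mismatch = hits$n_columns - n_match, gapopen = 0L,
    qstart = hits$q_start, qend = hits$q_end,
    sstart = ifelse(minus, hits$s_end, hits$s_start),
    send = ifelse(minus, hits$s_start, hits$s_end),
    evalue = ifelse(is.na(hits$evalue), 0, hits$evalue),
    bitscore = hits$score)
  write.table(dt, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Sliding-window identity rule
#'
#' A hit passes iff it is at least `w` columns long and every contiguous
#' window of `w` columns (step 1) contains at least
#' `ceiling(min_identity * w)` matching columns. Gap columns count as
#' mismatches.
#'
#' @param hit a one-row hit table, or a list/logical vector giving the
#'   match vector directly.
#' @param w window length in columns (default 100).
#' @param min_identity required per-window identity (default 0.90).
#' @return `TRUE` or `FALSE`.
#' @export
window_identity_pass <- function(hit, w = 100, min_identity = 0.90) {
  if (w <= 0) stop("window length must be positive")
  mv <- if (is.logical(hit)) hit
        else if (is.data.frame(hit)) hit$match_vector[[1]]
        else hit$match_vector
  if (is.null(mv)) stop("hit has no match vector; re-read hits with ",
                        "approximate_match_vector = TRUE or use the ",
                        "built-in aligner")
  .cpp_window_pass(mv, as.integer(w),
                   as.integer(ceiling(min_identity * w)))
}

# Hard-mask intervals (data.frame: read_id/seq_id, start, end) with N.
mask_sequences <- function(reads, mask) {
  if (is.null(mask) || nrow(mask) == 0) return(reads)
  idcol <- intersect(c("read_id", "seq_id"), names(mask))[1]
  if (is.na(idcol)) stop("mask must have a read_id or seq_id column")
  for (i in seq_len(nrow(mask))) {
    j <- match(mask[[idcol]][i], reads$read_id)
    if (is.na(j)) next
    s <- max(1L, mask$start[i])
    e <- min(reads$length[j], mask$end[i])
    if (s > e) next
    substr(reads$sequence[j], s, e) <- strrep("N", e - s + 1)
  }
  reads
}

#' All-vs-all self-comparison match counts
#'
#' Counts, for every read, the number of DISTINCT other reads with at
#' least one alignment passing the sliding-window identity rule.
#' Self-matches are excluded and counts are symmetric. With the built-in
#' engine, candidate pairs sharing an exact seed word (either orientation)
#' are aligned; with the tabular engine, a pre-computed hit table is
#' filtered instead.
#'
#' @param reads a `"bes_reads"` data.frame.
#' @param engine `"builtin"` (align here) or `"tabular"` (use `hits`).
#' @param hits for the tabular engine: a hit table whose rows carry match
#'   vectors (see [read_tabular_hits()]); rows failing the window rule or
#'   with `evalue > max_evalue` are ignored.
#' @param mask optional mask intervals (`read_id`, `start`, `end`),
#'   excluded from seeding and from passing windows (hard-masked to N).
#' @param params an [align_params()] for the built-in engine.
#' @param w,min_identity sliding-window rule parameters.
#' @param max_evalue E-value cutoff applied to tabular hits that carry
#'   E-values (default `Inf`).
#' @return a list of class `"match_counts"`: `counts` (named integer
#'   vector over all read ids), `pairs` (data.frame `id_a`, `id_b` of
#'   matching pairs), `n_matching` (reads with count >= 1).
#' @export
self_match_counts <- function(reads, engine = c("builtin", "tabular"),
                              hits = NULL, mask = NULL,
                              params = align_params(),
                              w = 100, min_identity = 0.90,
                              max_evalue = Inf) {
  engine <- match.arg(engine)
  counts <- setNames(integer(nrow(reads)), reads$read_id)
  pairs <- data.frame(id_a = character(), id_b = character(),
                      stringsAsFactors = FALSE)
  if (engine == "builtin") {
    masked <- mask_sequences(reads, mask)
    cand <- .cpp_candidate_pairs(masked$sequence, params$word)
    if (nrow(cand) > 0) {
      ok <- .cpp_pairs_window_pass(masked$sequence,
                                   cand[, 1], cand[, 2],
                                   params$word, params$match,
                                   params$mismatch, params$gap_open,
                                   params$gap_extend, params$xdrop,
                                   params$min_score,
                                   as.integer(w),
                                   as.integer(ceiling(min_identity * w)),
                                   3L)
      if (any(ok)) {
        pairs <- data.frame(id_a = reads$read_id[cand[ok, 1]],
                            id_b = reads$read_id[cand[ok, 2]],
                            stringsAsFactors = FALSE)
      }
    }
  } else {
    if (is.null(hits)) stop("tabular engine requires a hit table")
    keep <- hits$query_id != hits$subject_id
    if (!is.null(hits$evalue)) {
      keep <- keep & (is.na(hits$evalue) | hits$evalue <= max_evalue)
    }
    h <- hits[keep, , drop = FALSE]
    if (nrow(h) > 0) {
      pass <- vapply(h$match_vector, function(mv) {
        !is.null(mv) && .cpp_window_pass(mv, as.integer(w),
                                         as.integer(ceiling(min_identity * w)))
      }, logical(1))
      h <- h[pass, , drop = FALSE]
      if (nrow(h) > 0) {
        a <- pmin(h$query_id, h$subject_id)
        b <- pmax(h$query_id, h$subject_id)
        keyed <- !duplicated(paste(a, b))
        pairs <- data.frame(id_a = a[keyed], id_b = b[keyed],
                            stringsAsFactors = FALSE)
      }
    }
  }
  if (nrow(pairs) > 0) {
    tab <- table(c(pairs$id_a, pairs$id_b))
    tab <- tab[names(tab) %in% names(counts)]
    counts[names(tab)] <- as.integer(tab)
  }
  structure(list(counts = counts, pairs = pairs,
                 n_matching = sum(counts > 0)),
            class = "match_counts")
}
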