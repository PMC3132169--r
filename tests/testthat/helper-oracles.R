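# Independent oracles and small data builders used across the suite.

random_seq <- function(n, freqs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Substitute bases at `rate` (uniform over the three alternatives).
mutate_seq <- function(x, rate) {
  ch <- strsplit(x, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# Smith-Waterman best local score, independently of the package's aligner.
# Gap of length L costs |gap_open| + L * |gap_extend|, as in align_params().
sw_oracle_score <- function(q, s, match = 1, mismatch = -2,
                            gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(s), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend, scoreOnly = TRUE)
}

# Brute-force perfect-SSR enumeration: every (start, period) pair is
# extended; maximal loci are filtered with the same span/primitivity/
# containment rules as the production finder.
ssr_oracle <- function(seq, min_span = c("1" = 10, "2" = 16, "3" = 15,
                                         "4" = 16, "5" = 15, "6" = 18),
                       report_mono = FALSE) {
  x <- strsplit(toupper(seq), "")[[1]]
  n <- length(x)
  prim <- function(m) {
    p <- nchar(m)
    if (p == 1) return(TRUE)
    for (q in seq_len(p - 1)) {
      if (p %% q == 0 && m == strrep(substr(m, 1, q), p / q)) return(FALSE)
    }
    TRUE
  }
  rows <- list()
  for (p in 1:6) {
    s <- 1
    while (s <= n - p) {
      ok <- function(i) i + p <= n && x[i] == x[i + p] &&
        x[i] != "N" && x[i + p] != "N"
      if (!ok(s)) { s <- s + 1; next }
      e <- s
      while (ok(e + 1)) e <- e + 1
      start <- s; end <- e + p
      span <- end - start + 1
      motif <- paste(x[start:(start + p - 1)], collapse = "")
      if (span >= min_span[[as.character(p)]] &&
          !grepl("N", motif, fixed = TRUE) && prim(motif)) {
        rows[[length(rows) + 1]] <- data.frame(
          start = start, end = end, period = p, motif = motif,
          span = span, stringsAsFactors = FALSE)
      }
      s <- e + 2
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      period = integer(), motif = character(),
                      span = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (any(df$period < df$period[i] & df$start <= df$start[i] &
              df$end >= df$end[i])) keep[i] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  if (!report_mono) df <- df[df$period > 1, , drop = FALSE]
  df <- df[order(df$start, df$period), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Exact binomial upper-tail threshold by direct log-space enumeration.
binom_threshold_oracle <- function(p0, n, alpha) {
  if (p0 == 0) return(1L)
  tail_ge <- function(t) {
    if (t > n) return(0)
    k <- t:n
    sum(exp(lchoose(n, k) + k * log(p0) + (n - k) * log1p(-p0)))
  }
  t <- 1L
  while (tail_ge(t) > alpha) t <- t + 1L
  t
}

# Reads that all carry one shared element (for self-match tests).
reads_with_element <- function(n_reads, element, flank = 220,
                               ids = sprintf("clone%02d.F", seq_len(n_reads))) {
  seqs <- vapply(seq_len(n_reads), function(i) {
    paste0(random_seq(flank), element, random_seq(flank))
  }, character(1))
  bes_reads(ids, seqs)
}

extdata <- function(f) system.file("extdata", f, package = "oakbes")
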