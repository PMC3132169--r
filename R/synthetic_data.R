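# Synthetic genomes, BAC libraries and BES reads with fully known planted
# truth: interspersed repeat families, perfect SSRs, gene-like segments and
# organelle segments, plus clone sampling and end-read simulation.

#' Specify a synthetic genome with planted features
#'
#' @param genome_len genome length in bp.
#' @param base_freqs background base frequencies in A, C, G, T order. The
#'   default reproduces a 35.33% GC composition typical of the broadleaf
#'   tree genomes this simulator emulates.
#' @param repeat_families `NULL` or a data.frame with columns `family_id`,
#'   `consensus_len` (bp), `copy_number`, `divergence` (per-base
#'   substitution rate in `[0,1]`).
#' @param ssr_plants `NULL` or a data.frame with columns `motif`
#'   (primitive, 1-6 bp), `copies` (tandem copies, may be fractional),
#'   `count` (number of loci to plant).
#' @param gene_plants `NULL` or a list/data.frame with `n_genes` and
#'   `gene_len` (default 2000 bp, the canonical mean plant gene length).
#' @param organelle `NULL` or a list with `cp_len` and `mt_len`: lengths of
#'   a single planted chloroplast/mitochondrial segment (0 = none).
#' @param min_gap minimum background gap separating planted features (bp).
#'   A generous gap keeps planted features independently recoverable (no
#'   read can bridge two features when `min_gap` exceeds the read length).
#' @return an object of class `"genome_spec"`.
#' @export
genome_spec <- function(genome_len,
                        base_freqs = c(A = 0.32335, C = 0.17665,
                                       G = 0.17665, T = 0.32335),
                        repeat_families = NULL,
                        ssr_plants = NULL,
                        gene_plants = NULL,
                        organelle = NULL,
                        min_gap = 100) {
  check_base_freqs(base_freqs)
  stopifnot(genome_len > 0, min_gap >= 1)
  if (!is.null(repeat_families)) {
    stopifnot(all(c("family_id", "consensus_len", "copy_number",
                    "divergence") %in% names(repeat_families)),
              all(repeat_families$divergence >= 0),
              all(repeat_families$divergence <= 1),
              !anyDuplicated(repeat_families$family_id))
  }
  if (!is.null(ssr_plants)) {
    stopifnot(all(c("motif", "copies", "count") %in% names(ssr_plants)))
    ssr_plants$motif <- toupper(ssr_plants$motif)
    ok <- vapply(ssr_plants$motif, function(m)
      nchar(m) >= 1 && nchar(m) <= 6 && !grepl("[^ACGT]", m) &&
        is_primitive_motif(m), logical(1))
    if (!all(ok)) stop("SSR motifs must be primitive 1-6 bp over {A,C,G,T}")
  }
  if (!is.null(gene_plants)) {
    gene_plants <- as.list(gene_plants)
    gene_plants$gene_len <- gene_plants$gene_len %||% 2000
    stopifnot(gene_plants$n_genes >= 0, gene_plants$gene_len > 0)
  }
  if (!is.null(organelle)) {
    organelle <- as.list(organelle)
    organelle$cp_len <- organelle$cp_len %||% 0
    organelle$mt_len <- organelle$mt_len %||% 0
  }
  structure(list(genome_len = as.integer(genome_len),
                 base_freqs = base_freqs,
                 repeat_families = repeat_families,
                 ssr_plants = ssr_plants,
                 gene_plants = gene_plants,
                 organelle = organelle,
                 min_gap = as.integer(min_gap)),
            class = "genome_spec")
}

# TRUE iff motif is not a whole-number repetition of a shorter unit.
is_primitive_motif <- function(motif) {
  p <- nchar(motif)
  if (p == 1) return(TRUE)
  for (q in seq_len(p - 1)) {
    if (p %% q == 0 &&
        motif == strrep(substr(motif, 1, q), p / q)) return(FALSE)
  }
  TRUE
}

random_dna <- function(n, base_freqs) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = base_freqs)
}

# Substitute each base independently with probability `rate` (uniform over
# the three alternatives).
mutate_dna <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    alt <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit],
                         function(b) sample(setdiff(alt, b), 1),
                         character(1), USE.NAMES = FALSE)
  }
  chars
}

#' Build a synthetic genome with planted truth
#'
#' The background is drawn i.i.d. from the spec's base frequencies. Each
#' repeat copy is the family consensus with independent per-base
#' substitutions at the family's divergence rate. SSRs, gene-like segments
#' and organelle segments are placed at non-overlapping recorded intervals
#' (1-based inclusive), separated by at least `min_gap` bp of background.
#' Bases flanking a planted SSR are adjusted so the planted locus is
#' maximal (it cannot be extended in either direction).
#'
#' @param spec a [genome_spec()].
#' @param seed integer seed; the build is fully deterministic given
#'   `(spec, seed)`.
#' @return a list of class `"synthetic_genome"`: `sequence` (character
#'   string), `truth` (data.frame: `type`, `label`, `start`, `end`,
#'   `motif`, `period`), `spec`, `seed`.
#' @export
build_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(derive_seed(seed, "genome"))
  G <- spec$genome_len

  feats <- list()
  add_feat <- function(type, label, len, motif = NA, period = NA) {
    feats[[length(feats) + 1]] <<- list(type = type, label = label,
                                        len = as.integer(len),
                                        motif = motif, period = period)
  }
  if (!is.null(spec$repeat_families)) {
    for (i in seq_len(nrow(spec$repeat_families))) {
      fam <- spec$repeat_families[i, ]
      for (k in seq_len(fam$copy_number)) {
        add_feat("repeat", fam$family_id, fam$consensus_len)
      }
    }
  }
  if (!is.null(spec$ssr_plants)) {
    for (i in seq_len(nrow(spec$ssr_plants))) {
      row <- spec$ssr_plants[i, ]
      span <- round(row$copies * nchar(row$motif))
      for (k in seq_len(row$count)) {
        add_feat("ssr", row$motif, span, motif = row$motif,
                 period = nchar(row$motif))
      }
    }
  }
  if (!is.null(spec$gene_plants) && spec$gene_plants$n_genes > 0) {
    for (k in seq_len(spec$gene_plants$n_genes)) {
      add_feat("gene", sprintf("gene%04d", k), spec$gene_plants$gene_len)
    }
  }
  if (!is.null(spec$organelle)) {
    if (spec$organelle$cp_len > 0) add_feat("cp", "cp", spec$organelle$cp_len)
    if (spec$organelle$mt_len > 0) add_feat("mt", "mt", spec$organelle$mt_len)
  }

  lens <- vapply(feats, `[[`, integer(1), "len")
  nfeat <- length(feats)
  starts <- integer(nfeat)
  if (nfeat > 0) {
    slack <- G - sum(lens) - (nfeat - 1) * spec$min_gap
    if (slack < 0) stop("planted features (plus gaps) exceed genome capacity")
    # place in random order left-to-right with random inter-feature gaps:
    # every arrangement keeps features non-overlapping and >= min_gap
    # apart; splitting the slack by uniform spacings gives near-
    # exponential gaps, i.e. Poisson-process-like feature positions
    ord <- sample.int(nfeat)
    extra <- floor(diff(c(0, sort(runif(nfeat)), 1)) * slack)
    pos <- 1L + extra[1]
    for (k in seq_len(nfeat)) {
      i <- ord[k]
      starts[i] <- pos
      pos <- pos + lens[i] + spec$min_gap + extra[k + 1]
    }
  }

  genome <- random_dna(G, spec$base_freqs)

  # Family consensus sequences.
  consensus <- list()
  if (!is.null(spec$repeat_families)) {
    for (i in seq_len(nrow(spec$repeat_families))) {
      fam <- spec$repeat_families[i, ]
      consensus[[fam$family_id]] <- random_dna(fam$consensus_len,
                                               spec$base_freqs)
    }
  }
  divergence <- if (!is.null(spec$repeat_families)) {
    setNames(spec$repeat_families$divergence,
             spec$repeat_families$family_id)
  } else c()

  n <- length(feats)
  truth <- data.frame(type = character(n), label = character(n),
                      start = integer(n), end = integer(n),
                      motif = rep(NA_character_, n),
                      period = rep(NA_integer_, n),
                      stringsAsFactors = FALSE)
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    s <- starts[i]; e <- s + f$len - 1L
    seq_i <- switch(f$type,
      "repeat" = mutate_dna(consensus[[f$label]], divergence[[f$label]]),
      ssr = strsplit(substr(strrep(f$motif, ceiling(f$len / f$period)),
                            1, f$len), "")[[1]],
      random_dna(f$len, spec$base_freqs))
    genome[s:e] <- seq_i
    truth$type[i] <- f$type; truth$label[i] <- f$label
    truth$start[i] <- s; truth$end[i] <- e
    if (f$type == "ssr") {
      truth$motif[i] <- f$motif
      truth$period[i] <- f$period
    }
  }

  # Make planted SSR loci maximal: the flanking bases must break the period.
  for (i in which(truth$type == "ssr")) {
    s <- truth$start[i]; e <- truth$end[i]; p <- truth$period[i]
    alt <- c("A", "C", "G", "T")
    if (s - 1 >= 1 && genome[s - 1] == genome[s - 1 + p]) {
      genome[s - 1] <- sample(setdiff(alt, genome[s - 1 + p]), 1)
    }
    if (e + 1 <= G && genome[e + 1] == genome[e + 1 - p]) {
      genome[e + 1] <- sample(setdiff(alt, genome[e + 1 - p]), 1)
    }
  }

  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(sequence = paste(genome, collapse = ""),
                 truth = truth, spec = spec, seed = seed),
            class = "synthetic_genome")
}

#' Specify a simulated BAC library
#'
#' Defaults reproduce the study conditions of the oak BAC library this
#' package's analyses were designed around: mean insert 135 kb in
#' `[50, 205]` kb, 7% empty clones, 2.2% chloroplast clones, 599 bp mean
#' reads retained at 66.96%.
#'
#' @param n_clones number of clones.
#' @param insert_mean,insert_sd,insert_min,insert_max truncated-normal
#'   insert size parameters (bp).
#' @param empty_rate fraction of clones with no insert.
#' @param cp_rate fraction of clones carrying chloroplast DNA.
#' @param read_len_mean,read_len_sd,read_len_min,read_len_max
#'   truncated-normal end-read length parameters (bp).
#' @param read_retention probability a sequenced end read survives quality
#'   trimming.
#' @param seed integer seed.
#' @return an object of class `"library_sim_spec"`.
#' @export
library_sim_spec <- function(n_clones,
                             insert_mean = 135000, insert_sd = 30000,
                             insert_min = 50000, insert_max = 205000,
                             empty_rate = 0.07, cp_rate = 0.022,
                             read_len_mean = 599, read_len_sd = 100,
                             read_len_min = 100, read_len_max = 967,
                             read_retention = 0.6696, seed = 1) {
  stopifnot(n_clones >= 0,
            insert_min <= insert_mean, insert_mean <= insert_max,
            empty_rate >= 0, empty_rate <= 1,
            cp_rate >= 0, cp_rate <= 1,
            read_retention >= 0, read_retention <= 1,
            read_len_min <= read_len_mean, read_len_mean <= read_len_max)
  structure(as.list(environment()), class = "library_sim_spec")
}

#' Sample BAC clone inserts from a genome
#'
#' Insert lengths are drawn from a truncated normal; start positions are
#' uniform. Empty and chloroplast flags are independent Bernoulli draws at
#' the spec rates. If `cp_region` is supplied, chloroplast clones are
#' placed inside it (inserts truncated to the region if necessary).
#'
#' @param genome_len genome length (bp).
#' @param spec a [library_sim_spec()].
#' @param cp_region optional `c(start, end)` of a chloroplast segment.
#' @return a data.frame: `clone_id`, `start`, `end`, `insert_len`,
#'   `is_empty`, `is_cp`.
#' @export
sample_clones <- function(genome_len, spec, cp_region = NULL) {
  stopifnot(inherits(spec, "library_sim_spec"),
            spec$insert_max <= genome_len)
  set.seed(derive_seed(spec$seed, "clones"))
  n <- spec$n_clones
  len <- round(rtruncnorm(n, spec$insert_mean, spec$insert_sd,
                          spec$insert_min, spec$insert_max))
  is_empty <- runif(n) < spec$empty_rate
  is_cp <- runif(n) < spec$cp_rate
  start <- integer(n)
  if (n > 0) {
    start <- 1L + floor(runif(n) * (genome_len - len + 1))
    if (!is.null(cp_region)) {
      w <- cp_region[2] - cp_region[1] + 1
      idx <- which(is_cp)
      len[idx] <- pmin(len[idx], w)
      start[idx] <- cp_region[1] + floor(runif(length(idx)) *
                                           (w - len[idx] + 1))
    }
  }
  data.frame(clone_id = sprintf("clone%06d", seq_len(n)),
             start = as.integer(start),
             end = as.integer(start + len - 1),
             insert_len = as.integer(len),
             is_empty = is_empty, is_cp = is_cp,
             stringsAsFactors = FALSE)
}

#' Simulate BAC end reads from sampled clones
#'
#' For each non-empty clone the forward read is taken from the left end of
#' the insert on the plus strand and the reverse read from the right end as
#' the reverse complement. Each read is retained independently with the
#' spec's retention probability. Read names follow the
#' [naming_convention()] `<clone>.<F|R>`.
#'
#' @param genome a `"synthetic_genome"` or a plain character sequence.
#' @param clones a clone table from [sample_clones()].
#' @param spec the [library_sim_spec()] used for the clones.
#' @return a list with `reads` (a `"bes_reads"` data.frame), `truth` (a
#'   data.frame mapping each retained read to its genome interval and
#'   strand) and `n_sequenced` (2 x non-empty clones, the retention
#'   denominator).
#' @export
simulate_bes_reads <- function(genome, clones, spec) {
  seq_chr <- if (inherits(genome, "synthetic_genome")) genome$sequence
             else genome
  set.seed(derive_seed(spec$seed, "reads"))
  live <- clones[!clones$is_empty, , drop = FALSE]
  n <- nrow(live)
  lf <- pmin(round(rtruncnorm(n, spec$read_len_mean, spec$read_len_sd,
                              spec$read_len_min, spec$read_len_max)),
             live$insert_len)
  lr <- pmin(round(rtruncnorm(n, spec$read_len_mean, spec$read_len_sd,
                              spec$read_len_min, spec$read_len_max)),
             live$insert_len)
  keep_f <- runif(n) < spec$read_retention
  keep_r <- runif(n) < spec$read_retention

  f_start <- live$start
  f_end <- live$start + lf - 1L
  r_start <- live$end - lr + 1L
  r_end <- live$end

  truth <- data.frame(
    read_id = c(paste0(live$clone_id, ".F"), paste0(live$clone_id, ".R")),
    clone_id = rep(live$clone_id, 2),
    end_label = rep(c("F", "R"), each = n),
    start = c(f_start, r_start), end = c(f_end, r_end),
    strand = rep(c("+", "-"), each = n),
    is_cp = rep(live$is_cp, 2),
    stringsAsFactors = FALSE)
  keep <- c(keep_f, keep_r)
  truth <- truth[keep, , drop = FALSE]
  rownames(truth) <- NULL

  seqs <- substring(seq_chr, truth$start, truth$end)
  flip <- truth$strand == "-"
  if (any(flip)) seqs[flip] <- revcomp_chr(seqs[flip])
  reads <- bes_reads(truth$read_id, seqs)
  list(reads = reads, truth = truth, n_sequenced = 2L * n)
}

#' Simulate a single-locus marker screen of a BAC library
#'
#' Markers are placed uniformly at random single-bp loci on the nuclear
#' genome; a clone scores a hit iff its insert covers the locus. Empty and
#' chloroplast clones carry no nuclear target and never hit. The mean hit
#' count estimates the library's effective fold coverage.
#'
#' @param clones a clone table from [sample_clones()].
#' @param n_markers number of marker loci.
#' @param genome_len genome length (bp).
#' @param seed integer seed.
#' @return a data.frame: `marker_id`, `pos`, `hits`.
#' @export
simulate_marker_screen <- function(clones, n_markers, genome_len, seed) {
  set.seed(derive_seed(seed, "markers"))
  pos <- 1L + floor(runif(n_markers) * genome_len)
  live <- clones[!clones$is_empty & !clones$is_cp, , drop = FALSE]
  ir <- IRanges::IRanges(live$start, live$end)
  hits <- IRanges::countOverlaps(IRanges::IRanges(pos, pos), ir)
  data.frame(marker_id = sprintf("marker%04d", seq_len(n_markers)),
             pos = pos, hits = hits, stringsAsFactors = FALSE)
}

#' Simulate protein-homology hits from planted gene truth
#'
#' Surrogate for a protein-database search on synthetic data: a read is
#' called genic when at least `min_overlap_frac` of the mean read length
#' overlaps a planted gene segment. Requiring a majority-genic read mirrors
#' a translated homology search, where a marginal overlap rarely yields a
#' significant alignment, and makes the downstream gene-number estimator
#' unbiased for reads of the default length.
#'
#' @param read_truth the `truth` component of [simulate_bes_reads()].
#' @param genome_truth the `truth` track of [build_genome()].
#' @param min_overlap_frac minimum genic fraction of the mean read length
#'   (default 0.5).
#' @param read_len_mean mean read length used to set the overlap cutoff.
#' @return character vector of read ids with a simulated protein hit.
#' @export
simulate_protein_hits <- function(read_truth, genome_truth,
                                  min_overlap_frac = 0.5,
                                  read_len_mean = 599) {
  genes <- genome_truth[genome_truth$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0 || nrow(read_truth) == 0) return(character())
  min_ov <- ceiling(min_overlap_frac * read_len_mean)
  ir_reads <- IRanges::IRanges(read_truth$start, read_truth$end)
  ir_genes <- IRanges::IRanges(genes$start, genes$end)
  ov <- IRanges::findOverlaps(ir_reads, ir_genes, minoverlap = min_ov)
  unique(read_truth$read_id[S4Vectors::queryHits(ov)])
}

#' Write a truth track as BED
#'
#' Intervals are stored 0-based half-open on disk (BED convention) and
#' converted back to the package's 1-based inclusive convention on load.
#' The BED name field is `type:label`.
#'
#' @param truth a truth data.frame from [build_genome()].
#' @param path output path.
#' @param seqname chromosome name to record (default `"genome"`).
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path, seqname = "genome") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(truth$start, truth$end),
    name = paste0(truth$type, ":", truth$label))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a truth track from BED
#'
#' @param path BED file written by [write_truth_bed()].
#' @return a data.frame with `type`, `label`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_truth_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  name <- strsplit(gr$name, ":", fixed = TRUE)
  data.frame(type = vapply(name, `[[`, character(1), 1),
             label = vapply(name, function(x)
               paste(x[-1], collapse = ":"), character(1)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
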