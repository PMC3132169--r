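# End-to-end synthetic pipeline: simulate -> stats -> coverage ->
# selfmatch -> repeats -> ssr -> genes -> synteny [-> annotate-stats],
# with one config, one seed, and a consolidated JSON report.

#' Pipeline configuration
#'
#' A flat list of module parameter blocks with a single global seed. Every
#' stochastic stage derives a tagged sub-seed from `seed`, so reruns with
#' identical config are byte-identical (no timestamps are written).
#'
#' @param outdir output directory (created if absent).
#' @param seed global integer seed.
#' @param genome a [genome_spec()].
#' @param library a [library_sim_spec()]; its `seed` is overridden by the
#'   global seed.
#' @param n_markers marker-screen size (default 200).
#' @param align an [align_params()].
#' @param min_matches novel-repeat candidate threshold (default 6).
#' @param ssr an [ssr_params()].
#' @param synteny a [synteny_params()].
#' @param gene_novel_fraction fraction of genes assumed absent from the
#'   homology database (default 0, since synthetic hits are truth-based).
#' @param go_file,go_reference_file optional TSV paths for GO assignments
#'   and reference proportions; the annotation stage runs only when both
#'   are given.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(outdir, seed, genome, library,
                            n_markers = 200,
                            align = align_params(),
                            min_matches = 6,
                            ssr = ssr_params(),
                            synteny = synteny_params(),
                            gene_novel_fraction = 0,
                            go_file = NULL, go_reference_file = NULL) {
  stopifnot(inherits(genome, "genome_spec"),
            inherits(library, "library_sim_spec"),
            inherits(align, "align_params"),
            inherits(ssr, "ssr_params"),
            inherits(synteny, "synteny_params"))
  if (library$insert_max > genome$genome_len) {
    stop("config invalid: insert_max exceeds genome length")
  }
  for (f in c(go_file, go_reference_file)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("config invalid: file not found: ", f)
    }
  }
  library$seed <- seed
  structure(list(outdir = outdir, seed = as.integer(seed),
                 genome = genome, library = library,
                 n_markers = n_markers, align = align,
                 min_matches = min_matches, ssr = ssr, synteny = synteny,
                 gene_novel_fraction = gene_novel_fraction,
                 go_file = go_file, go_reference_file = go_reference_file),
            class = "pipeline_config")
}

#' Run the full synthetic BES analysis pipeline
#'
#' Stages run in dependency order, each writing its outputs before the
#' next consumes them; a manifest lists stage parameters, the seed, and
#' md5 checksums of every written file. A stage failure halts the run
#' with the failing stage named; outputs written so far are retained next
#' to a `FAILED` marker file.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage progress messages.
#' @return the consolidated report (a list), invisibly; also written to
#'   `<outdir>/report.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[oakbes] ", ...)
  report <- list(seed = config$seed)
  stage <- "init"
  on_fail <- function(e) {
    writeLines(paste0("stage ", stage, ": ", conditionMessage(e)),
               file.path(config$outdir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    stage <- "simulate"
    say("simulate: genome + library + reads")
    genome <- build_genome(config$genome, config$seed)
    clones <- sample_clones(config$genome$genome_len, config$library)
    sim <- simulate_bes_reads(genome, clones, config$library)
    writeLines(c(">genome", genome$sequence),
               file.path(config$outdir, "genome.fasta"))
    write_truth_bed(genome$truth, file.path(config$outdir, "truth.bed"))
    write_bes_fasta(sim$reads, file.path(config$outdir, "reads.fasta"))

    stage <- "stats"
    say("stats: dataset summary")
    st <- dataset_stats(sim$reads)
    mates <- pair_reads(sim$reads)
    report$stats <- list(
      n_reads = st$n_reads, total_bp = st$total_bp,
      min_len = st$min_len, max_len = st$max_len,
      mean_len = st$mean_len,
      gc_pct = round_half_up(100 * st$gc_fraction, 2),
      retention_pct = retention_rate(sim$n_sequenced / 2, st$n_reads),
      n_pairs = nrow(mates$pairs),
      paired_pct = round_half_up(100 * mates$paired_fraction, 2))

    stage <- "coverage"
    say("coverage: library mathematics + marker screen")
    lp <- library_params(config$library$n_clones, config$library$insert_mean,
                         config$genome$genome_len,
                         empty_fraction = config$library$empty_rate,
                         organelle_fraction = config$library$cp_rate)
    screen <- simulate_marker_screen(clones, config$n_markers,
                                     config$genome$genome_len, config$seed)
    report$coverage <- list(
      fold_coverage = coverage_depth(lp),
      recovery_probability = recovery_probability(
        lp$N * (1 - lp$empty_fraction), lp$I, lp$GS),
      marker_mean_hits = mean(screen$hits),
      marker_zero_fraction = mean(screen$hits == 0),
      empty_pct = contamination_rate(sum(clones$is_empty),
                                     nrow(clones))$percent,
      cp_pct = contamination_rate(sum(clones$is_cp),
                                  nrow(clones))$percent)

    stage <- "selfmatch"
    say("selfmatch: all-vs-all comparison (", st$n_reads, " reads)")
    counts <- self_match_counts(sim$reads, engine = "builtin",
                                params = config$align)
    base_freqs <- read_base_freqs(sim$reads)
    nm <- null_model(base_freqs, n_trials = st$n_reads - 1)
    report$selfmatch <- list(
      n_matching = counts$n_matching,
      matching_pct = round_half_up(100 * counts$n_matching / st$n_reads, 2),
      p0 = nm$p0, threshold = nm$threshold)

    stage <- "repeats"
    say("repeats: candidates, families, extrapolation")
    cand <- candidate_repeats(counts, config$min_matches)
    fams <- cluster_families(cand, counts$pairs)
    covered <- 0
    if (nrow(fams) > 0) {
      for (i in seq_len(nrow(fams))) {
        fh <- within_family_hits(sim$reads, fams$members[[i]],
                                 params = config$align)
        fams$covered_bp[i] <- if (nrow(fh) > 0) {
          spans <- split(IRanges::IRanges(fh$q_start, fh$q_end),
                         fh$query_id)
          sum(vapply(spans, function(x)
            sum(IRanges::width(IRanges::reduce(x))), numeric(1)))
        } else 0L
      }
      fams$genome_copies <- extrapolate_copies(
        fams$size, config$genome$genome_len, st$total_bp)
      covered <- sum(fams$covered_bp)
    }
    fam_tsv <- fams
    fam_tsv$members <- vapply(fams$members, paste, character(1),
                              collapse = ",")
    write.table(fam_tsv, file.path(config$outdir, "families.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$repeats <- list(
      n_candidates = length(cand), n_families = nrow(fams),
      family_sizes = fams$size,
      genome_copies = if (nrow(fams)) fams$genome_copies else integer(),
      novel_density = repeat_density(min(covered, st$total_bp),
                                     st$total_bp))

    stage <- "ssr"
    say("ssr: perfect tandem repeats")
    loci <- find_ssrs_in_reads(sim$reads, config$ssr)
    write.table(loci, file.path(config$outdir, "ssrs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ssum <- ssr_summary(loci, st$total_bp)
    report$ssr <- list(n_ssr = ssum$n_ssr,
                       per_100kb = ssum$per_100kb,
                       kb_per_ssr = ssum$kb_per_ssr,
                       by_period = ssum$by_period)

    stage <- "genes"
    say("genes: gene-content estimate")
    hit_ids <- simulate_protein_hits(sim$truth, genome$truth,
                                     read_len_mean =
                                       config$library$read_len_mean)
    gp <- gene_estimate_params(length(hit_ids), st$mean_len, st$total_bp,
                               config$genome$genome_len,
                               novel_fraction = config$gene_novel_fraction)
    est <- estimate_gene_number(gp)
    report$genes <- list(
      n_hit_bes = length(hit_ids),
      estimate = est,
      adjusted = adjust_for_novel(est, config$gene_novel_fraction),
      true_genes = if (!is.null(config$genome$gene_plants))
        config$genome$gene_plants$n_genes else 0L)

    stage <- "synteny"
    say("synteny: mate-pair classification vs own genome")
    truth_hits <- truth_to_hits(sim$truth)
    syn <- classify_dataset(mates, truth_hits, config$synteny)
    report$synteny <- as.list(syn$counts)

    if (!is.null(config$go_file) && !is.null(config$go_reference_file)) {
      stage <- "annotate-stats"
      say("annotate-stats: GO category comparison")
      assignments <- read_go_assignments(config$go_file)
      counts_go <- count_terms(assignments)
      ref <- read.table(config$go_reference_file, sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
      obs <- setNames(counts_go$top_level_counts$count,
                      counts_go$top_level_counts$top_level_term)
      refp <- setNames(ref$proportion, ref$term)
      refp <- refp[names(obs)] / sum(refp[names(obs)])
      cmp <- chi2_category_compare(obs, refp)
      report$annotation <- list(
        n_annotated_reads = counts_go$n_annotated_reads,
        n_terms = counts_go$n_terms,
        comparison = cmp)
    }

    stage <- "report"
    jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- setdiff(list.files(config$outdir, full.names = TRUE),
                     file.path(config$outdir, "manifest.json"))
    manifest <- list(seed = config$seed,
                     stages = c("simulate", "stats", "coverage",
                                "selfmatch", "repeats", "ssr", "genes",
                                "synteny"),
                     checksums = as.list(tools::md5sum(files)))
    jsonlite::write_json(manifest,
                         file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }, error = on_fail)
  invisible(report)
}

# Base frequencies (A, C, G, T) of a read set, N excluded.
read_base_freqs <- function(reads) {
  freq <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(reads$sequence), c("A", "C", "G", "T"))
  tot <- colSums(freq)
  tot / sum(tot)
}

# Exact reference hits from the simulator's read-truth mapping: each read
# maps back to its source interval with full identity.
truth_to_hits <- function(read_truth) {
  n <- nrow(read_truth)
  out <- data.frame(query_id = read_truth$read_id,
                    subject_id = "genome",
                    q_start = 1L,
                    q_end = read_truth$end - read_truth$start + 1L,
                    s_start = read_truth$start,
                    s_end = read_truth$end,
                    subject_strand = read_truth$strand,
                    n_columns = read_truth$end - read_truth$start + 1L,
                    identity = 1, score = NA_real_, evalue = 0,
                    stringsAsFactors = FALSE)
  out$match_vector <- lapply(out$n_columns, function(n) rep(TRUE, n))
  out
}
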