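# Gene-content estimation: homology hit filtering, organelle fractions,
# and the genome-wide gene-number estimate.

#' Hit filter parameters for gene-content searches
#'
#' @param protein_evalue_max E-value cutoff for protein (translated)
#'   searches (default 1e-4).
#' @param est_evalue_max E-value cutoff for high-stringency nucleotide
#'   (EST) searches (default 1e-50).
#' @param nucleotide_window_rule apply the sliding-window identity rule to
#'   nucleotide hits (default `TRUE`).
#' @return an object of class `"hit_filter_params"`.
#' @export
hit_filter_params <- function(protein_evalue_max = 1e-4,
                              est_evalue_max = 1e-50,
                              nucleotide_window_rule = TRUE) {
  stopifnot(protein_evalue_max > 0, est_evalue_max > 0)
  structure(list(protein_evalue_max = protein_evalue_max,
                 est_evalue_max = est_evalue_max,
                 nucleotide_window_rule = nucleotide_window_rule),
            class = "hit_filter_params")
}

#' Filter homology hits by mode-specific cutoffs
#'
#' Protein mode retains hits with `evalue <= protein_evalue_max`.
#' Nucleotide mode retains hits with `evalue <= est_evalue_max` that also
#' pass the sliding-window identity rule (when enabled).
#'
#' @param hits a hit table (see [read_tabular_hits()]); rows must carry
#'   E-values.
#' @param params a [hit_filter_params()].
#' @param mode `"protein"` or `"nucleotide"`.
#' @param w,min_identity window-rule parameters for nucleotide mode.
#' @return the retained rows of `hits`.
#' @export
filter_hits <- function(hits, params = hit_filter_params(),
                        mode = c("protein", "nucleotide"),
                        w = 100, min_identity = 0.90) {
  mode <- match.arg(mode)
  if (nrow(hits) == 0) return(hits)
  if (any(is.na(hits$evalue))) {
    stop("hits without E-values cannot be filtered; supply E-values")
  }
  if (mode == "protein") {
    return(hits[hits$evalue <= params$protein_evalue_max, , drop = FALSE])
  }
  keep <- hits$evalue <= params$est_evalue_max
  if (params$nucleotide_window_rule) {
    pass <- vapply(hits$match_vector, function(mv) {
      if (is.null(mv)) stop("nucleotide window filtering requires match ",
                            "vectors; re-read hits with ",
                            "approximate_match_vector = TRUE")
      .cpp_window_pass(mv, as.integer(w),
                       as.integer(ceiling(min_identity * w)))
    }, logical(1))
    keep <- keep & pass
  }
  hits[keep, , drop = FALSE]
}

#' Organelle-matching fraction of a read set
#'
#' @param n_matching reads matching an organelle (cp or mt) reference.
#' @param n_total_reads total reads.
#' @return percentage, rounded half-up to 2 decimals.
#' @examples
#' organelle_fraction(166, 20056)  # 0.83
#' @export
organelle_fraction <- function(n_matching, n_total_reads) {
  if (n_total_reads <= 0) stop("n_total_reads must be positive")
  stopifnot(n_matching >= 0, n_matching <= n_total_reads)
  round_half_up(100 * n_matching / n_total_reads, 2)
}

#' Parameters of the genome-wide gene-number estimate
#'
#' @param n_hit_bes reads with at least one protein-database hit
#'   (organelle hits excluded).
#' @param mean_bes_len mean read length (bp).
#' @param total_bes_bp total read base count.
#' @param genome_size genome size (bp).
#' @param mean_gene_len mean gene length (bp, default 2000).
#' @param novel_fraction fraction of genes with no database homology
#'   (default 0.11).
#' @return an object of class `"gene_estimate_params"`.
#' @export
gene_estimate_params <- function(n_hit_bes, mean_bes_len, total_bes_bp,
                                 genome_size, mean_gene_len = 2000,
                                 novel_fraction = 0.11) {
  stopifnot(n_hit_bes >= 0, mean_bes_len > 0, total_bes_bp > 0,
            genome_size > 0, mean_gene_len > 0,
            novel_fraction >= 0, novel_fraction < 1)
  structure(as.list(environment()), class = "gene_estimate_params")
}

#' Estimate the genome-wide gene number
#'
#' The genic fraction of sampled nucleotides, `n_hit_bes * mean_bes_len /
#' total_bes_bp`, scaled to the genome and divided by the mean gene
#' length:
#' `round((n_hit_bes * mean_bes_len / total_bes_bp) * genome_size /
#' mean_gene_len)`.
#'
#' @param params a [gene_estimate_params()].
#' @return integer gene-number estimate.
#' @examples
#' estimate_gene_number(
#'   gene_estimate_params(1591, 599, 12018238, 740e6))  # 29340
#' @export
estimate_gene_number <- function(params) {
  stopifnot(inherits(params, "gene_estimate_params"))
  genic_fraction <- params$n_hit_bes * params$mean_bes_len /
    params$total_bes_bp
  round(genic_fraction * params$genome_size / params$mean_gene_len)
}

#' Adjust a gene estimate for genes without database homology
#'
#' If a fraction `novel_fraction` of true genes has no homolog in the
#' search database, the homology-based estimate covers only
#' `1 - novel_fraction` of genes and is scaled up by
#' `1 / (1 - novel_fraction)`.
#'
#' @param estimate a homology-based gene-number estimate.
#' @param novel_fraction fraction of genes with no homology, in `[0, 1)`.
#' @return integer adjusted estimate.
#' @examples
#' adjust_for_novel(29340, 0.11)  # 32966
#' @export
adjust_for_novel <- function(estimate, novel_fraction) {
  if (novel_fraction < 0 || novel_fraction >= 1) {
    stop("novel_fraction must be in [0, 1)")
  }
  round(estimate / (1 - novel_fraction))
}
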