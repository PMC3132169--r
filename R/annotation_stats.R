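# GO annotation counting and per-category chi-squared comparison against
# a reference distribution.

GO_NAMESPACES <- c("molecular_function", "biological_process",
                   "cellular_component")

#' Read GO assignments from TSV
#'
#' Expected columns (with header): `bes_id`, `go_id`, `namespace`,
#' `top_level_term`.
#'
#' @param path path to the TSV.
#' @return a validated assignment data.frame.
#' @export
read_go_assignments <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, quote = "")
  need <- c("bes_id", "go_id", "namespace", "top_level_term")
  if (!all(need %in% names(df))) {
    stop("GO assignment table must have columns: ",
         paste(need, collapse = ", "))
  }
  validate_go_assignments(df)
}

validate_go_assignments <- function(assignments) {
  bad <- setdiff(unique(assignments$namespace), GO_NAMESPACES)
  if (length(bad)) {
    stop("unknown GO namespace(s): ", paste(bad, collapse = ", "))
  }
  assignments[!duplicated(assignments[c("bes_id", "go_id")]), ,
              drop = FALSE]
}

#' Count GO term assignments
#'
#' A read annotated with k distinct terms contributes to k term counts
#' but only once to coverage.
#'
#' @param assignments a data.frame of GO assignments (`bes_id`, `go_id`,
#'   `namespace`, `top_level_term`).
#' @return a list of class `"go_counts"`: `term_counts` (data.frame:
#'   `go_id`, `namespace`, `top_level_term`, `count`),
#'   `top_level_counts` (per namespace and top-level term),
#'   `namespace_coverage` (reads annotated per namespace),
#'   `n_annotated_reads`, `n_terms`.
#' @export
count_terms <- function(assignments) {
  assignments <- validate_go_assignments(assignments)
  if (nrow(assignments) == 0) {
    return(structure(list(
      term_counts = data.frame(go_id = character(),
                               namespace = character(),
                               top_level_term = character(),
                               count = integer(), stringsAsFactors = FALSE),
      top_level_counts = data.frame(namespace = character(),
                                    top_level_term = character(),
                                    count = integer(),
                                    stringsAsFactors = FALSE),
      namespace_coverage = setNames(integer(length(GO_NAMESPACES)),
                                    GO_NAMESPACES),
      n_annotated_reads = 0L, n_terms = 0L), class = "go_counts"))
  }
  term_counts <- as.data.frame(
    table(go_id = assignments$go_id), stringsAsFactors = FALSE)
  names(term_counts)[2] <- "count"
  meta <- assignments[!duplicated(assignments$go_id),
                      c("go_id", "namespace", "top_level_term")]
  term_counts <- merge(meta, term_counts, by = "go_id", sort = TRUE)
  top_level_counts <- as.data.frame(
    table(namespace = assignments$namespace,
          top_level_term = assignments$top_level_term),
    stringsAsFactors = FALSE)
  names(top_level_counts)[3] <- "count"
  top_level_counts <- top_level_counts[top_level_counts$count > 0, ,
                                       drop = FALSE]
  rownames(top_level_counts) <- NULL
  cov <- vapply(GO_NAMESPACES, function(ns)
    length(unique(assignments$bes_id[assignments$namespace == ns])),
    integer(1))
  structure(list(term_counts = term_counts,
                 top_level_counts = top_level_counts,
                 namespace_coverage = cov,
                 n_annotated_reads = length(unique(assignments$bes_id)),
                 n_terms = length(unique(assignments$go_id))),
            class = "go_counts")
}

#' Per-category chi-squared comparison against a reference distribution
#'
#' For each top-level term, a one-vs-rest goodness-of-fit chi-squared test
#' (df = 1) of the observed split `[x, n - x]` against the expected split
#' `[n p, n (1 - p)]` under the reference proportion `p`. No
#' multiple-testing correction is applied by default (per-category
#' significance is reported as-is); Bonferroni correction is available.
#'
#' @param observed named integer vector of observed counts per term.
#' @param reference named numeric vector of reference proportions per
#'   term (must sum to 1 over the compared terms).
#' @param alpha significance level (default 0.05).
#' @param bonferroni divide alpha by the number of tests (default
#'   `FALSE`).
#' @return a data.frame of class `"category_comparison"`: `term`,
#'   `observed`, `expected`, `reference_prop`, `chisq`, `p_value`,
#'   `direction` (`"over"`/`"under"`/`"equal"`), `significant`,
#'   `low_expected` (flag when an expected cell is below 5).
#' @examples
#' chi2_category_compare(c(a = 30, b = 70), c(a = 0.5, b = 0.5))
#' @export
chi2_category_compare <- function(observed, reference, alpha = 0.05,
                                  bonferroni = FALSE) {
  terms <- names(observed)
  if (is.null(terms) || is.null(names(reference))) {
    stop("observed and reference must be named vectors")
  }
  missing_ref <- setdiff(terms, names(reference))
  if (length(missing_ref)) {
    stop("no reference proportion for term(s): ",
         paste(missing_ref, collapse = ", "))
  }
  reference <- reference[terms]
  if (abs(sum(reference) - 1) > 1e-6) {
    stop("reference proportions must sum to 1 over the compared terms")
  }
  n <- sum(observed)
  if (n <= 0) stop("observed total must be positive")
  alpha_eff <- if (bonferroni) alpha / length(terms) else alpha
  res <- lapply(terms, function(tm) {
    x <- observed[[tm]]
    p <- reference[[tm]]
    expected <- n * p
    if (p <= 0 || p >= 1) {
      stop("reference proportion for '", tm, "' must be in (0, 1)")
    }
    ct <- suppressWarnings(
      chisq.test(c(x, n - x), p = c(p, 1 - p), correct = FALSE))
    data.frame(term = tm, observed = x, expected = expected,
               reference_prop = p,
               chisq = unname(ct$statistic), p_value = ct$p.value,
               direction = if (x > expected) "over"
                           else if (x < expected) "under" else "equal",
               significant = ct$p.value < alpha_eff,
               low_expected = min(expected, n - expected) < 5,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("category_comparison", "data.frame")
  out
}
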