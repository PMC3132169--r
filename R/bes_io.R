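# BES input/output: FASTA parsing with clone/end naming, mate pairing,
# dataset summary statistics, and read retention accounting.

#' Describe the clone/end naming convention of BES FASTA headers
#'
#' BES read identifiers encode the clone and which insert end was sequenced,
#' e.g. `"cloneA.F"`. The convention is the separator between clone id and
#' end token, plus the tokens used for the forward and reverse end.
#'
#' @param sep separator between clone id and end token (default `"."`).
#' @param forward token marking the forward end (default `"F"`).
#' @param reverse token marking the reverse end (default `"R"`).
#' @return an object of class `"naming_convention"`.
#' @examples
#' naming_convention()                       # cloneA.F / cloneA.R
#' naming_convention("_", "F1", "R1")        # cloneB_R1
#' @export
naming_convention <- function(sep = ".", forward = "F", reverse = "R") {
  stopifnot(nzchar(sep), nzchar(forward), nzchar(reverse),
            forward != reverse)
  structure(list(sep = sep, forward = forward, reverse = reverse),
            class = "naming_convention")
}

# Split read ids into clone id and end label under a convention.
decode_read_ids <- function(read_id, naming) {
  sep <- naming$sep
  # use the LAST occurrence of the separator so clone ids may contain it
  last <- vapply(read_id, function(id) {
    hits <- gregexpr(sep, id, fixed = TRUE)[[1]]
    if (hits[1] == -1) -1L else hits[length(hits)]
  }, integer(1), USE.NAMES = FALSE)
  bad <- last <= 1 | last + nchar(sep) > nchar(read_id)
  if (any(bad)) {
    stop("read id does not match naming convention: ",
         paste(utils::head(read_id[bad], 5), collapse = ", "))
  }
  clone_id <- substr(read_id, 1, last - 1)
  token <- substr(read_id, last + nchar(sep), nchar(read_id))
  end_label <- ifelse(token == naming$forward, "F",
                      ifelse(token == naming$reverse, "R", NA_character_))
  if (anyNA(end_label)) {
    bad <- read_id[is.na(end_label)]
    stop("end token not in convention {", naming$forward, ",",
         naming$reverse, "}: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  list(clone_id = clone_id, end_label = end_label)
}

#' Build a BES read table from ids and sequences
#'
#' @param read_id character vector of read identifiers.
#' @param sequence character vector of sequences over `{A,C,G,T,N}`.
#' @param naming a [naming_convention()].
#' @param on_invalid what to do with characters outside `{A,C,G,T,N}`:
#'   `"error"` (default) or `"mask"` (replace with `N`).
#' @return a `data.frame` of class `"bes_reads"` with columns `read_id`,
#'   `clone_id`, `end_label`, `sequence`, `length`.
#' @export
bes_reads <- function(read_id, sequence, naming = naming_convention(),
                      on_invalid = c("error", "mask")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(length(read_id) == length(sequence))
  if (anyDuplicated(read_id)) {
    stop("duplicate read ids: ",
         paste(utils::head(unique(read_id[duplicated(read_id)]), 5),
               collapse = ", "))
  }
  sequence <- toupper(sequence)
  has_bad <- grepl("[^ACGTN]", sequence)
  if (any(has_bad)) {
    if (on_invalid == "error") {
      stop("sequence contains characters outside {A,C,G,T,N}: ",
           paste(utils::head(read_id[has_bad], 5), collapse = ", "))
    }
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  if (any(nchar(sequence) == 0)) stop("empty sequence not allowed")
  dec <- decode_read_ids(read_id, naming)
  out <- data.frame(read_id = read_id, clone_id = dec$clone_id,
                    end_label = dec$end_label, sequence = sequence,
                    length = nchar(sequence), stringsAsFactors = FALSE)
  class(out) <- c("bes_reads", "data.frame")
  out
}

#' Parse a BES FASTA file
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA and decodes clone ids
#' and end labels from the headers.
#'
#' @param path path to a FASTA file.
#' @inheritParams bes_reads
#' @return a `"bes_reads"` data.frame; see [bes_reads()].
#' @export
parse_bes_fasta <- function(path, naming = naming_convention(),
                            on_invalid = c("error", "mask")) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  bes_reads(ids, as.character(set), naming = naming,
            on_invalid = on_invalid)
}

#' Write BES reads as FASTA
#'
#' @param reads a `"bes_reads"` data.frame.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_bes_fasta <- function(reads, path, width = 70) {
  set <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Pair forward and reverse reads into mate pairs
#'
#' Clones contributing exactly one forward and one reverse read become mate
#' pairs; every other read is a singleton.
#'
#' @param reads a `"bes_reads"` data.frame.
#' @return a list of class `"mate_pair_set"` with elements `pairs` (a
#'   data.frame: `clone_id`, `forward_id`, `reverse_id`), `singletons`
#'   (character read ids), `n_reads`, and `paired_fraction`
#'   (`2 * n_pairs / n_reads`).
#' @export
pair_reads <- function(reads) {
  if (nrow(reads) == 0) {
    out <- list(pairs = data.frame(clone_id = character(),
                                   forward_id = character(),
                                   reverse_id = character()),
                singletons = character(), n_reads = 0L,
                paired_fraction = NA_real_)
    class(out) <- "mate_pair_set"
    return(out)
  }
  key <- paste(reads$clone_id, reads$end_label)
  if (anyDuplicated(key)) {
    dup <- reads$clone_id[duplicated(key)]
    stop("duplicate (clone, end) combination for clone(s): ",
         paste(unique(utils::head(dup, 5)), collapse = ", "))
  }
  tab <- split(reads$end_label, reads$clone_id)
  paired_clones <- names(tab)[vapply(tab, function(e)
    length(e) == 2 && all(sort(e) == c("F", "R")), logical(1))]
  is_paired <- reads$clone_id %in% paired_clones
  f <- reads[is_paired & reads$end_label == "F", ]
  r <- reads[is_paired & reads$end_label == "R", ]
  pairs <- merge(data.frame(clone_id = f$clone_id, forward_id = f$read_id),
                 data.frame(clone_id = r$clone_id, reverse_id = r$read_id),
                 by = "clone_id", sort = TRUE)
  out <- list(pairs = pairs,
              singletons = reads$read_id[!is_paired],
              n_reads = nrow(reads),
              paired_fraction = 2 * nrow(pairs) / nrow(reads))
  class(out) <- "mate_pair_set"
  out
}

#' Summary statistics of a BES dataset
#'
#' GC content is computed over unambiguous bases only: `N` is excluded from
#' both numerator and denominator.
#'
#' @param reads a `"bes_reads"` data.frame with at least one read.
#' @return a list of class `"dataset_stats"`: `n_reads`, `total_bp`,
#'   `min_len`, `max_len`, `mean_len`, `gc_fraction`.
#' @export
dataset_stats <- function(reads) {
  if (nrow(reads) == 0) stop("no reads: dataset statistics undefined")
  set <- Biostrings::DNAStringSet(reads$sequence)
  freq <- Biostrings::letterFrequency(set, c("A", "C", "G", "T"))
  acgt <- sum(freq)
  gc <- sum(freq[, c("C", "G")])
  out <- list(n_reads = nrow(reads),
              total_bp = sum(reads$length),
              min_len = min(reads$length),
              max_len = max(reads$length),
              mean_len = mean(reads$length),
              gc_fraction = if (acgt > 0) gc / acgt else NA_real_)
  class(out) <- "dataset_stats"
  out
}

#' @export
print.dataset_stats <- function(x, ...) {
  cat(sprintf(
    "BES dataset: %d reads, %d bp total\n  length %d-%d bp (mean %.1f)\n  GC %.2f%%\n",
    x$n_reads, x$total_bp, x$min_len, x$max_len, x$mean_len,
    100 * x$gc_fraction))
  invisible(x)
}

#' Read retention rate of an end-sequencing run
#'
#' Clones are sequenced from both ends, so the denominator is twice the
#' number of clones attempted.
#'
#' @param n_clones_attempted clones sequenced from both ends.
#' @param n_reads_retained reads surviving trimming/quality control.
#' @return retention percentage, rounded half-up to 2 decimals.
#' @examples
#' retention_rate(14976, 20056)  # 66.96
#' @export
retention_rate <- function(n_clones_attempted, n_reads_retained) {
  stopifnot(n_clones_attempted >= 0, n_reads_retained >= 0)
  if (n_clones_attempted == 0) stop("no clones attempted: rate undefined")
  if (n_reads_retained > 2 * n_clones_attempted) {
    stop("retained reads exceed 2 x attempted clones")
  }
  round_half_up(100 * n_reads_retained / (2 * n_clones_attempted), 2)
}
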