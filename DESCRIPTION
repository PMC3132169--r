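Package: oakbes
Title: BAC-End-Sequence Genome Survey Analysis with Simulated Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for surveying genome composition from BAC-end sequences
    (BES): library coverage statistics via the Clarke-Carbon equation,
    ab-initio repeat discovery by all-vs-all self-comparison under a binomial
    null model, novel-repeat family clustering and genome copy-number
    extrapolation, perfect microsatellite (SSR) detection and motif-class
    summaries, gene-content estimation from homology hit tables, GO-category
    chi-squared comparison, and mate-pair microsynteny classification against
    a reference genome. Includes a synthetic-data generator that plants
    repeat families, SSRs, gene-like segments and organelle contamination
    with fully known truth, so every stage of the pipeline is testable
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
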