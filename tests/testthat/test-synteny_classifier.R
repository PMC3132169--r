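mk_hit <- function(q, chr, start, end, strand) {
  data.frame(query_id = q, subject_id = chr, q_start = 1,
             q_end = end - start + 1, s_start = start, s_end = end,
             subject_strand = strand, n_columns = end - start + 1,
             identity = 1, score = end - start + 1, evalue = 1e-20,
             stringsAsFactors = FALSE)
}

test_that("orientation test requires inward-facing opposite strands", {
  f <- mk_hit("f", "chr1", 100000, 100500, "+")
  r <- mk_hit("r", "chr1", 180000, 180500, "-")
  expect_true(orientation_consistent(f, r))
  # outward-facing
  f2 <- mk_hit("f", "chr1", 100000, 100500, "-")
  r2 <- mk_hit("r", "chr1", 180000, 180500, "+")
  expect_false(orientation_consistent(f2, r2))
  # same strand
  expect_false(orientation_consistent(f, mk_hit("r", "chr1", 180000,
                                                180500, "+")))
  expect_error(orientation_consistent(f, mk_hit("r", "chr2", 1, 500, "-")),
               "different target")
})

test_that("pair classification applies the category rules in order", {
  p <- synteny_params()
  f <- mk_hit("f", "chr1", 100000, 100500, "+")
  r <- mk_hit("r", "chr1", 180000, 180500, "-")
  cl <- classify_pair(f, r, p)
  expect_equal(cl$category, "collinear")
  expect_equal(cl$span, 80500)

  # same span, same strands: rearranged
  r_plus <- mk_hit("r", "chr1", 180000, 180500, "+")
  expect_equal(classify_pair(f, r_plus, p)$category, "rearranged")

  # span below the minimum: gapped
  r_near <- mk_hit("r", "chr1", 108000, 108500, "-")
  expect_equal(classify_pair(f, r_near, p)$category, "gapped")

  # different chromosomes only: paired_end
  r_chr2 <- mk_hit("r", "chr2", 108000, 108500, "-")
  expect_equal(classify_pair(f, r_chr2, p)$category, "paired_end")

  expect_equal(classify_pair(f, f[0, ], p)$category, "single_end")
  expect_equal(classify_pair(f[0, ], f[0, ], p)$category, "no_hit")
})

test_that("span bounds are inclusive", {
  p <- synteny_params()
  f <- mk_hit("f", "chr1", 100000, 100500, "+")
  # span exactly 15000: end 115000, start 100000
  r <- mk_hit("r", "chr1", 114600, 115000, "-")
  expect_equal(classify_pair(f, r, p)$category, "collinear")
  r2 <- mk_hit("r", "chr1", 114599, 114999, "-")
  expect_equal(classify_pair(f, r2, p)$category, "gapped")
  # span exactly 250000
  r3 <- mk_hit("r", "chr1", 349600, 350000, "-")
  expect_equal(classify_pair(f, r3, p)$category, "collinear")
  r4 <- mk_hit("r", "chr1", 349601, 350001, "-")
  expect_equal(classify_pair(f, r4, p)$category, "gapped")
})

test_that("best in-range combination maximizes summed hit lengths", {
  p <- synteny_params()
  f <- mk_hit("f", "chr1", 100000, 100500, "+")
  # two reverse hits in range: a short one oriented badly, a long one well
  r <- rbind(mk_hit("r", "chr1", 150000, 150100, "+"),
             mk_hit("r", "chr1", 180000, 180500, "-"))
  expect_equal(classify_pair(f, r, p)$category, "collinear")
  # make the badly-oriented one the longest: rearranged
  r2 <- rbind(mk_hit("r", "chr1", 150000, 150900, "+"),
              mk_hit("r", "chr1", 180000, 180500, "-"))
  expect_equal(classify_pair(f, r2, p)$category, "rearranged")
})

random_hit_table <- function(pairs, n_hits) {
  ids <- c(pairs$pairs$forward_id, pairs$pairs$reverse_id)
  q <- sample(ids, n_hits, replace = TRUE)
  start <- sample.int(400000, n_hits)
  # distinct hit lengths keep best-combination selection tie-free
  len <- sample(300:899, n_hits)
  do.call(rbind, lapply(seq_len(n_hits), function(i) {
    mk_hit(q[i], sample(c("chr1", "chr2"), 1), start[i],
           start[i] + len[i], sample(c("+", "-"), 1))
  }))
}

test_that("category hierarchy identities hold on randomized hit tables", {
  set.seed(19)
  ids <- c(sprintf("c%02d.F", 1:12), sprintf("c%02d.R", 1:12))
  reads <- bes_reads(ids, vapply(ids, function(i) random_seq(50),
                                 character(1)))
  mates <- pair_reads(reads)
  for (rep in 1:15) {
    hits <- random_hit_table(mates, sample(5:60, 1))
    syn <- classify_dataset(mates, hits)
    cts <- syn$counts
    expect_equal(cts[["colocalized"]],
                 cts[["gapped"]] + cts[["non_gapped"]])
    expect_equal(cts[["non_gapped"]],
                 cts[["collinear"]] + cts[["rearranged"]])
    expect_gte(cts[["paired_end"]], cts[["colocalized"]])
    expect_equal(cts[["no_hit"]] + cts[["single_end"]] +
                   cts[["paired_end"]], nrow(mates$pairs))
  }
})

test_that("classification is invariant under relabeling and reflection", {
  set.seed(20)
  ids <- c(sprintf("c%02d.F", 1:10), sprintf("c%02d.R", 1:10))
  reads <- bes_reads(ids, vapply(ids, function(i) random_seq(50),
                                 character(1)))
  mates <- pair_reads(reads)
  hits <- random_hit_table(mates, 50)
  base <- classify_dataset(mates, hits)

  # swapping which end is called F and which R changes nothing
  swapped <- hits
  is_f <- grepl("\\.F$", hits$query_id)
  swapped$query_id <- ifelse(is_f, sub("\\.F$", ".R", hits$query_id),
                             sub("\\.R$", ".F", hits$query_id))
  expect_equal(classify_dataset(mates, swapped)$counts, base$counts)

  # reflecting the reference axis (mirrored coordinates, flipped strands)
  # changes nothing either
  L <- 500000
  mirrored <- hits
  mirrored$s_start <- L - hits$s_end + 1
  mirrored$s_end <- L - hits$s_start + 1
  mirrored$subject_strand <- ifelse(hits$subject_strand == "+", "-", "+")
  expect_equal(classify_dataset(mates, mirrored)$counts, base$counts)
})

test_that("empty hit tables classify every pair as no_hit", {
  ids <- c("a.F", "a.R", "b.F", "b.R")
  reads <- bes_reads(ids, rep("ACGTACGT", 4))
  mates <- pair_reads(reads)
  syn <- classify_dataset(mates, mk_hit("x", "chr1", 1, 100, "+")[0, ])
  expect_equal(unname(syn$counts[["no_hit"]]), 2)
})

test_that("pairs from in-range inserts with exact hits are collinear", {
  genome <- random_seq(400000)
  spec <- library_sim_spec(n_clones = 30, insert_mean = 50000,
                           insert_sd = 10000, insert_min = 20000,
                           insert_max = 100000, empty_rate = 0,
                           cp_rate = 0, read_retention = 1, seed = 25)
  cl <- sample_clones(400000, spec)
  sim <- simulate_bes_reads(genome, cl, spec)
  mates <- pair_reads(sim$reads)
  hits <- oakbes:::truth_to_hits(sim$truth)
  syn <- classify_dataset(mates, hits)
  expect_equal(unname(syn$counts[["collinear"]]), nrow(mates$pairs))
})
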