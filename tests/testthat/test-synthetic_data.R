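test_that("genome build is deterministic and truth tracks are sound", {
  fams <- data.frame(family_id = "fam1", consensus_len = 150,
                     copy_number = 5, divergence = 0)
  spec <- genome_spec(60000, repeat_families = fams,
                      ssr_plants = data.frame(motif = "AT", copies = 8,
                                              count = 2),
                      gene_plants = list(n_genes = 3),
                      min_gap = 150)
  g1 <- build_genome(spec, 42)
  g2 <- build_genome(spec, 42)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$truth, g2$truth)
  g3 <- build_genome(spec, 43)
  expect_false(identical(g1$sequence, g3$sequence))

  # five identical copies planted at the recorded intervals
  copies <- g1$truth[g1$truth$type == "repeat", ]
  expect_equal(nrow(copies), 5)
  seqs <- substring(g1$sequence, copies$start, copies$end)
  expect_equal(length(unique(seqs)), 1)
  expect_equal(unique(nchar(seqs)), 150)

  # truth intervals never overlap and respect the minimum gap
  tr <- g1$truth[order(g1$truth$start), ]
  expect_true(all(tr$start[-1] - tr$end[-nrow(tr)] - 1 >= 150))
  expect_true(all(tr$start >= 1 & tr$end <= 60000))
})

test_that("features exceeding genome capacity raise an error", {
  fams <- data.frame(family_id = "fam1", consensus_len = 1000,
                     copy_number = 20, divergence = 0)
  expect_error(build_genome(genome_spec(10000, repeat_families = fams),
                            1), "capacity")
})

test_that("copy divergence produces the expected pairwise identity", {
  fams <- data.frame(family_id = "fam1", consensus_len = 400,
                     copy_number = 10, divergence = 0.05)
  g <- build_genome(genome_spec(50000, repeat_families = fams), 9)
  copies <- g$truth[g$truth$type == "repeat", ]
  seqs <- strsplit(substring(g$sequence, copies$start, copies$end), "")
  idents <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    idents <- c(idents, mean(seqs[[i]] == seqs[[j]]))
  }
  # independent substitutions: P(agree) = (1-d)^2 + d^2/3 ~ 0.9033
  expect_equal(mean(idents), 0.9033, tolerance = 0.01)
})

test_that("clone sampling honors rates and insert bounds", {
  spec <- library_sim_spec(n_clones = 4000, insert_mean = 1000,
                           insert_sd = 300, insert_min = 500,
                           insert_max = 2000, empty_rate = 0.07,
                           cp_rate = 0, seed = 5)
  cl <- sample_clones(100000, spec)
  expect_true(all(cl$insert_len >= 500 & cl$insert_len <= 2000))
  expect_true(all(cl$start >= 1 & cl$end <= 100000))
  # empty fraction within a generous binomial band around 7%
  expect_lt(abs(mean(cl$is_empty) - 0.07), 0.015)

  all_empty <- sample_clones(100000,
    library_sim_spec(n_clones = 50, insert_mean = 1000, insert_sd = 0,
                     insert_min = 1000, insert_max = 1000,
                     empty_rate = 1, seed = 1))
  expect_true(all(all_empty$is_empty))
  expect_true(all(all_empty$insert_len == 1000))
})

test_that("end reads come from insert ends with correct orientation", {
  genome <- random_seq(3000)
  clones <- data.frame(clone_id = "cloneX", start = 1001L, end = 1600L,
                       insert_len = 600L, is_empty = FALSE, is_cp = FALSE)
  spec <- library_sim_spec(n_clones = 1, insert_mean = 600, insert_sd = 0,
                           insert_min = 600, insert_max = 600,
                           empty_rate = 0, cp_rate = 0,
                           read_len_mean = 100, read_len_sd = 0,
                           read_len_min = 100, read_len_max = 100,
                           read_retention = 1, seed = 2)
  sim <- simulate_bes_reads(genome, clones, spec)
  expect_equal(nrow(sim$reads), 2)
  f <- sim$reads[sim$reads$end_label == "F", ]
  r <- sim$reads[sim$reads$end_label == "R", ]
  expect_equal(f$sequence, substring(genome, 1001, 1100))
  expect_equal(r$sequence, revcomp(substring(genome, 1501, 1600)))
})

test_that("read retention matches the configured probability", {
  genome <- random_seq(50000)
  full <- library_sim_spec(n_clones = 200, insert_mean = 2000,
                           insert_sd = 200, insert_min = 1000,
                           insert_max = 3000, empty_rate = 0, cp_rate = 0,
                           read_len_mean = 300, read_len_sd = 0,
                           read_len_min = 300, read_len_max = 300,
                           read_retention = 1, seed = 3)
  sim <- simulate_bes_reads(genome, sample_clones(50000, full), full)
  expect_equal(pair_reads(sim$reads)$paired_fraction, 1)

  part <- full
  part$read_retention <- 0.6696
  part$n_clones <- 3000L
  class(part) <- "library_sim_spec"
  sim2 <- simulate_bes_reads(genome, sample_clones(50000, part), part)
  expect_equal(nrow(sim2$reads) / sim2$n_sequenced, 0.6696,
               tolerance = 0.02)
})

test_that("a clone covering the whole genome hits every marker", {
  clones <- data.frame(clone_id = "c1", start = 1L, end = 10000L,
                       insert_len = 10000L, is_empty = FALSE,
                       is_cp = FALSE)
  scr <- simulate_marker_screen(clones, 50, 10000, 4)
  expect_true(all(scr$hits >= 1))
})

test_that("background composition reproduces the target GC content", {
  g <- build_genome(genome_spec(300000), 21)
  gc <- dataset_stats(bes_reads("g.F", g$sequence))$gc_fraction
  expect_equal(gc, 0.3533, tolerance = 0.005)
})

test_that("truth tracks survive a BED round trip", {
  fams <- data.frame(family_id = "fam1", consensus_len = 120,
                     copy_number = 3, divergence = 0)
  g <- build_genome(genome_spec(20000, repeat_families = fams,
                                gene_plants = list(n_genes = 2)), 6)
  f <- withr::local_tempfile(fileext = ".bed")
  write_truth_bed(g$truth, f)
  back <- read_truth_bed(f)
  expect_equal(back$start, g$truth$start)
  expect_equal(back$end, g$truth$end)
  expect_equal(back$type, g$truth$type)
  expect_equal(back$label, g$truth$label)
})
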