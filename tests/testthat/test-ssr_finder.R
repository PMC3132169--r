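test_that("span thresholds bound detection per period", {
  # dinucleotide: 16 bp passes, 14 bp does not
  hit <- find_perfect_ssrs(strrep("AT", 8))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$motif, "AT")
  expect_equal(hit$span, 16)
  expect_equal(hit$copies, 8)
  expect_equal(nrow(find_perfect_ssrs(strrep("AT", 7))), 0)
  # trinucleotide at 15 bp, not also reported as a hexamer
  tri <- find_perfect_ssrs("AAGAAGAAGAAGAAG")
  expect_equal(nrow(tri), 1)
  expect_equal(tri$period, 3)
  expect_equal(tri$copies, 5)
  # tetra 16, penta 15, hexa 18
  expect_equal(find_perfect_ssrs(strrep("ACGT", 4))$period, 4)
  expect_equal(nrow(find_perfect_ssrs(strrep("ACGT", 3))), 0)
  expect_equal(find_perfect_ssrs(strrep("AACGT", 3))$period, 5)
  expect_equal(find_perfect_ssrs(strrep("AACGTT", 3))$period, 6)
  expect_equal(nrow(find_perfect_ssrs(strrep("AACGTT", 2))), 0)
})

test_that("non-primitive motifs are reported at their base period", {
  hit <- find_perfect_ssrs(strrep("ATAT", 5))
  expect_equal(hit$period, 2)
  expect_equal(hit$motif, "AT")
})

test_that("partial trailing copies give fractional copy numbers", {
  hit <- find_perfect_ssrs(paste0(strrep("AAG", 6), "A"))
  expect_equal(hit$span, 19)
  expect_equal(hit$copies, 19 / 3)
})

test_that("runs are broken at N and detection is case-insensitive", {
  expect_equal(nrow(find_perfect_ssrs(paste0(strrep("AT", 4), "N",
                                             strrep("AT", 4)))), 0)
  hit <- find_perfect_ssrs(tolower(strrep("at", 8)))
  expect_equal(hit$motif, "AT")
})

test_that("canonical classes merge rotations and reverse complements", {
  expect_equal(canonical_class("GA"), "AG")
  expect_equal(canonical_class("TC"), "AG")
  expect_equal(canonical_class("CT"), "AG")
  expect_equal(canonical_class("AT"), "AT")
  expect_equal(canonical_class("GGC"), "CCG")
  expect_error(canonical_class("AX"), "motif")
  set.seed(14)
  for (rep in 1:20) {
    m <- random_seq(sample(1:6, 1))
    expect_equal(canonical_class(revcomp(m)), canonical_class(m))
    r <- sample(nchar(m), 1)
    rot <- paste0(substr(m, r, nchar(m)), substr(m, 1, r - 1))
    expect_equal(canonical_class(rot), canonical_class(m))
  }
})

test_that("finder agrees with the brute-force enumeration oracle", {
  set.seed(15)
  for (rep in 1:12) {
    s <- random_seq(sample(800:2000, 1))
    # plant a few SSRs to guarantee non-trivial cases
    for (m in list(c("AT", 9), c("AAG", 7), c("ACAT", 5), c("AACGTT", 4))) {
      pos <- sample(nchar(s) - 60, 1)
      ins <- strrep(m[1], as.integer(m[2]))
      substr(s, pos, pos + nchar(ins) - 1) <- ins
    }
    got <- find_perfect_ssrs(s)
    ora <- ssr_oracle(s)
    expect_equal(got$start, ora$start)
    expect_equal(got$end, ora$end)
    expect_equal(got$period, ora$period)
    expect_equal(got$motif, ora$motif)
  }
})

test_that("reverse-complementing the input mirrors loci coordinates", {
  set.seed(16)
  s <- paste0(random_seq(100), strrep("AG", 10), random_seq(60),
              strrep("AAT", 6), random_seq(100))
  fwd <- find_perfect_ssrs(s)
  rev <- find_perfect_ssrs(revcomp(s))
  n <- nchar(s)
  expect_equal(nrow(fwd), nrow(rev))
  mirrored <- data.frame(start = n - rev$end + 1, end = n - rev$start + 1,
                         class = rev$canonical_class)
  mirrored <- mirrored[order(mirrored$start), ]
  expect_equal(mirrored$start, fwd$start)
  expect_equal(mirrored$end, fwd$end)
  expect_equal(mirrored$class, fwd$canonical_class)
})

test_that("planted SSRs are recovered exactly from synthetic genomes", {
  plants <- data.frame(motif = c("AT", "AG", "AAC", "ACGT"),
                       copies = c(10, 8, 6, 5),
                       count = c(4, 3, 3, 2))
  g <- build_genome(genome_spec(150000, ssr_plants = plants,
                                min_gap = 120), 23)
  found <- find_perfect_ssrs(g$sequence, seq_id = "genome")
  truth <- g$truth[g$truth$type == "ssr", ]
  truth <- truth[order(truth$start), ]
  # every planted locus is present with exact position, motif and span
  key_found <- paste(found$start, found$end, found$motif)
  key_truth <- paste(truth$start, truth$end, truth$motif)
  expect_true(all(key_truth %in% key_found))
})

test_that("summaries report counts, classes and frequencies", {
  loci <- rbind(
    data.frame(seq_id = "s", start = 1, end = 16, period = 2, motif = "AT",
               canonical_class = "AT", span = 16, copies = 8),
    data.frame(seq_id = "s", start = 100, end = 115, period = 2,
               motif = "AG", canonical_class = "AG", span = 16, copies = 8),
    data.frame(seq_id = "s", start = 200, end = 214, period = 3,
               motif = "AAG", canonical_class = "AAG", span = 15,
               copies = 5))
  sm <- ssr_summary(loci, 100000)
  expect_equal(sm$n_ssr, 3)
  expect_equal(sm$per_100kb, 3)
  expect_equal(sm$kb_per_ssr, 100 / 3)
  di <- sm$by_period[sm$by_period$period == 2, ]
  expect_equal(di$count, 2)
  expect_equal(di$pct, 66.67)
  at <- sm$by_class[sm$by_class$class == "AT", ]
  expect_equal(at$pct_within_period, 50)

  # the observed-scale dinucleotide share: 1672 of 3531 is 47.35%
  big <- data.frame(seq_id = "s", start = 1, end = 16,
                    period = rep(c(2, 3, 4, 5, 6),
                                 c(1672, 564, 386, 590, 319)),
                    motif = "AT", canonical_class = "AT", span = 16,
                    copies = 8)
  sm2 <- ssr_summary(big, 12018238)
  expect_equal(sm2$n_ssr, 3531)
  expect_equal(sm2$by_period$pct[sm2$by_period$period == 2], 47.35)

  none <- ssr_summary(loci[0, ], 1000)
  expect_equal(none$n_ssr, 0)
  expect_true(is.na(none$kb_per_ssr))
  expect_error(ssr_summary(loci, 0), "positive")
})
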