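test_that("identical and reverse-complement sequences align as expected", {
  set.seed(1)
  s <- random_seq(120)
  h <- local_align(s, s)
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 1)
  expect_equal(h$n_columns, 120)
  expect_equal(h$subject_strand, "+")
  expect_equal(c(h$q_start, h$q_end, h$s_start, h$s_end),
               c(1L, 120L, 1L, 120L))

  h2 <- local_align(s, revcomp(s))
  expect_equal(nrow(h2), 1)
  expect_equal(h2$subject_strand, "-")
  expect_equal(h2$identity, 1)
  expect_equal(c(h2$s_start, h2$s_end), c(1L, 120L))

  expect_error(local_align("", s), "empty")
})

test_that("best-hit score equals the Smith-Waterman oracle", {
  set.seed(2)
  # a 200-bp pair with 12 scattered substitutions
  a <- random_seq(200)
  b <- a
  pos <- sample(200, 12)
  for (i in pos) {
    substr(b, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(a, i, i)), 1)
  }
  h <- local_align(a, b)
  expect_equal(max(h$score), sw_oracle_score(a, b))
})

test_that("seed-gated alignment agrees with the DP oracle on random pairs", {
  set.seed(4)
  for (rep in 1:60) {
    # shared diverged segment embedded in unrelated flanks
    seg <- random_seq(sample(100:250, 1))
    fa <- sample(0:150, 2); fb <- sample(0:150, 2)
    q <- paste0(random_seq(fa[1]), seg, random_seq(fa[2]))
    s <- paste0(random_seq(fb[1]), mutate_seq(seg, 0.03), random_seq(fb[2]))
    h <- local_align(q, s)
    ora <- sw_oracle_score(q, s)
    if (nrow(h) > 0) {
      expect_equal(max(h$score), ora)
    } else {
      # no report is only legitimate without a seed or below min score
      expect_true(ora < 28 ||
                    nrow(oakbes:::.cpp_candidate_pairs(c(q, s), 11L)) == 0)
    }
  }
  # unrelated pairs: no hit, and the oracle confirms nothing reportable
  for (rep in 1:20) {
    q <- random_seq(400); s <- random_seq(400)
    h <- local_align(q, s)
    if (nrow(h) == 0) expect_lt(sw_oracle_score(q, s), 28)
  }
})

test_that("sliding-window identity rule thresholds exactly", {
  pass100 <- rep(TRUE, 100)
  expect_true(window_identity_pass(pass100))
  mv10 <- pass100; mv10[sample(100, 10)] <- FALSE
  expect_true(window_identity_pass(mv10))
  mv11 <- pass100; mv11[sample(100, 11)] <- FALSE
  expect_false(window_identity_pass(mv11))
  # 200 columns, 15 mismatches concentrated in columns 50-149
  mv <- rep(TRUE, 200); mv[sample(50:149, 15)] <- FALSE
  expect_false(window_identity_pass(mv))
  # shorter than one window never passes
  expect_false(window_identity_pass(rep(TRUE, 99)))
  expect_error(window_identity_pass(pass100, w = 0), "positive")
})

test_that("tabular hits are parsed with canonical coordinates", {
  hits <- read_tabular_hits(extdata("example_hits.tsv"))
  expect_equal(nrow(hits), 3)
  expect_equal(hits$query_id, c("readA.F", "readA.R", "readB.F"))
  expect_equal(hits$subject_strand, c("+", "-", "+"))
  # reverse-strand subject coordinates are swapped to start <= end
  expect_equal(hits$s_start[2], 180021)
  expect_equal(hits$s_end[2], 180200)
  expect_equal(hits$identity[3], 0.91)
  expect_equal(hits$evalue[1], 1e-80)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_equal(nrow(read_tabular_hits(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t90\t100\t1\t0\t1\t100\t1\t100\t1e-5\t90",
               "a\tb\t90"), bad)
  expect_error(read_tabular_hits(bad), "line 2")
})

test_that("tabular write/read round-trips hit coordinates and strand", {
  set.seed(5)
  a <- random_seq(300)
  b <- paste0(random_seq(40), revcomp(substr(a, 51, 250)), random_seq(40))
  h <- local_align(a, b, query_id = "qA", subject_id = "sB")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tabular_hits(h, f)
  back <- read_tabular_hits(f)
  expect_equal(back$q_start, h$q_start)
  expect_equal(back$s_start, h$s_start)
  expect_equal(back$s_end, h$s_end)
  expect_equal(back$subject_strand, h$subject_strand)
})

test_that("approximate match vectors honor identity and window rule", {
  hits <- read_tabular_hits(extdata("example_hits.tsv"),
                            approximate_match_vector = TRUE)
  mv <- hits$match_vector[[1]]
  expect_length(mv, hits$n_columns[1])
  expect_equal(sum(mv), round(hits$identity[1] * hits$n_columns[1]))
})

test_that("reads sharing one planted element all match each other", {
  set.seed(6)
  element <- random_seq(150)
  reads <- reads_with_element(5, element)
  mc <- self_match_counts(reads)
  expect_equal(unname(mc$counts), rep(4L, 5))
  expect_equal(nrow(mc$pairs), choose(5, 2))
})

test_that("unrelated random reads produce no matches", {
  set.seed(8)
  reads <- bes_reads(sprintf("c%03d.F", 1:60),
                     vapply(1:60, function(i) random_seq(600),
                            character(1)))
  mc <- self_match_counts(reads)
  expect_equal(mc$n_matching, 0)
})

test_that("masking the shared element removes matches, never adds them", {
  set.seed(9)
  element <- random_seq(150)
  reads <- reads_with_element(6, element)
  mc <- self_match_counts(reads)
  expect_true(all(mc$counts == 5))
  # mask the element interval (columns 221-370 of every read)
  mask <- data.frame(read_id = reads$read_id, start = 221, end = 370)
  mc2 <- self_match_counts(reads, mask = mask)
  expect_true(all(mc2$counts <= mc$counts))
  expect_equal(mc2$n_matching, 0)
})

test_that("tabular engine counts distinct window-passing partners", {
  mv_pass <- rep(TRUE, 120)
  mv_fail <- c(rep(FALSE, 15), rep(TRUE, 105))
  hits <- empty <- read_tabular_hits(extdata("example_hits.tsv"))[0, ]
  add <- function(h, q, s, mv) {
    row <- data.frame(query_id = q, subject_id = s, q_start = 1,
                      q_end = length(mv), s_start = 1, s_end = length(mv),
                      subject_strand = "+", n_columns = length(mv),
                      identity = mean(mv), score = 100, evalue = 1e-60,
                      stringsAsFactors = FALSE)
    row$match_vector <- list(mv)
    rbind(h, row)
  }
  hits <- add(hits, "r1", "r2", mv_pass)
  hits <- add(hits, "r2", "r1", mv_pass)  # symmetric duplicate
  hits <- add(hits, "r1", "r3", mv_fail)
  hits <- add(hits, "r2", "r2", mv_pass)  # self-hit ignored
  reads <- bes_reads(c("r1.F", "r2.F", "r3.F"),
                     c("ACGTACGT", "ACGTACGT", "ACGTACGT"))
  reads$read_id <- c("r1", "r2", "r3")
  mc <- self_match_counts(reads, engine = "tabular", hits = hits)
  expect_equal(unname(mc$counts), c(1L, 1L, 0L))
  expect_equal(nrow(mc$pairs), 1)
})
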