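test_that("self-alignment and strand symmetry behave as expected", {
  sch <- scoring_scheme()
  h <- smith_waterman("ACGTACGT", "ACGTACGT", sch)
  expect_equal(h$score[1], 40)         # 8 matches x 5
  expect_equal(h$identity[1], 1)
  expect_equal(h$strand[1], "+")       # "+" preferred on exact ties
  # no positive forward alignment, full reverse-complement alignment
  h2 <- smith_waterman("AAAA", "TTTT", sch, score_floor = 5)
  expect_true(all(h2$strand == "-"))
  expect_equal(h2$score[1], 20)
  expect_error(smith_waterman("", "ACGT", sch), "parameter error")
})

test_that("optimal scores equal an independent full-matrix DP oracle", {
  sch <- scoring_scheme()
  set.seed(21)
  for (i in 1:60) {
    q <- random_seq(30)
    s <- random_seq(200)
    got <- smith_waterman(q, s, sch, both_strands = FALSE,
                          score_floor = 1, max_hsps = 1)
    expect_equal(got$score[1], sw_score_oracle(q, s))
  }
})

test_that("alignment score is symmetric in its arguments", {
  sch <- scoring_scheme()
  set.seed(22)
  for (i in 1:15) {
    a <- random_seq(80); b <- random_seq(80)
    sa <- smith_waterman(a, b, sch, both_strands = FALSE, score_floor = 1,
                         max_hsps = 1)$score[1]
    sb <- smith_waterman(b, a, sch, both_strands = FALSE, score_floor = 1,
                         max_hsps = 1)$score[1]
    expect_equal(sa, sb)
  }
})

test_that("lambda matches an independently coded bisection to 1e-6", {
  sch <- scoring_scheme()
  expect_equal(sch$lambda, lambda_bisect_oracle(), tolerance = 1e-6)
  expect_gt(sch$lambda, 0)
  # lambda solves the defining equation
  expect_equal(0.25 * exp(sch$lambda * 5) + 0.75 * exp(-sch$lambda * 4), 1,
               tolerance = 1e-9)
  # a non-negative expected step score has no local-alignment statistics
  expect_error(karlin_altschul(4L, -1L), "parameter error")
})

test_that("E-values are monotone in score and linear in search space", {
  sch <- scoring_scheme()
  expect_gt(estimate_evalue(50, 200, 1000, sch),
            estimate_evalue(60, 200, 1000, sch))
  expect_equal(estimate_evalue(80, 200, 2000, sch),
               2 * estimate_evalue(80, 200, 1000, sch))
  expect_error(estimate_evalue(50, 0, 1000, sch), "parameter error")
})

test_that("a read aligns to its error-free source with identity 1", {
  ref <- fixture_reference()
  sim <- fixture_clean_sim()
  tr <- head(sim$truth[sim$truth$source_id == "MT_ND4", ], 5)
  reads <- fixture_clean_demux()$bins
  for (k in seq_len(nrow(tr))) {
    ts <- tr$tissue[k]
    r <- reads[[ts]]$reads[[tr$read_id[k]]]
    h <- smith_waterman(r, ref$seqs[["MT_ND4"]], score_floor = 50,
                        max_hsps = 1)
    expect_equal(h$identity[1], 1)
    expect_equal(h$score[1], 5 * nchar(r))
  }
})

test_that("seeded search reproduces exact-mode top HSPs", {
  ref <- fixture_reference()
  sch <- scoring_scheme()
  dm <- fixture_demux()
  reads <- head(dm$bins$digestive_gland$reads, 60)
  seeded <- seeded_search(reads, c(genome = ref$genome), sch,
                          score_floor = 120)
  for (id in unique(seeded$query)) {
    exact <- smith_waterman(reads[[id]], ref$genome, sch,
                            score_floor = 120, max_hsps = 1)
    expect_equal(max(seeded$score[seeded$query == id]), exact$score[1])
  }
})

test_that("homology matrix handles identity, disjoint and planted cases", {
  set.seed(23)
  ref_set <- setNames(vapply(1:30, function(i) random_seq(600), ""),
                      sprintf("R%02d", 1:30))
  # planted: exactly 10 of 100 query contigs carry a reference substring
  query <- setNames(vapply(1:100, function(i) random_seq(600), ""),
                    sprintf("Q%03d", 1:100))
  for (i in 1:10) {
    donor <- ref_set[[i]]
    query[[i]] <- paste0(substr(query[[i]], 1, 300),
                         substr(donor, 151, 450))
  }
  m <- homology_matrix(list(A = query, B = ref_set))
  expect_equal(m["A", "A"], 100.0)
  expect_equal(m["B", "B"], 100.0)
  expect_equal(m["B", "A"], 10.0)    # row = reference, column = query
  # disjoint random sets share nothing
  other <- setNames(vapply(1:20, function(i) random_seq(500), ""),
                    sprintf("O%02d", 1:20))
  m2 <- homology_matrix(list(A = ref_set, B = other))
  expect_equal(m2["A", "B"], 0.0)
  expect_equal(m2["B", "A"], 0.0)
  expect_error(homology_matrix(list(A = ref_set, B = character(0))),
               "parameter error")
})

test_that("HSP tables export in 12-column tabular form", {
  sch <- scoring_scheme()
  h <- smith_waterman("ACGTACGTACGTACGT", "ACGTACGTACGTACGT", sch)
  f <- tempfile()
  write_hsps(h, f)
  tab <- read.delim(f, header = FALSE)
  expect_equal(ncol(tab), 12L)
  expect_equal(tab$V7[1], 1)   # 1-based inclusive in the file
  expect_equal(tab$V8[1], 16)
})
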