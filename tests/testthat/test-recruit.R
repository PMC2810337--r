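test_that("an exact genome substring recruits at its true coordinates", {
  ref <- fixture_reference()
  r <- substr(ref$genome, 2001, 2200)
  hits <- recruit_reads(c(read1 = r), ref$genome)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$sstart, 2000L)
  expect_equal(hits$send, 2200L)
  expect_equal(hits$identity, 1)
  # a read with no genome homology is omitted
  set.seed(31)
  none <- recruit_reads(c(read2 = random_seq(200)), ref$genome)
  expect_equal(nrow(none), 0L)
  expect_error(recruit_reads(c(a = "ACGT"), ""), "parameter error")
})

test_that("recruitment recovers exactly the mitochondrial truth set", {
  ref <- fixture_reference()
  sim <- fixture_clean_sim()
  bin <- fixture_clean_demux()$bins$digestive_gland
  hits <- recruit_reads(bin, ref$genome)
  truth <- sim$truth[sim$truth$tissue == "digestive_gland", ]
  mito_ids <- truth$read_id[startsWith(truth$source_id, "MT_")]
  expect_setequal(hits$read, mito_ids)
  expect_true(all(hits$identity == 1))
})

test_that("recruitment rates order as digestive gland, gill > foot, mantle", {
  rec <- fixture_recruit()
  dm <- fixture_demux()
  rate <- vapply(names(rec), function(ts)
    nrow(rec[[ts]]) / dm$bins[[ts]]$n_assigned, numeric(1))
  expect_gt(min(rate[c("digestive_gland", "gill")]),
            max(rate[c("foot", "mantle")]))
})

test_that("sub-pixel hits are invisible at the published scale", {
  mk <- function(len) data.frame(read = "r", sstart = 1000L,
                                 send = 1000L + len, strand = "+",
                                 identity = 1, score = 5L * len,
                                 length = len, evalue = 0)
  m16 <- build_matrix(mk(16L), 16744L)
  expect_equal(m16$n_visible, 0L)
  expect_equal(sum(m16$counts), 0L)
  m17 <- build_matrix(mk(17L), 16744L)
  expect_equal(m17$n_visible, 1L)
  expect_gt(sum(m17$counts), 0)
  expect_error(build_matrix(mk(17L), 1000L), "parameter error")
})

test_that("a full-genome hit fills the top identity row", {
  h <- data.frame(read = "r", sstart = 0L, send = 16744L, strand = "+",
                  identity = 1, score = 1L, length = 16744L, evalue = 0)
  m <- build_matrix(h, 16744L)
  top <- m$counts[nrow(m$counts), ]
  expect_true(all(top == 1))
  expect_equal(sum(m$counts), 1024)
})

test_that("visible-hit bookkeeping matches direct filtering", {
  set.seed(32)
  n <- 500
  st <- sample.int(16000, n)
  len <- sample(5:400, n, replace = TRUE)
  hits <- data.frame(read = sprintf("r%d", 1:n), sstart = st,
                     send = pmin(st + len, 16744L), strand = "+",
                     identity = runif(n, 0.5, 1), score = 100L,
                     length = len, evalue = 0)
  m <- build_matrix(hits, 16744L)
  expect_equal(m$n_visible,
               sum(floor((hits$send - hits$sstart) * 1024 / 16744) >= 1))
  # per-hit increments: one count per covered pixel column, so the total
  # equals the summed pixel spans of visible hits
  expect_gte(sum(m$counts), m$n_visible)
  # invariance to hit ordering
  m2 <- build_matrix(hits[sample.int(n), ], 16744L)
  expect_identical(m$counts, m2$counts)
})

test_that("gene abundance counts qualifying overlaps per annotation", {
  ref <- fixture_reference()
  ann <- ref$annotations
  expect_true(all(gene_abundance(
    data.frame(read = character(0), sstart = integer(0), send = integer(0),
               strand = character(0), identity = numeric(0),
               score = integer(0), length = integer(0),
               evalue = numeric(0)),
    ann, 10000)$abundance == 0))
  nd4 <- ann[ann$name == "ND4", ]
  h <- data.frame(read = sprintf("r%d", 1:100),
                  sstart = nd4$start + 10L, send = nd4$start + 110L,
                  strand = "+", identity = 1, score = 500L, length = 100L,
                  evalue = 0)
  ga <- gene_abundance(h, ann, 10000)
  expect_equal(ga$abundance[ga$name == "ND4"], 0.01)
  # identity and length cutoffs both bind
  h$identity <- 0.97
  expect_equal(sum(gene_abundance(h, ann, 10000)$count), 0)
  h$identity <- 1; h$length <- 49L
  expect_equal(sum(gene_abundance(h, ann, 10000)$count), 0)
  expect_error(gene_abundance(h, ann, 0), "parameter error")
})

test_that("recruitment recovers the 2:1 ND4 vs COX1 expression ratio", {
  ref <- fixture_reference()
  rec <- fixture_recruit()
  counts <- Reduce(`+`, lapply(rec, function(h) {
    ga <- gene_abundance(h, ref$annotations, 1000)
    setNames(ga$count, ga$name)
  }))
  ratio <- counts[["ND4"]] / counts[["COX1"]]
  se <- ratio * sqrt(1 / counts[["ND4"]] + 1 / counts[["COX1"]])
  expect_lt(abs(ratio - 2), 3 * se)
})

test_that("the planted cryptic segment is found only in digestive gland", {
  ref <- fixture_reference()
  rec <- fixture_recruit()
  for (ts in names(rec)) {
    reg <- unannotated_regions(rec[[ts]], ref$annotations,
                               nchar(ref$genome))
    if (ts == "digestive_gland") {
      expect_equal(nrow(reg), 1L)
      expect_lt(reg$start[1], ref$cryptic[2])
      expect_gt(reg$end[1], ref$cryptic[1])
      expect_gt(reg$mean_identity[1], 0.95)
      expect_gte(reg$max_coverage[1], 5)
    } else {
      expect_equal(nrow(reg), 0L)
    }
  }
})

test_that("coverage below threshold yields no unannotated regions", {
  ref <- fixture_reference()
  # 4 identical intergenic hits: one short of the default threshold
  s0 <- ref$cryptic[1]
  h <- data.frame(read = sprintf("r%d", 1:4), sstart = s0,
                  send = s0 + 100L, strand = "+", identity = 1,
                  score = 500L, length = 100L, evalue = 0)
  expect_equal(nrow(unannotated_regions(h, ref$annotations,
                                        nchar(ref$genome))), 0L)
  h5 <- rbind(h, h[1, ])
  h5$read <- sprintf("r%d", 1:5)
  expect_equal(nrow(unannotated_regions(h5, ref$annotations,
                                        nchar(ref$genome))), 1L)
  # hits confined to annotated genes produce nothing
  nd5 <- ref$annotations[ref$annotations$name == "ND5", ]
  hg <- data.frame(read = sprintf("g%d", 1:20), sstart = nd5$start,
                   send = nd5$start + 200L, strand = "+", identity = 1,
                   score = 1000L, length = 200L, evalue = 0)
  expect_equal(nrow(unannotated_regions(hg, ref$annotations,
                                        nchar(ref$genome))), 0L)
})
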