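test_that("reference generation is deterministic and well-formed", {
  r1 <- make_reference(seed = 1)
  r2 <- make_reference(seed = 1)
  expect_identical(r1, r2)
  r3 <- make_reference(seed = 2)
  expect_false(identical(r1$genome, r3$genome))

  ann <- r1$annotations
  expect_equal(sum(ann$category == "CDS"), 12L)
  expect_equal(sum(ann$category == "rRNA"), 2L)
  expect_equal(nchar(r1$genome), 16744L)
  expect_true(all(ann$start >= 0 & ann$start < ann$end & ann$end <= 16744))
  # cryptic segment sits 5' of CYTB, outside every annotation
  cytb <- ann[ann$name == "CYTB", ]
  expect_lt(r1$cryptic[2], cytb$start + 1)
  expect_true(all(r1$cryptic[2] <= ann$start | r1$cryptic[1] >= ann$end))
  expect_false("MT_cryptic_CYTB5p" %in% r1$db$id)
  # marker inventory
  expect_true(all(c("vdg3", "HSP90", "VERL", "VCL", "fp_pm1", "fp_pm2") %in%
                    r1$transcripts$id))
  expect_false(anyDuplicated(r1$transcripts$id) > 0)
  # db labels: exactly one taxon and one subsystem per entry
  expect_true(all(nzchar(r1$db$taxon) & nzchar(r1$db$subsystem)))
})

test_that("oversized gene request is rejected", {
  cfg <- default_reference_config()
  cfg$cds["ND5"] <- 20000L
  expect_error(make_reference(cfg, seed = 1), "config error")
})

test_that("tissue profiles encode the marker and fraction structure", {
  prof <- fixture_profiles()
  for (p in prof) {
    expect_s3_class(p, "tissue_profile")
    expect_equal(sum(p$weights), 1, tolerance = 1e-9)
    expect_true(all(p$weights >= 0))
  }
  expect_identical(prof$foot$weights[["vdg3"]], 0)
  expect_identical(prof$gill$weights[["vdg3"]], 0)
  expect_identical(prof$mantle$weights[["vdg3"]], 0)
  expect_gt(prof$digestive_gland$weights[["vdg3"]], 0)
  expect_gt(prof$gill$weights[["HSP90"]], 0)
  expect_identical(prof$foot$weights[["HSP90"]], 0)
  expect_gt(prof$foot$weights[["fp_pm1"]], 0)
  expect_identical(prof$gill$weights[["fp_pm1"]], 0)
  expect_equal(prof$digestive_gland$bacterial_fraction /
                 prof$mantle$bacterial_fraction, 3, tolerance = 1e-12)
  # equal sex mix gives equal VERL and VCL template weights
  for (p in prof) expect_equal(p$weights[["VERL"]], p$weights[["VCL"]])
  # expressed-transcript richness: digestive gland and gill exceed
  # foot and mantle (drives their higher singleton rates)
  rich <- vapply(prof, function(p) sum(p$weights > 0), integer(1))
  expect_gt(min(rich[c("digestive_gland", "gill")]),
            max(rich[c("foot", "mantle")]))
})

test_that("out-of-range fractions are rejected", {
  cfg <- default_profile_config()
  cfg$mito_fraction["foot"] <- 1.4
  expect_error(make_profiles(fixture_reference(), cfg), "parameter error")
})

test_that("MID tags are 10-mers with pairwise Hamming distance >= 4", {
  tags <- default_mid_tags()
  expect_true(all(nchar(tags) == 10))
  splits <- strsplit(tags, "")
  for (i in seq_along(tags)) for (j in seq_along(tags)) {
    if (i >= j) next
    expect_gte(sum(splits[[i]] != splits[[j]]), 4)
  }
})

test_that("zero-noise reads reproduce MID + transcript exactly", {
  ref <- fixture_reference()
  w <- setNames(numeric(nrow(ref$transcripts)), ref$transcripts$id)
  w["hk001"] <- 1
  p <- structure(list(tissue = "gill", weights = w, mito_fraction = 0,
                      bacterial_fraction = 0, sex_mix = 0.5),
                 class = "tissue_profile")
  L <- nchar(ref$seqs[["hk001"]])
  sim <- simulate_reads(ref, list(gill = p), n_reads = c(gill = 30L),
                        error_model = list(sub_rate = 0,
                                           homopolymer_rate = 0),
                        length_model = list(mean = c(gill = L + 50),
                                            sd = 0, bounds = c(50L, L + 50)),
                        seed = 3)
  tag <- default_mid_tags()[["gill"]]
  want <- c(paste0(tag, ref$seqs[["hk001"]]),
            paste0(tag, revcomp(ref$seqs[["hk001"]])))
  expect_true(all(sim$reads$sequence %in% want))
  expect_true(all(sim$truth$source_id == "hk001"))
})

test_that("read pool conserves counts and is byte-deterministic", {
  sim <- fixture_sim()
  expect_equal(nrow(sim$reads), sum(default_n_reads()))
  expect_equal(nrow(sim$truth), nrow(sim$reads))
  expect_false(anyDuplicated(sim$reads$id) > 0)
  expect_setequal(sim$truth$read_id, sim$reads$id)
  # identical seed, identical FASTA bytes
  sim2 <- simulate_reads(fixture_reference(), fixture_profiles(), seed = 7)
  f1 <- tempfile(); f2 <- tempfile()
  write_reads_fasta(sim, f1); write_reads_fasta(sim2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(sim$truth, sim2$truth)
})

test_that("emitted read lengths match the configured mean", {
  # independent recount from the written FASTA
  f <- tempfile()
  write_reads_fasta(fixture_sim(), f)
  lens <- nchar(read_fasta(f))
  expect_gt(length(lens), 10000)
  expect_lt(abs(mean(lens) - 196), 5)
})

test_that("per-transcript sampling recovers the profile weights", {
  sim <- fixture_clean_sim()
  prof <- fixture_profiles()
  for (ts in names(prof)) {
    tr <- sim$truth[sim$truth$tissue == ts, ]
    n <- nrow(tr)
    w <- prof[[ts]]$weights
    for (id in names(w)[w >= 0.01]) {
      phat <- mean(tr$source_id == id)
      se <- sqrt(w[[id]] * (1 - w[[id]]) / n)
      expect_lt(abs(phat - w[[id]]), 3 * se + 1e-12)
    }
  }
})

test_that("degenerate read requests error out", {
  expect_error(simulate_reads(fixture_reference(), fixture_profiles(),
                              n_reads = c(gill = 0L), seed = 1),
               "parameter error")
})
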