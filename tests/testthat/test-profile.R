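test_that("contig annotation assigns exact copies and skips noise", {
  ref <- fixture_reference()
  db <- ref$seqs[ref$db$id]
  ann <- annotate_contigs(c(c1 = ref$seqs[["hk010"]]), db)
  expect_equal(ann$feature[ann$contig == "c1"], "hk010")
  set.seed(41)
  none <- annotate_contigs(c(c2 = random_seq(400)), db)
  expect_equal(nrow(none), 0L)
  expect_error(annotate_contigs(c(c1 = "ACGT"), character(0)),
               "configuration error")
})

test_that("single-source contigs annotate to their source transcript", {
  ref <- fixture_reference()
  sim <- fixture_clean_sim()
  bin <- fixture_clean_demux()$bins$foot
  asm <- greedy_assemble(bin)
  ann <- annotate_contigs(asm, ref$seqs[ref$db$id])
  truth_src <- setNames(sim$truth$source_id, sim$truth$read_id)
  feats <- setNames(ann$feature, ann$contig)
  checked <- 0L
  for (k in seq_len(nrow(asm$contigs))) {
    src <- unique(truth_src[asm$members[[k]]])
    if (length(src) != 1 || startsWith(src, "MT_cryptic")) next
    expect_equal(unname(feats[[asm$contigs$id[k]]]), unname(src))
    checked <- checked + 1L
  }
  expect_gt(checked, 10)
})

test_that("abundance percentages follow the half-up rounding rule", {
  p1 <- abundance_profile(c(ND4 = 1190), 175547, sample = "all")
  expect_equal(top_features(list(p1))$pct, 0.7)
  p2 <- abundance_profile(c(fp = 477), 31227, sample = "foot")
  expect_equal(top_features(list(p2))$pct, 1.5)
  empty <- abundance_profile(setNames(numeric(0), character(0)), 100)
  expect_equal(nrow(top_features(list(empty))), 0L)
  expect_error(abundance_profile(c(a = 200), 100), "consistency error")
})

test_that("marker ratio and distribution handle the simple identities", {
  mk <- function(v, c, n = 10000, s = "t")
    abundance_profile(c(VERL = v, VCL = c), n, sample = s)
  r <- marker_ratio(list(a = mk(500, 500)))
  expect_equal(r$ratio, 1)
  r2 <- marker_ratio(list(a = mk(120, 60, s = "a"), b = mk(0, 40, s = "b")))
  expect_equal(r2$ratio, 1.2)
  expect_equal(unname(r2$distribution_pct["VERL", "a"]), 100)
  expect_error(marker_ratio(list(a = mk(10, 0))), "undefined ratio")
})

test_that("read classification enforces both cutoffs and keeps labels", {
  ref <- fixture_reference()
  # an exact 49-base match is strong but one column too short
  short <- substr(ref$seqs[["bact001"]], 1, 49)
  cl <- classify_reads(c(r1 = short), ref)
  expect_equal(nrow(cl$assignments), 0L)
  expect_equal(cl$n_unassigned, 1L)
  # at 50 columns the same read passes and carries the right labels
  ok <- substr(ref$seqs[["bact001"]], 1, 60)
  cl2 <- classify_reads(c(r2 = ok), ref)
  expect_equal(cl2$assignments$feature, "bact001")
  expect_equal(cl2$assignments$taxon,
               ref$db$taxon[ref$db$id == "bact001"])
  expect_equal(cl2$assignments$length, 60L)
})

test_that("digestive gland bacterial fraction is recovered within 3 SE", {
  cls <- fixture_classify()
  cl <- cls$digestive_gland
  bact <- grepl("^Bacteria:", cl$assignments$taxon)
  phat <- sum(bact) / nrow(cl$assignments)
  se <- sqrt(0.042 * (1 - 0.042) / nrow(cl$assignments))
  expect_lt(abs(phat - 0.042), 3 * se)
  # three-fold enrichment over the other tissues, qualitatively
  others <- vapply(cls[c("foot", "gill", "mantle")], function(x)
    mean(grepl("^Bacteria:", x$assignments$taxon)), numeric(1))
  expect_gt(phat, 2 * mean(others))
})

test_that("bacterial richness (Margalef) peaks in the digestive gland", {
  cls <- fixture_classify()
  d <- vapply(cls, function(cl) {
    b <- grepl("^Bacteria:", cl$assignments$taxon)
    margalef(length(unique(cl$assignments$taxon[b])), sum(b))
  }, numeric(1))
  expect_gt(d[["digestive_gland"]], max(d[c("foot", "gill", "mantle")]))
})

test_that("Margalef's d follows its closed form", {
  expect_equal(margalef(1, 50), 0)
  expect_equal(margalef(11, 22026), 10 / log(22026))
  expect_equal(margalef(11, 22026), 1.0000021, tolerance = 1e-6)
  d <- vapply(2:20, margalef, numeric(1), N = 500)
  expect_true(all(diff(d) > 0))
  expect_error(margalef(3, 1), "parameter error")
})

test_that("Bray-Curtis reproduces hand computations and its axioms", {
  x <- rbind(a = c(4, 0), b = c(1, 1))
  expect_equal(bray_curtis(x)["a", "b"], 0.5)  # sqrt transform
  same <- rbind(a = c(2, 3, 1), b = c(2, 3, 1))
  expect_equal(bray_curtis(same)["a", "b"], 0)
  disj <- rbind(a = c(5, 0), b = c(0, 7))
  expect_equal(bray_curtis(disj)["a", "b"], 1)
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "all-zero")
  set.seed(43)
  for (rep in 1:5) {
    m <- matrix(rexp(5 * 20), 5, 20,
                dimnames = list(paste0("s", 1:5), NULL))
    bc <- bray_curtis(m, transform = identity)
    expect_true(all(bc >= 0 & bc <= 1 + 1e-12))
    expect_equal(bc, t(bc))
    expect_true(all(diag(bc) == 0))
  }
})

test_that("NMDS embeds exact plane configurations at zero stress", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4))
  d <- as.matrix(dist(pts))
  fit <- nmds(d, n_restarts = 10, seed = 2)
  expect_lte(fit$stress, 1e-6)
  expect_equal(colMeans(fit$coordinates), c(MDS1 = 0, MDS2 = 0),
               tolerance = 1e-8)
  expect_error(nmds(matrix(c(0, 1, 2, 0), 2, 2)), "parameter error")
})

test_that("NMDS stress is invariant to rescaling the dissimilarities", {
  set.seed(44)
  m <- matrix(runif(49), 7); m <- (m + t(m)) / 2; diag(m) <- 0
  f1 <- nmds(m, n_restarts = 8, seed = 3)
  f2 <- nmds(2 * m, n_restarts = 8, seed = 3)
  expect_equal(f1$stress, f2$stress, tolerance = 1e-8)
})

test_that("reported stress matches an independent recomputation", {
  set.seed(45)
  m <- matrix(runif(64), 8); m <- (m + t(m)) / 2; diag(m) <- 0
  fit <- nmds(m, n_restarts = 10, seed = 4)
  expect_equal(fit$stress, stress1(m, fit$coordinates), tolerance = 1e-4)
})

test_that("tissue resemblance reproduces the expected ordering", {
  cls <- fixture_classify()
  bc <- bray_curtis(lapply(cls, `[[`, "subsystems"))
  off <- bc[lower.tri(bc)]
  expect_equal(bc["digestive_gland", "gill"], min(off))
  tissues <- rownames(bc)
  avg <- vapply(tissues, function(t) mean(bc[t, setdiff(tissues, t)]),
                numeric(1))
  expect_equal(names(which.max(avg)), "foot")
})

test_that("simulated sex mixes are recovered as VERL fractions", {
  ref <- fixture_reference()
  for (p in c(0.3, 0.5, 0.7)) {
    cfg <- default_profile_config()
    cfg$sex_mix[] <- p
    prof <- make_profiles(ref, cfg)
    sim <- simulate_reads(ref, prof,
                          n_reads = c(digestive_gland = 700L, foot = 700L,
                                      gill = 700L, mantle = 700L),
                          seed = round(1000 * p))
    dm <- demultiplex(sim$reads, fixture_barcodes())
    cnt <- c(VERL = 0, VCL = 0)
    for (b in dm$bins) {
      cl <- classify_reads(b, ref)
      f <- cl$assignments$feature
      cnt["VERL"] <- cnt["VERL"] + sum(f == "VERL")
      cnt["VCL"] <- cnt["VCL"] + sum(f == "VCL")
    }
    n <- sum(cnt)
    phat <- cnt[["VERL"]] / n
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
  }
})
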