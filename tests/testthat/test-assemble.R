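test_that("two overlapping reads merge into one exact-consensus contig", {
  set.seed(5)
  src <- random_seq(240)
  r1 <- substr(src, 1, 150)
  r2 <- substr(src, 91, 240)   # 60 bp overlap
  asm <- greedy_assemble(c(a = r1, b = r2), tissue = "t")
  expect_equal(nrow(asm$contigs), 1L)
  expect_equal(length(asm$singletons), 0L)
  expect_equal(nchar(asm$contigs$consensus), 150 + 150 - 60)
  expect_identical(asm$contigs$consensus, src)
  expect_setequal(asm$members[[1]], c("a", "b"))
})

test_that("a reverse-complement overlap is found and merged", {
  set.seed(6)
  src <- random_seq(240)
  r1 <- substr(src, 1, 150)
  r2 <- revcomp(substr(src, 91, 240))
  asm <- greedy_assemble(c(a = r1, b = r2))
  expect_equal(nrow(asm$contigs), 1L)
  expect_true(asm$contigs$consensus %in% c(src, revcomp(src)))
})

test_that("non-overlapping reads all stay singletons", {
  set.seed(7)
  reads <- setNames(vapply(1:3, function(i) random_seq(120), ""),
                    c("x", "y", "z"))
  asm <- greedy_assemble(reads)
  expect_equal(nrow(asm$contigs), 0L)
  expect_setequal(asm$singletons, c("x", "y", "z"))
})

test_that("tiled error-free reads reassemble their source transcripts", {
  set.seed(8)
  tx <- vapply(1:3, function(i) random_seq(2000), "")
  reads <- character(0)
  for (t in 1:3) {
    starts <- seq(1, 1801, by = 40)   # 5x coverage, 200 bp reads
    r <- vapply(starts, function(s) substr(tx[t], s, s + 199), "")
    names(r) <- sprintf("t%d_r%03d", t, seq_along(starts))
    reads <- c(reads, r)
  }
  asm <- greedy_assemble(reads)
  expect_equal(nrow(asm$contigs), 3L)
  expect_equal(length(asm$singletons), 0L)
  expect_setequal(asm$contigs$consensus, tx)
  # every contig's members come from a single source transcript
  for (k in seq_len(3)) {
    pref <- unique(substr(asm$members[[k]], 1, 2))
    expect_equal(length(pref), 1L)
  }
})

test_that("read conservation holds on random bins", {
  ref <- fixture_reference()
  set.seed(9)
  for (rep in 1:4) {
    ids <- sample(ref$transcripts$id[ref$transcripts$length >= 400], 5)
    reads <- unlist(lapply(ids, function(id) {
      L <- nchar(ref$seqs[[id]])
      starts <- sort(sample.int(L - 150, 30, replace = TRUE))
      setNames(vapply(starts, function(s)
        substr(ref$seqs[[id]], s, s + 149), ""),
        sprintf("%s_%02d_%d", id, seq_along(starts), rep))
    }))
    asm <- greedy_assemble(reads)
    expect_setequal(c(unlist(asm$members), asm$singletons), names(reads))
  }
})

test_that("adding duplicate reads never increases the singleton count", {
  set.seed(10)
  src <- random_seq(800)
  starts <- c(1, 120, 260, 420, 601)
  reads <- setNames(vapply(starts, function(s) substr(src, s, s + 199), ""),
                    sprintf("r%d", seq_along(starts)))
  base <- greedy_assemble(reads)
  dup <- c(reads, setNames(reads, paste0("dup_", names(reads))))
  more <- greedy_assemble(dup)
  expect_lte(length(more$singletons), length(base$singletons))
})

test_that("assembler input contracts are enforced", {
  expect_error(greedy_assemble(c(a = "ACGT"), min_overlap = 5),
               "parameter error")
  expect_error(greedy_assemble(character(0)), "empty bin")
})

test_that("summary statistics reproduce the printed-table arithmetic", {
  gill <- summary_stats(total_reads = 58271, total_bp = 12157845,
                        n_contigs = 4713, n_contigs_gt500 = 96,
                        n_singletons = 14093, n_annotated = 320)
  expect_equal(gill$reads_in_contigs, 44178)
  expect_equal(gill$avg_length, 208)       # floor(208.6)
  expect_equal(gill$singleton_pct, 24.2)
  dg <- summary_stats(33992, 6988845, 2103, 78, 8564, 407)
  expect_equal(dg$avg_length, 205)         # floor(205.6)
  mantle <- summary_stats(52057, 9293253, 1046, 25, 5877, 151)
  expect_equal(mantle$singleton_pct, 11.3)
})

test_that("summarize_dataset computes stats from real assemblies", {
  dm <- fixture_demux()
  asm <- fixture_assemblies()
  st <- summarize_dataset(asm$foot, dm$bins$foot)
  expect_equal(st$reads_in_contigs + st$n_singletons, st$total_reads)
  expect_equal(st$total_reads, dm$bins$foot$n_assigned)
  expect_equal(st$avg_length, st$total_bp %/% st$total_reads)
  expect_error(summarize_dataset(asm$foot, dm$bins$gill),
               "consistency error")
  tab <- summary_table(list(foot = st))
  expect_equal(nrow(tab), 8L)
  expect_true("Total reads within contigs" %in% tab$statistic)
})

test_that("richer tissues assemble with higher singleton rates", {
  dm <- fixture_demux()
  asm <- fixture_assemblies()
  pct <- vapply(names(asm), function(ts)
    summarize_dataset(asm[[ts]], dm$bins[[ts]])$singleton_pct, numeric(1))
  expect_gt(mean(pct[c("digestive_gland", "gill")]),
            mean(pct[c("foot", "mantle")]))
})
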