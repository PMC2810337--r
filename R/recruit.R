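#' Recruit raw reads to the mitochondrial genome
#'
#' Aligns every read of a tissue bin to the genome and keeps, for each
#' read with at least one HSP at `max_evalue` or better, its single top
#' HSP (ties broken by lower subject start, then "+" strand). Reads with
#' no qualifying HSP are omitted.
#'
#' @param bin a `sample_bin` (or named character vector of reads)
#' @param genome genome sequence (single string)
#' @param scheme a `scoring_scheme`
#' @param max_evalue E-value cutoff for recruiting a read
#' @param word seed word size
#' @return data.frame of recruitment hits: read, sstart, send (0-based
#'   half-open genome coordinates), strand, identity, score, length, evalue
#' @export
recruit_reads <- function(bin, genome, scheme = scoring_scheme(),
                          max_evalue = 1e-5, word = 11L) {
  reads <- if (inherits(bin, "sample_bin")) bin$reads else bin
  if (!nzchar(genome)) stop("parameter error: empty genome")
  if (length(reads) == 0)
    return(data.frame(read = character(0), sstart = integer(0),
                      send = integer(0), strand = character(0),
                      identity = numeric(0), score = integer(0),
                      length = integer(0), evalue = numeric(0)))
  floor_r <- score_floor_for_evalue(max_evalue, max(nchar(reads)),
                                    nchar(genome), scheme)
  hits <- seeded_search(reads, c(genome = genome), scheme, word = word,
                        score_floor = max(20L, floor_r - 10L))
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  top <- top_hsp_per_query(hits)
  data.frame(read = top$query, sstart = top$sstart, send = top$send,
             strand = top$strand, identity = top$identity,
             score = top$score, length = top$length, evalue = top$evalue,
             stringsAsFactors = FALSE)
}

#' Build the fragment recruitment matrix
#'
#' Bins the recruited hits into an identity-by-coordinate count matrix
#' scaled to a fixed pixel width. A hit whose genome span scales to less
#' than one pixel (`floor(len * width / genome_length) < 1`) is invisible
#' and excluded; at a genome of 16,744 bp and width 1024 this reproduces
#' the rule that fragments shorter than 17 bp do not appear.
#'
#' @param hits data.frame from [recruit_reads()]
#' @param genome_length genome length in bp
#' @param width matrix width in pixels
#' @param bin_width_pct identity bin width, percent
#' @param min_identity_pct lowest identity percent shown
#' @return a `recruitment_matrix`: `counts` (identity bins x pixels, low
#'   bin first), `bins` (low/high percent per row), `width`,
#'   `genome_length`, `bp_per_pixel`, `n_visible`
#' @export
build_matrix <- function(hits, genome_length, width = 1024L,
                         bin_width_pct = 0.5, min_identity_pct = 50) {
  if (genome_length < width)
    stop("parameter error: genome shorter than the pixel width")
  lows <- seq(min_identity_pct, 100 - bin_width_pct, by = bin_width_pct)
  nb <- length(lows)
  counts <- matrix(0L, nb, width,
                   dimnames = list(sprintf("[%g,%g)", lows,
                                           lows + bin_width_pct), NULL))
  if (nrow(hits)) {
    span <- hits$send - hits$sstart
    visible <- floor(span * width / genome_length) >= 1
    h <- hits[visible, , drop = FALSE]
    for (i in seq_len(nrow(h))) {
      idp <- 100 * h$identity[i]
      if (idp < min_identity_pct) next
      bi <- min(nb, floor((idp - min_identity_pct) / bin_width_pct) + 1L)
      p0 <- floor(h$sstart[i] * width / genome_length)
      p1 <- floor((h$send[i] - 1) * width / genome_length)
      cols <- (p0:p1) + 1L
      cols <- cols[cols >= 1 & cols <= width]
      counts[bi, cols] <- counts[bi, cols] + 1L
    }
  }
  structure(list(counts = counts,
                 bins = data.frame(low = lows, high = lows + bin_width_pct),
                 width = width, genome_length = genome_length,
                 bp_per_pixel = genome_length / width,
                 n_visible = if (nrow(hits))
                   sum(floor((hits$send - hits$sstart) * width /
                               genome_length) >= 1 &
                         100 * hits$identity >= min_identity_pct) else 0L),
            class = "recruitment_matrix")
}

#' Per-gene normalized abundance from recruitment hits
#'
#' A hit counts toward every annotation its genome interval overlaps by at
#' least one base, provided its identity and alignment length pass the
#' cutoffs (98% identity as in the mitochondrial abundance figure; the
#' 50 bp minimum reuses the annotation pipeline's length cutoff).
#' Abundance is the qualifying hit count divided by the sequencing effort
#' of the sample.
#'
#' @param hits data.frame from [recruit_reads()]
#' @param annotations annotation data.frame (0-based half-open)
#' @param sample_size total reads sequenced for this sample
#' @param min_identity identity fraction cutoff
#' @param min_len minimum alignment length (columns)
#' @return data.frame: name, category, count, abundance
#' @export
gene_abundance <- function(hits, annotations, sample_size,
                           min_identity = 0.98, min_len = 50L) {
  if (sample_size <= 0) stop("parameter error: sample_size must be positive")
  q <- hits[hits$identity >= min_identity & hits$length >= min_len, ,
            drop = FALSE]
  counts <- integer(nrow(annotations))
  if (nrow(q)) {
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = q$sstart + 1L, end = q$send),
      IRanges::IRanges(start = annotations$start + 1L,
                       end = annotations$end))
    tab <- table(S4Vectors::subjectHits(ov))
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  data.frame(name = annotations$name, category = annotations$category,
             count = counts, abundance = counts / sample_size,
             stringsAsFactors = FALSE)
}

#' Transcribed regions outside the annotations
#'
#' Maximal intervals of at least `min_span` bases where per-base hit
#' coverage reaches `min_coverage` and no annotation overlaps, reported
#' with the mean identity of the contributing hits (separating a
#' low-identity recruitment pile-up from a well-defined high-identity
#' transcribed region) and the maximum coverage attained.
#'
#' @param hits data.frame from [recruit_reads()]
#' @param annotations annotation data.frame (0-based half-open)
#' @param genome_length genome length
#' @param min_coverage per-base coverage threshold
#' @param min_span minimum region length
#' @return data.frame: start, end (0-based half-open), mean_identity,
#'   max_coverage
#' @export
unannotated_regions <- function(hits, annotations, genome_length,
                                min_coverage = 5L, min_span = 30L) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      mean_identity = numeric(0), max_coverage = integer(0))
  if (nrow(hits) == 0) return(empty)
  cov <- as.integer(IRanges::coverage(
    IRanges::IRanges(start = hits$sstart + 1L, end = hits$send),
    width = genome_length))
  annotated <- logical(genome_length)
  for (i in seq_len(nrow(annotations)))
    annotated[(annotations$start[i] + 1L):annotations$end[i]] <- TRUE
  ok <- cov >= min_coverage & !annotated
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths >= min_span)
  if (!length(sel)) return(empty)
  out <- lapply(sel, function(k) {
    s0 <- starts[k] - 1L; e0 <- ends[k]   # back to 0-based half-open
    touching <- hits$sstart < e0 & hits$send > s0
    data.frame(start = s0, end = e0,
               mean_identity = mean(hits$identity[touching]),
               max_coverage = max(cov[(s0 + 1L):e0]))
  })
  do.call(rbind, out)
}

#' Write a recruitment matrix as TSV and as a portable graymap
#'
#' The TSV (identity bins as rows, pixel columns) is the normative output;
#' the PGM is a cosmetic log2-gray rendering with the highest identity bin
#' at the top.
#'
#' @param mat a `recruitment_matrix`
#' @param tsv_path,pgm_path output paths (either may be NULL)
#' @return invisibly, the written paths
#' @export
write_recruitment_matrix <- function(mat, tsv_path = NULL, pgm_path = NULL) {
  if (!is.null(tsv_path)) {
    tab <- data.frame(identity_bin = rownames(mat$counts), mat$counts)
    names(tab)[-1] <- sprintf("px%04d", seq_len(mat$width))
    write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(pgm_path)) {
    m <- mat$counts[rev(seq_len(nrow(mat$counts))), , drop = FALSE]
    g <- log2(1 + m)
    mx <- max(g, 1e-9)
    lev <- round(255 * g / mx)
    con <- file(pgm_path, "w")
    writeLines(c("P2", paste(ncol(lev), nrow(lev)), "255"), con)
    write.table(lev, con, sep = " ", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    close(con)
  }
  invisible(c(tsv_path, pgm_path))
}

#' Write regions as BED
#'
#' @param regions data.frame with start and end (0-based half-open)
#' @param path output path
#' @param chrom chromosome/sequence name
#' @return the path, invisibly
#' @export
write_bed <- function(regions, path, chrom = "mito_synth") {
  tab <- data.frame(chrom = rep(chrom, nrow(regions)),
                    start = regions$start, end = regions$end)
  if ("mean_identity" %in% names(regions)) {
    tab$name <- sprintf("region_%d", seq_len(nrow(regions)))
    tab$score <- round(1000 * regions$mean_identity)
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
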