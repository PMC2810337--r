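#' Abundance profile constructor
#'
#' @param counts named numeric vector, feature -> read count
#' @param sample_size total reads sequenced in the sample
#' @param sample sample label
#' @param space feature space label (transcript, gene, subsystem, taxon)
#' @return an `abundance_profile` with counts and effort-normalized values
#' @export
abundance_profile <- function(counts, sample_size, sample = "sample",
                              space = "transcript") {
  if (sum(counts) > sample_size)
    stop("consistency error: counts exceed sample size")
  structure(list(sample = sample, space = space, counts = counts,
                 sample_size = sample_size,
                 normalized = counts / sample_size),
            class = "abundance_profile")
}

#' Annotate contigs against the reference database
#'
#' Best hit by raw score per contig; a contig is annotated when its best
#' hit reaches `e_cutoff` or better, otherwise it stays unannotated.
#'
#' @param assembly an `est_assembly` (or named character vector of contigs)
#' @param db_seqs named character vector of database sequences
#' @param scheme a `scoring_scheme`
#' @param e_cutoff annotation E-value cutoff
#' @param word seed word size (13 by default: ample sensitivity at the
#'   pipeline's cutoffs, and far fewer chance seed windows to resolve)
#' @return data.frame (contig, feature, score, evalue) for annotated
#'   contigs; attribute `n_input` holds the number of contigs searched
#' @export
annotate_contigs <- function(assembly, db_seqs, scheme = scoring_scheme(),
                             e_cutoff = 1e-5, word = 13L) {
  if (length(db_seqs) == 0) stop("configuration error: empty protein db")
  contigs <- if (inherits(assembly, "est_assembly"))
    setNames(assembly$contigs$consensus, assembly$contigs$id) else assembly
  if (length(contigs) == 0) {
    out <- data.frame(contig = character(0), feature = character(0),
                      score = integer(0), evalue = numeric(0))
    attr(out, "n_input") <- 0L
    return(out)
  }
  hits <- seeded_search(contigs, db_seqs, scheme, word = word,
                        score_floor = 30L)
  top <- top_hsp_per_query(hits)
  top <- top[top$evalue <= e_cutoff, , drop = FALSE]
  out <- data.frame(contig = top$query, feature = top$subject,
                    score = top$score, evalue = top$evalue,
                    stringsAsFactors = FALSE)
  attr(out, "n_input") <- length(contigs)
  out
}

#' Per-tissue transcript abundance from annotated assemblies
#'
#' The read count of a feature is the summed member-read count of every
#' contig annotated to it (contigs sharing an annotation label pool their
#' reads), normalized by the sequencing effort of the sample.
#'
#' @param assemblies named list of `est_assembly`, one per tissue
#' @param annotations named list of [annotate_contigs()] results
#' @param sample_sizes named numeric vector, tissue -> reads sequenced
#' @return named list of transcript-space `abundance_profile`
#' @export
abundance_table <- function(assemblies, annotations, sample_sizes) {
  if (!all(names(assemblies) %in% names(sample_sizes)))
    stop("consistency error: unknown sample in sample_sizes")
  out <- lapply(names(assemblies), function(ts) {
    asm <- assemblies[[ts]]
    ann <- annotations[[ts]]
    nmem <- setNames(vapply(asm$members, length, integer(1)),
                     asm$contigs$id)
    counts <- tapply(nmem[ann$contig], ann$feature, sum)
    counts <- setNames(as.numeric(counts), names(counts))
    abundance_profile(counts, sample_sizes[[ts]], sample = ts,
                      space = "transcript")
  })
  names(out) <- names(assemblies)
  out
}

#' Top-N features by normalized abundance
#'
#' @param profiles named list of `abundance_profile`
#' @param n how many features per sample
#' @return data.frame: sample, rank, feature, reads, normalized, pct
#'   (percent of sequencing effort, rounded half-up to one decimal)
#' @export
top_features <- function(profiles, n = 10L) {
  rows <- lapply(profiles, function(p) {
    if (length(p$counts) == 0) return(NULL)
    o <- order(-p$normalized, names(p$counts))
    k <- head(o, n)
    data.frame(sample = p$sample, rank = seq_along(k),
               feature = names(p$counts)[k], reads = unname(p$counts[k]),
               normalized = unname(p$normalized[k]),
               pct = round_half_up(100 * unname(p$normalized[k]), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample = character(0), rank = integer(0),
                      feature = character(0), reads = numeric(0),
                      normalized = numeric(0), pct = numeric(0))
  rownames(out) <- NULL
  out
}

#' Marker-based sex ratio and tissue distribution
#'
#' Overall ratio of female-marker to male-marker read counts summed over
#' tissues, plus each marker's distribution across tissues (the share of
#' that marker's reads found in each tissue, from raw counts; the
#' effort-normalized shares are reported alongside).
#'
#' @param profiles named list of transcript-space `abundance_profile`
#' @param female_marker,male_marker feature labels
#' @return list: `ratio`, `counts` (marker x tissue), `distribution_pct`
#'   (percent of each marker's reads per tissue, raw counts),
#'   `distribution_norm_pct` (same from effort-normalized abundances)
#' @export
marker_ratio <- function(profiles, female_marker = "VERL",
                         male_marker = "VCL") {
  get1 <- function(p, f) if (f %in% names(p$counts)) p$counts[[f]] else 0
  cnt <- vapply(profiles, function(p)
    c(get1(p, female_marker), get1(p, male_marker)), numeric(2))
  rownames(cnt) <- c(female_marker, male_marker)
  tot <- rowSums(cnt)
  if (tot[male_marker] == 0)
    stop("undefined ratio: no ", male_marker, " reads observed")
  nrm <- vapply(profiles, function(p)
    c(get1(p, female_marker), get1(p, male_marker)) / p$sample_size,
    numeric(2))
  rownames(nrm) <- c(female_marker, male_marker)
  list(ratio = unname(tot[female_marker] / tot[male_marker]),
       counts = cnt,
       distribution_pct = 100 * sweep(cnt, 1, pmax(tot, 1), "/"),
       distribution_norm_pct = 100 * sweep(nrm, 1,
                                           pmax(rowSums(nrm), 1e-12), "/"))
}

#' Classify raw reads by taxon and metabolic subsystem
#'
#' Each read inherits the taxon and subsystem labels of its best database
#' hit, provided the hit reaches `e_cutoff` or better AND spans at least
#' `min_align` alignment columns; reads failing either constraint are
#' counted as unassigned.
#'
#' @param bin a `sample_bin` (or named character vector of reads)
#' @param reference an `est_reference` (its `db` supplies the labels)
#' @param scheme a `scoring_scheme`
#' @param e_cutoff classification E-value cutoff
#' @param min_align minimum alignment length in columns
#' @param word seed word size
#' @return list: `assignments` (read, feature, taxon, subsystem, evalue,
#'   length), `taxa` and `subsystems` (`abundance_profile`s over assigned
#'   reads), `n_unassigned`, `sample_size`
#' @export
classify_reads <- function(bin, reference, scheme = scoring_scheme(),
                           e_cutoff = 1e-10, min_align = 50L, word = 13L) {
  reads <- if (inherits(bin, "sample_bin")) bin$reads else bin
  ts <- if (inherits(bin, "sample_bin")) bin$tissue else "sample"
  db <- reference$db
  db_seqs <- reference$seqs[db$id]
  hits <- seeded_search(reads, db_seqs, scheme, word = word,
                        score_floor = 60L)
  top <- top_hsp_per_query(hits)
  top <- top[top$evalue <= e_cutoff & top$length >= min_align, ,
             drop = FALSE]
  ix <- match(top$subject, db$id)
  assignments <- data.frame(read = top$query, feature = top$subject,
                            taxon = db$taxon[ix],
                            subsystem = db$subsystem[ix],
                            evalue = top$evalue, length = top$length,
                            stringsAsFactors = FALSE)
  n <- length(reads)
  mkprof <- function(field) {
    tab <- table(assignments[[field]])
    abundance_profile(setNames(as.numeric(tab), names(tab)), n,
                      sample = ts, space = sub("s$", "", field))
  }
  list(assignments = assignments, taxa = mkprof("taxon"),
       subsystems = mkprof("subsystem"),
       n_unassigned = n - nrow(assignments), sample_size = n)
}

#' Margalef's species richness
#'
#' d = (S - 1) / ln(N) for S species among N classified individuals.
#'
#' @param S species (taxon) count, >= 1
#' @param N classified individual count, >= 2
#' @return richness d
#' @export
margalef <- function(S, N) {
  if (any(N < 2)) stop("parameter error: Margalef's d requires N >= 2")
  if (any(S < 1)) stop("parameter error: S must be >= 1")
  (S - 1) / log(N)
}
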