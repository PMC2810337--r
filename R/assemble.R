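#' Greedy overlap-consensus assembly of one tissue bin
#'
#' Iteratively merges the pair of reads/contigs (either orientation) with
#' the longest gap-free suffix-prefix overlap of at least `min_overlap`
#' bases at `min_identity` or better, recomputing a majority-vote
#' consensus after every merge, until no mergeable pair remains. Ties on
#' overlap length are broken by the lexicographically smallest pair of
#' entity ids, so the result is deterministic for a given input order.
#' This is a deliberately simple desk-scale stand-in for a production
#' 454 assembler and is not claimed equivalent to one.
#'
#' @param bin a `sample_bin` (or named character vector of reads)
#' @param min_overlap minimum overlap length in bases (>= 10)
#' @param min_identity minimum overlap identity fraction
#' @param tissue tissue label when `bin` is a plain vector
#' @return an `est_assembly`: `contigs` (data.frame id, consensus,
#'   n_members plus a `members` list), `singletons` (read ids), `tissue`
#' @export
greedy_assemble <- function(bin, min_overlap = 40L, min_identity = 0.95,
                            tissue = NULL) {
  if (inherits(bin, "sample_bin")) {
    reads <- bin$reads
    tissue <- bin$tissue
  } else reads <- bin
  if (length(reads) == 0) stop("assembly error: empty bin")
  if (min_overlap < 10)
    stop("parameter error: min_overlap < 10 invites spurious joins")
  if (is.null(names(reads))) names(reads) <- sprintf("r%05d", seq_along(reads))
  # k = 12 guarantees a shared exact word inside any overlap of >= 40 bp
  # at >= 95% identity (pigeonhole over at most floor(L/20) mismatches)
  res <- cpp_greedy_assemble(names(reads), unname(reads),
                             as.integer(min_overlap), min_identity, 12L)
  n_contigs <- length(res$contig_seq)
  members <- lapply(res$contig_members, function(ix) names(reads)[ix])
  contigs <- data.frame(
    id = if (n_contigs) sprintf("%s_c%05d", if (is.null(tissue)) "asm" else
      tissue, seq_len(n_contigs)) else character(0),
    consensus = res$contig_seq,
    n_members = vapply(members, length, integer(1)),
    stringsAsFactors = FALSE)
  structure(list(contigs = contigs, members = members,
                 singletons = names(reads)[res$singletons],
                 tissue = tissue),
            class = "est_assembly")
}

#' Summary statistics constructor
#'
#' Pure arithmetic over dataset-level counts, replicating the summary
#' table's derived quantities: average length by floor division, singleton
#' percentage rounded half-up to one decimal, and reads-within-contigs as
#' the complement of the singletons.
#'
#' @param total_reads,total_bp,n_contigs,n_contigs_gt500,n_singletons counts
#' @param n_annotated contigs with a functional assignment (optional)
#' @return a `summary_stats` list
#' @export
summary_stats <- function(total_reads, total_bp, n_contigs,
                          n_contigs_gt500, n_singletons, n_annotated = NA) {
  stopifnot(total_reads > 0, n_singletons <= total_reads)
  out <- list(total_reads = total_reads, total_bp = total_bp,
              avg_length = total_bp %/% total_reads,
              n_contigs = n_contigs, n_contigs_gt500 = n_contigs_gt500,
              n_annotated = n_annotated,
              reads_in_contigs = total_reads - n_singletons,
              n_singletons = n_singletons,
              singleton_pct = round_half_up(100 * n_singletons / total_reads,
                                            1))
  structure(out, class = "summary_stats")
}

#' Summarize an assembled dataset
#'
#' @param assembly an `est_assembly` produced from `bin`
#' @param bin the `sample_bin` the assembly was built from
#' @param n_annotated optional count of annotated contigs
#' @return a `summary_stats` list
#' @export
summarize_dataset <- function(assembly, bin, n_annotated = NA) {
  reads <- if (inherits(bin, "sample_bin")) bin$reads else bin
  asm_ids <- sort(c(unlist(assembly$members, use.names = FALSE),
                    assembly$singletons))
  if (!identical(asm_ids, sort(names(reads))))
    stop("consistency error: assembly and bin cover different read sets")
  summary_stats(
    total_reads = length(reads),
    total_bp = sum(nchar(reads)),
    n_contigs = nrow(assembly$contigs),
    # ">500 bp" means a consensus of at least 501 bases
    n_contigs_gt500 = sum(nchar(assembly$contigs$consensus) >= 501L),
    n_singletons = length(assembly$singletons),
    n_annotated = n_annotated)
}

#' Combine per-tissue summary statistics into a pooled total
#'
#' @param stats_list list of `summary_stats`
#' @return a `summary_stats` for the pooled dataset
#' @export
summary_total <- function(stats_list) {
  g <- function(f) sum(vapply(stats_list, `[[`, numeric(1), f))
  ann <- vapply(stats_list, `[[`, numeric(1), "n_annotated")
  summary_stats(total_reads = g("total_reads"), total_bp = g("total_bp"),
                n_contigs = g("n_contigs"),
                n_contigs_gt500 = g("n_contigs_gt500"),
                n_singletons = g("n_singletons"),
                n_annotated = if (any(is.na(ann))) NA else sum(ann))
}

#' Summary table in the printed-table schema
#'
#' @param stats_list named list of `summary_stats`, one per tissue
#' @return data.frame with the familiar row labels, one column per sample
#' @export
summary_table <- function(stats_list) {
  fmt <- function(s) c(
    "Total No. of reads" = format(s$total_reads, big.mark = ","),
    "Total size (bp)" = format(s$total_bp, big.mark = ","),
    "Average length (bp)" = as.character(s$avg_length),
    "Total No. of contigs" = format(s$n_contigs, big.mark = ","),
    "Contigs with functional assignment" =
      if (is.na(s$n_annotated)) "NA" else format(s$n_annotated,
                                                 big.mark = ","),
    "Contigs >500 bp" = as.character(s$n_contigs_gt500),
    "Total reads within contigs" = format(s$reads_in_contigs,
                                          big.mark = ","),
    "Singleton reads" = sprintf("%s (%s%%)",
                                format(s$n_singletons, big.mark = ","),
                                s$singleton_pct))
  cols <- lapply(stats_list, fmt)
  out <- data.frame(statistic = names(cols[[1]]), stringsAsFactors = FALSE)
  for (nm in names(cols)) out[[nm]] <- unname(cols[[nm]])
  out
}

#' Write assembly products
#'
#' Contigs as FASTA, contig membership as a two-column TSV.
#'
#' @param assembly an `est_assembly`
#' @param fasta_path,members_path output paths
#' @return invisibly, the paths
#' @export
write_assembly <- function(assembly, fasta_path, members_path) {
  if (nrow(assembly$contigs) > 0)
    write_fasta(setNames(assembly$contigs$consensus, assembly$contigs$id),
                fasta_path)
  mem <- data.frame(
    contig_id = rep(assembly$contigs$id,
                    vapply(assembly$members, length, integer(1))),
    read_id = unlist(assembly$members, use.names = FALSE),
    stringsAsFactors = FALSE)
  write.table(mem, members_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta_path, members_path))
}
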