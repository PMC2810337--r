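IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

#' Read a FASTA file
#'
#' Accepts multi-line records, mixed case (upper-cased on read) and CRLF
#' line endings. Fails with a format error naming the offending record on
#' duplicate ids, empty sequences or non-IUPAC characters.
#'
#' @param path FASTA file
#' @return named character vector of upper-case sequences
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA format error: file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("FASTA format error in ", path, ": ",
                         conditionMessage(e)))
  if (length(set) == 0) stop("FASTA format error: empty file: ", path)
  seqs <- toupper(gsub("[\r ]", "", as.character(set)))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("FASTA format error: duplicate id '", dup[1], "'")
  bad <- !grepl(paste0("^[", IUPAC_CHARS, "]+$"), seqs)
  if (any(bad))
    stop("FASTA format error: record '", ids[which(bad)[1]],
         "' contains non-IUPAC characters or is empty")
  setNames(seqs, ids)
}

#' Write a FASTA file
#'
#' @param records named character vector of sequences
#' @param path output path
#' @param wrap sequence line width
#' @return the path, invisibly
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  if (length(records) == 0) stop("FASTA write error: no records")
  if (is.null(names(records)) || any(names(records) == ""))
    stop("FASTA write error: records must be named")
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = wrap)
  invisible(path)
}

GFF3_TYPES <- c(CDS = "gene", rRNA = "rRNA", tRNA = "tRNA",
                control_region = "region")

#' Read gene annotations from GFF3
#'
#' Converts 1-based inclusive file coordinates to the package's 0-based
#' half-open convention and maps feature types gene/rRNA/tRNA/region to
#' the annotation categories.
#'
#' @param path GFF3 file
#' @return data.frame with name, start, end, strand, category
#' @export
read_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("GFF3 format error in ", path, ": ",
                        conditionMessage(e)))
  type <- as.character(gr$type)
  keep <- type %in% GFF3_TYPES
  gr <- gr[keep]
  type <- type[keep]
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("GFF3 format error: unknown strand symbol")
  s <- BiocGenerics::start(gr) - 1L
  e <- BiocGenerics::end(gr)
  if (any(s >= e)) stop("GFF3 format error: start > end")
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$ID)
  cat <- names(GFF3_TYPES)[match(type, GFF3_TYPES)]
  data.frame(name = nm, start = s, end = e, strand = strand, category = cat,
             stringsAsFactors = FALSE)
}

#' Write gene annotations as GFF3
#'
#' @param annotations data.frame with name, start, end, strand, category
#'   (0-based half-open coordinates)
#' @param path output path
#' @param seqid sequence identifier for the annotated genome
#' @return the path, invisibly
#' @export
write_gff3 <- function(annotations, path, seqid = "mito_synth") {
  stopifnot(all(c("name", "start", "end", "strand", "category") %in%
                  names(annotations)))
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = annotations$start + 1L,
                              end = annotations$end),
    strand = annotations$strand)
  gr$type = unname(GFF3_TYPES[annotations$category])
  gr$ID <- annotations$name
  gr$Name <- annotations$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read / write a barcode table
#'
#' Two-column TSV with header `tissue` and `mid`. Tags must be unique and
#' of equal length; tissue labels must be unique.
#'
#' @param path TSV file
#' @return data.frame with tissue and mid columns
#' @export
read_barcodes <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tissue", "mid") %in% names(tab)))
    stop("barcode table error: header must be 'tissue\tmid'")
  validate_barcodes(tab)
  tab
}

#' @rdname read_barcodes
#' @param barcodes data.frame with tissue and mid columns
#' @export
write_barcodes <- function(barcodes, path) {
  validate_barcodes(barcodes)
  write.table(barcodes[, c("tissue", "mid")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_barcodes <- function(tab) {
  if (anyDuplicated(tab$mid))
    stop("barcode configuration error: duplicate MID tags")
  if (anyDuplicated(tab$tissue))
    stop("barcode configuration error: duplicate tissue labels")
  if (length(unique(nchar(tab$mid))) != 1)
    stop("barcode configuration error: tags must share one length")
  invisible(tab)
}

#' Demultiplex a pooled read set by MID tag
#'
#' A read is assigned to the unique tag whose prefix Hamming distance is
#' at most `max_mismatch`; reads matching no tag, or more than one
#' (including exact ties at the best distance), go to the unassigned bin
#' rather than being attributed arbitrarily. Tag prefixes are trimmed from
#' assigned reads.
#'
#' @param reads named character vector of sequences (or the `reads`
#'   data.frame from [simulate_reads()])
#' @param barcodes data.frame with tissue and mid columns
#' @param max_mismatch maximum prefix Hamming distance
#' @return list with `bins` (named list of `sample_bin`: tissue, trimmed
#'   reads, n_assigned) and `unassigned` (untrimmed named reads)
#' @export
demultiplex <- function(reads, barcodes, max_mismatch = 0L) {
  if (is.data.frame(reads)) reads <- setNames(reads$sequence, reads$id)
  validate_barcodes(barcodes)
  tl <- nchar(barcodes$mid[1])
  if (any(nchar(reads) < tl))
    stop("demultiplex error: reads shorter than the tag length")
  pre <- substr(reads, 1L, tl)
  mm <- vapply(barcodes$mid, function(tag) {
    d <- integer(length(pre))
    for (i in seq_len(tl))
      d <- d + (substr(pre, i, i) != substr(tag, i, i))
    d
  }, integer(length(pre)))
  if (length(pre) == 1L) mm <- matrix(mm, nrow = 1)
  ok <- mm <= max_mismatch
  nok <- rowSums(ok)
  assign_to <- ifelse(nok == 1L, max.col(ok, ties.method = "first"), NA_integer_)
  bins <- lapply(seq_len(nrow(barcodes)), function(k) {
    sel <- !is.na(assign_to) & assign_to == k
    r <- substring(reads[sel], tl + 1L)
    structure(list(tissue = barcodes$tissue[k],
                   reads = setNames(r, names(reads)[sel]),
                   n_assigned = sum(sel)),
              class = "sample_bin")
  })
  names(bins) <- barcodes$tissue
  un <- is.na(assign_to)
  structure(list(bins = bins, unassigned = reads[un],
                 n_input = length(reads)),
            class = "demux_result")
}
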