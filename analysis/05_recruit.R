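#!/usr/bin/env Rscript
# Stage 5: fragment recruitment of the raw reads of every tissue to the
# mitochondrial genome: the 1024-pixel coordinate-by-identity heat map
# (fragments scaling below one pixel are invisible), per-gene normalized
# abundance at >= 98% identity, and transcribed regions outside the
# annotations -- the planted cryptic segment 5' of CYTB should surface in
# the digestive gland only.

suppressPackageStartupMessages(library(musselEST))

genome <- read_fasta("results/data/reference.fasta")[[1]]
annotations <- read_gff3("results/data/reference.gff3")
barcodes <- read_barcodes("results/data/barcodes.tsv")

for (ts in barcodes$tissue) {
  reads <- read_fasta(sprintf("results/data/reads_%s.fasta", ts))
  hits <- recruit_reads(reads, genome)
  mat <- build_matrix(hits, nchar(genome))
  write_recruitment_matrix(mat, sprintf("results/recruitment_%s.tsv", ts),
                           sprintf("results/recruitment_%s.pgm", ts))
  ga <- gene_abundance(hits, annotations, length(reads))
  write.table(ga, sprintf("results/gene_abundance_%s.tsv", ts), sep = "\t",
              quote = FALSE, row.names = FALSE)
  reg <- unannotated_regions(hits, annotations, nchar(genome))
  write_bed(reg, sprintf("results/unannotated_regions_%s.bed", ts))
  cat(sprintf("%-16s %4d/%4d reads recruited; %d unannotated region(s)\n",
              ts, nrow(hits), length(reads), nrow(reg)))
  if (nrow(reg))
    cat(sprintf("  region %d-%d, mean identity %.3f, max coverage %d\n",
                reg$start, reg$end, reg$mean_identity, reg$max_coverage))
}
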