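#!/usr/bin/env Rscript
# Stage 4: all-against-all contig homology between tissues. Each entry is
# the percentage of the query tissue's contigs with at least one hit at
# E <= 1e-5 in the reference tissue's contig set (rows = reference,
# columns = query; the matrix is not symmetric by construction).

suppressPackageStartupMessages(library(musselEST))

barcodes <- read_barcodes("results/data/barcodes.tsv")
sets <- lapply(setNames(barcodes$tissue, barcodes$tissue), function(ts)
  read_fasta(sprintf("results/data/contigs_%s.fasta", ts)))

hm <- homology_matrix(sets)
write.table(data.frame(reference = rownames(hm), hm),
            "results/homology_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(hm)

off <- hm; diag(off) <- NA
cat(sprintf("\nmost self-contained tissue (lowest mean off-diagonal as query): %s\n",
            colnames(off)[which.min(colMeans(off, na.rm = TRUE))]))
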