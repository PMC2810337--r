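# musselEST

Multi-tissue EST transcriptome profiling for the Mediterranean mussel
(*Mytilus galloprovincialis*), re-implemented as a tested, fully
reproducible R workflow.

Pooled-tissue pyrosequencing EST surveys answer a simple question with a
lot of moving parts: which transcripts does each tissue express, how much
of the signal is mitochondrial or bacterial, and how similar are the
tissues overall? This package implements every computational stage of
such a survey for four tissues (digestive gland, foot, gill, mantle),
together with a first-class synthetic-data generator that encodes the
study conditions, so each stage can be verified against known ground
truth:

1. **simulate** — MID-barcoded 454-style cDNA reads from a synthetic
   reference: a 16,744 bp mitochondrial genome (12 CDS, 2 rRNAs, 23
   tRNAs, control region, plus one planted *unannotated* transcribed
   segment 5′ of CYTB), 400 housekeeping transcripts, tissue markers
   (vdg3, HSP90, foot adhesive-plaque proteins, VERL/VCL) and bacterial
   contaminants over ten taxonomic classes;
2. **demultiplex** — prefix Hamming matching of 10-mer MID tags, with
   ties going to the unassigned bin;
3. **assemble** — greedy overlap-consensus assembly per tissue
   (suffix–prefix overlaps ≥ 40 bp at ≥ 95% identity, majority-vote
   consensus) and the standard summary-statistics table (average length
   by floor division, singleton percentages rounded half-up);
4. **align / recruit** — exact affine-gap Smith–Waterman with the
   nucleotide scoring (+5 / −4; gaps 8 + 6L) and Karlin–Altschul
   E-values `E = K·m·n·exp(−λ·score)` (λ by root-finding, K by an exact
   renewal computation on the local-score chain; K(5, −4) = 0.1753).
   Raw reads are recruited to the mitochondrial genome into a
   1024-pixel coordinate × identity heat map in which fragments shorter
   than 17 bp are invisible, per-gene abundance is counted at ≥ 98%
   identity, and transcribed regions outside the annotations are
   reported;
5. **profile** — contig annotation (E ≤ 1e−5), read classification
   (E ≤ 1e−10 and ≥ 50 aligned columns) into taxa and 144 metabolic
   subsystems, VERL:VCL sex-ratio estimation, Margalef richness
   d = (S−1)/ln N, Bray–Curtis dissimilarity on square-root-transformed
   profiles, and 2-D NMDS (Kruskal stress-1, 20 restarts).

The alignment engine and assembler are compiled (Rcpp); standard steps go
through the established packages (Biostrings/rtracklayer for formats,
vegan for dissimilarity and NMDS).

## Worked example

The workflow ships as numbered drivers under `analysis/`; run them in
order from the repository root:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_demultiplex.R
Rscript analysis/03_assemble.R
Rscript analysis/04_homology.R
Rscript analysis/05_recruit.R
Rscript analysis/06_profile.R
```

With the default conditions (10,973 reads, seed 42) stage 3 prints the
per-tissue assembly summary:

```
digestive_gland   2125 reads ->  342 contigs (58 >500 bp),  494 singletons (23.2%)
foot              1952 reads ->  335 contigs (53 >500 bp),  365 singletons (18.7%)
gill              3642 reads ->  572 contigs (102 >500 bp),  575 singletons (15.8%)
mantle            3254 reads ->  551 contigs (83 >500 bp),  530 singletons (16.3%)
```

— the digestive gland, with the richest transcript pool plus the
bacterial load, assembles worst. Stage 5 recruits reads to the
mitochondrial genome and surfaces the planted cryptic transcript in the
digestive gland only:

```
digestive_gland   675/2125 reads recruited; 1 unannotated region(s)
  region 13850-13970, mean identity 0.995, max coverage 13
foot              206/1952 reads recruited; 0 unannotated region(s)
```

Stage 6 closes the loop on the tissue-level claims — the top digestive
gland and gill transcripts are the mitochondrial rRNAs while the top foot
transcript is an adhesive-plaque protein; the sex markers balance and the
ordination collapses to zero stress:

```
VERL:VCL ratio = 1.003; gill shares 53% / 55% of the markers

           tissue bacterial_pct margalef_d
1 digestive_gland          4.83      1.946
2            foot          0.97      1.019
3            gill          1.24      0.788
4          mantle          1.29      0.803

2-D NMDS stress: 0.000000 (20 restarts)
```

In the Bray–Curtis matrix the digestive gland and gill are the closest
pair (0.097) and the foot is the most dissimilar tissue (mean ≥ 0.30
against every other), reproducing the expected tissue relationships.
All tables land under `results/`.

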