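#' Default reference configuration
#'
#' Describes the synthetic reference emulated by [make_reference()]: a
#' linear mitochondrial genome of 16,744 bp carrying the 12 protein-coding
#' genes named on mussel mitochondrial maps (ND1-ND6, ND4L, COX1-3, ATP6,
#' CYTB; mussel mtDNA lacks atp8), two rRNAs, 23 tRNAs and a control
#' region; a nuclear transcript set with housekeeping, tissue-marker and
#' foot-adhesive classes; bacterial contaminant transcripts over ten
#' taxonomic classes; and a labelled protein-database stand-in assigning
#' each transcript one taxon and one of 144 metabolic subsystem labels.
#'
#' @return a list of reference parameters
#' @export
default_reference_config <- function() {
  list(
    genome_length = 16744L,
    genome_id = "mito_synth",
    # CDS lengths, in genome order
    cds = c(COX1 = 1600L, COX2 = 690L, ATP6 = 700L, ND2 = 960L, ND3 = 350L,
            ND4 = 1300L, ND4L = 280L, ND5 = 1700L, ND6 = 480L, ND1 = 900L,
            CYTB = 1140L, COX3 = 780L),
    rrna = c(rrnS = 950L, rrnL = 1250L),
    n_trna = 23L,
    trna_length = 70L,
    control_region_length = 800L,
    cryptic_length = 120L,   # unannotated transcribed segment 5' of CYTB
    cryptic_gap = 15L,       # bp between cryptic segment end and CYTB start
    n_housekeeping = 400L,
    hk_length_range = c(300L, 2500L),
    hk_length_meanlog = log(800),
    hk_length_sdlog = 0.4,
    n_bacterial = 30L,
    bacterial_taxa = c("Gammaproteobacteria", "Alphaproteobacteria",
                       "Bacilli", "Flavobacteriia", "Mollicutes",
                       "Spirochaetia", "Clostridia", "Actinobacteria",
                       "Cyanobacteria", "Epsilonproteobacteria"),
    bacterial_length_range = c(400L, 1200L),
    n_subsystems = 144L,
    marker_lengths = c(vdg3 = 650L, HSP90 = 2200L, fp_pm1 = 900L,
                       fp_pm2 = 760L, fp_pm3 = 1100L, VERL = 1800L,
                       VCL = 1500L)
  )
}

# internal: lay out genome features left to right; returns annotation table
# plus the cryptic (unannotated) interval, 0-based half-open
layout_genome <- function(config) {
  cds <- config$cds
  rrna <- config$rrna
  n_trna <- config$n_trna
  feats <- data.frame(
    name = c(names(rrna)[1], paste0("trnA", 1:3), names(rrna)[2],
             "trnB1",
             "ND1", "ND2", "trnC1", "COX1", "COX2",
             paste0("trnD", 1:3), "ATP6", "ND4L", "ND4", "trnE1",
             "ND5", paste0("trnF", 1:3), "ND6", paste0("trnG", 1:3),
             "control_region", paste0("trnH", 1:4),
             "CRYPTIC", "CYTB", "COX3", "ND3", paste0("trnI", 1:4)),
    stringsAsFactors = FALSE
  )
  len_of <- function(nm) {
    if (nm %in% names(cds)) return(cds[[nm]])
    if (nm %in% names(rrna)) return(rrna[[nm]])
    if (nm == "control_region") return(config$control_region_length)
    if (nm == "CRYPTIC") return(config$cryptic_length)
    config$trna_length
  }
  cat_of <- function(nm) {
    if (nm %in% names(cds)) return("CDS")
    if (nm %in% names(rrna)) return("rRNA")
    if (nm == "control_region") return("control_region")
    if (nm == "CRYPTIC") return("cryptic")
    "tRNA"
  }
  feats$length <- vapply(feats$name, len_of, integer(1))
  feats$category <- vapply(feats$name, cat_of, character(1))
  if (sum(feats$length) >= config$genome_length)
    stop("reference config error: features longer than the genome")
  spare <- config$genome_length - sum(feats$length)
  n_gaps <- nrow(feats) + 1L
  gap <- rep(spare %/% n_gaps, n_gaps)
  extra <- spare %% n_gaps
  if (extra > 0) gap[seq_len(extra)] <- gap[seq_len(extra)] + 1L
  # the cryptic segment sits a fixed short distance 5' of CYTB
  i_cryptic <- which(feats$name == "CRYPTIC")
  gap[i_cryptic + 1L] <- config$cryptic_gap
  pos <- 0L
  starts <- integer(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    pos <- pos + gap[i]
    starts[i] <- pos
    pos <- pos + feats$length[i]
  }
  if (pos > config$genome_length)
    stop("reference config error: layout exceeds genome length")
  feats$start <- starts
  feats$end <- starts + feats$length
  cryptic <- c(feats$start[i_cryptic], feats$end[i_cryptic])
  ann <- feats[feats$category != "cryptic",
               c("name", "start", "end", "category")]
  ann$strand <- "+"
  rownames(ann) <- NULL
  list(annotations = ann[, c("name", "start", "end", "strand", "category")],
       cryptic = cryptic)
}

#' Build the synthetic reference set
#'
#' Generates the mitochondrial genome (i.i.d. uniform bases with planted
#' homopolymer runs), its gene annotations, the nuclear/bacterial
#' transcript set, and the labelled protein-database stand-in. One
#' unannotated "cryptic" transcribed segment is planted immediately 5' of
#' CYTB; it is deliberately absent from the protein database so that it can
#' only be discovered by fragment recruitment.
#'
#' @param config reference configuration, see [default_reference_config()]
#' @param seed integer seed fixing all randomness
#' @return an `est_reference` list: `genome`, `genome_id`, `annotations`
#'   (0-based half-open), `cryptic` interval, `transcripts` table,
#'   `seqs` (named transcript sequences), `db` (id, taxon, subsystem)
#' @export
make_reference <- function(config = default_reference_config(), seed = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  with_seed(seed, {
    lay <- layout_genome(config)
    genome <- random_dna(config$genome_length, run_every = 150)
    ann <- lay$annotations
    stopifnot(all(ann$start >= 0), all(ann$end <= config$genome_length),
              all(ann$start < ann$end))

    seg <- function(a, b) substr(genome, a + 1L, b)
    genic <- ann[ann$category %in% c("CDS", "rRNA"), ]
    mito_ids <- paste0("MT_", genic$name)
    seqs <- setNames(
      vapply(seq_len(nrow(genic)),
             function(i) seg(genic$start[i], genic$end[i]), character(1)),
      mito_ids)
    cls <- setNames(rep("mito", length(mito_ids)), mito_ids)

    cry_id <- "MT_cryptic_CYTB5p"
    seqs[cry_id] <- seg(lay$cryptic[1], lay$cryptic[2])
    cls[cry_id] <- "cryptic"

    nh <- config$n_housekeeping
    hk_len <- pmin(pmax(round(exp(rnorm(nh, config$hk_length_meanlog,
                                        config$hk_length_sdlog))),
                        config$hk_length_range[1]), config$hk_length_range[2])
    hk_ids <- sprintf("hk%03d", seq_len(nh))
    for (i in seq_len(nh)) seqs[hk_ids[i]] <- random_dna(hk_len[i])
    cls[hk_ids] <- "housekeeping"

    ml <- config$marker_lengths
    for (nm in names(ml)) seqs[nm] <- random_dna(ml[[nm]])
    cls[names(ml)] <- ifelse(grepl("^fp_", names(ml)), "foot_protein",
                             "marker")

    nb <- config$n_bacterial
    taxa <- config$bacterial_taxa
    b_len <- sample(config$bacterial_length_range[1]:
                    config$bacterial_length_range[2], nb, replace = TRUE)
    b_ids <- sprintf("bact%03d", seq_len(nb))
    # taxa in blocks so a tissue expressing the first 3k transcripts sees
    # exactly k taxa (bacterial richness contrast between tissues)
    b_tax <- taxa[pmin((seq_len(nb) - 1L) %/% 3L + 1L, length(taxa))]
    for (i in seq_len(nb)) seqs[b_ids[i]] <- random_dna(b_len[i])
    cls[b_ids] <- paste0("bacterial:", b_tax)

    if (anyDuplicated(names(seqs)))
      stop("reference config error: duplicate transcript ids")

    # protein-db stand-in: every transcript except the cryptic segment,
    # with exactly one taxon and one subsystem label each
    ss <- function(i) sprintf("SS%03d", i)
    db_ids <- setdiff(names(seqs), cry_id)
    subsystem <- setNames(character(length(db_ids)), db_ids)
    subsystem[mito_ids[genic$category == "CDS"]] <-
      ss(((seq_len(sum(genic$category == "CDS")) - 1L) %% 4L) + 1L)
    subsystem[mito_ids[genic$category == "rRNA"]] <- ss(5L)
    subsystem[hk_ids] <- ss(((seq_len(nh) - 1L) %% 133L) + 6L)
    subsystem["VERL"] <- ss(139L)
    subsystem["VCL"] <- ss(140L)
    subsystem[c("fp_pm1", "fp_pm2", "fp_pm3")] <- ss(141:143)
    subsystem["vdg3"] <- ss(144L)
    subsystem["HSP90"] <- ss(6L)
    subsystem[b_ids] <- ss(((seq_len(nb) * 7L) %% 133L) + 6L)
    taxon <- ifelse(startsWith(cls[db_ids], "bacterial:"),
                    sub("^bacterial:", "Bacteria:", cls[db_ids]),
                    "Eukaryota")
    db <- data.frame(id = db_ids, taxon = unname(taxon),
                     subsystem = unname(subsystem),
                     stringsAsFactors = FALSE)

    transcripts <- data.frame(id = names(seqs), class = unname(cls),
                              length = nchar(unname(seqs)),
                              stringsAsFactors = FALSE)
    structure(list(genome = genome, genome_id = config$genome_id,
                   annotations = ann, cryptic = lay$cryptic,
                   transcripts = transcripts, seqs = seqs, db = db,
                   config = config),
              class = "est_reference")
  })
}

#' Default tissue-profile configuration
#'
#' Expression parameters per tissue. Mitochondrial and bacterial fractions,
#' expressed-transcript richness and marker placement follow the study's
#' qualitative structure: highest mitochondrial abundance in digestive
#' gland and gill, a 4.2% bacterial fraction in the digestive gland that is
#' three-fold the other tissues, vdg3 restricted to the digestive gland,
#' HSP90 to the gill, adhesive plaque proteins to the foot, and an equal
#' female/male template mix driving VERL vs VCL. Mitochondrial fractions
#' are calibration choices (the study reports no numbers); flagged here.
#'
#' @return list of per-tissue profile parameters
#' @export
default_profile_config <- function() {
  list(
    mito_fraction = c(digestive_gland = 0.30, foot = 0.10, gill = 0.26,
                      mantle = 0.08),  # calibration choice, not a reported value
    bacterial_fraction = c(digestive_gland = 0.042, foot = 0.014,
                           gill = 0.014, mantle = 0.014),
    sex_mix = c(digestive_gland = 0.5, foot = 0.5, gill = 0.5, mantle = 0.5),
    # combined VERL+VCL weight; gill largest as in the marker distribution
    sex_marker_weight = c(digestive_gland = 0.04, foot = 0.04, gill = 0.088,
                          mantle = 0.04),
    vdg3_weight = 0.015,      # digestive gland only
    hsp90_weight = 0.001,     # gill only
    foot_protein_weight = c(fp_pm1 = 0.05, fp_pm2 = 0.03, fp_pm3 = 0.02),
    cryptic_weight = 0.008,   # digestive gland only
    # expressed housekeeping transcripts (richness: dg, gill > foot, mantle)
    hk_expressed = list(digestive_gland = 1:350, foot = 201:380,
                        gill = 1:330, mantle = 1:200),
    # bacterial richness: all 10 taxa in digestive gland, 4 elsewhere
    bacterial_expressed = list(digestive_gland = 1:30, foot = 1:12,
                               gill = 1:12, mantle = 1:12),
    # relative weights of mitochondrial gene transcripts (rRNAs dominate,
    # ND4 the most abundant mRNA at twice COX1)
    mito_gene_weights = c(rrnS = 0.18, rrnL = 0.22, ND4 = 0.10, COX1 = 0.05,
                          ND1 = 0.05, ND2 = 0.05, ND3 = 0.04, ND4L = 0.02,
                          ND5 = 0.06, ND6 = 0.03, COX2 = 0.05, COX3 = 0.05,
                          ATP6 = 0.05, CYTB = 0.05)
  )
}

#' Build per-tissue expression profiles
#'
#' @param reference an `est_reference`
#' @param config see [default_profile_config()]
#' @param seed unused by the deterministic default construction; kept so
#'   stochastic profile variants stay reproducible
#' @return named list of `tissue_profile` objects (weights over every
#'   transcript id, mito/bacterial fractions, sex mix)
#' @export
make_profiles <- function(reference, config = default_profile_config(),
                          seed = 1L) {
  stopifnot(inherits(reference, "est_reference"))
  fr <- c(config$mito_fraction, config$bacterial_fraction, config$sex_mix)
  if (any(fr < 0 | fr > 1))
    stop("profile parameter error: fractions must lie in [0, 1]")
  ids <- reference$transcripts$id
  cls <- setNames(reference$transcripts$class, ids)
  mg <- config$mito_gene_weights
  if (abs(sum(mg) - 1) > 1e-9)
    stop("profile parameter error: mito gene weights must sum to 1")
  hk_ids <- ids[cls == "housekeeping"]
  b_ids <- ids[startsWith(cls, "bacterial:")]

  out <- lapply(tissues_all(), function(ts) {
    w <- setNames(numeric(length(ids)), ids)
    w[paste0("MT_", names(mg))] <- config$mito_fraction[[ts]] * mg
    bi <- b_ids[config$bacterial_expressed[[ts]]]
    bw <- 1 / seq_along(bi)
    w[bi] <- config$bacterial_fraction[[ts]] * bw / sum(bw)
    sx <- config$sex_mix[[ts]]
    w["VERL"] <- config$sex_marker_weight[[ts]] * sx
    w["VCL"] <- config$sex_marker_weight[[ts]] * (1 - sx)
    if (ts == "digestive_gland") {
      w["vdg3"] <- config$vdg3_weight
      w["MT_cryptic_CYTB5p"] <- config$cryptic_weight
    }
    if (ts == "gill") w["HSP90"] <- config$hsp90_weight
    if (ts == "foot")
      w[names(config$foot_protein_weight)] <- config$foot_protein_weight
    rem <- 1 - sum(w)
    if (rem <= 0)
      stop("profile parameter error: fixed weights exceed 1 for ", ts)
    hi <- hk_ids[config$hk_expressed[[ts]]]
    hw <- 1 / (seq_along(hi) + 10)
    w[hi] <- rem * hw / sum(hw)
    w <- w / sum(w)
    structure(list(tissue = ts, weights = w,
                   mito_fraction = config$mito_fraction[[ts]],
                   bacterial_fraction = config$bacterial_fraction[[ts]],
                   sex_mix = config$sex_mix[[ts]]),
              class = "tissue_profile")
  })
  names(out) <- tissues_all()
  out
}

#' Default MID barcode tags
#'
#' Four 10-mer multiplex identifiers with pairwise Hamming distance >= 4,
#' prepended at the 5' end of every simulated read.
#'
#' @return named character vector, tissue -> tag
#' @export
default_mid_tags <- function() {
  c(digestive_gland = "ACGAGTGCGT", foot = "ACGCTCGACA",
    gill = "AGACGCACTC", mantle = "AGCACTGTAG")
}

#' Default 454-style error model
#'
#' Per-base substitutions plus homopolymer over/under-calls (length +/- 1
#' per run with probability proportional to run length), the signature
#' error mode of pyrosequencing.
#'
#' @return list with `sub_rate` and `homopolymer_rate` (per run of
#'   length >= 3, scaled by run length)
#' @export
default_error_model <- function() {
  list(sub_rate = 0.002, homopolymer_rate = 0.005)
}

#' Default read-length model
#'
#' Truncated-normal read lengths (tag included), calibrated to the
#' per-tissue means of the study's summary table (205/191/208/178 bp;
#' 196 bp overall).
#'
#' @return list with per-tissue `mean`, common `sd`, and `bounds`
#' @export
default_length_model <- function() {
  list(mean = c(digestive_gland = 205, foot = 191, gill = 208, mantle = 178),
       sd = 30, bounds = c(50L, 600L))
}

#' Default per-tissue read counts
#'
#' Desk-scale counts proportional to the study's per-tissue totals
#' (33,992 / 31,227 / 58,271 / 52,057), scaled down 16-fold.
#'
#' @return named integer vector
#' @export
default_n_reads <- function() {
  c(digestive_gland = 2125L, foot = 1952L, gill = 3642L, mantle = 3254L)
}

# internal: apply the 454 error model to one fragment
apply_errors <- function(frag, sub_rate, hp_rate) {
  ch <- strsplit(frag, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (sub_rate > 0) {
    hit <- which(runif(n) < sub_rate)
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1)
    }
  }
  if (hp_rate > 0) {
    r <- rle(ch)
    runs <- which(r$lengths >= 3)
    if (length(runs)) {
      p <- pmin(0.5, hp_rate * r$lengths[runs])
      ev <- runs[runif(length(runs)) < p]
      if (length(ev)) {
        delta <- sample(c(-1L, 1L), length(ev), replace = TRUE)
        r$lengths[ev] <- pmax(1L, r$lengths[ev] + delta)
        ch <- inverse.rle(r)
      }
    }
  }
  paste(ch, collapse = "")
}

#' Simulate a multiplexed pool of barcoded reads
#'
#' Draws reads per tissue from the profile weights, from either strand,
#' with truncated-normal lengths (tag included; the cDNA fragment is the
#' drawn length minus the tag, clamped to the source transcript length),
#' applies the 454 error model to the fragment, prepends the tissue MID
#' tag, and shuffles the pool. A truth row is kept for every read.
#'
#' @param reference an `est_reference`
#' @param profiles output of [make_profiles()]
#' @param n_reads named integer vector, tissue -> read count
#' @param error_model see [default_error_model()]
#' @param length_model see [default_length_model()]
#' @param mids named character vector of MID tags
#' @param seed integer seed
#' @return list with `reads` (data.frame: id, sequence, mid) and `truth`
#'   (data.frame: read_id, source_id, source_start, strand, tissue)
#' @export
simulate_reads <- function(reference, profiles, n_reads = default_n_reads(),
                           error_model = default_error_model(),
                           length_model = default_length_model(),
                           mids = default_mid_tags(), seed = 1L) {
  stopifnot(inherits(reference, "est_reference"))
  if (any(n_reads <= 0)) stop("parameter error: n_reads must be positive")
  if (!all(names(n_reads) %in% names(profiles)))
    stop("parameter error: n_reads names must match profiles")
  with_seed(seed, {
    pieces <- lapply(names(n_reads), function(ts) {
      n <- n_reads[[ts]]
      w <- profiles[[ts]]$weights
      mid <- mids[[ts]]
      tl <- nchar(mid)
      src <- sample(names(w), n, replace = TRUE, prob = w)
      len <- round(rnorm(n, length_model$mean[[ts]], length_model$sd))
      len <- pmin(pmax(len, length_model$bounds[1]), length_model$bounds[2])
      slen <- nchar(reference$seqs[src])
      frag_len <- pmin(pmax(len - tl, 1L), slen)
      off <- floor(runif(n) * (slen - frag_len + 1L))
      strand <- ifelse(runif(n) < 0.5, "+", "-")
      frag <- substr(reference$seqs[src], off + 1L, off + frag_len)
      neg <- strand == "-"
      if (any(neg)) frag[neg] <- cpp_revcomp(frag[neg])
      if (error_model$sub_rate > 0 || error_model$homopolymer_rate > 0)
        frag <- vapply(frag, apply_errors, character(1),
                       sub_rate = error_model$sub_rate,
                       hp_rate = error_model$homopolymer_rate,
                       USE.NAMES = FALSE)
      data.frame(sequence = paste0(mid, frag), mid = mid,
                 source_id = src, source_start = off, strand = strand,
                 tissue = ts, stringsAsFactors = FALSE)
    })
    pool <- do.call(rbind, pieces)
    pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
    pool$id <- sprintf("MGR%07d", seq_len(nrow(pool)))
    rownames(pool) <- NULL
    list(reads = pool[, c("id", "sequence", "mid")],
         truth = data.frame(read_id = pool$id, source_id = pool$source_id,
                            source_start = pool$source_start,
                            strand = pool$strand, tissue = pool$tissue,
                            stringsAsFactors = FALSE))
  })
}

#' Write simulated reads, truth table and reference to disk
#'
#' @param sim output of [simulate_reads()]
#' @param path output FASTA path
#' @return the path, invisibly
#' @export
write_reads_fasta <- function(sim, path) {
  write_fasta(setNames(sim$reads$sequence, sim$reads$id), path)
}

#' @rdname write_reads_fasta
#' @param truth truth table data.frame
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reads_fasta
#' @param reference an `est_reference`
#' @param fasta_path,gff3_path output paths
#' @export
write_reference <- function(reference, fasta_path, gff3_path) {
  write_fasta(setNames(reference$genome, reference$genome_id), fasta_path)
  write_gff3(reference$annotations, gff3_path, seqid = reference$genome_id)
  invisible(c(fasta_path, gff3_path))
}
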