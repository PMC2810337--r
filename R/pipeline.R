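#' Pipeline configuration
#'
#' Assembles the full configuration for [run_pipeline()] with documented
#' defaults; any element can be overridden. The seed governs every
#' stochastic step.
#'
#' @param outdir output directory
#' @param seed master seed
#' @param n_reads per-tissue read counts
#' @param error_model,length_model,mids simulator settings
#' @param reference_config,profile_config reference and expression settings
#' @param min_overlap,min_identity assembler thresholds
#' @param recruit_identity identity cutoff for per-gene abundance
#' @param matrix_width recruitment matrix width in pixels
#' @param annotate_e,classify_e,homology_e E-value cutoffs
#' @param classify_min_align minimum classification alignment length
#' @param top_n top-N table depth
#' @param nmds_restarts NMDS random restarts
#' @return a validated `pipeline_config`
#' @export
pipeline_config <- function(outdir = "results", seed = 42L,
                            n_reads = default_n_reads(),
                            error_model = default_error_model(),
                            length_model = default_length_model(),
                            mids = default_mid_tags(),
                            reference_config = default_reference_config(),
                            profile_config = default_profile_config(),
                            min_overlap = 40L, min_identity = 0.95,
                            recruit_identity = 0.98,
                            matrix_width = 1024L,
                            annotate_e = 1e-5, classify_e = 1e-10,
                            homology_e = 1e-5, classify_min_align = 50L,
                            top_n = 10L, nmds_restarts = 20L) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`
#' @export
validate_config <- function(config) {
  with(config, {
    if (is.null(seed) || !is.finite(seed))
      stop("config validation error: a seed is mandatory")
    if (any(n_reads <= 0))
      stop("config validation error: n_reads must be positive")
    if (min_identity <= 0 || min_identity > 1)
      stop("config validation error: min_identity must lie in (0, 1]")
    if (recruit_identity <= 0 || recruit_identity > 1)
      stop("config validation error: recruit_identity must lie in (0, 1]")
    if (min_overlap < 10)
      stop("config validation error: min_overlap < 10")
    if (any(c(annotate_e, classify_e, homology_e) <= 0))
      stop("config validation error: E-value cutoffs must be positive")
    if (matrix_width < 1)
      stop("config validation error: matrix_width must be positive")
  })
  invisible(config)
}

#' Run the full pipeline
#'
#' Stages run in order simulate -> demultiplex -> assemble -> recruit ->
#' profile, writing deterministically named TSV/BED/FASTA/PGM outputs
#' under `config$outdir`. Reruns with the same configuration are
#' byte-identical for all TSV and BED outputs. A failing stage aborts
#' with the stage name.
#'
#' @param config a `pipeline_config`
#' @return invisibly, a list with the stage objects and the output paths
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  logfile <- out("run_log.txt")
  loglines <- character(0)
  log <- function(...) {
    msg <- paste0(...)
    message(msg)
    loglines <<- c(loglines, msg)
    writeLines(loglines, logfile)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log("musselEST pipeline, seed ", config$seed)
  log("thresholds: min_overlap=", config$min_overlap,
      " min_identity=", config$min_identity,
      " recruit_identity=", config$recruit_identity,
      " annotate_e=", config$annotate_e, " classify_e=", config$classify_e)

  scheme <- scoring_scheme()

  # --- simulate ---------------------------------------------------------
  sim <- stage("simulate", {
    reference <- make_reference(config$reference_config, seed = config$seed)
    profiles <- make_profiles(reference, config$profile_config)
    sim <- simulate_reads(reference, profiles, config$n_reads,
                          config$error_model, config$length_model,
                          config$mids, seed = config$seed + 1L)
    write_reads_fasta(sim, out("reads.fasta"))
    write_truth_table(sim$truth, out("truth.tsv"))
    write_reference(reference, out("reference.fasta"), out("reference.gff3"))
    write_barcodes(data.frame(tissue = names(config$mids),
                              mid = unname(config$mids)), out("barcodes.tsv"))
    log("simulate: ", nrow(sim$reads), " reads pooled from ",
        length(config$n_reads), " tissues")
    list(reference = reference, profiles = profiles, sim = sim)
  })
  reference <- sim$reference

  # --- demultiplex ------------------------------------------------------
  demux <- stage("demultiplex", {
    barcodes <- data.frame(tissue = names(config$mids),
                           mid = unname(config$mids))
    dm <- demultiplex(sim$sim$reads, barcodes)
    counts <- data.frame(
      tissue = c(names(dm$bins), "unassigned"),
      reads = c(vapply(dm$bins, function(b) b$n_assigned, integer(1)),
                length(dm$unassigned)))
    write.table(counts, out("demux_counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    for (ts in names(dm$bins))
      write_fasta(dm$bins[[ts]]$reads, out(paste0("reads_", ts, ".fasta")))
    log("demultiplex: ", length(dm$unassigned), " of ", dm$n_input,
        " reads unassigned")
    dm
  })

  # --- assemble ---------------------------------------------------------
  assemblies <- stage("assemble", {
    asm <- lapply(demux$bins, greedy_assemble,
                  min_overlap = config$min_overlap,
                  min_identity = config$min_identity)
    for (ts in names(asm))
      write_assembly(asm[[ts]], out(paste0("contigs_", ts, ".fasta")),
                     out(paste0("members_", ts, ".tsv")))
    log("assemble: ",
        paste(vapply(asm, function(a) nrow(a$contigs), integer(1)),
              collapse = "/"), " contigs per tissue")
    asm
  })

  # --- recruit ----------------------------------------------------------
  recruit <- stage("recruit", {
    lapply(names(demux$bins), function(ts) {
      hits <- recruit_reads(demux$bins[[ts]], reference$genome, scheme)
      mat <- build_matrix(hits, nchar(reference$genome),
                          width = config$matrix_width)
      write_recruitment_matrix(mat,
                               out(paste0("recruitment_", ts, ".tsv")),
                               out(paste0("recruitment_", ts, ".pgm")))
      ga <- gene_abundance(hits, reference$annotations,
                           demux$bins[[ts]]$n_assigned,
                           min_identity = config$recruit_identity)
      write.table(ga, out(paste0("gene_abundance_", ts, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      reg <- unannotated_regions(hits, reference$annotations,
                                 nchar(reference$genome))
      write_bed(reg, out(paste0("unannotated_regions_", ts, ".bed")),
                chrom = reference$genome_id)
      list(hits = hits, matrix = mat, gene_abundance = ga, regions = reg)
    }) -> rec
    names(rec) <- names(demux$bins)
    log("recruit: ",
        paste(vapply(rec, function(r) nrow(r$hits), integer(1)),
              collapse = "/"), " reads recruited per tissue")
    rec
  })

  # --- profile ----------------------------------------------------------
  prof <- stage("profile", {
    db_seqs <- reference$seqs[reference$db$id]
    anns <- lapply(assemblies, annotate_contigs, db_seqs = db_seqs,
                   scheme = scheme, e_cutoff = config$annotate_e)
    sizes <- vapply(demux$bins, function(b) b$n_assigned, integer(1))
    stats <- lapply(names(assemblies), function(ts)
      summarize_dataset(assemblies[[ts]], demux$bins[[ts]],
                        n_annotated = nrow(anns[[ts]])))
    names(stats) <- names(assemblies)
    stats$Total <- summary_total(stats)
    write.table(summary_table(stats), out("table1_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    profiles_t <- abundance_table(assemblies, anns, sizes)
    topn <- top_features(profiles_t, config$top_n)
    write.table(topn, out("top_transcripts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cls <- lapply(demux$bins, classify_reads, reference = reference,
                  scheme = scheme, e_cutoff = config$classify_e,
                  min_align = config$classify_min_align)
    # marker counting at read level so annotated singletons contribute
    read_prof <- lapply(names(cls), function(ts) {
      tab <- table(cls[[ts]]$assignments$feature)
      abundance_profile(setNames(as.numeric(tab), names(tab)),
                        cls[[ts]]$sample_size, sample = ts)
    })
    names(read_prof) <- names(cls)
    mk <- marker_ratio(read_prof)
    write.table(data.frame(statistic = c("VERL:VCL ratio"),
                           value = round(mk$ratio, 4)),
                out("marker_ratio.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    taxa_tab <- do.call(rbind, lapply(names(cls), function(ts)
      data.frame(tissue = ts, taxon = names(cls[[ts]]$taxa$counts),
                 reads = as.numeric(cls[[ts]]$taxa$counts),
                 stringsAsFactors = FALSE)))
    write.table(taxa_tab, out("taxa_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ss_tab <- do.call(rbind, lapply(names(cls), function(ts)
      data.frame(tissue = ts, subsystem = names(cls[[ts]]$subsystems$counts),
                 reads = as.numeric(cls[[ts]]$subsystems$counts),
                 stringsAsFactors = FALSE)))
    write.table(ss_tab, out("subsystem_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    marg <- vapply(cls, function(cl) {
      bact <- grepl("^Bacteria:", cl$assignments$taxon)
      if (sum(bact) < 2) return(NA_real_)
      margalef(length(unique(cl$assignments$taxon[bact])), sum(bact))
    }, numeric(1))
    write.table(data.frame(tissue = names(marg),
                           margalef_d = round(marg, 3)),
                out("margalef.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    bc <- bray_curtis(lapply(cls, `[[`, "subsystems"))
    write.table(data.frame(tissue = rownames(bc), round(bc, 6)),
                out("bray_curtis.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    ord <- nmds(bc, n_restarts = config$nmds_restarts,
                seed = config$seed + 2L)
    write.table(data.frame(tissue = rownames(ord$coordinates),
                           round(ord$coordinates, 6),
                           stress = round(ord$stress, 6)),
                out("nmds_coordinates.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    log("profile: VERL:VCL ratio ", round(mk$ratio, 3), ", 2-D stress ",
        signif(ord$stress, 3))
    list(annotations = anns, stats = stats, profiles = profiles_t,
         top = topn, marker = mk, classify = cls, margalef = marg,
         bray_curtis = bc, nmds = ord)
  })

  # homology matrix (needs contigs in every tissue)
  hom <- stage("homology", {
    sets <- lapply(assemblies, function(a)
      setNames(a$contigs$consensus, a$contigs$id))
    if (all(vapply(sets, length, integer(1)) > 0)) {
      hm <- homology_matrix(sets, scheme, e_cutoff = config$homology_e)
      write.table(data.frame(reference = rownames(hm), hm),
                  out("homology_matrix.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      hm
    } else {
      log("homology: skipped (a tissue produced no contigs)")
      NULL
    }
  })

  log("pipeline complete")
  invisible(list(reference = reference, sim = sim$sim, demux = demux,
                 assemblies = assemblies, recruit = recruit,
                 profile = prof, homology = hom, outdir = config$outdir))
}
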