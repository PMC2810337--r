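# Shared fixtures, built once per test run and cached. The default
# simulation uses the package's default study conditions; the error-free
# simulation backs the truth-recovery oracles.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- force(expr)
  .fx_cache[[name]]
}

fixture_barcodes <- function() {
  data.frame(tissue = names(default_mid_tags()),
             mid = unname(default_mid_tags()), stringsAsFactors = FALSE)
}

fixture_reference <- function() fx("ref", make_reference(seed = 1))

fixture_profiles <- function() fx("prof", make_profiles(fixture_reference()))

fixture_sim <- function() fx("sim",
  simulate_reads(fixture_reference(), fixture_profiles(), seed = 7))

fixture_demux <- function() fx("demux",
  demultiplex(fixture_sim()$reads, fixture_barcodes()))

fixture_assemblies <- function() fx("asm",
  lapply(fixture_demux()$bins, greedy_assemble))

fixture_classify <- function() fx("cls",
  lapply(fixture_demux()$bins, classify_reads,
         reference = fixture_reference()))

fixture_recruit <- function() fx("rec",
  lapply(fixture_demux()$bins, recruit_reads,
         genome = fixture_reference()$genome))

# error-free pool: 5,000 reads per tissue, no substitutions or
# homopolymer events, so every read is an exact fragment of its source
fixture_clean_sim <- function() fx("clean",
  simulate_reads(fixture_reference(), fixture_profiles(),
                 n_reads = c(digestive_gland = 5000L, foot = 5000L,
                             gill = 5000L, mantle = 5000L),
                 error_model = list(sub_rate = 0, homopolymer_rate = 0),
                 seed = 11))

fixture_clean_demux <- function() fx("clean_demux",
  demultiplex(fixture_clean_sim()$reads, fixture_barcodes()))
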