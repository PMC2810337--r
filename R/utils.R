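#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), the convention used by
#' the printed summary tables, as opposed to R's round-half-even.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Reverse complement of nucleotide sequences
#'
#' @param x character vector of sequences
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  cpp_revcomp(x)
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# internal: random DNA with planted homopolymer runs (length 4-8) so the
# pyrosequencing error model has substrate to act on
random_dna <- function(len, run_every = 150) {
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, len, replace = TRUE)
  n_runs <- len %/% run_every
  if (n_runs > 0) {
    starts <- sample.int(max(1L, len - 8L), n_runs)
    lens <- sample(4:8, n_runs, replace = TRUE)
    rb <- sample(bases, n_runs, replace = TRUE)
    for (i in seq_len(n_runs)) {
      idx <- starts[i]:min(len, starts[i] + lens[i] - 1L)
      s[idx] <- rb[i]
    }
  }
  paste(s, collapse = "")
}

tissues_all <- function() c("digestive_gland", "foot", "gill", "mantle")
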