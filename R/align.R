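#' Nucleotide scoring scheme with Karlin-Altschul parameters
#'
#' The match/mismatch scores follow the fragment-recruitment setting
#' (+5/-4); affine gap penalties default to the standard pairing for that
#' reward/penalty ratio (a gap of length L costs
#' `gap_open + L * gap_extend`). The Gumbel parameters lambda and K for
#' ungapped statistics are derived numerically under uniform base
#' composition.
#'
#' @param match,mismatch match reward (> 0) and mismatch penalty (< 0)
#' @param gap_open,gap_extend affine gap penalties (positive costs)
#' @return a `scoring_scheme` list with lambda, K and relative entropy H
#' @export
scoring_scheme <- function(match = 5L, mismatch = -4L, gap_open = 8L,
                           gap_extend = 6L) {
  if (!(match > 0 && mismatch < 0))
    stop("parameter error: need match > 0 > mismatch")
  ka <- karlin_altschul(match, mismatch)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = ka$lambda, K = ka$K, H = ka$H),
            class = "scoring_scheme")
}

.ka_cache <- new.env(parent = emptyenv())

#' Karlin-Altschul parameters for a two-valued nucleotide score
#'
#' lambda solves sum_ij p_i p_j exp(lambda s_ij) = 1 (root-finding). K is
#' obtained by an exact renewal computation on the local-score (Lindley)
#' chain h <- max(0, h + X): the long-run rate of score excursions whose
#' peak reaches a threshold s equals K exp(-lambda s) for large s, so K is
#' read off at a high threshold where the lattice wobble has died out.
#' This reproduces the exact geometric tail in the solvable +1/-1 walk and
#' the simulated Gumbel location for +5/-4 (K ~ 0.175).
#'
#' @param match,mismatch integer scores
#' @param p base composition (default uniform)
#' @return list with lambda, K and relative entropy H (nats)
#' @export
karlin_altschul <- function(match = 5L, mismatch = -4L, p = rep(0.25, 4)) {
  key <- paste(match, mismatch, paste(signif(p, 10), collapse = ","),
               sep = "|")
  if (!is.null(.ka_cache[[key]])) return(.ka_cache[[key]])
  pm <- sum(p^2)
  px <- 1 - pm
  mu <- pm * match + px * mismatch
  if (mu >= 0)
    stop("parameter error: expected score must be negative for local statistics")
  f <- function(l) pm * exp(l * match) + px * exp(l * mismatch) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lambda <- uniroot(f, c(1e-9, hi), tol = 1e-12)$root
  mexp <- pm * match * exp(lambda * match) +
    px * mismatch * exp(lambda * mismatch)
  s0 <- 16L * match
  K <- mean(vapply(s0 + 0:1, function(s)
    excursion_rate(match, mismatch, pm, s) * exp(lambda * s), numeric(1)))
  out <- list(lambda = lambda, K = K, H = lambda * mexp)
  .ka_cache[[key]] <- out
  out
}

# long-run rate (per alignment cell) of local-score excursions whose peak
# reaches >= s, for the two-valued step distribution
excursion_rate <- function(match, mismatch, pm, s) {
  px <- 1 - pm
  N <- s + 60L * abs(mismatch)        # truncation; drift is negative
  # f(h) = P(reach >= s before returning to 0 | h), transient h = 1..s-1
  h <- 1:(s - 1)
  up <- h + match
  dn <- pmax(h + mismatch, 0L)
  A <- matrix(0, s - 1, s - 1)
  b <- numeric(s - 1)
  for (i in seq_along(h)) {
    if (up[i] >= s) b[i] <- b[i] + pm else A[i, up[i]] <- A[i, up[i]] + pm
    if (dn[i] >= 1) A[i, dn[i]] <- A[i, dn[i]] + px
  }
  fvec <- solve(diag(s - 1) - A, b)
  f_at <- function(x) if (x >= s) 1 else if (x <= 0) 0 else fvec[x]
  # stationary distribution of the truncated Lindley chain on 0..N
  P <- matrix(0, N + 1, N + 1)
  for (hh in 0:N) {
    uu <- min(hh + match, N)
    dd <- max(hh + mismatch, 0L)
    P[hh + 1, uu + 1] <- P[hh + 1, uu + 1] + pm
    P[hh + 1, dd + 1] <- P[hh + 1, dd + 1] + px
  }
  M <- t(P) - diag(N + 1)
  M[N + 1, ] <- 1                      # replace one equation by sum = 1
  rhs <- c(numeric(N), 1)
  pi0 <- solve(M, rhs)[1]
  pi0 * pm * f_at(match)               # cycle starts at 0; only +step can reach
}

#' Expectation value of a local alignment score
#'
#' E = K * m * n * exp(-lambda * score), the ungapped Karlin-Altschul
#' formula; used as the working approximation for the gapped scores too,
#' which is why every cutoff in the pipeline can also be expressed as a
#' raw-score floor.
#'
#' @param score raw alignment score (vectorized)
#' @param m,n query and subject lengths
#' @param scheme a `scoring_scheme`
#' @return numeric expectation values
#' @export
estimate_evalue <- function(score, m, n, scheme) {
  if (any(m <= 0) || any(n <= 0))
    stop("parameter error: sequence lengths must be positive")
  scheme$K * m * n * exp(-scheme$lambda * score)
}

# raw-score floor equivalent to an E-value cutoff for given search space
score_floor_for_evalue <- function(e, m, n, scheme) {
  ceiling(log(scheme$K * m * n / e) / scheme$lambda)
}

#' Smith-Waterman local alignment
#'
#' Exact full-matrix affine-gap Smith-Waterman. Returns the optimal local
#' alignment plus subject-disjoint suboptimal HSPs above `score_floor`
#' (found by masking and re-aligning). Reverse-complement alignments are
#' reported with strand "-" and subject coordinates on the forward strand.
#' Coordinates are 0-based half-open.
#'
#' @param query,subject nucleotide sequences (single strings)
#' @param scheme a `scoring_scheme`
#' @param both_strands also search the reverse complement of the query
#' @param score_floor minimum reported raw score
#' @param max_hsps maximum HSPs per strand
#' @return data.frame of HSPs sorted by decreasing score (ties: lower
#'   subject start, then "+" strand), with identity = identities / length
#'   and an ungapped-statistics E-value
#' @export
smith_waterman <- function(query, subject, scheme = scoring_scheme(),
                           both_strands = TRUE, score_floor = 20L,
                           max_hsps = 10L) {
  if (!nzchar(query) || !nzchar(subject))
    stop("parameter error: empty sequence")
  run <- function(q, strand) {
    h <- cpp_sw_pair(q, subject, scheme$match, scheme$mismatch,
                     scheme$gap_open, scheme$gap_extend,
                     as.integer(score_floor), as.integer(max_hsps))
    if (nrow(h) == 0) return(cbind(h, strand = character(0)))
    if (strand == "-") {
      m <- nchar(query)
      qs <- m - h$qend
      h$qend <- m - h$qstart
      h$qstart <- qs
    }
    h$strand <- strand
    h
  }
  out <- run(query, "+")
  if (both_strands) out <- rbind(out, run(revcomp(query), "-"))
  if (nrow(out)) {
    out$identity <- out$identities / out$length
    out$evalue <- estimate_evalue(out$score, nchar(query), nchar(subject),
                                  scheme)
    out <- out[order(-out$score, out$sstart, out$strand != "+"), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Seeded many-vs-many local alignment search
#'
#' Word-seeded (default word size 11) windowed Smith-Waterman over a
#' subject set: exact word matches nominate subject windows, each resolved
#' by the same full affine DP as [smith_waterman()]. On sequences with a
#' shared word in every true alignment this reproduces the exact-mode top
#' HSP; it is the engine behind read recruitment, annotation and the
#' homology matrix.
#'
#' @param queries,subjects named character vectors
#' @param scheme a `scoring_scheme`
#' @param word seed word size
#' @param score_floor minimum raw score
#' @return data.frame of HSPs (query, subject, strand, score, coordinates
#'   0-based half-open, identity, evalue)
#' @export
seeded_search <- function(queries, subjects, scheme = scoring_scheme(),
                          word = 11L, score_floor = 20L) {
  stopifnot(length(queries) > 0, length(subjects) > 0)
  if (is.null(names(queries))) names(queries) <- sprintf("q%d", seq_along(queries))
  if (is.null(names(subjects))) names(subjects) <- sprintf("s%d", seq_along(subjects))
  h <- cpp_map_reads(unname(queries), unname(subjects), as.integer(word),
                     scheme$match, scheme$mismatch, scheme$gap_open,
                     scheme$gap_extend, as.integer(score_floor))
  h$query <- names(queries)[h$qidx]
  h$subject <- names(subjects)[h$sidx]
  h$identity <- ifelse(h$length > 0, h$identities / h$length, 0)
  h$evalue <- estimate_evalue(h$score, nchar(queries)[h$qidx],
                              nchar(subjects)[h$sidx], scheme)
  h[, c("query", "subject", "strand", "score", "qstart", "qend", "sstart",
        "send", "identities", "length", "mismatches", "gapopens",
        "identity", "evalue")]
}

# internal: best HSP per query under the deterministic tie rule
# (max score, then lower subject start, then "+" strand, then subject id)
top_hsp_per_query <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  o <- order(hits$query, -hits$score, hits$sstart,
             hits$strand != "+", hits$subject)
  h <- hits[o, , drop = FALSE]
  h <- h[!duplicated(h$query), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' All-against-all contig homology matrix
#'
#' For every ordered tissue pair, the percentage of the query tissue's
#' contigs with at least one HSP against any contig of the reference
#' tissue at `e_cutoff` or better. Rows are the reference tissue, columns
#' the query tissue; the diagonal is 100 by definition. The matrix is not
#' symmetric: each entry is a fraction of its query set.
#'
#' @param contig_sets named list, tissue -> named character vector of
#'   contig consensus sequences
#' @param scheme a `scoring_scheme`
#' @param e_cutoff E-value threshold for calling homology
#' @param word seed word size
#' @return numeric matrix (reference x query), one-decimal percentages
#' @export
homology_matrix <- function(contig_sets, scheme = scoring_scheme(),
                            e_cutoff = 1e-5, word = 11L) {
  if (any(vapply(contig_sets, length, integer(1)) == 0))
    stop("parameter error: empty contig set")
  ts <- names(contig_sets)
  m <- matrix(100.0, length(ts), length(ts), dimnames = list(ts, ts))
  for (qi in ts) for (ri in ts) {
    if (qi == ri) next
    floor_r <- score_floor_for_evalue(
      e_cutoff, max(nchar(contig_sets[[qi]])),
      sum(nchar(contig_sets[[ri]])), scheme)
    hits <- seeded_search(contig_sets[[qi]], contig_sets[[ri]], scheme,
                          word = word,
                          score_floor = max(20L, floor_r - 10L))
    hits <- hits[hits$evalue <= e_cutoff, , drop = FALSE]
    m[ri, qi] <- round_half_up(
      100 * length(unique(hits$query)) / length(contig_sets[[qi]]), 1)
  }
  m
}

#' Write HSPs as BLAST-style tabular output
#'
#' Twelve-column outfmt-6-like TSV with 1-based inclusive coordinates and
#' the raw alignment score in the final column.
#'
#' @param hits data.frame from [seeded_search()] or [smith_waterman()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_hsps <- function(hits, path) {
  tab <- data.frame(
    qseqid = if ("query" %in% names(hits)) hits$query else "query",
    sseqid = if ("subject" %in% names(hits)) hits$subject else "subject",
    pident = round(100 * hits$identity, 2),
    length = hits$length,
    mismatch = hits$mismatches,
    gapopen = hits$gapopens,
    qstart = hits$qstart + 1L, qend = hits$qend,
    sstart = hits$sstart + 1L, send = hits$send,
    evalue = signif(hits$evalue, 3),
    score = hits$score)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
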