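# Independent oracles, deliberately written as plain, slow reference code.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# plain full-matrix affine-gap local alignment, score only
sw_score_oracle <- function(q, s, match = 5, mismatch = -4, gap_open = 8,
                            gap_extend = 6) {
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  m <- length(qv); n <- length(sv)
  Hprev <- numeric(n + 1)
  Fcol <- rep(-1e18, n + 1)
  best <- 0
  for (i in 1:m) {
    Hcur <- numeric(n + 1)
    Ecur <- -1e18
    for (j in 1:n) {
      Ecur <- max(Hcur[j] - gap_open - gap_extend, Ecur - gap_extend)
      Fcol[j + 1] <- max(Hprev[j + 1] - gap_open - gap_extend,
                         Fcol[j + 1] - gap_extend)
      d <- Hprev[j] + if (qv[i] == sv[j]) match else mismatch
      h <- max(0, d, Ecur, Fcol[j + 1])
      Hcur[j + 1] <- h
      if (h > best) best <- h
    }
    Hprev <- Hcur
  }
  best
}

# hand-rolled bisection for the Gumbel decay rate
lambda_bisect_oracle <- function(match = 5, mismatch = -4, pm = 0.25,
                                 tol = 1e-10) {
  f <- function(l) pm * exp(l * match) + (1 - pm) * exp(l * mismatch) - 1
  lo <- 1e-9; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
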