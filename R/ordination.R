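#' Bray-Curtis resemblance matrix
#'
#' BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i) on transformed abundance
#' vectors (square-root by default, the standard variance-stabilizing
#' choice for subsystem profiles).
#'
#' @param x numeric matrix (samples x features) or a named list of
#'   `abundance_profile` (their normalized abundances are used, features
#'   unioned and zero-filled)
#' @param transform transformation applied to each value before the
#'   dissimilarity (identity, sqrt, ...)
#' @return symmetric dissimilarity matrix with zero diagonal
#' @export
bray_curtis <- function(x, transform = sqrt) {
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    feats <- sort(unique(unlist(lapply(x, function(p) names(p$counts)))))
    m <- t(vapply(x, function(p) {
      v <- setNames(numeric(length(feats)), feats)
      v[names(p$normalized)] <- p$normalized
      v
    }, numeric(length(feats))))
    rownames(m) <- names(x)
    x <- m
  }
  x <- as.matrix(x)
  if (any(rowSums(x) == 0))
    stop("undefined dissimilarity: all-zero profile")
  tx <- transform(x)
  d <- vegan::vegdist(tx, method = "bray")
  as.matrix(d)
}

#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Rank-based NMDS of a dissimilarity matrix, minimizing Kruskal's
#' stress-1 with monotone regression on the dissimilarity ranks (primary
#' tie treatment), restarted from `n_restarts` random configurations with
#' the best (lowest-stress) solution returned. The returned coordinates
#' are centered at the origin.
#'
#' @param resemblance square symmetric dissimilarity matrix, zero diagonal
#' @param dims embedding dimensionality
#' @param n_restarts random restarts
#' @param max_iter iterations per restart
#' @param seed integer seed for the random starts
#' @return an `nmds_result`: `coordinates` (samples x dims), `stress`
#'   (Kruskal stress-1), `n_restarts`, `seed`
#' @export
nmds <- function(resemblance, dims = 2L, n_restarts = 20L, max_iter = 500L,
                 seed = 1L) {
  m <- as.matrix(resemblance)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-12) ||
      any(abs(diag(m)) > 1e-12))
    stop("parameter error: resemblance must be square, symmetric, zero-diagonal")
  d <- stats::as.dist(m)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      init <- matrix(rnorm(nrow(m) * dims), nrow(m), dims)
      fit <- suppressWarnings(
        vegan::monoMDS(d, y = init, k = dims, model = "global",
                       maxit = max_iter))
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    coords <- sweep(best$points, 2, colMeans(best$points))
    rownames(coords) <- rownames(m)
    colnames(coords) <- paste0("MDS", seq_len(dims))
    structure(list(coordinates = coords, stress = best$stress,
                   n_restarts = n_restarts, seed = seed),
              class = "nmds_result")
  })
}

#' Recompute Kruskal stress-1 for a configuration
#'
#' Independent stress evaluation: configuration distances are fitted by
#' monotone (isotonic) regression against the dissimilarity order and
#' stress-1 = sqrt(sum (d - dhat)^2 / sum d^2). Used as a self-consistency
#' oracle for [nmds()].
#'
#' @param resemblance dissimilarity matrix
#' @param coordinates configuration matrix (samples x dims)
#' @return Kruskal stress-1
#' @export
stress1 <- function(resemblance, coordinates) {
  delta <- as.vector(stats::as.dist(as.matrix(resemblance)))
  dconf <- as.vector(stats::dist(coordinates))
  o <- order(delta)
  fit <- stats::isoreg(dconf[o])
  sqrt(sum((fit$y - fit$yf)^2) / sum(fit$y^2))
}
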