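#' Marker PCA for population-structure correction
#'
#' Markers with a missing fraction of at least `missingFilter` are
#' dropped; remaining missing calls are imputed to the marker mean of the
#' 0/1 coding (A = 0, B = 1); zero-variance markers are removed; the coded
#' matrix is centred and scaled and decomposed with `prcomp`.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param missingFilter drop markers with missing fraction `>=` this value
#'   (default 0.20).
#' @return A [PcaResult-class].
#' @export
pcaMarkers <- function(genotypes, missingFilter = 0.20) {
  stopifnot(is(genotypes, "GenotypeMatrix"))
  calls <- genoCalls(genotypes)
  if (nrow(calls) < 2L) stop("need >= 2 lines")
  X <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  X[calls == "A"] <- 0; X[calls == "B"] <- 1
  keep <- colMeans(is.na(X)) < missingFilter
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 2L) stop("fewer than 2 markers survive the missing-data filter")
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  v <- apply(X, 2L, stats::var)
  X <- X[, v > 0, drop = FALSE]
  if (ncol(X) < 2L) stop("fewer than 2 polymorphic markers after filtering")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  new("PcaResult", scores = pc$x, varExplained = ve,
      nMarkersUsed = ncol(X))
}

#' K-means clustering on leading principal components
#'
#' Clusters lines on the first `nPCs` principal components with multiple
#' random restarts; labels are renumbered by descending cluster size so
#' cluster 1 is always the largest.
#'
#' @param pcs a [PcaResult-class] or a numeric score matrix.
#' @param k number of clusters (default 3).
#' @param nPCs number of leading components to cluster on (default 3).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return integer vector of cluster labels in 1..k, named by line.
#' @export
kmeansClusters <- function(pcs, k = 3L, nPCs = 3L, seed = NULL) {
  S <- if (is(pcs, "PcaResult")) pcScores(pcs) else as.matrix(pcs)
  nPCs <- min(nPCs, ncol(S))
  S <- S[, seq_len(nPCs), drop = FALSE]
  if (k > nrow(S)) stop("k exceeds the number of lines")
  .withSeed(seed, {
    km <- stats::kmeans(S, centers = k, nstart = 25L, iter.max = 100L)
    sizes <- tabulate(km$cluster, nbins = k)
    relab <- match(seq_len(k), order(sizes, decreasing = TRUE))
    stats::setNames(relab[km$cluster], rownames(S))
  })
}
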