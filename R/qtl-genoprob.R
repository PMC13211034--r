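#' Genotype probabilities by forward-backward HMM
#'
#' Posterior P(AA), P(BB) for every line and marker from a two-state
#' hidden Markov chain run along each chromosome: initial distribution
#' (1/2, 1/2), transition probability equal to the Haldane recombination
#' fraction of the adjacent-marker cM gap, and emission 1 - errorProb on a
#' matching observed call, errorProb on a mismatch, and 1 on a missing
#' call (so flanking markers carry the information across gaps).
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param map a [GeneticMap-class] covering exactly the genotype markers,
#'   in the same order.
#' @param errorProb genotyping error probability in `[0, 0.5)`.
#' @return A [GenoProb-class] (lines x markers x 2; states "AA", "BB").
#' @examples
#' map <- simulateMap(c(10L), c(100), seed = 1)
#' g <- simulateDHGenotypes(map, 5, missingRate = 0.1, seed = 2)
#' pr <- calcGenoprob(g, map)
#' @export
calcGenoprob <- function(genotypes, map, errorProb = 0.002) {
  stopifnot(is(genotypes, "GenotypeMatrix"), is(map, "GeneticMap"))
  if (errorProb < 0 || errorProb >= 0.5) stop("errorProb must be in [0, 0.5)")
  mk <- markerTable(map)
  calls <- genoCalls(genotypes)
  if (!identical(colnames(calls), mk$marker_id))
    stop("genotype markers do not match the map (same markers, same order, required)")
  nL <- nrow(calls); nM <- ncol(calls)
  post <- array(NA_real_, dim = c(nL, nM, 2L),
                dimnames = list(rownames(calls), mk$marker_id, c("AA", "BB")))
  e <- errorProb
  for (ch in unique(mk$chromosome)) {
    j <- which(mk$chromosome == ch)
    m <- length(j)
    rf <- if (m > 1L) haldane(diff(mk$pos_cM[j])) else numeric(0)
    # emission likelihood per state, nL x m
    oA <- calls[, j, drop = FALSE] == "A"
    emA <- matrix(1, nL, m); emB <- matrix(1, nL, m)
    hasA <- !is.na(oA) & oA
    hasB <- !is.na(oA) & !oA
    emA[hasA] <- 1 - e; emA[hasB] <- e
    emB[hasB] <- 1 - e; emB[hasA] <- e
    # scaled forward
    fA <- matrix(0, nL, m); fB <- matrix(0, nL, m)
    a <- 0.5 * emA[, 1L]; b <- 0.5 * emB[, 1L]
    s <- a + b; fA[, 1L] <- a / s; fB[, 1L] <- b / s
    for (k in seq_len(m - 1L)) {
      r <- rf[k]
      a <- (fA[, k] * (1 - r) + fB[, k] * r) * emA[, k + 1L]
      b <- (fB[, k] * (1 - r) + fA[, k] * r) * emB[, k + 1L]
      s <- a + b
      fA[, k + 1L] <- a / s; fB[, k + 1L] <- b / s
    }
    # scaled backward
    bA <- matrix(1, nL, m); bB <- matrix(1, nL, m)
    for (k in rev(seq_len(m - 1L))) {
      r <- rf[k]
      a <- (1 - r) * emA[, k + 1L] * bA[, k + 1L] + r * emB[, k + 1L] * bB[, k + 1L]
      b <- (1 - r) * emB[, k + 1L] * bB[, k + 1L] + r * emA[, k + 1L] * bA[, k + 1L]
      s <- a + b
      bA[, k] <- a / s; bB[, k] <- b / s
    }
    pa <- fA * bA; pb <- fB * bB
    s <- pa + pb
    post[, j, 1L] <- pa / s
    post[, j, 2L] <- pb / s
  }
  new("GenoProb", prob = post, map = map, errorProb = errorProb)
}
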