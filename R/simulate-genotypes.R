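#' Haldane map function
#'
#' Converts a map distance in centimorgans to a recombination fraction
#' assuming no crossover interference: rf = (1 - exp(-2 d / 100)) / 2.
#'
#' @param d_cM distance in centimorgans (vectorised).
#' @return recombination fraction in `[0, 0.5)`.
#' @export
haldane <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

#' Simulate a doubled-haploid genotype matrix
#'
#' Each DH line is a single recombinant gamete doubled, so every call is
#' homozygous: the first marker of each chromosome is "A" or "B" with
#' probability 1/2, and the state switches between adjacent markers with
#' the Haldane recombination fraction of their cM gap. Observed calls are
#' then masked to missing at `missingRate` and flipped at `errorRate`
#' (error applied after masking, so only retained calls can be wrong). The
#' pre-masking truth is kept in the object for validation harnesses.
#'
#' @param map a [GeneticMap-class].
#' @param nLines number of DH lines.
#' @param missingRate per-call missing probability in `[0, 1)`.
#' @param errorRate per-call flip probability in `[0, 1)`.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A [GenotypeMatrix-class].
#' @examples
#' map <- simulateMap(c(5L, 5L), c(100, 100), seed = 1)
#' g <- simulateDHGenotypes(map, 20, seed = 2)
#' table(genoCalls(g))   # only "A" and "B": DH lines are fully homozygous
#' @export
simulateDHGenotypes <- function(map, nLines, missingRate = 0,
                                errorRate = 0, seed = NULL) {
  stopifnot(is(map, "GeneticMap"))
  mk <- markerTable(map)
  if (nrow(mk) == 0L) stop("empty map")
  if (missingRate < 0 || missingRate >= 1) stop("missingRate must be in [0, 1)")
  if (errorRate < 0 || errorRate >= 1) stop("errorRate must be in [0, 1)")
  if (nLines < 1) stop("nLines must be >= 1")
  .withSeed(seed, {
    nM <- nrow(mk)
    truth <- matrix(0L, nLines, nM)   # 0 = A, 1 = B
    chrs <- unique(mk$chromosome)
    for (ch in chrs) {
      j <- which(mk$chromosome == ch)
      truth[, j[1L]] <- stats::rbinom(nLines, 1L, 0.5)
      if (length(j) > 1L) {
        rf <- haldane(diff(mk$pos_cM[j]))
        for (k in seq_along(rf)) {
          sw <- stats::rbinom(nLines, 1L, rf[k])
          truth[, j[k + 1L]] <- (truth[, j[k]] + sw) %% 2L
        }
      }
    }
    codes <- c("A", "B")
    truthC <- matrix(codes[truth + 1L], nLines, nM)
    obs <- truthC
    if (missingRate > 0)
      obs[stats::runif(length(obs)) < missingRate] <- NA_character_
    if (errorRate > 0) {
      flip <- !is.na(obs) & stats::runif(length(obs)) < errorRate
      obs[flip] <- ifelse(obs[flip] == "A", "B", "A")
    }
    ln <- sprintf("DH%03d", seq_len(nLines))
    dimnames(obs) <- list(ln, mk$marker_id)
    dimnames(truthC) <- list(ln, mk$marker_id)
    new("GenotypeMatrix", calls = obs, truth = truthC)
  })
}
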