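#' Simulate a genetic map
#'
#' Draws marker positions for a multi-chromosome linkage map. Within each
#' chromosome, cM positions are sorted uniform draws over `[0, length]`;
#' physical (bp) positions are affine in cM with a per-chromosome scale, so
#' they are monotone with map position. Defaults reproduce the study map:
#' seven barley chromosomes (1H-7H) with marker counts
#' 204/493/472/236/609/308/454 (2776 markers in total).
#'
#' @param markersPerChromosome integer vector, markers on each chromosome.
#' @param chrLengthCM numeric vector of chromosome lengths in centimorgans
#'   (same length as `markersPerChromosome`).
#' @param chromosomeNames labels; defaults to "1H".."7H"-style names.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A [GeneticMap-class].
#' @examples
#' map <- simulateMap(seed = 1)
#' nMarkers(map)  # 2776
#' @export
simulateMap <- function(markersPerChromosome = c(204L, 493L, 472L, 236L,
                                                 609L, 308L, 454L),
                        chrLengthCM = rep(180, length(markersPerChromosome)),
                        chromosomeNames = paste0(
                          seq_along(markersPerChromosome), "H"),
                        seed = NULL) {
  if (length(markersPerChromosome) != length(chrLengthCM))
    stop("markersPerChromosome and chrLengthCM must have the same length")
  if (length(chromosomeNames) != length(markersPerChromosome))
    stop("chromosomeNames must match markersPerChromosome in length")
  if (any(markersPerChromosome < 1)) stop("each chromosome needs >= 1 marker")
  if (any(chrLengthCM <= 0)) stop("chromosome lengths must be positive")
  .withSeed(seed, {
    pieces <- lapply(seq_along(markersPerChromosome), function(ci) {
      n <- markersPerChromosome[ci]
      cm <- sort(stats::runif(n, 0, chrLengthCM[ci]))
      # bp affine in cM: per-chromosome Mb/cM scale jittered around ~3.5
      scale_bp <- stats::runif(1, 2.5e6, 4.5e6)
      offset <- stats::runif(1, 1e5, 1e6)
      bp <- as.numeric(round(offset + cm * scale_bp))
      bp <- cummax(bp + seq_len(n))   # strictly increasing even at cM ties
      data.frame(chromosome = chromosomeNames[ci], pos_cM = cm, pos_bp = bp,
                 stringsAsFactors = FALSE)
    })
    m <- do.call(rbind, pieces)
    m <- data.frame(marker_id = sprintf("m%d", seq_len(nrow(m))), m,
                    stringsAsFactors = FALSE)
    new("GeneticMap", markers = m)
  })
}
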