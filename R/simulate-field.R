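#' Default partially replicated field configuration
#'
#' The study conditions: 183 genotypes over 229 plots with 36 duplicated
#' and 5 triplicated genotypes (41 replicated lines, a 22.4% replication
#' rate), 3-7 sampled heads per plot. The trial's grid dimensions are not
#' part of those conditions; a 12 x 20 grid (240 cells) is used.
#'
#' @return list of configuration fields accepted by [simulateField()].
#' @export
fieldConfig <- function() {
  list(nGenotypes = 183L, nDuplicates = 36L, nTriplicates = 5L,
       nRows = 12L, nRanges = 20L, headsRange = c(3L, 7L))
}

#' Simulate a partially replicated field design
#'
#' Assigns genotypes to plots on a row/range grid with the configured
#' replicate-class counts, randomising both which genotypes are replicated
#' and which grid cells are used.
#'
#' @param genotypes a [GenotypeMatrix-class] (or character vector of
#'   genotype ids) supplying the ids to plant; the first
#'   `config$nGenotypes` are used.
#' @param config list as returned by [fieldConfig()]; fields can be
#'   overridden individually.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A [FieldDesign-class].
#' @examples
#' map <- simulateMap(c(10L), c(100), seed = 1)
#' g <- simulateDHGenotypes(map, 183, seed = 1)
#' d <- simulateField(g, seed = 3)
#' nrow(plotData(d))   # 229
#' @export
simulateField <- function(genotypes, config = fieldConfig(), seed = NULL) {
  cfg <- utils::modifyList(fieldConfig(), as.list(config))
  ids <- if (is(genotypes, "GenotypeMatrix")) lineNames(genotypes)
         else as.character(genotypes)
  if (length(ids) < cfg$nGenotypes)
    stop("need at least ", cfg$nGenotypes, " genotypes, got ", length(ids))
  ids <- ids[seq_len(cfg$nGenotypes)]
  if (cfg$nDuplicates + cfg$nTriplicates > cfg$nGenotypes)
    stop("more replicated genotypes than genotypes")
  nPlots <- cfg$nGenotypes + cfg$nDuplicates + 2L * cfg$nTriplicates
  if (nPlots > cfg$nRows * cfg$nRanges)
    stop("field grid too small: ", nPlots, " plots requested, ",
         cfg$nRows * cfg$nRanges, " cells available")
  .withSeed(seed, {
    repIds <- sample(ids, cfg$nDuplicates + cfg$nTriplicates)
    dupIds <- repIds[seq_len(cfg$nDuplicates)]
    tripIds <- setdiff(repIds, dupIds)
    plotGeno <- c(ids, dupIds, rep(tripIds, each = 2L))
    plotGeno <- sample(plotGeno)              # randomise field order
    cells <- sample(cfg$nRows * cfg$nRanges, nPlots)
    plots <- data.frame(
      plot_id = sprintf("P%03d", seq_len(nPlots)),
      genotype_id = plotGeno,
      row = ((cells - 1L) %% cfg$nRows) + 1L,
      range = ((cells - 1L) %/% cfg$nRows) + 1L,
      stringsAsFactors = FALSE)
    new("FieldDesign", plots = plots, nRows = as.integer(cfg$nRows),
        nRanges = as.integer(cfg$nRanges),
        headsRange = as.integer(cfg$headsRange))
  })
}
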