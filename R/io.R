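# Plain-text readers/writers for the pipeline's tabular objects, plus
# PNG + truth-JSON emission for spike images.

#' Write / read a genetic map as CSV
#'
#' Columns: marker, chr, cM, bp.
#'
#' @param map a [GeneticMap-class].
#' @param path output CSV path.
#' @export
writeGeneticMap <- function(map, path) {
  mk <- markerTable(map)
  utils::write.csv(data.frame(marker = mk$marker_id, chr = mk$chromosome,
                              cM = mk$pos_cM, bp = mk$pos_bp),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGeneticMap
#' @export
readGeneticMap <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  new("GeneticMap",
      markers = data.frame(marker_id = as.character(d$marker),
                           chromosome = as.character(d$chr),
                           pos_cM = d$cM, pos_bp = d$bp,
                           stringsAsFactors = FALSE))
}

#' Write / read a genotype matrix as CSV
#'
#' Lines as rows, markers as columns, values A/B/NA.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param path output CSV path.
#' @export
writeGenotypeMatrix <- function(genotypes, path) {
  utils::write.csv(as.data.frame(genoCalls(genotypes)), path,
                   row.names = TRUE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeGenotypeMatrix
#' @export
readGenotypeMatrix <- function(path) {
  d <- utils::read.csv(path, row.names = 1L, stringsAsFactors = FALSE,
                       check.names = FALSE)
  m <- as.matrix(d)
  mode(m) <- "character"
  new("GenotypeMatrix", calls = m,
      truth = matrix(character(0), 0L, 0L))
}

#' Write / read a plot table as long CSV
#'
#' Columns: plot_id, genotype_id, row, range, head_index, grain_count.
#'
#' @param plotTable a [PlotTable-class].
#' @param path output CSV path.
#' @export
writePlotTable <- function(plotTable, path) {
  utils::write.csv(headData(plotTable), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname writePlotTable
#' @export
readPlotTable <- function(path) {
  new("PlotTable", heads = utils::read.csv(path, stringsAsFactors = FALSE))
}

# Run-length encode a logical matrix (column-major) for compact JSON truth.
.rleMask <- function(mask) {
  r <- rle(as.vector(mask))
  list(dims = dim(mask), lengths = r$lengths, values = as.integer(r$values))
}

.unrleMask <- function(enc) {
  v <- inverse.rle(list(lengths = enc$lengths,
                        values = as.logical(enc$values)))
  matrix(v, enc$dims[1L], enc$dims[2L])
}

#' Write a spike image as PNG plus truth JSON
#'
#' The PNG holds the 8-bit RGB raster; the JSON records the grain count,
#' run-length-encoded per-grain masks and the rachis parameters.
#'
#' @param image a [SpikeImage-class].
#' @param pngPath output PNG path.
#' @param truthPath output JSON path (`NULL` to skip truth emission).
#' @export
writeSpikeImage <- function(image, pngPath, truthPath = NULL) {
  stopifnot(is(image, "SpikeImage"))
  png::writePNG(spikePixels(image) / 255, pngPath)
  if (!is.null(truthPath)) {
    tr <- imageTruth(image)
    jsonlite::write_json(
      list(count = tr$count, masks = lapply(tr$masks, .rleMask),
           rachis = tr$rachis),
      truthPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(pngPath)
}

#' Read a spike image PNG (and optional truth JSON) back
#'
#' @param pngPath PNG path written by [writeSpikeImage()].
#' @param truthPath truth JSON path, or `NULL`.
#' @return list with `pixels` (8-bit RGB array) and, when truth is given,
#'   `count` and `masks`.
#' @export
readSpikeImage <- function(pngPath, truthPath = NULL) {
  px <- png::readPNG(pngPath)
  out <- list(pixels = array(as.integer(round(px * 255)), dim = dim(px)))
  if (!is.null(truthPath)) {
    tr <- jsonlite::read_json(truthPath, simplifyVector = TRUE)
    out$count <- tr$count
    out$masks <- lapply(seq_len(nrow_or_len(tr$masks)), function(i)
      .unrleMask(extract_mask(tr$masks, i)))
  }
  out
}

# jsonlite may simplify the mask list to a data.frame; normalise access.
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
extract_mask <- function(x, i) {
  if (is.data.frame(x)) list(dims = x$dims[[i]], lengths = x$lengths[[i]],
                             values = x$values[[i]])
  else x[[i]]
}
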