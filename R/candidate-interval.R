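#' Genes overlapping a physical QTL interval
#'
#' Reads a GFF3 annotation and returns every feature of type "gene" with
#' at least one base overlapping `[start_bp, end_bp]` (1-based inclusive,
#' any-overlap semantics — a gene containing an interval endpoint counts)
#' on the given chromosome, sorted by start. mRNA/CDS children are
#' ignored.
#'
#' @param gff3Path path to a GFF3 file.
#' @param chromosome sequence name as it appears in the GFF3.
#' @param start_bp,end_bp interval bounds, 1-based inclusive,
#'   `start_bp <= end_bp`.
#' @return data.frame with `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, sorted by `start`.
#' @export
genesInInterval <- function(gff3Path, chromosome, start_bp, end_bp) {
  if (start_bp > end_bp) stop("start_bp must be <= end_bp")
  if (!file.exists(gff3Path)) stop("GFF3 file not found: ", gff3Path)
  .checkGff3(gff3Path)
  gff <- rtracklayer::readGFF(gff3Path,
                              filter = list(type = "gene"))
  gr <- GenomicRanges::makeGRangesFromDataFrame(as.data.frame(gff),
                                                keep.extra.columns = TRUE)
  if (!chromosome %in% as.character(GenomicRanges::seqnames(gr))) {
    warning("chromosome ", chromosome, " not present in the annotation")
    return(data.frame(gene_id = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  q <- GenomicRanges::GRanges(chromosome,
                              IRanges::IRanges(start_bp, end_bp))
  hits <- IRanges::subsetByOverlaps(gr, q)
  ids <- if ("ID" %in% names(S4Vectors::mcols(hits)))
    as.character(S4Vectors::mcols(hits)$ID)
  else as.character(seq_along(hits))
  out <- data.frame(gene_id = sub("^gene:", "", ids),
                    chromosome = as.character(GenomicRanges::seqnames(hits)),
                    start = GenomicRanges::start(hits),
                    end = GenomicRanges::end(hits),
                    strand = as.character(GenomicRanges::strand(hits)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

# Light structural validation so a malformed line is reported with its
# line number rather than an opaque parser failure.
.checkGff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L)
      stop("malformed GFF3 line ", i, ": expected >= 8 tab-separated fields")
    s <- suppressWarnings(as.numeric(f[4L])); e <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(s) || is.na(e))
      stop("malformed GFF3 line ", i, ": non-numeric coordinates")
  }
  invisible(TRUE)
}

#' Physical coordinate of a marker
#'
#' Looks a marker up in the genetic map and returns its chromosome and bp
#' position, for building physical QTL intervals from flanking markers.
#'
#' @param map a [GeneticMap-class].
#' @param marker_id marker to look up.
#' @return list with `chromosome` and `bp`.
#' @export
markerToBp <- function(map, marker_id) {
  mk <- markerTable(map)
  i <- match(marker_id, mk$marker_id)
  if (is.na(i)) stop("unknown marker: ", marker_id)
  list(chromosome = mk$chromosome[i], bp = mk$pos_bp[i])
}

#' Physical interval between two flanking markers
#'
#' @param map a [GeneticMap-class].
#' @param left_marker,right_marker flanking marker ids (order-agnostic;
#'   the returned bounds are swapped into increasing order). Must be on
#'   the same chromosome.
#' @return list with `chromosome`, `start_bp`, `end_bp`.
#' @export
flankingInterval <- function(map, left_marker, right_marker) {
  a <- markerToBp(map, left_marker)
  b <- markerToBp(map, right_marker)
  if (a$chromosome != b$chromosome)
    stop("flanking markers lie on different chromosomes")
  list(chromosome = a$chromosome,
       start_bp = min(a$bp, b$bp), end_bp = max(a$bp, b$bp))
}
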