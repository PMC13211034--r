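# Accessor and show methods.

#' @describeIn GeneticMap marker table (marker_id, chromosome, pos_cM, pos_bp)
#' @param x object
#' @export
setMethod("markerTable", "GeneticMap", function(x) x@markers)

#' @describeIn GeneticMap number of markers
#' @export
setMethod("nMarkers", "GeneticMap", function(x) nrow(x@markers))

#' @describeIn GeneticMap chromosome labels in map order
#' @export
setMethod("chromosomes", "GeneticMap", function(x) unique(x@markers$chromosome))

setMethod("show", "GeneticMap", function(object) {
  m <- object@markers
  cat("GeneticMap:", nrow(m), "markers on",
      length(unique(m$chromosome)), "chromosomes\n")
  tab <- table(factor(m$chromosome, levels = unique(m$chromosome)))
  print(tab)
})

#' @describeIn GenotypeMatrix observed calls (lines x markers, "A"/"B"/NA)
#' @param x object
#' @export
setMethod("genoCalls", "GenotypeMatrix", function(x) x@calls)

#' @describeIn GenotypeMatrix simulated true calls before masking/error
#'   (0x0 matrix for non-simulated data)
#' @export
setMethod("trueCalls", "GenotypeMatrix", function(x) x@truth)

#' @describeIn GenotypeMatrix line identifiers
#' @export
setMethod("lineNames", "GenotypeMatrix", function(x) rownames(x@calls))

#' @describeIn GenotypeMatrix number of markers
#' @export
setMethod("nMarkers", "GenotypeMatrix", function(x) ncol(x@calls))

setMethod("show", "GenotypeMatrix", function(object) {
  v <- object@calls
  cat("GenotypeMatrix:", nrow(v), "DH lines x", ncol(v), "markers\n")
  cat(sprintf("  A frequency %.3f, missing %.3f\n",
              mean(v == "A", na.rm = TRUE), mean(is.na(v))))
})

#' @describeIn FieldDesign plot assignments (plot_id, genotype_id, row, range)
#' @param x object
#' @export
setMethod("plotData", "FieldDesign", function(x) x@plots)

setMethod("show", "FieldDesign", function(object) {
  p <- object@plots
  reps <- table(table(p$genotype_id))
  cat("FieldDesign:", nrow(p), "plots,", length(unique(p$genotype_id)),
      "genotypes on a", object@nRows, "x", object@nRanges, "grid\n")
  cat("  replicate classes:",
      paste(sprintf("%s plots x %s", names(reps), as.integer(reps)),
            collapse = ", "), "\n")
})

#' @describeIn PlotTable per-head records in long format
#' @param x object
#' @export
setMethod("headData", "PlotTable", function(x) x@heads)

setMethod("show", "PlotTable", function(object) {
  h <- object@heads
  cat("PlotTable:", length(unique(h$plot_id)), "plots,", nrow(h),
      "sampled heads\n")
  cat(sprintf("  grain count mean %.2f, SD %.2f\n",
              mean(h$grain_count), stats::sd(h$grain_count)))
})

#' @describeIn SpikeImage 8-bit RGB pixel array (h x w x 3)
#' @param x object
#' @export
setMethod("spikePixels", "SpikeImage", function(x) x@pixels)

#' @describeIn SpikeImage ground truth: count, per-grain masks, rachis curve
#' @export
setMethod("imageTruth", "SpikeImage", function(x) x@truth)

setMethod("show", "SpikeImage", function(object) {
  d <- dim(object@pixels)
  cat("SpikeImage:", d[1], "x", d[2], "px,", object@truth$count,
      "grains,", object@background, "background\n")
})

#' @describeIn GenoProb probability array (lines x markers x 2; "AA","BB")
#' @param x object
#' @export
setMethod("probArray", "GenoProb", function(x) x@prob)

#' @describeIn GenoProb the map the probabilities are laid out on
#' @export
setMethod("markerTable", "GenoProb", function(x) x@map@markers)

setMethod("show", "GenoProb", function(object) {
  d <- dim(object@prob)
  cat("GenoProb:", d[1], "lines x", d[2], "markers (error prob",
      object@errorProb, ")\n")
})

#' @describeIn KinshipMatrix similarity matrix
#' @param x object
#' @export
setMethod("kinshipValues", "KinshipMatrix", function(x) x@K)

setMethod("show", "KinshipMatrix", function(object) {
  off <- object@K[upper.tri(object@K)]
  cat("KinshipMatrix (", object@scope,
      if (object@scope == "loco") paste0(", leaving out ", object@chromosome),
      "): ", nrow(object@K), " lines, mean pairwise ",
      sprintf("%.3f", mean(off)), "\n", sep = "")
})

#' @describeIn ScanResult per-marker LOD table
#' @param x object
#' @export
setMethod("lodTable", "ScanResult", function(x) x@table)

#' @describeIn ScanResult row of the table at the maximal LOD
#' @export
setMethod("scanPeak", "ScanResult", function(x) {
  x@table[which.max(x@table$lod), , drop = FALSE]
})

#' @describeIn ScanResult permutation LOD threshold (NA if not attached)
#' @export
setMethod("scanThreshold", "ScanResult", function(x) x@threshold)

setMethod("show", "ScanResult", function(object) {
  pk <- scanPeak(object)
  cat("ScanResult (", object@mode, "): ", nrow(object@table), " markers, peak LOD ",
      sprintf("%.3f", pk$lod), " at ", pk$marker_id, " (", pk$chromosome, " ",
      sprintf("%.2f", pk$pos_cM), " cM)\n", sep = "")
  if (!is.na(object@threshold))
    cat(sprintf("  threshold %.3f at alpha %.3g\n", object@threshold,
                object@alpha))
})

#' @describeIn PcaResult line scores on the retained components
#' @param x object
#' @export
setMethod("pcScores", "PcaResult", function(x) x@scores)

#' @describeIn PcaResult per-component fraction of total variance
#' @export
setMethod("varExplained", "PcaResult", function(x) x@varExplained)

setMethod("show", "PcaResult", function(object) {
  cat("PcaResult:", nrow(object@scores), "lines,", object@nMarkersUsed,
      "markers used\n")
  cat("  var explained (first 5):",
      paste(sprintf("%.3f", utils::head(object@varExplained, 5)),
            collapse = " "), "\n")
})

#' @describeIn VarianceComponents broad-sense heritability H2 (proportion)
#' @param x object
#' @export
setMethod("heritability", "VarianceComponents", function(x) x@H2)

#' @describeIn VarianceComponents percentage shares of the total variance
#' @export
setMethod("componentShares", "VarianceComponents", function(x) x@shares)

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents (REML, y = mu + g + r + c + e):\n")
  comps <- c(Genotype = object@sigma2_G, Row = object@sigma2_R,
             Range = object@sigma2_C, Residual = object@sigma2_E)
  for (i in seq_along(comps))
    cat(sprintf("  %-9s %12.6f  (%.1f%%)\n", names(comps)[i], comps[i],
                object@shares[i]))
  cat(sprintf("  H2 = %.4f%% (plot level)\n", 100 * object@H2))
})

setMethod("show", "AgreementMetrics", function(object) {
  cat("AgreementMetrics over", object@n, "count pairs (errors = model - manual):\n")
  cat(sprintf("  r %.4f (R2 %.4f), slope %.4f, intercept %.4f\n",
              object@r, object@r2, object@slope, object@intercept))
  cat(sprintf("  mean bias %.3f, MAE %.3f, SD %.3f, range [%g, %g]\n",
              object@mean_bias, object@mae, object@sd_error,
              object@min_error, object@max_error))
  cat(sprintf("  within 1/2/3 grains: %.1f%% / %.1f%% / %.1f%%\n",
              100 * object@within_k[1], 100 * object@within_k[2],
              100 * object@within_k[3]))
})

setMethod("show", "QtlEffect", function(object) {
  cat("QtlEffect at", object@marker_id, "\n")
  cat(sprintf("  A: n=%d mean %.2f | B: n=%d mean %.2f\n", object@n_A,
              object@mean_A, object@n_B, object@mean_B))
  cat(sprintf("  effect %.2f grains, t = %.3f, p = %.3g, PVE %.1f%%\n",
              object@effect, object@t_stat, object@p_value, object@pve))
})

setMethod("show", "PreprocessResult", function(object) {
  cat("PreprocessResult:", paste(dim(object@cropped)[1:2], collapse = " x "),
      "px, final mask covers",
      sprintf("%.1f%%", 100 * mean(object@finalMask)), "of the frame")
  if (object@degenerate) cat(" [degenerate Otsu input]")
  cat("\n")
})

#' @describeIn PreprocessResult final binary spike mask
#' @param x object
#' @export
setMethod("finalMask", "PreprocessResult", function(x) x@finalMask)

#' @describeIn PreprocessResult black-background composite image
#' @export
setMethod("composite", "PreprocessResult", function(x) x@composite)
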