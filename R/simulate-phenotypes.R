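#' Specify a planted QTL
#'
#' Exactly one of `effect` and `targetPVE` must be given; the other is
#' derived at simulation time. The additive effect is coded so that
#' `effect = mean(A lines) - mean(B lines)` in grains per spike.
#'
#' @param marker_id marker carrying the QTL.
#' @param effect additive effect in grains per spike.
#' @param targetPVE intended phenotypic variance explained, in `[0, 1]`.
#' @return A [QtlSpec-class].
#' @export
qtlSpec <- function(marker_id, effect = NA_real_, targetPVE = NA_real_) {
  if (is.na(effect) == is.na(targetPVE))
    stop("give exactly one of effect and targetPVE")
  if (!is.na(targetPVE) && (targetPVE < 0 || targetPVE >= 1))
    stop("targetPVE must be in [0, 1)")
  new("QtlSpec", marker_id = as.character(marker_id),
      effect = as.numeric(effect), target_pve = as.numeric(targetPVE))
}

#' Table-style default variance components
#'
#' The study's plot-level REML partition for mean grain number per spike:
#' genotype 0.009938871, row 0.786657886, range 0.523202051, residual
#' 7.286333883.
#'
#' @return named numeric vector (G, R, C, E).
#' @export
studyVariances <- function() {
  c(G = 0.009938871, R = 0.786657886, C = 0.523202051, E = 7.286333883)
}

#' Simulate plot phenotypes with an optional planted QTL
#'
#' Generates per-head grain counts under the row-column model
#' `y = mu + g + r + c + a*x + e`, where g, r, c and e are independent
#' zero-mean Gaussians with the given variances and `x` is +1/2 for the A
#' allele and -1/2 for the B allele at the QTL marker (so the A-vs-B mean
#' difference equals the additive effect `a`). Each plot receives a
#' uniform number of heads within the design's range; head counts are the
#' plot value plus Gaussian head-to-head noise, rounded to integers >= 1
#' (the latent pre-rounding plot value is kept in column `plot_value` for
#' parameter-recovery harnesses).
#'
#' The QTL allele of a line is taken from the simulated truth when the
#' genotype matrix carries it (so masking/typing error downstream cannot
#' distort the planted signal); observed calls are used otherwise, with
#' missing calls contributing x = 0.
#'
#' @param design a [FieldDesign-class].
#' @param genotypes a [GenotypeMatrix-class] covering the design's
#'   genotypes.
#' @param qtl a [QtlSpec-class] or `NULL` for no QTL.
#' @param mu population mean grain number per spike.
#' @param variances named numeric (G, R, C, E); see [studyVariances()].
#' @param headNoiseSD SD of head-to-head noise within a plot (grains).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A [PlotTable-class].
#' @examples
#' map <- simulateMap(c(10L), c(100), seed = 1)
#' g <- simulateDHGenotypes(map, 183, seed = 2)
#' d <- simulateField(g, seed = 3)
#' pt <- simulatePhenotypes(d, g, seed = 4)
#' @export
simulatePhenotypes <- function(design, genotypes, qtl = NULL, mu = 25.36,
                               variances = studyVariances(),
                               headNoiseSD = 2.0, seed = NULL) {
  stopifnot(is(design, "FieldDesign"), is(genotypes, "GenotypeMatrix"))
  if (any(variances < 0)) stop("variances must be non-negative")
  if (mu <= 0) stop("mu must be positive")
  if (headNoiseSD < 0) stop("headNoiseSD must be non-negative")
  plots <- plotData(design)
  calls <- genoCalls(genotypes)
  tc <- trueCalls(genotypes)
  src <- if (length(tc)) tc else calls
  if (!all(plots$genotype_id %in% rownames(calls)))
    stop("design contains genotypes absent from the genotype matrix")
  a <- 0
  x <- rep(0, nrow(plots))
  if (!is.null(qtl)) {
    stopifnot(is(qtl, "QtlSpec"))
    if (!qtl@marker_id %in% colnames(calls))
      stop("QTL marker ", qtl@marker_id, " absent from the genotype matrix")
    if (!is.na(qtl@effect)) {
      a <- qtl@effect
    } else {
      # derive a from target PVE: var(a*x) = a^2/4 must be the requested
      # fraction of the total plot variance a^2/4 + sum(variances)
      a <- sqrt(4 * qtl@target_pve / (1 - qtl@target_pve) * sum(variances))
    }
    al <- src[plots$genotype_id, qtl@marker_id]
    x <- ifelse(is.na(al), 0, ifelse(al == "A", 0.5, -0.5))
  }
  .withSeed(seed, {
    gids <- unique(plots$genotype_id)
    gEff <- stats::setNames(stats::rnorm(length(gids), 0, sqrt(variances["G"])), gids)
    rEff <- stats::rnorm(design@nRows, 0, sqrt(variances["R"]))
    cEff <- stats::rnorm(design@nRanges, 0, sqrt(variances["C"]))
    eps <- stats::rnorm(nrow(plots), 0, sqrt(variances["E"]))
    y <- unname(mu + gEff[plots$genotype_id] + rEff[plots$row] +
                  cEff[plots$range] + a * x + eps)
    hseq <- seq.int(design@headsRange[1L], design@headsRange[2L])
    nh <- if (length(hseq) == 1L) rep(hseq, nrow(plots))
          else sample(hseq, nrow(plots), replace = TRUE)
    heads <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
      counts <- round(y[i] + stats::rnorm(nh[i], 0, headNoiseSD))
      data.frame(plot_id = plots$plot_id[i],
                 genotype_id = plots$genotype_id[i],
                 row = plots$row[i], range = plots$range[i],
                 head_index = seq_len(nh[i]),
                 grain_count = pmax(counts, 1),
                 plot_value = y[i],     # latent plot value, pre-rounding
                 stringsAsFactors = FALSE)
    }))
    rownames(heads) <- NULL
    new("PlotTable", heads = heads)
  })
}
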