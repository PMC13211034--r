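#' GeneticMap: ordered markers on a linkage map
#'
#' Holds marker identifiers with chromosome assignment, genetic (cM) and
#' physical (bp) coordinates. Markers are stored in map order: grouped by
#' chromosome with non-decreasing cM position within each chromosome.
#'
#' @slot markers data.frame with columns `marker_id`, `chromosome`,
#'   `pos_cM`, `pos_bp`.
#' @export
setClass("GeneticMap", slots = c(markers = "data.frame"))

setValidity("GeneticMap", function(object) {
  m <- object@markers
  need <- c("marker_id", "chromosome", "pos_cM", "pos_bp")
  if (!all(need %in% names(m)))
    return(paste("markers must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(m$marker_id)) return("marker_id values must be unique")
  if (any(m$pos_cM < 0)) return("pos_cM must be non-negative")
  if (any(m$pos_bp < 1)) return("pos_bp must be positive")
  ok <- vapply(split(m$pos_cM, m$chromosome), function(p) !is.unsorted(p),
               logical(1))
  if (!all(ok)) return("pos_cM must be non-decreasing within chromosome")
  TRUE
})

#' GenotypeMatrix: doubled-haploid marker calls
#'
#' Lines x markers matrix of calls coded "A" (one parent), "B" (the other)
#' or NA (missing). DH lines are fully homozygous, so no heterozygous code
#' exists. When produced by [simulateDHGenotypes()] the error-free,
#' unmasked calls are retained in `truth` for validation harnesses.
#'
#' @slot calls character matrix, rownames = line ids, colnames = marker ids.
#' @slot truth character matrix of the simulated true calls (0x0 when the
#'   object was not simulated).
#' @export
setClass("GenotypeMatrix",
         slots = c(calls = "matrix", truth = "matrix"))

setValidity("GenotypeMatrix", function(object) {
  v <- object@calls
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("calls must have line rownames and marker colnames")
  bad <- !(v %in% c("A", "B")) & !is.na(v)
  if (any(bad)) return("calls must be 'A', 'B' or NA (DH lines carry no heterozygous code)")
  TRUE
})

#' QtlSpec: a planted QTL for simulation
#'
#' @slot marker_id marker carrying the QTL.
#' @slot effect additive effect in grains per spike, defined as
#'   mean(A) - mean(B) across lines.
#' @slot target_pve intended phenotypic variance explained, in `[0,1]`
#'   (NA when the effect is given directly).
#' @export
setClass("QtlSpec",
         slots = c(marker_id = "character", effect = "numeric",
                   target_pve = "numeric"))

#' FieldDesign: a partially replicated row/range layout
#'
#' @slot plots data.frame with columns `plot_id`, `genotype_id`, `row`,
#'   `range`.
#' @slot nRows,nRanges grid dimensions.
#' @slot headsRange integer length-2, inclusive range of sampled heads per
#'   plot.
#' @export
setClass("FieldDesign",
         slots = c(plots = "data.frame", nRows = "integer",
                   nRanges = "integer", headsRange = "integer"))

setValidity("FieldDesign", function(object) {
  p <- object@plots
  need <- c("plot_id", "genotype_id", "row", "range")
  if (!all(need %in% names(p)))
    return(paste("plots must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(p[c("row", "range")])) return("each field cell may hold at most one plot")
  if (any(p$row < 1 | p$row > object@nRows) ||
      any(p$range < 1 | p$range > object@nRanges))
    return("plot coordinates outside the field grid")
  TRUE
})

#' PlotTable: per-head grain counts in long format
#'
#' One row per sampled head: the raw phenotype records that feed plot
#' aggregation, QC and the mixed model y = mu + g + r + c + e.
#'
#' @slot heads data.frame with columns `plot_id`, `genotype_id`, `row`,
#'   `range`, `head_index`, `grain_count`.
#' @export
setClass("PlotTable", slots = c(heads = "data.frame"))

setValidity("PlotTable", function(object) {
  h <- object@heads
  need <- c("plot_id", "genotype_id", "row", "range", "head_index",
            "grain_count")
  if (!all(need %in% names(h)))
    return(paste("heads must have columns", paste(need, collapse = ", ")))
  if (any(h$grain_count < 1)) return("grain counts must be >= 1")
  TRUE
})

#' SpikeImage: a rendered two-row spike with exact ground truth
#'
#' @slot pixels integer array h x w x 3, 8-bit channels, origin top-left.
#' @slot truth list with elements `count`, `masks` (list of logical
#'   matrices, one per grain), and `rachis` (curve parameters).
#' @slot background "dark" or "cluttered".
#' @export
setClass("SpikeImage",
         slots = c(pixels = "array", truth = "list", background = "character"))

setValidity("SpikeImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3L] != 3L) return("pixels must be h x w x 3")
  tr <- object@truth
  if (!all(c("count", "masks") %in% names(tr))) return("truth needs count and masks")
  if (tr$count != length(tr$masks)) return("truth count must equal the number of per-grain masks")
  okdim <- vapply(tr$masks, function(m) all(dim(m) == d[1:2]), logical(1))
  if (length(okdim) && !all(okdim)) return("grain masks must match image shape")
  TRUE
})

#' PreprocessResult: all stages of the spike isolation chain
#'
#' @slot cropped cropped RGB array.
#' @slot colourMask,valueMask,otsuMask,hullMask,finalMask logical matrices,
#'   same shape as `cropped`.
#' @slot composite RGB array, original pixels inside `finalMask`, black
#'   elsewhere.
#' @slot edgeOverlay RGB array with edge pixels highlighted (annotation aid
#'   only).
#' @slot otsuThreshold integer threshold chosen by Otsu's method.
#' @slot degenerate logical, TRUE when the grey image was constant.
#' @export
setClass("PreprocessResult",
         slots = c(cropped = "array", colourMask = "matrix",
                   valueMask = "matrix", otsuMask = "matrix",
                   hullMask = "matrix", finalMask = "matrix",
                   composite = "array", edgeOverlay = "array",
                   otsuThreshold = "integer", degenerate = "logical"))

#' AgreementMetrics: model-vs-manual count agreement
#'
#' Errors are model - manual throughout.
#'
#' @slot r,r2 Pearson correlation and its square.
#' @slot slope,intercept OLS fit of model counts on manual counts.
#' @slot mean_bias,mae,sd_error mean error, mean absolute error, sample SD
#'   of errors (grains).
#' @slot min_error,max_error error range (grains).
#' @slot within_k named numeric, fraction of pairs with |error| <= k for
#'   k = 1, 2, 3.
#' @slot n number of pairs.
#' @export
setClass("AgreementMetrics",
         slots = c(r = "numeric", r2 = "numeric", slope = "numeric",
                   intercept = "numeric", mean_bias = "numeric",
                   mae = "numeric", sd_error = "numeric",
                   min_error = "numeric", max_error = "numeric",
                   within_k = "numeric", n = "integer"))

#' VarianceComponents: row-column REML partition and heritability
#'
#' @slot sigma2_G,sigma2_R,sigma2_C,sigma2_E variance components for
#'   genotype, row, range and residual.
#' @slot mu_hat fitted intercept (grand mean grain number per spike).
#' @slot shares named numeric, percentage share of each component in the
#'   total phenotypic variance.
#' @slot H2 plot-level broad-sense heritability,
#'   sigma2_G / (sigma2_G + sigma2_R + sigma2_C + sigma2_E).
#' @export
setClass("VarianceComponents",
         slots = c(sigma2_G = "numeric", sigma2_R = "numeric",
                   sigma2_C = "numeric", sigma2_E = "numeric",
                   mu_hat = "numeric", shares = "numeric", H2 = "numeric"))

#' GenoProb: two-state genotype probabilities
#'
#' Posterior P(AA), P(BB) per line and marker from the forward-backward
#' algorithm over each chromosome, with genotyping-error emission.
#'
#' @slot prob numeric array lines x markers x 2 (states "AA", "BB").
#' @slot map the [GeneticMap-class] the probabilities refer to.
#' @slot errorProb genotyping error probability used in the emission model.
#' @export
setClass("GenoProb",
         slots = c(prob = "array", map = "GeneticMap", errorProb = "numeric"))

setValidity("GenoProb", function(object) {
  d <- dim(object@prob)
  if (length(d) != 3L || d[3L] != 2L) return("prob must be lines x markers x 2")
  s <- object@prob[, , 1L] + object@prob[, , 2L]
  if (max(abs(s - 1)) > 1e-10) return("state probabilities must sum to 1")
  if (min(object@prob) < -1e-12 || max(object@prob) > 1 + 1e-12)
    return("probabilities must lie in [0,1]")
  TRUE
})

#' KinshipMatrix: GRM allele-sharing similarity
#'
#' K[i,j] is the mean over markers of the probability that lines i and j
#' carry the same genotype; entries lie in `[0,1]` with unit diagonal.
#'
#' @slot K symmetric lines x lines matrix.
#' @slot scope "all" or "loco".
#' @slot chromosome chromosome left out ("" when scope = "all").
#' @export
setClass("KinshipMatrix",
         slots = c(K = "matrix", scope = "character",
                   chromosome = "character"))

setValidity("KinshipMatrix", function(object) {
  K <- object@K
  if (nrow(K) != ncol(K)) return("K must be square")
  if (max(abs(K - t(K))) > 1e-8) return("K must be symmetric")
  if (max(abs(diag(K) - 1)) > 1e-8) return("diagonal must equal 1")
  if (min(K) < -1e-8 || max(K) > 1 + 1e-8) return("entries must lie in [0,1]")
  if (!object@scope %in% c("all", "loco")) return("scope must be 'all' or 'loco'")
  TRUE
})

#' ScanResult: per-marker LOD profile
#'
#' @slot table data.frame with columns `marker_id`, `chromosome`, `pos_cM`,
#'   `lod`.
#' @slot mode "hk", "lmm_loco" or "hk_pc".
#' @slot nCovariates number of fixed-effect covariate columns used.
#' @slot threshold genome-wide LOD threshold (NA until permutation testing
#'   is attached).
#' @slot alpha significance level the threshold refers to.
#' @export
setClass("ScanResult",
         slots = c(table = "data.frame", mode = "character",
                   nCovariates = "integer", threshold = "numeric",
                   alpha = "numeric"))

setValidity("ScanResult", function(object) {
  need <- c("marker_id", "chromosome", "pos_cM", "lod")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  if (any(object@table$lod < -1e-8, na.rm = TRUE))
    return("LOD scores must be non-negative")
  TRUE
})

#' PcaResult: marker PCA for structure correction
#'
#' @slot scores lines x PCs score matrix.
#' @slot varExplained fraction of total variance per component
#'   (non-increasing).
#' @slot nMarkersUsed markers retained after the missing-data filter.
#' @export
setClass("PcaResult",
         slots = c(scores = "matrix", varExplained = "numeric",
                   nMarkersUsed = "integer"))

#' QtlEffect: allele-effect statistics at a marker
#'
#' @slot marker_id marker tested.
#' @slot n_A,n_B lines per allele class.
#' @slot mean_A,mean_B class means (grains per spike).
#' @slot effect mean_A - mean_B (grains).
#' @slot t_stat,p_value pooled-variance two-sample t-test.
#' @slot pve phenotypic variance explained, percent (100 * R^2).
#' @export
setClass("QtlEffect",
         slots = c(marker_id = "character", n_A = "integer", n_B = "integer",
                   mean_A = "numeric", mean_B = "numeric", effect = "numeric",
                   t_stat = "numeric", p_value = "numeric", pve = "numeric"))
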