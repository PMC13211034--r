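# Single-QTL genome scans: Haley-Knott regression on genotype
# probabilities, with optional fixed covariates (e.g. principal
# components), and a LOCO-kinship linear mixed model scan.

# Align phenotype/covariates/probabilities on lines with complete
# phenotype data. Missing genotype data never drops a line: it is already
# absorbed into the HMM posterior.
.alignScanData <- function(genoprob, phenotype, covariates = NULL) {
  pr <- probArray(genoprob)
  if (is.null(names(phenotype)))
    stop("phenotype must be named by line id")
  ids <- intersect(rownames(pr), names(phenotype))
  ids <- ids[!is.na(phenotype[ids])]
  if (length(ids) < 3L) stop("fewer than 3 lines with phenotype data")
  X0 <- matrix(1, length(ids), 1L)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(rownames(covariates)))
      stop("covariates must have line rownames")
    if (!all(ids %in% rownames(covariates)))
      stop("covariates missing for some phenotyped lines")
    X0 <- cbind(X0, covariates[ids, , drop = FALSE])
  }
  if (qr(X0)$rank < ncol(X0)) stop("covariates are rank deficient")
  PA <- pr[ids, , 1L, drop = FALSE]
  PA <- matrix(PA, nrow = length(ids),
               dimnames = dimnames(PA)[1:2])        # drop the state axis
  list(ids = ids, y = unname(phenotype[ids]), PA = PA, X0 = X0)
}

# Residualize columns of A on the column space of qrX.
.resid0 <- function(qrX, A) qr.resid(qrX, A)

# Per-marker HK LOD for one (possibly whitened) design: LOD =
# (n/2) log10(RSS_null / RSS_full), RSS_full from adding the residualized
# probability column to the null model. Degenerate markers (probability
# column collinear with the null design) get NA.
.hkLod <- function(Gres, yres, n, yss = sum(yres^2)) {
  gss <- colSums(Gres^2)
  rss0 <- sum(yres^2)
  if (rss0 <= 1e-14 * max(yss, 1)) {    # null model already fits perfectly
    lod <- rep(0, ncol(Gres))
    lod[gss < 1e-10 * n] <- NA_real_
    return(lod)
  }
  num <- as.vector(crossprod(Gres, yres))
  bad <- gss < 1e-10 * n
  rss1 <- rss0 - num^2 / pmax(gss, 1e-300)
  rss1 <- pmax(rss1, 1e-14 * rss0)
  lod <- (n / 2) * log10(rss0 / rss1)
  lod[bad] <- NA_real_
  pmax(lod, 0)
}

#' Haley-Knott regression scan
#'
#' At every marker, the phenotype is regressed on intercept + covariates +
#' P(AA); the null model omits the probability term. The LOD score is
#' (n/2) * log10(RSS_null / RSS_full) with n the number of lines with
#' complete phenotype data. Markers whose probability column is collinear
#' with the null design are skipped (NA) with a warning.
#'
#' @param genoprob a [GenoProb-class].
#' @param phenotype numeric vector named by line id (one value per
#'   genotype, e.g. from [adjustReplicates()]).
#' @param covariates optional numeric matrix of fixed covariates with line
#'   rownames (e.g. principal components); must be full rank.
#' @return A [ScanResult-class] (mode "hk", or "hk_pc" when covariates are
#'   supplied).
#' @examples
#' map <- simulateMap(c(20L), c(100), seed = 1)
#' g <- simulateDHGenotypes(map, 100, seed = 2)
#' pr <- calcGenoprob(g, map)
#' y <- stats::setNames(rnorm(100, 25, 2.8), lineNames(g))
#' scan1HK(pr, y)
#' @export
scan1HK <- function(genoprob, phenotype, covariates = NULL) {
  dat <- .alignScanData(genoprob, phenotype, covariates)
  qrX <- qr(dat$X0)
  yres <- .resid0(qrX, dat$y)
  Gres <- .resid0(qrX, dat$PA)
  lod <- .hkLod(Gres, yres, length(dat$y))
  if (anyNA(lod))
    warning(sum(is.na(lod)), " marker(s) skipped: rank-deficient design")
  mk <- markerTable(genoprob)
  new("ScanResult",
      table = data.frame(marker_id = mk$marker_id,
                         chromosome = mk$chromosome, pos_cM = mk$pos_cM,
                         lod = lod, stringsAsFactors = FALSE),
      mode = if (is.null(covariates)) "hk" else "hk_pc",
      nCovariates = if (is.null(covariates)) 0L else ncol(as.matrix(covariates)),
      threshold = NA_real_, alpha = NA_real_)
}

# REML criterion (up to a constant) for the polygenic variance fraction h
# in the eigenrotated model: Var(y*) = s2 * diag(h*d + (1-h)).
.remlCrit <- function(h, yr, Xr, d) {
  w <- h * d + (1 - h)
  if (any(w <= 0)) return(-Inf)
  sw <- sqrt(w)
  qrX <- qr(Xr / sw)
  rss <- sum(qr.resid(qrX, yr / sw)^2)
  n <- length(yr); p <- ncol(Xr)
  ldXX <- 2 * sum(log(abs(diag(qr.R(qrX)))))
  -0.5 * (sum(log(w)) + (n - p) * log(rss) + ldXX)
}

.estHsq <- function(yr, Xr, d) {
  opt <- stats::optimize(.remlCrit, c(1e-6, 1 - 1e-6), yr = yr, Xr = Xr,
                         d = d, maximum = TRUE)
  h <- opt$maximum
  if (.remlCrit(0, yr, Xr, d) >= opt$objective) h <- 0
  h
}

# Eigen-decompose a kinship matrix restricted to `ids`, with a PSD guard.
.kinshipEigen <- function(kin, ids) {
  K <- kinshipValues(kin)
  if (!all(ids %in% rownames(K))) stop("kinship missing some scan lines")
  ed <- eigen(K[ids, ids], symmetric = TRUE)
  if (min(ed$values) < -1e-6)
    stop("kinship matrix is not positive semi-definite after adjustment")
  ed$values <- pmax(ed$values, 0)
  ed
}

#' LOCO linear mixed model scan
#'
#' Per chromosome, the leave-one-chromosome-out kinship matrix enters as
#' the covariance of a random polygenic effect. The polygenic variance
#' fraction is estimated once per chromosome by REML under the null model
#' (no marker term) and held fixed across that chromosome's markers; each
#' marker is then tested by generalized least squares in the eigenrotated
#' model, with LOD = (n/2) * log10(RSS_null / RSS_full) on the whitened
#' data (the log10 likelihood ratio with residual variance profiled out).
#' With an identity kinship matrix the scan collapses exactly to
#' [scan1HK()].
#'
#' @param genoprob a [GenoProb-class].
#' @param phenotype numeric vector named by line id.
#' @param kinship named list of LOCO [KinshipMatrix-class] objects, one
#'   per chromosome (from `kinshipGRM(genoprob, loco = TRUE)`), or a
#'   single matrix to use for every chromosome.
#' @param covariates optional fixed-covariate matrix with line rownames.
#' @return A [ScanResult-class] (mode "lmm_loco") whose table carries the
#'   per-chromosome polygenic fraction in column `hsq`.
#' @export
scan1LMM <- function(genoprob, phenotype, kinship, covariates = NULL) {
  dat <- .alignScanData(genoprob, phenotype, covariates)
  mk <- markerTable(genoprob)
  chrs <- unique(mk$chromosome)
  if (is(kinship, "KinshipMatrix"))
    kinship <- stats::setNames(rep(list(kinship), length(chrs)), chrs)
  if (!all(chrs %in% names(kinship)))
    stop("LOCO kinship list must cover every chromosome in the map")
  n <- length(dat$y)
  lod <- rep(NA_real_, nrow(mk))
  hsq <- rep(NA_real_, nrow(mk))
  for (ch in chrs) {
    j <- which(mk$chromosome == ch)
    ed <- .kinshipEigen(kinship[[ch]], dat$ids)
    Ut <- t(ed$vectors)
    yr <- as.vector(Ut %*% dat$y)
    Xr <- Ut %*% dat$X0
    h <- .estHsq(yr, Xr, ed$values)
    w <- sqrt(h * ed$values + (1 - h))
    qrX <- qr(Xr / w)
    yres <- qr.resid(qrX, yr / w)
    Gres <- qr.resid(qrX, (Ut %*% dat$PA[, j, drop = FALSE]) / w)
    lod[j] <- .hkLod(Gres, yres, n)
    hsq[j] <- h
  }
  if (anyNA(lod))
    warning(sum(is.na(lod)), " marker(s) skipped: rank-deficient design")
  new("ScanResult",
      table = data.frame(marker_id = mk$marker_id,
                         chromosome = mk$chromosome, pos_cM = mk$pos_cM,
                         lod = lod, hsq = hsq, stringsAsFactors = FALSE),
      mode = "lmm_loco",
      nCovariates = if (is.null(covariates)) 0L else ncol(as.matrix(covariates)),
      threshold = NA_real_, alpha = NA_real_)
}
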