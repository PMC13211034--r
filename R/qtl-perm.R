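#' Permutation LOD significance threshold
#'
#' Shuffles the phenotype vector across lines (covariates and kinship stay
#' bound to their genotype rows), reruns the requested scan for each
#' permutation, records the genome-wide maximum LOD, and returns the
#' empirical (1 - alpha) quantile (order-statistic quantile with linear
#' interpolation). Permutations are batched through the same closed-form
#' least-squares algebra as the scans, so 1000 permutations of a
#' full-size map run in seconds. For the mixed-model mode the
#' per-chromosome polygenic fraction is estimated once from the observed
#' (unpermuted) null model and held fixed, as in the scan itself.
#'
#' @param genoprob a [GenoProb-class].
#' @param phenotype numeric vector named by line id.
#' @param covariates optional fixed-covariate matrix (hk_pc mode).
#' @param kinship LOCO kinship list; supplying it selects the mixed-model
#'   scan mode.
#' @param nPerm number of permutations (>= 100; default 1000).
#' @param alpha genome-wide significance level (default 0.05).
#' @param seed integer RNG seed for the permutation draws (default 123).
#' @return list with `threshold`, `alpha`, `nPerm` and the per-permutation
#'   genome-wide maxima `maxLods`.
#' @export
permutationThreshold <- function(genoprob, phenotype, covariates = NULL,
                                 kinship = NULL, nPerm = 1000L,
                                 alpha = 0.05, seed = 123L) {
  if (nPerm < 100L) stop("nPerm must be >= 100")
  dat <- .alignScanData(genoprob, phenotype, covariates)
  n <- length(dat$y)
  perm <- .withSeed(seed, {
    vapply(seq_len(nPerm), function(i) sample.int(n), integer(n))
  })
  Yp <- matrix(dat$y[perm], n, nPerm)
  mk <- markerTable(genoprob)
  if (is.null(kinship)) {
    qrX <- qr(dat$X0)
    Yres <- qr.resid(qrX, Yp)
    Gres <- qr.resid(qrX, dat$PA)
    maxLods <- .permMaxLod(Gres, Yres, n)
  } else {
    chrs <- unique(mk$chromosome)
    if (is(kinship, "KinshipMatrix"))
      kinship <- stats::setNames(rep(list(kinship), length(chrs)), chrs)
    maxLods <- rep(-Inf, nPerm)
    for (ch in chrs) {
      j <- which(mk$chromosome == ch)
      ed <- .kinshipEigen(kinship[[ch]], dat$ids)
      Ut <- t(ed$vectors)
      yr <- as.vector(Ut %*% dat$y)
      Xr <- Ut %*% dat$X0
      h <- .estHsq(yr, Xr, ed$values)
      w <- sqrt(h * ed$values + (1 - h))
      qrX <- qr(Xr / w)
      Yres <- qr.resid(qrX, (Ut %*% Yp) / w)
      Gres <- qr.resid(qrX, (Ut %*% dat$PA[, j, drop = FALSE]) / w)
      maxLods <- pmax(maxLods, .permMaxLod(Gres, Yres, n))
    }
  }
  list(threshold = unname(stats::quantile(maxLods, 1 - alpha, type = 7)),
       alpha = alpha, nPerm = as.integer(nPerm), maxLods = maxLods)
}

# Genome-wide max LOD per permutation column. For fixed RSS_null the LOD
# is monotone in the explained sum of squares, so only the per-column
# maximum of num^2/gss is needed.
.permMaxLod <- function(Gres, Yres, n) {
  gss <- colSums(Gres^2)
  ok <- gss >= 1e-10 * n
  Gres <- Gres[, ok, drop = FALSE]
  gss <- gss[ok]
  if (!length(gss)) stop("no non-degenerate markers in scope")
  NUM <- crossprod(Gres, Yres)          # markers x nPerm
  stat <- NUM^2 / gss                   # recycles gss down columns
  best <- apply(stat, 2L, max)
  rss0 <- colSums(Yres^2)
  (n / 2) * log10(rss0 / pmax(rss0 - best, 1e-300))
}
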