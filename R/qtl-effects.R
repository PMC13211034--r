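#' Allele-effect statistics at a marker
#'
#' Splits the genotype values by observed allele at the marker (lines with
#' missing calls are excluded), compares the two distributions with a
#' pooled-variance Student's t-test, reports the additive effect as
#' mean(A) - mean(B) in grains, and the phenotypic variance explained as
#' 100 * R^2 of the phenotype-on-genotype regression.
#'
#' @param values numeric genotype values named by line id.
#' @param calls character vector of calls ("A"/"B"/NA) named by line id,
#'   e.g. one column of [genoCalls()].
#' @param marker_id marker label carried into the result.
#' @return A [QtlEffect-class].
#' @examples
#' v <- c(a = 26, b = 27, c = 25, d = 24, e = 25, f = 23)
#' g <- c(a = "A", b = "A", c = "A", d = "B", e = "B", f = "B")
#' alleleEffect(v, g, "m1")
#' @export
alleleEffect <- function(values, calls, marker_id = "marker") {
  if (is.null(names(values)) || is.null(names(calls)))
    stop("values and calls must be named by line id")
  ids <- intersect(names(values), names(calls))
  v <- values[ids]; g <- calls[ids]
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  vA <- v[g == "A"]; vB <- v[g == "B"]
  if (!length(vA) || !length(vB)) stop("one allele class is empty at ", marker_id)
  tt <- tryCatch(stats::t.test(vA, vB, var.equal = TRUE),
                 error = function(e) NULL)
  if (is.null(tt)) {  # degenerate within-class variance: pooled SD is 0
    tstat <- if (mean(vA) == mean(vB)) 0 else sign(mean(vA) - mean(vB)) * Inf
    pval <- if (is.finite(tstat)) 1 else 0
  } else {
    tstat <- unname(tt$statistic); pval <- tt$p.value
  }
  r2 <- suppressWarnings(
    summary(stats::lm(v ~ factor(g, levels = c("A", "B"))))$r.squared)
  if (is.nan(r2)) r2 <- 0            # constant phenotype: nothing to explain
  new("QtlEffect", marker_id = as.character(marker_id),
      n_A = length(vA), n_B = length(vB),
      mean_A = mean(vA), mean_B = mean(vB),
      effect = mean(vA) - mean(vB),
      t_stat = tstat, p_value = pval, pve = 100 * r2)
}

#' Nested-model ANOVA: does the QTL add signal beyond cluster structure?
#'
#' Compares model 1, phenotype ~ cluster, against model 2, phenotype ~
#' cluster + marker genotype (a single QTL effect assumed equal across
#' clusters), with an F-test on the residual sums of squares. A marker
#' constant within every cluster is aliased with the cluster factor and
#' raises a confounding error.
#'
#' @param values numeric genotype values named by line id.
#' @param clusters cluster labels named by line id.
#' @param calls marker calls ("A"/"B"/NA) named by line id.
#' @return list with `F`, `p`, `df` (numerator, denominator) and both
#'   model residual sums of squares.
#' @export
nestedANOVA <- function(values, clusters, calls) {
  ids <- Reduce(intersect, list(names(values), names(clusters), names(calls)))
  v <- values[ids]; cl <- factor(unlist(clusters[ids])); g <- calls[ids]
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; cl <- droplevels(cl[keep]); g <- factor(g[keep])
  if (nlevels(cl) < 2L) stop("need >= 2 clusters")
  if (nlevels(g) < 2L) stop("marker has a single allele class")
  fit1 <- stats::lm(v ~ cl)
  fit2 <- stats::lm(v ~ cl + g)
  if (anyNA(stats::coef(fit2)))
    stop("confounded: marker genotype is aliased with cluster assignment")
  an <- stats::anova(fit1, fit2)
  list(F = an$F[2L], p = an$`Pr(>F)`[2L],
       df = c(an$Df[2L], an$Res.Df[2L]),
       rss_cluster = an$RSS[1L], rss_full = an$RSS[2L])
}

#' Pick the peak marker of a scan
#'
#' Returns the marker with the maximal LOD. Ties (within `tol`, which
#' covers perfectly concordant colocalized markers) are broken in favour
#' of the marker with the fewest missing genotype calls, then by map
#' order.
#'
#' @param scan a [ScanResult-class].
#' @param genotypes a [GenotypeMatrix-class] used for the
#'   missing-call tie-break (optional; map order alone is used if absent).
#' @param tol LOD difference treated as a tie (default 1e-6).
#' @return marker id (character).
#' @export
pickPeakMarker <- function(scan, genotypes = NULL, tol = 1e-6) {
  tab <- lodTable(scan)
  if (nrow(tab) == 0L || all(is.na(tab$lod))) stop("empty scan")
  top <- max(tab$lod, na.rm = TRUE)
  tied <- which(!is.na(tab$lod) & tab$lod >= top - tol)
  if (length(tied) > 1L && !is.null(genotypes)) {
    calls <- genoCalls(genotypes)
    nmiss <- vapply(tab$marker_id[tied], function(m) {
      if (m %in% colnames(calls)) sum(is.na(calls[, m])) else NA_integer_
    }, integer(1))
    if (!anyNA(nmiss)) tied <- tied[nmiss == min(nmiss)]
  }
  tab$marker_id[tied[1L]]   # earliest map position among remaining ties
}
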