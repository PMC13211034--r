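#' Aggregate head counts to plot means
#'
#' The plot phenotype is the arithmetic mean grain number per spike over
#' the plot's technical replicates (sampled heads).
#'
#' @param plotTable a [PlotTable-class].
#' @return data.frame with one row per plot: `plot_id`, `genotype_id`,
#'   `row`, `range`, `n_heads`, `mean_count`.
#' @export
aggregatePlots <- function(plotTable) {
  stopifnot(is(plotTable, "PlotTable"))
  h <- headData(plotTable)
  if (nrow(h) == 0L) stop("empty plot table")
  sp <- split(h, h$plot_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(plot_id = d$plot_id[1L], genotype_id = d$genotype_id[1L],
               row = d$row[1L], range = d$range[1L],
               n_heads = nrow(d), mean_count = mean(d$grain_count),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$plot_id), ]
  rownames(out) <- NULL
  out
}

#' Replicate-consistency CV and range
#'
#' For every replicated genotype, the coefficient of variation (sample SD
#' over mean of its plot means) and the range (max - min); class averages
#' are reported for two- and three-plot genotypes.
#'
#' @param plotTable a [PlotTable-class].
#' @return list with `perGenotype` (genotype_id, n_plots, cv, range) and
#'   `byClass` (n_plots, n_genotypes, mean_cv, mean_range).
#' @export
replicateCV <- function(plotTable) {
  pm <- aggregatePlots(plotTable)
  reps <- split(pm$mean_count, pm$genotype_id)
  reps <- reps[lengths(reps) >= 2L]
  if (length(reps) == 0L) {
    warning("no replicated genotypes")
    return(list(perGenotype = data.frame(), byClass = data.frame()))
  }
  per <- data.frame(
    genotype_id = names(reps),
    n_plots = lengths(reps),
    cv = vapply(reps, function(v) stats::sd(v) / mean(v), numeric(1)),
    range = vapply(reps, function(v) max(v) - min(v), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  byc <- do.call(rbind, lapply(split(per, per$n_plots), function(d) {
    data.frame(n_plots = d$n_plots[1L], n_genotypes = nrow(d),
               mean_cv = mean(d$cv), mean_range = mean(d$range))
  }))
  rownames(byc) <- NULL
  list(perGenotype = per, byClass = byc)
}

#' Repeatability of duplicate plots
#'
#' Pearson correlation between the first and second plot value of each
#' duplicated genotype (plots ordered by plot id), before and after
#' removing pairs whose absolute difference exceeds the outlier threshold.
#'
#' @param plotTable a [PlotTable-class].
#' @param outlierThreshold difference in grains beyond which a pair is an
#'   outlier (default 5).
#' @return list: `r_all`, `r_outliers_removed`, `n_pairs`, `n_outliers`,
#'   and the pair table.
#' @export
repeatability <- function(plotTable, outlierThreshold = 5) {
  pm <- aggregatePlots(plotTable)
  reps <- split(pm, pm$genotype_id)
  dup <- reps[vapply(reps, nrow, integer(1)) == 2L]
  if (length(dup) < 3L) stop("need at least 3 duplicate genotypes")
  pairs <- do.call(rbind, lapply(dup, function(d) {
    d <- d[order(d$plot_id), ]
    data.frame(genotype_id = d$genotype_id[1L], first = d$mean_count[1L],
               second = d$mean_count[2L], stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  out <- abs(pairs$first - pairs$second) > outlierThreshold
  r_all <- stats::cor(pairs$first, pairs$second)
  r_clean <- if (sum(!out) >= 3L) stats::cor(pairs$first[!out], pairs$second[!out])
             else NA_real_
  list(r_all = r_all, r_outliers_removed = r_clean,
       n_pairs = nrow(pairs), n_outliers = sum(out), pairs = pairs)
}

#' Genotype values with the outlier-median rule
#'
#' The genotype value is the mean of its plot means. When any two replicate
#' plots differ by more than `threshold` grains, the median is used instead
#' to damp plot-level stochastic noise: by default the median of the
#' genotype's pooled head-level counts (the median of two plot means would
#' equal their mean and the rule would have no effect), switchable to the
#' median of plot means via `medianOn`.
#'
#' @param plotTable a [PlotTable-class].
#' @param threshold pairwise plot-mean difference (grains) that triggers
#'   the median rule (default 5).
#' @param medianOn "pooled_heads" (default) or "plot_means".
#' @return data.frame: `genotype_id`, `value`, `method` ("mean"/"median"),
#'   `n_plots`.
#' @export
adjustReplicates <- function(plotTable, threshold = 5,
                             medianOn = c("pooled_heads", "plot_means")) {
  medianOn <- match.arg(medianOn)
  if (threshold <= 0) stop("threshold must be positive")
  pm <- aggregatePlots(plotTable)
  hd <- headData(plotTable)
  out <- do.call(rbind, lapply(split(pm, pm$genotype_id), function(d) {
    fire <- nrow(d) >= 2L && (max(d$mean_count) - min(d$mean_count)) > threshold
    value <- if (fire) {
      if (medianOn == "pooled_heads")
        stats::median(hd$grain_count[hd$genotype_id == d$genotype_id[1L]])
      else stats::median(d$mean_count)
    } else mean(d$mean_count)
    data.frame(genotype_id = d$genotype_id[1L], value = value,
               method = if (fire) "median" else "mean",
               n_plots = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Heritability and shares from fixed variance components
#'
#' Applies the plot-level broad-sense heritability formula
#' H2 = sG2 / (sG2 + sR2 + sC2 + sE2) and the percentage share of each
#' component in the total phenotypic variance.
#'
#' @param sigma2_G,sigma2_R,sigma2_C,sigma2_E variance components for
#'   genotype, row, range, residual.
#' @return list with `H2` (proportion), `H2_percent`, and `shares`
#'   (named percentages summing to 100).
#' @export
heritabilityFromComponents <- function(sigma2_G, sigma2_R, sigma2_C,
                                       sigma2_E) {
  if (any(c(sigma2_G, sigma2_R, sigma2_C, sigma2_E) < 0))
    stop("variance components must be non-negative")
  tot <- sigma2_G + sigma2_R + sigma2_C + sigma2_E
  if (tot <= 0) stop("total variance must be positive")
  shares <- 100 * c(Genotype = sigma2_G, Row = sigma2_R, Range = sigma2_C,
                    Residual = sigma2_E) / tot
  list(H2 = sigma2_G / tot, H2_percent = 100 * sigma2_G / tot,
       shares = shares)
}

#' REML variance components of the row-column model
#'
#' Fits y = mu + g + r + c + e to the plot means by REML, with genotype,
#' row and range as independent random intercepts and the intercept as the
#' only fixed effect, and derives the component percentage shares and
#' plot-level broad-sense heritability.
#'
#' @param plotTable a [PlotTable-class].
#' @return A [VarianceComponents-class].
#' @examples
#' map <- simulateMap(c(5L), c(100), seed = 1)
#' g <- simulateDHGenotypes(map, 183, seed = 2)
#' d <- simulateField(g, seed = 3)
#' pt <- simulatePhenotypes(d, g, headNoiseSD = 0, seed = 4)
#' varianceComponentsREML(pt)
#' @export
varianceComponentsREML <- function(plotTable) {
  pm <- aggregatePlots(plotTable)
  for (v in c("genotype_id", "row", "range"))
    if (length(unique(pm[[v]])) < 2L)
      stop("need >= 2 levels of ", v, " to separate its variance")
  pm$rowf <- factor(pm$row)
  pm$rangef <- factor(pm$range)
  fit <- lme4::lmer(
    mean_count ~ 1 + (1 | genotype_id) + (1 | rowf) + (1 | rangef),
    data = pm, REML = TRUE,
    control = lme4::lmerControl(optimizer = "bobyqa",
                                check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) vc$vcov[match(g, vc$grp)]
  sG <- getv("genotype_id"); sR <- getv("rowf"); sC <- getv("rangef")
  sE <- getv("Residual")
  h <- heritabilityFromComponents(sG, sR, sC, sE)
  new("VarianceComponents", sigma2_G = sG, sigma2_R = sR, sigma2_C = sC,
      sigma2_E = sE, mu_hat = unname(lme4::fixef(fit)[1L]),
      shares = h$shares, H2 = h$H2)
}

#' Shapiro-Wilk normality gate
#'
#' The phenotype distribution must look normal before QTL scanning;
#' the gate passes when the Shapiro-Wilk p-value exceeds 0.05.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with `W`, `p` and `pass`.
#' @export
normalityGate <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value, pass = sw$p.value > 0.05)
}
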