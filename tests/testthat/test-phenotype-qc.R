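# Plot aggregation, replicate QC, outlier-median rule, REML variance
# components, heritability, normality gate.

makePlotTable <- function(df) new("PlotTable", heads = df)

# long-format heads for given plot means (one head per mean value repeated)
headsFor <- function(genotype, plotMeans, headsPer = 3L, rowStart = 1L) {
  do.call(rbind, lapply(seq_along(plotMeans), function(i) {
    data.frame(plot_id = sprintf("%s_p%d", genotype, i),
               genotype_id = genotype, row = rowStart + i, range = i,
               head_index = seq_len(headsPer),
               grain_count = rep(plotMeans[i], headsPer))
  }))
}

test_that("plot aggregation averages technical replicates", {
  pt <- makePlotTable(data.frame(
    plot_id = "P1", genotype_id = "G1", row = 1L, range = 1L,
    head_index = 1:3, grain_count = c(24, 26, 28)))
  expect_equal(aggregatePlots(pt)$mean_count, 26)
  pt1 <- makePlotTable(data.frame(
    plot_id = "P1", genotype_id = "G1", row = 1L, range = 1L,
    head_index = 1L, grain_count = 30))
  expect_equal(aggregatePlots(pt1)$mean_count, 30)

  map <- tinyMap()
  g <- simulateDHGenotypes(map, 183, seed = 1)
  d <- simulateField(g, seed = 2)
  pt2 <- simulatePhenotypes(d, g, mu = 25, variances = c(G = 0, R = 0, C = 0, E = 0),
                            headNoiseSD = 0, seed = 3)
  expect_true(all(aggregatePlots(pt2)$mean_count == 25))
})

test_that("replicate CV and range match hand computations", {
  pt <- makePlotTable(rbind(headsFor("G1", c(25, 25)),
                            headsFor("G2", c(24, 27), rowStart = 5L)))
  cv <- replicateCV(pt)
  per <- cv$perGenotype[order(cv$perGenotype$genotype_id), ]
  expect_equal(per$cv[per$genotype_id == "G1"], 0)
  expect_equal(per$range[per$genotype_id == "G1"], 0)
  expect_equal(per$cv[per$genotype_id == "G2"], sd(c(24, 27)) / 25.5)
  expect_equal(per$range[per$genotype_id == "G2"], 3)
  expect_equal(cv$byClass$mean_cv, mean(per$cv))
})

test_that("repeatability is the duplicate-pair Pearson correlation with outlier removal", {
  pt <- makePlotTable(rbind(headsFor("G1", c(20, 20)),
                            headsFor("G2", c(25, 25), rowStart = 4L),
                            headsFor("G3", c(30, 30), rowStart = 8L)))
  expect_equal(repeatability(pt)$r_all, 1)

  anti <- makePlotTable(rbind(headsFor("G1", c(20, 30)),
                              headsFor("G2", c(25, 25), rowStart = 4L),
                              headsFor("G3", c(30, 20), rowStart = 8L)))
  expect_equal(repeatability(anti)$r_all, -1)
  rr <- repeatability(anti, outlierThreshold = 5)
  expect_equal(rr$n_outliers, 2L)

  expect_error(repeatability(makePlotTable(headsFor("G1", c(1, 2)))),
               "at least 3")

  # r -> 1 as residual noise vanishes relative to genetic variance
  map <- tinyMap()
  g <- simulateDHGenotypes(map, 183, seed = 4)
  d <- simulateField(g, seed = 5)
  ptg <- simulatePhenotypes(d, g, variances = c(G = 8, R = 0, C = 0, E = 0.01),
                            headNoiseSD = 0, seed = 6)
  expect_gt(repeatability(ptg)$r_all, 0.99)
})

test_that("the >5-grain rule switches genotype values from mean to pooled-head median", {
  dup <- makePlotTable(headsFor("G1", c(24, 26)))
  v <- adjustReplicates(dup)
  expect_equal(v$value, 25); expect_equal(v$method, "mean")

  trip <- makePlotTable(headsFor("G1", c(20, 24, 27)))
  v2 <- adjustReplicates(trip)
  expect_equal(v2$method, "median")
  expect_equal(v2$value, median(rep(c(20, 24, 27), each = 3L)))
  v2b <- adjustReplicates(trip, medianOn = "plot_means")
  expect_equal(v2b$value, 24)

  # threshold -> infinity reduces exactly to plain means
  mixed <- makePlotTable(rbind(headsFor("G1", c(20, 29)),
                               headsFor("G2", c(25), rowStart = 5L)))
  vInf <- adjustReplicates(mixed, threshold = Inf)
  expect_equal(vInf$method, c("mean", "mean"))
  expect_equal(vInf$value[vInf$genotype_id == "G1"], 24.5)
  # singleton passthrough
  expect_equal(vInf$value[vInf$genotype_id == "G2"], 25)
})

test_that("REML recovers planted variance components and heritability", {
  # 200 genotypes x 2 plots, components (4, 1, 1, 4), 20 seeds
  truth <- c(G = 4, R = 1, C = 1, E = 4)
  est <- matrix(0, 20L, 4L)
  map <- simulateMap(c(5L), c(100), seed = 1)
  g <- simulateDHGenotypes(map, 200, seed = 2)
  cfg <- list(nGenotypes = 200L, nDuplicates = 200L, nTriplicates = 0L,
              nRows = 20L, nRanges = 20L)
  for (s in 1:20) {
    d <- simulateField(g, config = cfg, seed = 100 + s)
    pt <- simulatePhenotypes(d, g, variances = truth, headNoiseSD = 0,
                             seed = 200 + s)
    # fit on the latent plot values to keep the harness free of rounding
    h <- headData(pt)
    h$grain_count <- h$plot_value
    vc <- varianceComponentsREML(makePlotTable(h))
    est[s, ] <- c(vc@sigma2_G, vc@sigma2_R, vc@sigma2_C, vc@sigma2_E)
  }
  rel <- abs(colMeans(est) - truth) / truth
  expect_true(all(rel < 0.25))

  vc <- varianceComponentsREML(simulatePhenotypes(
    simulateField(g, config = cfg, seed = 7), g, seed = 8))
  expect_equal(sum(componentShares(vc)), 100)
  expect_gte(heritability(vc), 0); expect_lte(heritability(vc), 1)
})

test_that("REML bias shrinks with genotype count and H2 is scale invariant", {
  map <- simulateMap(c(5L), c(100), seed = 3)
  relErr <- sapply(c(50L, 200L, 800L), function(nG) {
    g <- simulateDHGenotypes(map, nG, seed = nG)
    cfg <- list(nGenotypes = nG, nDuplicates = nG, nTriplicates = 0L,
                nRows = as.integer(ceiling(sqrt(2 * nG))) + 2L,
                nRanges = as.integer(ceiling(sqrt(2 * nG))) + 2L)
    est <- sapply(1:5, function(s) {
      d <- simulateField(g, config = cfg, seed = 1000L * nG + s)
      pt <- simulatePhenotypes(d, g, variances = c(G = 4, R = 1, C = 1, E = 4),
                               headNoiseSD = 0, seed = 2000L * nG + s)
      h <- headData(pt); h$grain_count <- h$plot_value
      varianceComponentsREML(makePlotTable(h))@sigma2_G
    })
    abs(mean(est) - 4) / 4
  })
  expect_lt(relErr[3L], relErr[1L] + 0.05)   # consistency trend with slack

  # scale invariance of H2
  g <- simulateDHGenotypes(map, 183, seed = 5)
  d <- simulateField(g, seed = 6)
  pt <- simulatePhenotypes(d, g, variances = c(G = 2, R = 1, C = 1, E = 3),
                           headNoiseSD = 0, seed = 7)
  h <- headData(pt)
  h2a <- heritability(varianceComponentsREML(makePlotTable(h)))
  h$grain_count <- h$grain_count * 7
  h2b <- heritability(varianceComponentsREML(makePlotTable(h)))
  expect_equal(h2a, h2b, tolerance = 1e-6)
})

test_that("fixed-component heritability reproduces the worked study partition", {
  h <- heritabilityFromComponents(0.009938871, 0.786657886, 0.523202051,
                                  7.286333883)
  expect_equal(round(h$H2_percent, 2), 0.12)
  expect_equal(unname(round(h$shares, 1)), c(0.1, 9.1, 6.1, 84.7))
  expect_equal(sum(h$shares), 100)
  expect_error(heritabilityFromComponents(-1, 1, 1, 1), "non-negative")
})

test_that("the Shapiro-Wilk gate is calibrated and has power", {
  set.seed(9)
  passes <- sapply(1:100, function(i) normalityGate(rnorm(183))$pass)
  expect_gt(mean(passes), 0.89)
  expect_lt(mean(passes), 0.995)

  bimodal <- c(rnorm(90, -4, 0.5), rnorm(93, 4, 0.5))
  expect_false(normalityGate(bimodal)$pass)
  expect_error(normalityGate(c(1, 2)), "3 <= n")
})
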