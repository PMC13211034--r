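# Synthetic-data generators: maps, DH genotypes, field designs,
# phenotypes, count errors.

test_that("simulated maps honour requested counts, ordering and determinism", {
  map <- simulateMap(seed = 1)
  mk <- markerTable(map)
  expect_equal(nMarkers(map), 2776L)
  expect_equal(as.integer(table(factor(mk$chromosome, levels = paste0(1:7, "H")))),
               c(204L, 493L, 472L, 236L, 609L, 308L, 454L))
  for (ch in unique(mk$chromosome)) {
    sub <- mk[mk$chromosome == ch, ]
    expect_false(is.unsorted(sub$pos_cM))
    expect_false(is.unsorted(sub$pos_bp))   # bp monotone with cM
  }
  expect_false(anyDuplicated(mk$marker_id) > 0)

  one <- simulateMap(c(1L), c(100), seed = 2)
  expect_equal(nMarkers(one), 1L)
  expect_gte(markerTable(one)$pos_cM, 0)
  expect_lte(markerTable(one)$pos_cM, 100)

  a <- simulateMap(c(3L), c(50), seed = 7)
  b <- simulateMap(c(3L), c(50), seed = 7)
  expect_identical(markerTable(a), markerTable(b))

  expect_error(simulateMap(c(3L, 4L), c(100)), "same length")
  expect_error(simulateMap(c(0L), c(100)), ">= 1 marker")
})

test_that("DH genotypes are homozygous with Haldane switch rates and 0.5 allele frequency", {
  map <- simulateMap(c(2L), c(100), seed = 3)
  mk <- markerTable(map)
  # force an exact 10 cM gap for the switch-rate check
  mk$pos_cM <- c(10, 20)
  map2 <- new("GeneticMap", markers = mk)
  n <- 10000L
  g <- simulateDHGenotypes(map2, n, seed = 4)
  calls <- genoCalls(g)
  expect_true(all(calls %in% c("A", "B")))

  sw <- mean(calls[, 1L] != calls[, 2L])
  rf <- 0.5 * (1 - exp(-0.2))              # 0.090635 by hand
  se <- sqrt(rf * (1 - rf) / n)
  expect_lt(abs(sw - rf), 3 * se)
  # chi-square goodness of fit of switch counts to the Haldane model
  chi <- stats::chisq.test(c(sum(calls[, 1L] != calls[, 2L]),
                             sum(calls[, 1L] == calls[, 2L])),
                           p = c(rf, 1 - rf))
  expect_gt(chi$p.value, 0.01)

  af <- colMeans(calls == "A")
  expect_true(all(abs(af - 0.5) < 3 * sqrt(0.25 / n)))

  # missing and error rates are realised at the requested levels
  g2 <- simulateDHGenotypes(map2, n, missingRate = 0.1, errorRate = 0.05,
                            seed = 5)
  obs <- genoCalls(g2); tru <- trueCalls(g2)
  expect_lt(abs(mean(is.na(obs)) - 0.1), 3 * sqrt(0.1 * 0.9 / (2 * n)))
  flip <- mean(obs[!is.na(obs)] != tru[!is.na(obs)])
  expect_lt(abs(flip - 0.05), 3 * sqrt(0.05 * 0.95 / (2 * n * 0.9)))

  expect_error(simulateDHGenotypes(map2, 10, missingRate = 1), "missingRate")
})

test_that("field designs meet the requested cardinalities exactly", {
  map <- tinyMap()
  g <- simulateDHGenotypes(map, 183, seed = 5)
  d <- simulateField(g, seed = 6)
  p <- plotData(d)
  expect_equal(nrow(p), 229L)
  expect_equal(length(unique(p$genotype_id)), 183L)
  reps <- table(p$genotype_id)
  expect_equal(sum(reps >= 2), 41L)                 # replicated lines
  expect_equal(sum(reps == 2), 36L)
  expect_equal(sum(reps == 3), 5L)
  expect_false(anyDuplicated(p[c("row", "range")]) > 0)

  singles <- simulateField(g, config = list(nDuplicates = 0L,
                                            nTriplicates = 0L), seed = 6)
  expect_equal(nrow(plotData(singles)), 183L)

  expect_identical(plotData(simulateField(g, seed = 9)),
                   plotData(simulateField(g, seed = 9)))
  expect_error(simulateField(g, config = list(nRows = 2L, nRanges = 2L)),
               "grid too small")
})

test_that("phenotypes follow the additive plot model and planted QTL effect", {
  map <- tinyMap()
  g <- simulateDHGenotypes(map, 183, seed = 7)
  d <- simulateField(g, seed = 8)
  zero <- c(G = 0, R = 0, C = 0, E = 0)

  pt <- simulatePhenotypes(d, g, mu = 25, variances = zero,
                           headNoiseSD = 0, seed = 9)
  expect_true(all(headData(pt)$grain_count == 25))

  qtl <- qtlSpec(markerTable(map)$marker_id[5], effect = 1.18)
  pt2 <- simulatePhenotypes(d, g, qtl = qtl, mu = 25, variances = zero,
                            headNoiseSD = 0, seed = 10)
  heads2 <- headData(pt2)
  pv <- tapply(heads2$plot_value, heads2$genotype_id, mean)
  al <- trueCalls(g)[names(pv), qtl@marker_id]
  # rounding to integer head counts hides sub-grain differences, so the
  # planted effect is asserted on the latent plot values, where it is exact
  expect_equal(mean(pv[al == "A"]) - mean(pv[al == "B"]), 1.18)
  heads <- headData(pt2)
  expect_true(all(heads$grain_count >= 1))
  expect_true(all(table(heads$plot_id) >= 3 & table(heads$plot_id) <= 7))

  expect_error(
    simulatePhenotypes(d, g, qtl = qtlSpec("nope", effect = 1)),
    "absent")
  expect_identical(
    headData(simulatePhenotypes(d, g, seed = 11)),
    headData(simulatePhenotypes(d, g, seed = 11)))
})

test_that("qtlSpec derives effect from target PVE and rejects double specification", {
  expect_error(qtlSpec("m1"), "exactly one")
  expect_error(qtlSpec("m1", effect = 1, targetPVE = 0.1), "exactly one")
  map <- tinyMap()
  g <- simulateDHGenotypes(map, 2000, seed = 20)
  d <- simulateField(g, config = list(nGenotypes = 2000L, nDuplicates = 0L,
                                      nTriplicates = 0L, nRows = 45L,
                                      nRanges = 45L), seed = 21)
  vv <- c(G = 0, R = 0, C = 0, E = 4)
  pt <- simulatePhenotypes(d, g, qtl = qtlSpec(markerTable(map)$marker_id[3],
                                               targetPVE = 0.2),
                           variances = vv, headNoiseSD = 0, seed = 22)
  heads <- headData(pt)
  pv <- tapply(heads$plot_value, heads$genotype_id, mean)
  al <- trueCalls(g)[names(pv), markerTable(map)$marker_id[3]]
  fit <- summary(stats::lm(pv ~ al))
  expect_lt(abs(fit$r.squared - 0.2), 0.04)
})

test_that("detector count errors have the configured bias and spread", {
  expect_equal(simulateCountErrors(c(20L, 25L), bias = 0, sd = 0), c(20L, 25L))
  expect_equal(simulateCountErrors(20L, bias = 2, sd = 0), 22L)
  manual <- rep(25L, 10000L)
  model <- simulateCountErrors(manual, bias = -0.18, sd = 1.86, seed = 12)
  err <- model - manual
  expect_lt(abs(mean(err) - (-0.18)), 3 * 1.86 / sqrt(10000))
  expect_identical(simulateCountErrors(manual, seed = 3),
                   simulateCountErrors(manual, seed = 3))
  expect_error(simulateCountErrors(1L, sd = -1), "non-negative")
})

test_that("spike images carry exact truth and the advertised geometry", {
  img <- simulateSpikeImage(25, seed = 13)
  tr <- imageTruth(img)
  expect_equal(tr$count, 25L)
  expect_length(tr$masks, 25L)
  # disjoint grains
  overlap <- Reduce(`+`, lapply(tr$masks, function(m) m * 1L))
  expect_lte(max(overlap), 1L)

  # curvature 0: grain centroids collinear within 1 px
  cents <- t(vapply(tr$masks, function(m) {
    idx <- which(m, arr.ind = TRUE); colMeans(idx)
  }, numeric(2)))
  expect_lt(max(abs(cents[, 2L] - mean(cents[, 2L]))), 1)

  # grain pixels sit inside the default yellow-brown HSV bounds
  cm <- hsvColourMask(spikePixels(img))
  gm <- Reduce(`|`, tr$masks)
  expect_gt(sum(cm & gm) / sum(gm), 0.95)

  expect_identical(spikePixels(simulateSpikeImage(5, seed = 4)),
                   spikePixels(simulateSpikeImage(5, seed = 4)))
  expect_error(simulateSpikeImage(50, height = 100), "incompatible")

  clut <- simulateSpikeImage(8, background = "cluttered", seed = 14)
  expect_false(is.null(imageTruth(clut)$clutter_band))
})
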