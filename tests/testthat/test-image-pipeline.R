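# Spike isolation chain: cropping, HSV/value masks, Otsu, morphology,
# hull, finalisation, composite, Canny overlay, full pipeline.

rgbFromHsv8 <- function(H, S, V) {
  # build a 1x1 8-bit RGB image from OpenCV-convention HSV values
  col <- grDevices::col2rgb(grDevices::hsv(H * 2 / 360, S / 255, V / 255))
  array(as.numeric(col), dim = c(1L, 1L, 3L))
}

test_that("cropping removes the configured margins and the clutter band", {
  img <- array(7, dim = c(100L, 100L, 3L))
  expect_identical(cropLabelRegion(img, c(0, 0, 0, 0)), img)
  expect_equal(dim(cropLabelRegion(img, c(0, 10, 0, 0))), c(90L, 100L, 3L))
  expect_error(cropLabelRegion(img, c(60, 60, 0, 0)), "entire image")

  clut <- simulateSpikeImage(8, background = "cluttered", seed = 1)
  band <- imageTruth(clut)$clutter_band
  cropped <- cropLabelRegion(spikePixels(clut),
                             c(0, band[2L] - band[1L] + 1L, 0, 0))
  # label/ruler pixels are bright near-white; none survive the crop
  mx <- pmin(cropped[, , 1L], cropped[, , 2L], cropped[, , 3L])
  expect_lt(max(mx), 230)
})

test_that("HSV and value masks implement inclusive 8-bit bounds", {
  black <- array(0, dim = c(4L, 4L, 3L))
  expect_false(any(hsvColourMask(black)))
  expect_true(all(hsvColourMask(black, c(0, 179), c(0, 255), c(0, 255))))

  px <- rgbFromHsv8(25, 180, 200)
  expect_true(hsvColourMask(px)[1L, 1L])
  expect_false(hsvColourMask(rgbFromHsv8(90, 180, 200))[1L, 1L])

  expect_true(all(valueChannelMask(black, 0)))
  expect_error(valueChannelMask(black, 300), "\\[0, 255\\]")

  img <- spikePixels(simulateSpikeImage(6, seed = 2))
  cm <- hsvColourMask(img); vm <- valueChannelMask(img)
  expect_true(all((cm | vm)[cm]))            # OR is a superset of each mask
  expect_true(all((cm | vm)[vm]))
})

test_that("Otsu matches the exhaustive search oracle and flags degeneracy", {
  # two-spike histogram
  g <- matrix(c(rep(10L, 50), rep(200L, 50)), 10L, 10L)
  res <- otsuThreshold(g)
  expect_equal(res$threshold, otsuOracle(g))
  expect_identical(res$mask, g > res$threshold)

  const <- matrix(42L, 8L, 8L)
  resC <- otsuThreshold(const)
  expect_true(resC$degenerate)
  expect_false(any(resC$mask))

  set.seed(42)
  for (i in 1:50) {
    r <- matrix(sample.int(256L, 256L, replace = TRUE) - 1L, 16L, 16L)
    expect_equal(otsuThreshold(r)$threshold, otsuOracle(r))
  }
})

test_that("opening breaks one-pixel bridges while preserving blocks", {
  m <- matrix(FALSE, 30L, 30L)
  m[5:14, 5:14] <- TRUE
  m[5:14, 17:26] <- TRUE
  m[9, 15:16] <- TRUE                       # 1-px bridge
  out <- refineMask(m, 2L)
  expect_false(any(out[9, 15:16]))          # bridge gone
  expect_true(all(out[6:13, 6:13]))         # blocks retained
  expect_equal(max(grainQTL:::.labelComponents(out)), 2L)
  expect_true(all(m[out]))                  # opening is anti-extensive
  expect_false(any(refineMask(matrix(FALSE, 5L, 5L), 2L)))
})

test_that("largest-component hull fills concavities and matches the brute-force hull", {
  # max-area rule: two far-apart components
  m <- matrix(FALSE, 60L, 60L)
  m[5:27, 5:27] <- TRUE                     # area 529
  m[50:56, 50:56] <- TRUE                   # area 49
  h <- largestHullMask(m, dilateKernel = 1L)
  expect_true(all(h[5:27, 5:27]))
  expect_false(any(h[50:56, 50:56]))

  # square blob dilated by a 15 x 15 element grows 7 px per side
  m2 <- matrix(FALSE, 40L, 40L)
  m2[15:20, 15:20] <- TRUE
  h2 <- largestHullMask(m2, dilateKernel = 15L)
  expect_true(all(h2[8:27, 8:27]))
  expect_false(any(h2[1:7, ])); expect_false(any(h2[28:40, ]))

  # C shape: hull area exceeds component area
  cshape <- matrix(FALSE, 20L, 20L)
  cshape[5:15, 5:7] <- TRUE; cshape[5:7, 5:15] <- TRUE
  cshape[13:15, 5:15] <- TRUE
  h3 <- largestHullMask(cshape, dilateKernel = 1L)
  expect_gt(sum(h3), sum(cshape))
  expect_true(all(h3[cshape]))

  expect_error(largestHullMask(matrix(FALSE, 4L, 4L)), "no spike")

  # hull fill vs all-pairs brute force on random point sets
  set.seed(7)
  for (rep in 1:3) {
    m4 <- matrix(FALSE, 15L, 15L)
    pts <- cbind(sample.int(15L, 40L, TRUE), sample.int(15L, 40L, TRUE))
    m4[unique(pts)] <- TRUE
    filled <- grainQTL:::.hullFill(m4)
    ptmat <- which(m4, arr.ind = TRUE)
    for (r in 1:15) for (cc in 1:15)
      expect_identical(filled[r, cc], inHullBrute(c(r, cc), ptmat))
  }
})

test_that("finalize and apply behave as strict pixelwise AND / masking", {
  a <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2L, 2L)
  allT <- matrix(TRUE, 2L, 2L)
  expect_identical(finalizeMask(a, allT), a)
  expect_false(any(finalizeMask(a, !a)))
  expect_lte(sum(finalizeMask(a, allT)), min(sum(a), sum(allT)))
  expect_error(finalizeMask(a, matrix(TRUE, 3L, 3L)), "mismatch")

  img <- spikePixels(simulateSpikeImage(5, seed = 3))
  d <- dim(img)
  expect_identical(applyMask(img, matrix(TRUE, d[1L], d[2L])), img)
  expect_true(all(applyMask(img, matrix(FALSE, d[1L], d[2L])) == 0))
  expect_error(applyMask(img, matrix(TRUE, 3L, 3L)), "mismatch")
})

test_that("Canny overlay marks square boundaries and nothing on constants", {
  const <- array(100, dim = c(30L, 30L, 3L))
  expect_identical(cannyOverlay(const), const)

  sq <- array(0, dim = c(40L, 40L, 3L))
  sq[10:30, 10:30, ] <- 220
  ov <- cannyOverlay(sq)
  expect_equal(dim(ov), dim(sq))
  edges <- ov[, , 2L] == 255 & ov[, , 1L] == 0
  expect_gt(sum(edges), 0)
  # every edge pixel lies within 3 px of the true square boundary
  idx <- which(edges, arr.ind = TRUE)
  nearB <- (abs(idx[, 1L] - 10) <= 3 | abs(idx[, 1L] - 30) <= 3) &
    idx[, 2L] >= 7 & idx[, 2L] <= 33 |
    (abs(idx[, 2L] - 10) <= 3 | abs(idx[, 2L] - 30) <= 3) &
    idx[, 1L] >= 7 & idx[, 1L] <= 33
  expect_true(all(nearB))
  expect_error(cannyOverlay(sq, 150, 50), "cannyLow")
})

test_that("the full pipeline isolates the spike and is deterministic", {
  img <- spikePixels(simulateSpikeImage(12, curvature = 8, seed = 4))
  r1 <- preprocessSpike(img)
  expect_gt(sum(finalMask(r1)), 0)
  expect_true(all(finalMask(r1)[finalMask(r1) & !r1@hullMask] == FALSE))
  expect_true(all(finalMask(r1) | (composite(r1)[, , 1L] == 0)))
  # composite is black exactly off the final mask
  off <- !finalMask(r1)
  for (ch in 1:3) expect_true(all(composite(r1)[, , ch][off] == 0))

  r2 <- preprocessSpike(img)
  expect_identical(r1@finalMask, r2@finalMask)
  expect_identical(composite(r1), composite(r2))

  blank <- array(0, dim = c(50L, 50L, 3L))
  expect_error(preprocessSpike(blank), "hull stage")
})
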