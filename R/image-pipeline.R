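# Spike isolation chain: crop -> HSV/value masks -> grey + blur -> Otsu ->
# morphological refinement -> largest-component convex hull -> final mask ->
# black-background composite. Canny edges are an annotation aid only.

#' Default pipeline configuration
#'
#' HSV bounds use the 8-bit convention H in `[0,179]`, S and V in
#' `[0,255]`. The yellow-brown hue band (H 10-40, S >= 50, V >= 50), blur
#' kernel and Canny thresholds are tunable defaults chosen for the
#' synthetic spike generator; every field can be overridden.
#'
#' @return list of pipeline parameters.
#' @export
pipelineConfig <- function() {
  list(cropMargins = c(top = 0L, bottom = 0L, left = 0L, right = 0L),
       hueBounds = c(10L, 40L), satBounds = c(50L, 255L),
       valBounds = c(50L, 255L), vThreshold = 120L,
       blurKernel = 5L, refineKernel = 2L, hullDilateKernel = 15L,
       cannyLow = 50, cannyHigh = 150)
}

#' Crop fixed margins from an image
#'
#' Removes label/ruler clutter placed in known border bands. Margins are
#' pixels per edge, in the order top, bottom, left, right.
#'
#' @param image h x w x 3 array (or h x w matrix).
#' @param margins integer length-4 (top, bottom, left, right).
#' @return the interior sub-raster.
#' @export
cropLabelRegion <- function(image, margins = c(0L, 0L, 0L, 0L)) {
  margins <- as.integer(rep_len(margins, 4L))
  if (any(margins < 0)) stop("margins must be non-negative")
  d <- dim(image)
  r0 <- 1L + margins[1L]; r1 <- d[1L] - margins[2L]
  c0 <- 1L + margins[3L]; c1 <- d[2L] - margins[4L]
  if (r0 > r1 || c0 > c1) stop("margins consume the entire image")
  if (length(d) == 3L) image[r0:r1, c0:c1, , drop = FALSE]
  else image[r0:r1, c0:c1, drop = FALSE]
}

#' HSV colour mask
#'
#' A pixel is kept iff all three HSV channels fall inside their inclusive
#' bounds (H in the 8-bit `[0,179]` convention).
#'
#' @param image h x w x 3 RGB array, 8-bit.
#' @param hueBounds,satBounds,valBounds inclusive `[lo, hi]` bounds.
#' @return logical matrix.
#' @export
hsvColourMask <- function(image, hueBounds = c(10L, 40L),
                          satBounds = c(50L, 255L),
                          valBounds = c(50L, 255L)) {
  .checkRGB(image)
  if (hueBounds[1L] < 0 || hueBounds[2L] > 179)
    stop("hue bounds must lie in [0, 179]")
  for (b in list(satBounds, valBounds))
    if (b[1L] < 0 || b[2L] > 255) stop("S/V bounds must lie in [0, 255]")
  hsv <- .rgbToHsv8(image)
  hsv$H >= hueBounds[1L] & hsv$H <= hueBounds[2L] &
    hsv$S >= satBounds[1L] & hsv$S <= satBounds[2L] &
    hsv$V >= valBounds[1L] & hsv$V <= valBounds[2L]
}

#' Value-channel mask
#'
#' Keeps pixels whose HSV value channel is at least `vThreshold`; combined
#' downstream with the colour mask by pixelwise OR to capture bright spike
#' regions the hue band misses.
#'
#' @param image h x w x 3 RGB array, 8-bit.
#' @param vThreshold threshold in `[0, 255]`.
#' @return logical matrix.
#' @export
valueChannelMask <- function(image, vThreshold = 120L) {
  .checkRGB(image)
  if (vThreshold < 0 || vThreshold > 255) stop("vThreshold must be in [0, 255]")
  V <- .rgbToHsv8(image)$V
  V >= vThreshold
}

#' Otsu threshold
#'
#' Chooses the 8-bit threshold maximising the between-class variance of the
#' 256-bin intensity histogram; the mask keeps intensities strictly above
#' the threshold. Ties are broken towards the smallest threshold. A
#' constant image is flagged degenerate and yields an all-false mask.
#'
#' @param gray single-channel matrix of 8-bit intensities.
#' @return list with `threshold` (integer), `mask` (logical matrix) and
#'   `degenerate` (logical).
#' @export
otsuThreshold <- function(gray) {
  if (!is.matrix(gray)) stop("gray must be a single-channel matrix")
  if (min(gray) < 0 || max(gray) > 255) stop("intensities must lie in [0, 255]")
  h <- tabulate(as.integer(gray) + 1L, nbins = 256L)
  n <- sum(h)
  if (sum(h > 0L) < 2L) {
    return(list(threshold = as.integer(gray[1L]),
                mask = matrix(FALSE, nrow(gray), ncol(gray)),
                degenerate = TRUE))
  }
  lev <- 0:255
  w0 <- cumsum(h)                       # pixels with intensity <= t
  s0 <- cumsum(h * lev)
  stot <- s0[256L]
  valid <- w0 > 0L & w0 < n             # both classes non-empty
  mu0 <- s0 / w0
  mu1 <- (stot - s0) / (n - w0)
  sb <- (w0 / n) * (1 - w0 / n) * (mu0 - mu1)^2
  sb[!valid] <- -Inf
  t <- lev[which.max(sb)]               # which.max takes the first maximum
  list(threshold = as.integer(t), mask = gray > t, degenerate = FALSE)
}

#' Refine a binary mask by morphological opening
#'
#' Opening (erosion then dilation) with a small square element breaks weak
#' pixel bridges between the spike and background artefacts while
#' preserving grain bodies.
#'
#' @param mask logical matrix.
#' @param kernel side of the square structuring element (default 2).
#' @return logical matrix.
#' @export
refineMask <- function(mask, kernel = 2L) {
  if (kernel < 1) stop("kernel must be >= 1")
  if (kernel == 1L) return(mask)
  .binDilate(.binErode(mask, kernel), kernel)
}

#' Convex hull of the largest component, dilated
#'
#' Selects the largest 8-connected component by pixel area (the presumed
#' spike), fills its convex hull to close concavities, and dilates once
#' with a square element to give the silhouette a safety margin.
#'
#' @param mask logical matrix (non-empty).
#' @param dilateKernel side of the square dilation element (default 15).
#' @return logical matrix covering the hull region.
#' @export
largestHullMask <- function(mask, dilateKernel = 15L) {
  if (!any(mask)) stop("no spike found: mask is empty")
  lab <- .labelComponents(mask)
  areas <- tabulate(lab[lab > 0L])
  big <- which.max(areas)
  hull <- .hullFill(lab == big)
  .binDilate(hull, dilateKernel)
}

#' Combine the Otsu mask with the hull mask
#'
#' Pixelwise AND: keeps Otsu-foreground pixels inside the dilated hull.
#'
#' @param otsuMask,hullMask logical matrices of identical shape.
#' @return logical matrix.
#' @export
finalizeMask <- function(otsuMask, hullMask) {
  if (!all(dim(otsuMask) == dim(hullMask))) stop("mask shape mismatch")
  otsuMask & hullMask
}

#' Apply a binary mask to an image
#'
#' Keeps original pixels where the mask is true and replaces everything
#' else with a high-contrast black background.
#'
#' @param image h x w x 3 RGB array.
#' @param mask logical matrix matching the image shape.
#' @return RGB array.
#' @export
applyMask <- function(image, mask) {
  .checkRGB(image)
  if (!all(dim(image)[1:2] == dim(mask))) stop("mask shape mismatch")
  out <- image
  for (ch in 1:3) {
    layer <- out[, , ch]
    layer[!mask] <- 0L
    out[, , ch] <- layer
  }
  out
}

# Bilateral filter on an 8-bit grey matrix (window diameter d).
.bilateral <- function(gray, d = 9L, sigmaColor = 75, sigmaSpace = 75) {
  r <- (as.integer(d) - 1L) %/% 2L
  acc <- matrix(0, nrow(gray), ncol(gray))
  wsum <- matrix(0, nrow(gray), ncol(gray))
  for (dr in -r:r) for (dc in -r:r) {
    nb <- .shiftMat(gray, dr, dc, "replicate")
    w <- exp(-(dr * dr + dc * dc) / (2 * sigmaSpace^2)) *
      exp(-(nb - gray)^2 / (2 * sigmaColor^2))
    acc <- acc + w * nb
    wsum <- wsum + w
  }
  acc / wsum
}

#' Canny edge overlay
#'
#' Greyscale conversion, bilateral filtering, Sobel gradients, non-maximum
#' suppression and double-threshold hysteresis; detected edges are painted
#' green over the input. The overlay is an aid for manual grain annotation
#' only and never feeds downstream mask computation.
#'
#' @param image h x w x 3 RGB array.
#' @param cannyLow,cannyHigh hysteresis thresholds (low < high).
#' @return RGB array of the same shape with edge pixels highlighted.
#' @export
cannyOverlay <- function(image, cannyLow = 50, cannyHigh = 150) {
  .checkRGB(image)
  if (cannyLow >= cannyHigh) stop("cannyLow must be < cannyHigh")
  g <- .bilateral(.toGray(image))
  gx <- .shiftMat(g, 0, -1, "replicate") - .shiftMat(g, 0, 1, "replicate") +
    0.5 * (.shiftMat(g, -1, -1, "replicate") - .shiftMat(g, -1, 1, "replicate")) +
    0.5 * (.shiftMat(g, 1, -1, "replicate") - .shiftMat(g, 1, 1, "replicate"))
  gy <- .shiftMat(g, -1, 0, "replicate") - .shiftMat(g, 1, 0, "replicate") +
    0.5 * (.shiftMat(g, -1, -1, "replicate") - .shiftMat(g, 1, -1, "replicate")) +
    0.5 * (.shiftMat(g, -1, 1, "replicate") - .shiftMat(g, 1, 1, "replicate"))
  mag <- sqrt(gx^2 + gy^2)
  # non-maximum suppression over 4 quantised gradient directions
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)
  keep <- matrix(FALSE, nrow(g), ncol(g))
  nbr <- list(`0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 0L),
              `3` = c(1L, -1L))
  for (s in 0:3) {
    dd <- nbr[[as.character(s)]]
    m1 <- .shiftMat(mag, dd[1L], dd[2L], 0)
    m2 <- .shiftMat(mag, -dd[1L], -dd[2L], 0)
    keep <- keep | (sector == s & mag >= m1 & mag >= m2)
  }
  strong <- keep & mag >= cannyHigh
  weak <- keep & mag >= cannyLow
  # hysteresis: grow strong edges through weak pixels (8-connected)
  repeat {
    grown <- .binDilate(strong, 3L) & weak
    if (identical(grown, strong)) break
    strong <- grown
  }
  out <- image
  layer <- out[, , 2L]; layer[strong] <- 255L; out[, , 2L] <- layer
  for (ch in c(1L, 3L)) {
    layer <- out[, , ch]; layer[strong] <- 0L; out[, , ch] <- layer
  }
  out
}

#' Run the full spike isolation pipeline
#'
#' Stages: crop the clutter margins; build the HSV colour mask and
#' value-channel mask and OR them; zero the background with the combined
#' mask; greyscale and Gaussian-blur; Otsu threshold; refine by opening to
#' break weak bridges; take the largest component's dilated convex hull;
#' AND the Otsu mask with the hull (the final mask); composite the original
#' pixels over black. All intermediates are returned for debugging.
#'
#' @param image h x w x 3 RGB array, 8-bit.
#' @param config list as from [pipelineConfig()] (fields can be overridden
#'   individually).
#' @param edges also compute the Canny annotation overlay (slower;
#'   annotation aid only).
#' @return A [PreprocessResult-class].
#' @examples
#' img <- simulateSpikeImage(8, seed = 1)
#' res <- preprocessSpike(spikePixels(img))
#' res
#' @export
preprocessSpike <- function(image, config = pipelineConfig(), edges = FALSE) {
  cfg <- utils::modifyList(pipelineConfig(), as.list(config))
  .checkRGB(image)
  cropped <- cropLabelRegion(image, cfg$cropMargins)
  colourMask <- hsvColourMask(cropped, cfg$hueBounds, cfg$satBounds,
                              cfg$valBounds)
  valueMask <- valueChannelMask(cropped, cfg$vThreshold)
  combined <- colourMask | valueMask
  masked <- applyMask(cropped, combined)
  gray <- .gaussBlur(.toGray(masked), cfg$blurKernel)
  ot <- otsuThreshold(gray)
  refined <- refineMask(ot$mask, cfg$refineKernel)
  hullMask <- tryCatch(
    largestHullMask(refined, cfg$hullDilateKernel),
    error = function(e) stop("hull stage: ", conditionMessage(e), call. = FALSE))
  fin <- finalizeMask(ot$mask, hullMask)
  comp <- applyMask(cropped, fin)
  overlay <- if (edges) cannyOverlay(comp, cfg$cannyLow, cfg$cannyHigh)
             else array(0L, c(0L, 0L, 3L))
  new("PreprocessResult", cropped = cropped, colourMask = colourMask,
      valueMask = valueMask, otsuMask = ot$mask, hullMask = hullMask,
      finalMask = fin, composite = comp, edgeOverlay = overlay,
      otsuThreshold = ot$threshold, degenerate = ot$degenerate)
}
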