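#' Simulate a two-row barley spike image with exact ground truth
#'
#' Renders a synthetic spike: elliptical grains whose centroids lie on a
#' (possibly curved) quadratic rachis, tilted alternately left/right of the
#' axis in the two-row pattern, in a yellow-brown hue band, on a dark or
#' cluttered background. A rachis stem connects the grains so the spike
#' forms a single connected silhouette, as in a real image. Optional thin
#' awns extend from grain tips; with `awnCrossing` they slant across
#' neighbouring grains (the main segmentation nuisance). In cluttered mode
#' a white label and ruler are placed inside a bottom clutter band so that
#' cropping that band removes them deterministically.
#'
#' Ground truth records the grain count, one pixel mask per grain and the
#' rachis curve parameters. Truth masks are exact: a pixel belongs to a
#' grain iff its centre satisfies that grain's ellipse equation, whatever
#' is painted over it later (awns may cross grains).
#'
#' @param nGrains number of grains (>= 1).
#' @param curvature lateral displacement, in pixels, of the rachis at its
#'   ends relative to its midpoint (0 = straight; grain centroids are then
#'   collinear).
#' @param awnCrossing logical; render awns that cross grain bodies.
#' @param awns logical; render awns at all.
#' @param background "dark" or "cluttered".
#' @param width image width in pixels.
#' @param height image height in pixels, or `NULL` to fit the spike.
#' @param clutterBand height in pixels of the bottom band reserved for
#'   label/ruler clutter.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A [SpikeImage-class].
#' @examples
#' img <- simulateSpikeImage(10, seed = 1)
#' imageTruth(img)$count   # 10
#' @export
simulateSpikeImage <- function(nGrains, curvature = 0, awnCrossing = FALSE,
                               awns = FALSE, background = c("dark", "cluttered"),
                               width = 240L, height = NULL,
                               clutterBand = 60L, seed = NULL) {
  background <- match.arg(background)
  if (nGrains < 1) stop("nGrains must be >= 1")
  ry <- 8; rx <- 5                      # grain semi-axes (px)
  step <- 18                            # vertical centroid spacing (px)
  topPad <- 50; botPad <- 40 + if (background == "cluttered") clutterBand else 0
  needH <- as.integer(ceiling(nGrains * step + topPad + botPad))
  if (is.null(height)) height <- max(needH, 200L)
  height <- as.integer(height); width <- as.integer(width)
  if (height < needH)
    stop("nGrains incompatible with image size: need height >= ", needH)
  if (width < 80L) stop("width too small for a spike")
  .withSeed(seed, {
    img <- array(0, dim = c(height, width, 3L))
    # dark background with mild sensor noise
    for (ch in 1:3)
      img[, , ch] <- matrix(stats::runif(height * width, 3, 20), height, width)

    y0 <- topPad; y1 <- y0 + (nGrains - 1) * step
    ymid <- (y0 + y1) / 2
    cx <- width / 2
    halfspan <- max((y1 - y0) / 2, 1)
    rachisX <- function(y) cx + curvature * ((y - ymid) / halfspan)^2

    painted <- matrix(FALSE, height, width)   # every spike pixel (rachis/grain/awn)

    # rachis stem (connects grains into one silhouette; not grain truth)
    rys <- seq(max(1, y0 - ry - 4), min(height, y1 + ry + 4))
    for (y in rys) {
      xc <- round(rachisX(y))
      xs <- max(1, xc - 2):min(width, xc + 2)
      for (ch in 1:3) img[y, xs, ch] <- c(150, 120, 50)[ch]
      painted[y, xs] <- TRUE
    }

    yc <- y0 + (seq_len(nGrains) - 1) * step
    xc <- rachisX(yc)
    tilt <- rep(c(25, -25), length.out = nGrains) * pi / 180
    masks <- vector("list", nGrains)
    rowIdx <- matrix(rep(seq_len(height), width), height, width)
    colIdx <- matrix(rep(seq_len(width), each = height), height, width)
    for (i in seq_len(nGrains)) {
      dy <- rowIdx - yc[i]; dx <- colIdx - xc[i]
      u <- dy * cos(tilt[i]) - dx * sin(tilt[i])
      v <- dy * sin(tilt[i]) + dx * cos(tilt[i])
      m <- (u / ry)^2 + (v / rx)^2 <= 1
      masks[[i]] <- m
      painted <- painted | m
      base <- c(205, 165, 70) + stats::runif(3, -8, 8)
      for (ch in 1:3) {
        layer <- img[, , ch]
        layer[m] <- pmin(pmax(base[ch] + stats::rnorm(sum(m), 0, 4), 0), 255)
        img[, , ch] <- layer
      }
    }

    if (awns || awnCrossing) {
      awnLen <- 50
      slope <- if (awnCrossing) 0.45 else 0.08   # dx per step up
      for (i in seq_len(nGrains)) {
        sgn <- if (i %% 2 == 0) 1 else -1
        ys <- round(yc[i] - ry - seq_len(awnLen))
        xs <- round(xc[i] + sgn * slope * seq_len(awnLen))
        ok <- ys >= 1 & ys <= height & xs >= 1 & xs <= width
        for (ch in 1:3) {
          layer <- img[, , ch]
          layer[cbind(ys[ok], xs[ok])] <- c(180, 150, 70)[ch]
          img[, , ch] <- layer
        }
        painted[cbind(ys[ok], xs[ok])] <- TRUE
      }
    }

    if (background == "cluttered") {
      band0 <- height - clutterBand + 1L
      # white paper label, bottom-right
      lr <- (band0 + 8L):min(height, band0 + 40L)
      lc <- (width - 70L):(width - 15L)
      for (ch in 1:3) img[lr, lc, ch] <- 245
      # ruler with dark ticks, bottom-left
      rr <- (band0 + 15L):min(height, band0 + 30L)
      rc <- 15L:130L
      for (ch in 1:3) img[rr, rc, ch] <- 235
      ticks <- seq(15L, 130L, by = 10L)
      for (ch in 1:3) img[rr[1:6], ticks, ch] <- 30
    }

    pix <- array(as.integer(pmin(pmax(round(img), 0), 255)),
                 dim = c(height, width, 3L))
    new("SpikeImage", pixels = pix,
        truth = list(count = as.integer(nGrains), masks = masks,
                     spike_mask = painted,
                     rachis = list(cx = cx, curvature = curvature,
                                   y0 = y0, y1 = y1),
                     clutter_band = if (background == "cluttered")
                       c(height - clutterBand + 1L, height) else NULL),
        background = background)
  })
}
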