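# Independent oracles used across the suite. These deliberately use
# different algorithms (enumeration, explicit normal equations, exhaustive
# search) from the implementation paths they check.

# Exhaustive hidden-path enumeration of the two-state genotype HMM for one
# line on one chromosome (<= 8 markers or so).
enumGenoprob <- function(calls, pos_cM, errorProb) {
  m <- length(calls)
  obs <- match(calls, c("A", "B")) - 1L          # 0 / 1 / NA
  rf <- haldane(diff(pos_cM))
  states <- as.matrix(expand.grid(rep(list(0:1), m)))
  w <- apply(states, 1L, function(s) {
    p <- 0.5
    for (k in seq_len(m)) {
      if (!is.na(obs[k]))
        p <- p * (if (s[k] == obs[k]) 1 - errorProb else errorProb)
      if (k < m) p <- p * (if (s[k + 1L] == s[k]) 1 - rf[k] else rf[k])
    }
    p
  })
  vapply(seq_len(m), function(k) sum(w[states[, k] == 0L]) / sum(w),
         numeric(1))                              # posterior P(AA) per marker
}

# Per-marker HK LOD via explicit normal equations.
hkLodOracle <- function(y, X0, g) {
  n <- length(y)
  rss <- function(X) {
    b <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% b)^2)
  }
  (n / 2) * log10(rss(X0) / rss(cbind(X0, g)))
}

# Exhaustive 256-point Otsu search straight from the pixel values.
otsuOracle <- function(gray) {
  v <- as.vector(gray)
  best <- -Inf; bt <- NA_integer_
  for (t in 0:255) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best) { best <- sb; bt <- t }        # strict: keeps smallest t
  }
  bt
}

# Brute-force convex-hull membership: p is inside iff for every directed
# point pair that supports the whole set on one side, p lies on that side.
inHullBrute <- function(p, pts, eps = 1e-9) {
  n <- nrow(pts)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dy <- pts[j, 1L] - pts[i, 1L]; dx <- pts[j, 2L] - pts[i, 2L]
    cr <- dx * (pts[, 1L] - pts[i, 1L]) - dy * (pts[, 2L] - pts[i, 2L])
    if (all(cr <= eps)) {
      crp <- dx * (p[1L] - pts[i, 1L]) - dy * (p[2L] - pts[i, 2L])
      if (crp > eps) return(FALSE)
    }
  }
  TRUE
}

# Small shared fixtures -------------------------------------------------

tinyMap <- function(markersPer = c(10L, 10L), len = c(100, 100), seed = 11) {
  simulateMap(markersPer, len, seed = seed)
}

# A population ready for scanning, with an optional planted QTL.
makeScanPop <- function(nLines = 100L, markersPer = c(20L, 20L),
                        len = c(100, 100), qtlMarker = NULL, effect = 1.2,
                        sdE = 2.8, seed = 1) {
  map <- simulateMap(markersPer, len, seed = seed)
  g <- simulateDHGenotypes(map, nLines, seed = seed + 1L)
  set.seed(seed + 2L)
  y <- stats::rnorm(nLines, 25.4, sdE)
  if (!is.null(qtlMarker)) {
    x <- ifelse(trueCalls(g)[, qtlMarker] == "A", 0.5, -0.5)
    y <- y + effect * x
  }
  list(map = map, genotypes = g, prob = calcGenoprob(g, map),
       phenotype = stats::setNames(y, lineNames(g)))
}
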