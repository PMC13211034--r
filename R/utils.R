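# Internal helpers: seeded evaluation, raster shifts, binary morphology,
# 8-connected labelling, colour-space conversion, convex-hull rasterisation.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Shift a matrix by (dr, dc); vacated cells get `fill`, or replicate the
# nearest border row/column when fill = "replicate".
.shiftMat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- seq_len(nr) - dr
  ci <- seq_len(nc) - dc
  if (identical(fill, "replicate")) {
    ri <- pmin(pmax(ri, 1L), nr)
    ci <- pmin(pmax(ci, 1L), nc)
    return(m[ri, ci, drop = FALSE])
  }
  out <- matrix(fill, nr, nc)
  rok <- ri >= 1L & ri <= nr
  cok <- ci >= 1L & ci <= nc
  out[rok, cok] <- m[ri[rok], ci[cok], drop = FALSE]
  out
}

# Window offsets for a k x k square structuring element anchored at its
# centre (even k anchors at the top-left of the central 2x2, matching the
# usual image-library convention).
.seOffsets <- function(k) {
  a <- (k - 1L) %/% 2L
  seq.int(-a, k - 1L - a)
}

# Separable binary erosion / dilation with a square element; pixels outside
# the image are treated as background.
.binErode <- function(mask, k) {
  off <- .seOffsets(as.integer(k))
  out <- mask
  for (d in off[off != 0L]) out <- out & .shiftMat(mask, -d, 0L, FALSE)
  res <- out
  for (d in off[off != 0L]) res <- res & .shiftMat(out, 0L, -d, FALSE)
  res
}

.binDilate <- function(mask, k) {
  off <- .seOffsets(as.integer(k))
  out <- mask
  for (d in off[off != 0L]) out <- out | .shiftMat(mask, d, 0L, FALSE)
  res <- out
  for (d in off[off != 0L]) res <- res | .shiftMat(out, 0L, d, FALSE)
  res
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# labels touching only diagonally are merged afterwards with union-find.
.labelComponents <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (dc in c(-1L, 1L)) {
    nb <- .shiftMat(lab, 1L, dc, 0L)
    hit <- lab > 0L & nb > 0L & lab != nb
    if (any(hit)) {
      pairs <- unique(cbind(lab[hit], nb[hit]))
      for (i in seq_len(nrow(pairs))) unite(pairs[i, 1L], pairs[i, 2L])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# RGB array (h x w x 3, 0..255) -> 8-bit HSV in the OpenCV convention:
# H in [0,179] (degrees / 2), S and V in [0,255].
.rgbToHsv8 <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3L] == 3L)
  d <- dim(img)
  hsv <- grDevices::rgb2hsv(r = as.vector(img[, , 1L]),
                            g = as.vector(img[, , 2L]),
                            b = as.vector(img[, , 3L]),
                            maxColorValue = 255)
  list(H = matrix(as.integer(round(hsv[1L, ] * 180)) %% 180L, d[1L], d[2L]),
       S = matrix(as.integer(round(hsv[2L, ] * 255)), d[1L], d[2L]),
       V = matrix(as.integer(round(hsv[3L, ] * 255)), d[1L], d[2L]))
}

# Standard luma greyscale, rounded to 8-bit.
.toGray <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3L] == 3L)
  g <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  matrix(as.integer(pmin(pmax(round(g), 0), 255)), dim(img)[1L], dim(img)[2L])
}

# Separable Gaussian blur on an 8-bit single-channel matrix; sigma derived
# from the kernel size by the usual 0.3*((k-1)/2 - 1) + 0.8 rule.
.gaussBlur <- function(gray, k = 5L) {
  k <- as.integer(k)
  stopifnot(k >= 1L, k %% 2L == 1L)
  if (k == 1L) return(gray)
  sigma <- 0.3 * ((k - 1) * 0.5 - 1) + 0.8
  off <- .seOffsets(k)
  w <- exp(-off^2 / (2 * sigma^2))
  w <- w / sum(w)
  acc <- matrix(0, nrow(gray), ncol(gray))
  for (i in seq_along(off)) acc <- acc + w[i] * .shiftMat(gray, off[i], 0L, "replicate")
  out <- matrix(0, nrow(gray), ncol(gray))
  for (i in seq_along(off)) out <- out + w[i] * .shiftMat(acc, 0L, off[i], "replicate")
  matrix(as.integer(pmin(pmax(round(out), 0), 255)), nrow(gray), ncol(gray))
}

# Fill the convex hull of the TRUE pixels of `mask` (pixel-centre polygon,
# inclusive boundary). Collinear point sets fall back to the points
# themselves. Implemented as a half-plane test over the bounding box so the
# semantics match an all-pairs brute-force hull exactly.
.hullFill <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (nrow(idx) == 0L) return(out)
  x <- idx[, 2L]; y <- idx[, 1L]
  h <- grDevices::chull(x, y)
  if (length(h) < 3L) {            # degenerate: collinear or tiny set
    out[idx] <- TRUE
    return(out)
  }
  hx <- x[h]; hy <- y[h]
  nv <- length(h)
  jj <- c(seq_len(nv)[-1L], 1L)
  ccw <- sum(hx * hy[jj] - hx[jj] * hy) > 0   # shoelace orientation
  r0 <- min(y); r1 <- max(y); c0 <- min(x); c1 <- max(x)
  pr <- rep(r0:r1, times = c1 - c0 + 1L)
  pc <- rep(c0:c1, each = r1 - r0 + 1L)
  inside <- rep(TRUE, length(pr))
  eps <- 1e-9
  for (i in seq_len(nv)) {
    j <- jj[i]
    cross <- (hx[j] - hx[i]) * (pr - hy[i]) - (hy[j] - hy[i]) * (pc - hx[i])
    inside <- inside & if (ccw) cross >= -eps else cross <= eps
  }
  out[cbind(pr[inside], pc[inside])] <- TRUE
  out
}

# Validate an 8-bit RGB image array.
.checkRGB <- function(image) {
  if (!(is.array(image) && length(dim(image)) == 3L && dim(image)[3L] == 3L))
    stop("image must be an h x w x 3 array")
  if (min(image) < 0 || max(image) > 255)
    stop("image channels must lie in [0, 255]")
  invisible(TRUE)
}
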