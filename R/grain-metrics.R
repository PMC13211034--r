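#' Count grains on a final binary mask
#'
#' Classical stand-in for a learned detector: grains are 8-connected
#' components of the mask with area at least `minArea`. With
#' `split = TRUE`, the mask is first divided at local maxima of its
#' distance transform (watershed), which separates touching grains and
#' carves grain bodies off the connecting rachis; basins shallower than
#' `tolerance` are merged into their neighbours so one grain yields one
#' region.
#'
#' @param mask logical matrix.
#' @param minArea minimum component area in pixels.
#' @param split divide components at distance-transform maxima.
#' @param tolerance watershed merge tolerance (distance-map units).
#' @return list with `count` and `labels` (integer matrix; 0 = background).
#' @examples
#' img <- simulateSpikeImage(6, seed = 1)
#' truthMask <- Reduce(`|`, imageTruth(img)$masks)
#' countGrains(truthMask)$count   # 6
#' @export
countGrains <- function(mask, minArea = 30L, split = FALSE, tolerance = 1) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  if (!any(mask)) return(list(count = 0L, labels = matrix(0L, nrow(mask), ncol(mask))))
  if (split) {
    dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
    lab <- EBImage::watershed(dm, tolerance = tolerance, ext = 1L)
    lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  } else {
    lab <- .labelComponents(mask)
  }
  if (max(lab) == 0L) return(list(count = 0L, labels = lab))
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(areas >= minArea)
  out <- matrix(0L, nrow(mask), ncol(mask))
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  out[lab > 0L] <- relab[lab[lab > 0L]]
  list(count = length(keep), labels = out)
}

#' Model-vs-manual count agreement statistics
#'
#' Errors are defined as model - manual. Reports Pearson r and R^2, the
#' OLS fit of model counts on manual counts (slope, intercept), mean error
#' bias, mean absolute error, the sample (n-1) SD of errors, the error
#' range, and the fraction of pairs within k grains (inclusive,
#' |error| <= k) for k = 1, 2, 3.
#'
#' @param pairs data.frame with numeric columns `manual` and `model`
#'   (additional columns such as `sample_id` are ignored).
#' @return An [AgreementMetrics-class].
#' @examples
#' agreement(data.frame(manual = c(20, 25, 30), model = c(21, 24, 31)))
#' @export
agreement <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("manual", "model") %in% names(pairs)))
  manual <- as.numeric(pairs$manual)
  model <- as.numeric(pairs$model)
  if (length(manual) < 3L) stop("need at least 3 count pairs")
  if (any(manual < 1)) stop("manual counts must be >= 1")
  if (stats::sd(manual) == 0) stop("correlation undefined: manual counts are constant")
  err <- model - manual
  fit <- stats::lm(model ~ manual)
  r <- stats::cor(manual, model)
  wk <- vapply(1:3, function(k) mean(abs(err) <= k), numeric(1))
  new("AgreementMetrics",
      r = r, r2 = r^2,
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      mean_bias = mean(err), mae = mean(abs(err)),
      sd_error = stats::sd(err),
      min_error = min(err), max_error = max(err),
      within_k = stats::setNames(wk, c("within_1", "within_2", "within_3")),
      n = length(err))
}

#' Flatten agreement metrics to a named list
#'
#' Convenience for JSON emission and reporting.
#'
#' @param x an [AgreementMetrics-class].
#' @return named list of numbers.
#' @export
agreementAsList <- function(x) {
  stopifnot(is(x, "AgreementMetrics"))
  list(n = x@n, r = x@r, r2 = x@r2, slope = x@slope, intercept = x@intercept,
       mean_bias = x@mean_bias, mae = x@mae, sd_error = x@sd_error,
       min_error = x@min_error, max_error = x@max_error,
       within_1 = unname(x@within_k[1L]), within_2 = unname(x@within_k[2L]),
       within_3 = unname(x@within_k[3L]))
}
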