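#' Simulate detector count errors
#'
#' Emulates an automated grain detector whose counts deviate from manual
#' truth with a systematic bias and Gaussian noise:
#' `model_i = max(0, round(manual_i + bias + N(0, sd^2)))`. The default
#' bias/SD reproduce the study detector's error profile (mean error bias
#' -0.18 grains, error SD 1.86 grains).
#'
#' @param manual integer vector of manual grain counts.
#' @param bias systematic count bias in grains.
#' @param sd error standard deviation in grains (>= 0).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return integer vector of simulated model counts.
#' @examples
#' simulateCountErrors(c(20L, 25L), bias = 2, sd = 0)  # 22 27
#' @export
simulateCountErrors <- function(manual, bias = -0.18, sd = 1.86,
                                seed = NULL) {
  if (sd < 0) stop("sd must be non-negative")
  .withSeed(seed, {
    noise <- if (sd > 0) stats::rnorm(length(manual), 0, sd) else 0
    as.integer(pmax(0, round(manual + bias + noise)))
  })
}
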