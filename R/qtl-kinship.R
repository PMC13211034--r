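#' GRM kinship from genotype probabilities
#'
#' K[i,j] is the mean over markers of the probability that lines i and j
#' share the same genotype, sum over states of p_ig * p_jg; the diagonal is
#' set to 1 (a line shares all alleles with itself). With
#' `loco = TRUE` one matrix is returned per chromosome, computed from all
#' markers except that chromosome's (leave-one-chromosome-out), protecting
#' the scan against proximal contamination.
#'
#' @param genoprob a [GenoProb-class].
#' @param loco compute leave-one-chromosome-out matrices.
#' @return A [KinshipMatrix-class], or a named list of them (one per
#'   chromosome) when `loco = TRUE`.
#' @export
kinshipGRM <- function(genoprob, loco = FALSE) {
  stopifnot(is(genoprob, "GenoProb"))
  pr <- probArray(genoprob)
  if (nrow(pr) < 2L) stop("need >= 2 lines")
  mk <- markerTable(genoprob)
  buildK <- function(j, scope, chrOut) {
    if (length(j) == 0L) stop("no markers in scope for kinship")
    PA <- matrix(pr[, j, 1L], nrow = dim(pr)[1L])
    PB <- matrix(pr[, j, 2L], nrow = dim(pr)[1L])
    K <- (tcrossprod(PA) + tcrossprod(PB)) / length(j)
    K <- (K + t(K)) / 2
    diag(K) <- 1
    dimnames(K) <- list(rownames(pr), rownames(pr))
    new("KinshipMatrix", K = K, scope = scope, chromosome = chrOut)
  }
  if (!loco) return(buildK(seq_len(nrow(mk)), "all", ""))
  chrs <- unique(mk$chromosome)
  if (length(chrs) < 2L)
    stop("LOCO needs >= 2 chromosomes (no markers would remain in scope)")
  out <- lapply(chrs, function(ch)
    buildK(which(mk$chromosome != ch), "loco", ch))
  stats::setNames(out, chrs)
}
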