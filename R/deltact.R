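#' Comparative delta-Ct stability scores
#'
#' For each gene, the mean over all other genes of the standard deviation
#' (n-1 denominator) over samples of the pairwise Cq difference. A gene
#' whose Cq tracks every other candidate closely gets a low score. With a
#' common amplification base of 2 this is algebraically identical to the
#' geNorm M value computed on the full candidate set (the per-gene minimum
#' constants of the relative-quantity transform cancel inside each SD), but
#' it is conventionally computed on raw Cq.
#'
#' @param cq A [cq_matrix()] with >= 2 genes and >= 2 samples.
#' @param samples Optional sample subset.
#' @return Named numeric vector of stability scores (cycles; lower = more
#'   stable).
#' @examples
#' sort(delta_ct_scores(bovine_pbmc_cq()))
#' @export
delta_ct_scores <- function(cq, samples = NULL) {
  stopifnot(inherits(cq, "cq_matrix"))
  cq <- resolve_samples(cq, samples)
  v <- cq$values
  if (nrow(v) < 2L) stop("need at least 2 samples")
  sdm <- pairwise_variability_matrix(v)   # sd of column differences
  rowSums(sdm) / (ncol(v) - 1L)
}
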