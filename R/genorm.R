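#' Pairwise expression variability of two genes
#'
#' The geNorm building block: the standard deviation (n-1 denominator) over
#' samples of the log2 expression ratio of two genes. Two ideal reference
#' genes have a constant ratio across samples, so their pairwise variability
#' is 0. With a common base E = 2 the log-ratio equals the Cq difference up
#' to an additive constant, so V depends only on Cq differences.
#'
#' @param rq An [relative_quantities()] matrix.
#' @param gene_a,gene_b Distinct gene ids.
#' @param samples Optional sample subset applied to the rows.
#' @return The pairwise variability V (log2 units).
#' @export
pairwise_variability <- function(rq, gene_a, gene_b, samples = NULL) {
  stopifnot(inherits(rq, "rq_matrix"))
  if (identical(gene_a, gene_b))
    stop("gene_a and gene_b must differ")
  l <- log2_rq(rq)
  if (!is.null(samples)) l <- l[samples, , drop = FALSE]
  if (nrow(l) < 2L) stop("need at least 2 samples")
  stats::sd(l[, gene_a] - l[, gene_b])
}

# All pairwise variabilities at once: k x k symmetric matrix of
# sd(log2 ratio), zero diagonal.
pairwise_variability_matrix <- function(l) {
  k <- ncol(l)
  v <- matrix(0, k, k, dimnames = list(colnames(l), colnames(l)))
  for (a in seq_len(k - 1L)) {
    d <- l[, (a + 1L):k, drop = FALSE] - l[, a]
    s <- apply(d, 2L, stats::sd)
    v[a, (a + 1L):k] <- s
    v[(a + 1L):k, a] <- s
  }
  v
}

#' geNorm M values
#'
#' The gene-stability measure M of each gene within a candidate set: the
#' arithmetic mean of its pairwise variabilities with every other gene in
#' the set. Lower M means more stable; the customary acceptability ceiling
#' is M < 1.5.
#'
#' @param rq An [relative_quantities()] matrix.
#' @param genes Gene ids to include (default: all, must be >= 2).
#' @param samples Optional sample subset.
#' @return Named numeric vector of M values.
#' @examples
#' rq <- relative_quantities(bovine_pbmc_cq())
#' m_values(rq)
#' @export
m_values <- function(rq, genes = NULL, samples = NULL) {
  stopifnot(inherits(rq, "rq_matrix"))
  l <- log2_rq(rq)
  if (!is.null(samples)) l <- l[samples, , drop = FALSE]
  if (!is.null(genes)) l <- l[, genes, drop = FALSE]
  if (ncol(l) < 2L) stop("M values need at least 2 genes")
  v <- pairwise_variability_matrix(l)
  rowSums(v) / (ncol(l) - 1L)
}

#' geNorm stepwise stability ranking
#'
#' Iteratively computes M values on the remaining gene set and removes the
#' gene with the highest M until two genes remain; those two form the tied
#' most-stable pair. The stability value reported for each exclusion step is
#' the average M of all genes still in the set at that step (the value the
#' geNorm software charts); it decreases monotonically toward the terminal
#' pair's shared M, which equals their pairwise variability.
#'
#' Ties on the maximal M are broken by removing the gene that comes later in
#' input column order, making the procedure deterministic.
#'
#' @param rq An [relative_quantities()] matrix with >= 3 genes.
#' @param samples Optional sample subset.
#' @return An object of class `genorm_result`: list with
#'   \describe{
#'     \item{ranking}{genes best to worst; the first two are tied.}
#'     \item{final_pair}{the two terminal genes (input column order).}
#'     \item{stability}{named vector, reported M per gene (average M of the
#'       remaining set at that gene's exclusion; terminal pair share their
#'       pairwise M).}
#'     \item{exclusion}{data.frame of step, set size, excluded gene(s),
#'       average M, and the excluded gene's own M.}
#'   }
#' @examples
#' g <- genorm_ranking(relative_quantities(bovine_pbmc_cq()))
#' g$final_pair
#' @export
genorm_ranking <- function(rq, samples = NULL) {
  stopifnot(inherits(rq, "rq_matrix"))
  l <- log2_rq(rq)
  if (!is.null(samples)) l <- l[samples, , drop = FALSE]
  if (ncol(l) < 3L) stop("stepwise ranking needs at least 3 genes")
  k <- ncol(l)
  excluded <- character(0)
  avg_m <- own_m <- numeric(0)
  cur <- l
  while (ncol(cur) > 2L) {
    v <- pairwise_variability_matrix(cur)
    m <- rowSums(v) / (ncol(cur) - 1L)
    w <- max(which(m == max(m)))          # later column loses the tie
    excluded <- c(excluded, colnames(cur)[w])
    avg_m <- c(avg_m, mean(m))
    own_m <- c(own_m, m[w])
    cur <- cur[, -w, drop = FALSE]
  }
  final_pair <- colnames(cur)
  final_m <- stats::sd(cur[, 1L] - cur[, 2L])
  ranking <- c(final_pair, rev(excluded))
  stability <- stats::setNames(
    c(final_m, final_m, rev(avg_m)), ranking)
  exclusion <- data.frame(
    step = seq_len(k - 2L),
    n_genes = k - seq_len(k - 2L) + 1L,
    excluded = excluded,
    avg_m = avg_m,
    gene_m = own_m,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(ranking = ranking, final_pair = final_pair,
                 stability = stability, exclusion = exclusion),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stepwise ranking (best to worst):\n")
  lab <- c(paste(x$final_pair, collapse = " = "), x$ranking[-(1:2)])
  val <- x$stability[c(x$final_pair[1L], x$ranking[-(1:2)])]
  cat(paste0("  ", format(seq_along(lab)), ". ", format(lab),
             "  M = ", formatC(val, digits = 3, format = "f")),
      sep = "\n")
  invisible(x)
}

#' Per-sample normalization factor
#'
#' The geometric mean of the selected genes' relative quantities within each
#' sample, the quantity by which target-gene expression is divided during
#' normalization.
#'
#' @param rq An [relative_quantities()] matrix.
#' @param genes Genes forming the normalizer panel (>= 1).
#' @param samples Optional sample subset.
#' @return Named numeric vector, one factor per sample.
#' @export
normalization_factor <- function(rq, genes, samples = NULL) {
  stopifnot(inherits(rq, "rq_matrix"), length(genes) >= 1L)
  l <- log2_rq(rq)
  if (!is.null(samples)) l <- l[samples, , drop = FALSE]
  2 ^ rowMeans(l[, genes, drop = FALSE])
}

#' geNorm pairwise variation V(n, n+1)
#'
#' For each n from 2 to k-1, the standard deviation over samples of
#' `log2(NF_n / NF_{n+1})`, where NF_n is the normalization factor built
#' from the n best-ranked genes. A small V(n, n+1) means the (n+1)-th gene
#' changes the normalization factor little, so n genes suffice: the optimal
#' panel size is the smallest n with V below the threshold (0.15 by
#' convention). If no V falls below the threshold the full candidate count
#' is returned with a warning.
#'
#' @param rq An [relative_quantities()] matrix.
#' @param ranking A `genorm_result` or a character vector of genes ranked
#'   best to worst; computed from `rq` if omitted.
#' @param samples Optional sample subset.
#' @param threshold Cut-off for V (default 0.15).
#' @return An object of class `pairwise_variation`: list with `v` (named
#'   `V2:3` etc.), `threshold`, `optimal_n`, and `ranking`.
#' @examples
#' pairwise_variation_series(relative_quantities(bovine_pbmc_cq()))
#' @export
pairwise_variation_series <- function(rq, ranking = NULL, samples = NULL,
                                      threshold = 0.15) {
  stopifnot(inherits(rq, "rq_matrix"), threshold > 0)
  if (is.null(ranking)) ranking <- genorm_ranking(rq, samples = samples)
  genes <- if (inherits(ranking, "genorm_result")) ranking$ranking
           else as.character(ranking)
  l <- log2_rq(rq)
  if (!is.null(samples)) l <- l[samples, , drop = FALSE]
  k <- length(genes)
  if (k < 3L) stop("pairwise variation needs at least 3 ranked genes")
  v <- vapply(2:(k - 1L), function(n) {
    nf_n <- rowMeans(l[, genes[1:n], drop = FALSE])
    nf_n1 <- rowMeans(l[, genes[1:(n + 1L)], drop = FALSE])
    stats::sd(nf_n - nf_n1)
  }, numeric(1L))
  names(v) <- paste0("V", 2:(k - 1L), ":", 3:k)
  below <- which(v < threshold)
  if (length(below)) {
    optimal_n <- below[1L] + 1L
  } else {
    warning("no V(n, n+1) below threshold ", threshold,
            "; reporting the full candidate count")
    optimal_n <- k
  }
  structure(list(v = v, threshold = threshold,
                 optimal_n = as.integer(optimal_n), ranking = genes),
            class = "pairwise_variation")
}

#' @export
print.pairwise_variation <- function(x, ...) {
  cat("geNorm pairwise variation (threshold ", x$threshold, "):\n", sep = "")
  flag <- ifelse(x$v < x$threshold, " *", "")
  cat(paste0("  ", names(x$v), " = ",
             formatC(x$v, digits = 3, format = "f"), flag), sep = "\n")
  cat("optimal number of reference genes: ", x$optimal_n, "\n", sep = "")
  invisible(x)
}
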