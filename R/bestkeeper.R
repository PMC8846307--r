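#' BestKeeper descriptive statistics
#'
#' Per-gene dispersion summaries on raw Cq (BestKeeper never transforms to
#' relative quantities). The headline statistic `sd_cp` is the mean absolute
#' deviation of Cq about the arithmetic mean (not the classical SD); genes
#' with `sd_cp < 1` cycle are conventionally considered acceptable
#' references. Fold-change extremes are anchored on the geometric mean:
#' `min_xfold = -E^(geo_mean - min)` (signed negative for under-expression)
#' and `max_xfold = +E^(max - geo_mean)`; `sd_xfold = E^sd_cp`.
#'
#' @param cq A [cq_matrix()] with >= 2 samples in the subset.
#' @param samples Optional sample subset.
#' @param efficiency Amplification base used for the x-fold columns
#'   (default 2).
#' @return A data.frame with one row per gene: `n`, `geo_mean`, `ar_mean`,
#'   `min`, `max`, `sd_cp`, `cv_pct`, `min_xfold`, `max_xfold`, `sd_xfold`,
#'   `acceptable`.
#' @examples
#' bestkeeper_descriptives(bovine_pbmc_cq())
#' @export
bestkeeper_descriptives <- function(cq, samples = NULL, efficiency = 2) {
  stopifnot(inherits(cq, "cq_matrix"))
  cq <- resolve_samples(cq, samples)
  v <- cq$values
  if (any(v <= 0)) stop("geometric mean undefined for non-positive Cq")
  geo <- exp(colMeans(log(v)))
  ar <- colMeans(v)
  sd_cp <- colMeans(abs(t(t(v) - ar)))
  mins <- apply(v, 2L, min)
  maxs <- apply(v, 2L, max)
  data.frame(gene = colnames(v),
             n = nrow(v),
             geo_mean = geo,
             ar_mean = ar,
             min = mins,
             max = maxs,
             sd_cp = sd_cp,
             cv_pct = 100 * sd_cp / ar,
             min_xfold = -efficiency ^ (geo - mins),
             max_xfold = efficiency ^ (maxs - geo),
             sd_xfold = efficiency ^ sd_cp,
             acceptable = sd_cp < 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise Pearson correlations between genes
#'
#' Pearson correlation of raw Cq for every unordered gene pair, with
#' two-sided p-values from the t distribution on n - 2 degrees of freedom.
#' Reported p-values are floored at `p_floor` (printed qPCR reports
#' conventionally bottom out at 0.001); the full-precision values are kept
#' in the `p_exact` component.
#'
#' @param cq A [cq_matrix()] with >= 3 samples in the subset.
#' @param samples Optional sample subset.
#' @param p_floor Reporting floor for p-values (default 0.001).
#' @return List with gene x gene matrices `r`, `p` (floored) and `p_exact`.
#'   A zero-variance gene yields `NA` correlations with a warning.
#' @export
pairwise_correlations <- function(cq, samples = NULL, p_floor = 0.001) {
  stopifnot(inherits(cq, "cq_matrix"))
  cq <- resolve_samples(cq, samples)
  v <- cq$values
  n <- nrow(v)
  if (n < 3L) stop("correlations need at least 3 samples")
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance gene(s): ",
            paste(colnames(v)[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  r <- suppressWarnings(stats::cor(v))
  diag(r) <- 1
  r[, sds == 0] <- NA_real_
  r[sds == 0, ] <- NA_real_
  diag(r)[sds == 0] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r ^ 2, .Machine$double.eps))
  p_exact <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p_exact) <- NA_real_
  list(r = r, p = pmax(p_exact, p_floor), p_exact = p_exact)
}

#' BestKeeper index
#'
#' The per-sample geometric mean of Cq over the chosen genes. By default all
#' candidates contribute; `genes = "acceptable"` restricts the index to
#' genes with `sd_cp < 1` (the original tool's behaviour of dropping
#' inconsistent candidates).
#'
#' @param cq A [cq_matrix()].
#' @param genes Character vector of gene ids, `"all"` (default) or
#'   `"acceptable"`.
#' @param samples Optional sample subset.
#' @return Named numeric vector, one index value (cycles) per sample.
#' @export
bestkeeper_index <- function(cq, genes = "all", samples = NULL) {
  stopifnot(inherits(cq, "cq_matrix"))
  cq <- resolve_samples(cq, samples)
  if (identical(genes, "all")) {
    genes <- colnames(cq$values)
  } else if (identical(genes, "acceptable")) {
    d <- bestkeeper_descriptives(cq)
    genes <- d$gene[d$acceptable]
    if (!length(genes)) stop("no gene with sd_cp < 1")
  }
  exp(rowMeans(log(cq$values[, genes, drop = FALSE])))
}

#' Correlation of each gene with the BestKeeper index
#'
#' @param cq A [cq_matrix()].
#' @param index Per-sample index from [bestkeeper_index()]; computed from
#'   all genes if omitted.
#' @param samples Optional sample subset.
#' @param p_floor Reporting floor for p-values.
#' @return data.frame with `gene`, `r`, `p`.
#' @export
index_correlations <- function(cq, index = NULL, samples = NULL,
                               p_floor = 0.001) {
  stopifnot(inherits(cq, "cq_matrix"))
  cq <- resolve_samples(cq, samples)
  if (is.null(index)) index <- bestkeeper_index(cq)
  v <- cq$values
  n <- nrow(v)
  if (n < 3L) stop("correlations need at least 3 samples")
  r <- apply(v, 2L, function(g)
    if (stats::sd(g) == 0) NA_real_ else stats::cor(g, index))
  tstat <- r * sqrt((n - 2) / pmax(1 - r ^ 2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  data.frame(gene = colnames(v), r = r, p = pmax(p, p_floor),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full BestKeeper analysis
#'
#' Runs the descriptive block, the pairwise correlation matrix, the index
#' and the gene-vs-index correlations in one call.
#'
#' @param cq A [cq_matrix()].
#' @param samples Optional sample subset.
#' @param efficiency Amplification base for x-fold columns.
#' @param index_genes `"all"` (default) or `"acceptable"`, see
#'   [bestkeeper_index()].
#' @param p_floor Reporting floor for p-values.
#' @return An object of class `bestkeeper_result`: list with
#'   `descriptives`, `pair_r`, `pair_p`, `index`, `index_cor` and the
#'   per-gene ranking vector `stability` (`sd_cp`, ascending = more stable).
#' @examples
#' bk <- bestkeeper(bovine_pbmc_cq())
#' bk$descriptives[, c("gene", "sd_cp", "cv_pct")]
#' @export
bestkeeper <- function(cq, samples = NULL, efficiency = 2,
                       index_genes = "all", p_floor = 0.001) {
  stopifnot(inherits(cq, "cq_matrix"))
  cq <- resolve_samples(cq, samples)
  desc <- bestkeeper_descriptives(cq, efficiency = efficiency)
  pc <- pairwise_correlations(cq, p_floor = p_floor)
  idx <- bestkeeper_index(cq, genes = index_genes)
  ic <- index_correlations(cq, index = idx, p_floor = p_floor)
  structure(list(descriptives = desc, pair_r = pc$r, pair_p = pc$p,
                 index = idx, index_cor = ic,
                 stability = stats::setNames(desc$sd_cp, desc$gene)),
            class = "bestkeeper_result")
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  cat("BestKeeper analysis (", nrow(x$descriptives), " genes, n = ",
      x$descriptives$n[1L], "):\n", sep = "")
  d <- x$descriptives[order(x$descriptives$sd_cp), ]
  cat(paste0("  ", format(d$gene), "  SD[+/-CP] = ",
             formatC(d$sd_cp, digits = 2, format = "f"),
             "  CV[%CP] = ", formatC(d$cv_pct, digits = 2, format = "f"),
             ifelse(d$acceptable, "", "  (unstable: SD >= 1)")),
      sep = "\n")
  invisible(x)
}
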