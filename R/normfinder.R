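#' NormFinder model-based stability, grouped
#'
#' Fits the additive model `x = gene effect + sample effect + group x gene
#' effect + noise` to log2 relative quantities and scores each gene by a
#' combination of its estimated intragroup variance and its shrunken
#' intergroup deviation. Lower is more stable. The estimator:
#'
#' 1. sample-center: `z = x - (per-sample mean over genes)`;
#' 2. per gene i and group g, group mean `zbar_ig` and sample variance
#'    `v_ig` (n_g - 1 denominator);
#' 3. bias-corrected intragroup variance
#'    `sigma2_ig = max(0, (v_ig - sum_i'(v_i'g) / (k (k - 1))) * k / (k - 2))`
#'    (sample-centering mixes a 1/k share of every gene's noise into each
#'    column; the correction removes it);
#' 4. intergroup deviation `d_ig = zbar_ig - mean_g'(zbar_ig')` (unweighted
#'    group mean, so `sum_g d_ig = 0` per gene);
#' 5. intergroup variance
#'    `gamma2 = max(0, sum(d^2) / ((k - 1)(G - 1)) - mean(sigma2_ig / n_g))`;
#' 6. shrunken deviation `dtilde_ig = d_ig * gamma2 / (gamma2 + sigma2_ig / n_g)`;
#' 7. per gene and group, stability
#'    `rho_ig = |dtilde_ig| + sqrt((sigma2_ig / n_g) * gamma2 / (gamma2 + sigma2_ig / n_g))`;
#' 8. the gene's stability value is the mean of `rho_ig` over groups.
#'
#' @param rq An [relative_quantities()] matrix with >= 3 genes.
#' @param group Group labels: `NULL` to use the groups carried by the
#'   Cq/RQ object, or a vector with one label per (selected) sample. At
#'   least 2 groups with >= 2 samples each.
#' @param samples Optional sample subset.
#' @return An object of class `normfinder_result`: list with `stability`
#'   (named per-gene vector), `sigma2`, `d`, `d_shrunk` (gene x group
#'   matrices), `gamma2`, `groups`, `n_g` and `grouped = TRUE`.
#' @examples
#' rq <- relative_quantities(bovine_pbmc_cq())
#' nf <- normfinder_grouped(rq)
#' sort(nf$stability)
#' @export
normfinder_grouped <- function(rq, group = NULL, samples = NULL) {
  stopifnot(inherits(rq, "rq_matrix"))
  l <- log2_rq(rq)
  grp <- as.character(rq$group)
  if (!is.null(samples)) {
    l <- l[samples, , drop = FALSE]
    grp <- as.character(rq$group[rownames(l)])
  }
  if (!is.null(group)) {
    if (length(group) != nrow(l))
      stop("'group' must have one label per selected sample")
    grp <- as.character(group)
  }
  gs <- unique(grp)
  k <- ncol(l)
  if (length(gs) < 2L)
    stop("grouped analysis needs >= 2 groups; use normfinder_ungrouped()")
  if (k < 3L) stop("NormFinder needs at least 3 genes")
  n_g <- vapply(gs, function(g) sum(grp == g), integer(1L))
  if (any(n_g < 2L)) stop("every group needs at least 2 samples")
  G <- length(gs)

  z <- l - rowMeans(l)
  zbar <- vapply(gs, function(g) colMeans(z[grp == g, , drop = FALSE]),
                 numeric(k))
  v <- vapply(gs, function(g) apply(z[grp == g, , drop = FALSE], 2L,
                                    stats::var), numeric(k))
  sigma2 <- apply(v, 2L, function(vg)
    pmax((vg - sum(vg) / (k * (k - 1))) * k / (k - 2), 0))
  dimnames(sigma2) <- list(colnames(l), gs)
  d <- zbar - rowMeans(zbar)
  dimnames(d) <- list(colnames(l), gs)
  q <- sweep(sigma2, 2L, n_g, "/")
  gamma2 <- max(0, sum(d ^ 2) / ((k - 1) * (G - 1)) - mean(q))
  denom <- gamma2 + q
  shrink <- ifelse(denom > 0, gamma2 / denom, 0)  # degenerate: no variation
  d_shrunk <- d * shrink
  rho <- abs(d_shrunk) + sqrt(q * shrink)
  stability <- rowMeans(rho)
  structure(list(stability = stability, sigma2 = sigma2, d = d,
                 d_shrunk = d_shrunk, gamma2 = gamma2, groups = gs,
                 n_g = n_g, grouped = TRUE),
            class = "normfinder_result")
}

#' NormFinder stability without groups
#'
#' The single-group reduction of [normfinder_grouped()]: steps 1-3 of the
#' estimator with G = 1, after which the gene's stability value is simply
#' its estimated noise standard deviation, `sqrt(sigma2)`.
#'
#' @param rq An [relative_quantities()] matrix with >= 3 genes (the
#'   `k / (k - 2)` bias correction is undefined below 3).
#' @param samples Optional sample subset.
#' @return An object of class `normfinder_result` with `stability`,
#'   `sigma2` (per-gene vector) and `grouped = FALSE`.
#' @export
normfinder_ungrouped <- function(rq, samples = NULL) {
  stopifnot(inherits(rq, "rq_matrix"))
  l <- log2_rq(rq)
  if (!is.null(samples)) l <- l[samples, , drop = FALSE]
  k <- ncol(l)
  if (k < 3L) stop("NormFinder needs at least 3 genes")
  z <- l - rowMeans(l)
  v <- apply(z, 2L, stats::var)
  sigma2 <- pmax((v - sum(v) / (k * (k - 1))) * k / (k - 2), 0)
  structure(list(stability = sqrt(sigma2), sigma2 = sigma2,
                 grouped = FALSE),
            class = "normfinder_result")
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("NormFinder stability values (",
      if (x$grouped) paste0(length(x$groups), " groups") else "ungrouped",
      "; lower = more stable):\n", sep = "")
  s <- sort(x$stability)
  cat(paste0("  ", format(names(s)), "  ",
             formatC(s, digits = 3, format = "f")), sep = "\n")
  if (x$grouped)
    cat("intergroup variance gamma^2 = ",
        formatC(x$gamma2, digits = 4, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Intergroup variation table
#'
#' The raw (unshrunken) intergroup deviations `d_ig` of a grouped NormFinder
#' fit, the quantity usually bar-plotted to inspect which genes shift between
#' conditions. Rows sum to zero by construction; with two groups the two
#' columns are mirror images.
#'
#' @param nf A grouped `normfinder_result`.
#' @return A gene x group matrix of deviations (log2 units).
#' @export
intergroup_variation <- function(nf) {
  stopifnot(inherits(nf, "normfinder_result"))
  if (!isTRUE(nf$grouped))
    stop("intergroup variation requires a grouped NormFinder result")
  nf$d
}
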