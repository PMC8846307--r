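#' Convert stability scores to ranks
#'
#' Ascending ranks (lower score = better rank 1). Two tie policies:
#' `"consecutive"` (default) assigns distinct consecutive ranks to tied
#' scores in input order; `"min"` gives tied scores the same minimal rank
#' (so a tied best pair both rank 1, and the next gene ranks 3).
#'
#' @param scores Named, finite numeric vector (lower = more stable).
#' @param ties `"consecutive"` or `"min"`.
#' @return Named integer ranks.
#' @examples
#' rank_from_scores(c(A = 0.1, B = 0.3, C = 0.2))
#' rank_from_scores(c(A = 0.1, B = 0.1), ties = "min")
#' @export
rank_from_scores <- function(scores, ties = c("consecutive", "min")) {
  ties <- match.arg(ties)
  if (anyNA(scores) || any(!is.finite(scores)))
    stop("scores must be finite")
  r <- rank(scores, ties.method = if (ties == "min") "min" else "first")
  stats::setNames(as.integer(r), names(scores))
}

#' Consensus ranking by geometric mean of per-method ranks
#'
#' Aggregates two or more per-method rank vectors over an identical gene set
#' into the comprehensive ranking: each gene's consensus score is the
#' geometric mean of its ranks, and genes are ordered by ascending score
#' (ties broken by input gene order).
#'
#' @param ranks A named list (or gene x method matrix) of per-method ranks
#'   over identical gene sets.
#' @return An object of class `consensus_ranking`: list with `geo_rank`
#'   (named vector in input gene order), `order` (genes best to worst) and
#'   `ranks` (the gene x method matrix).
#' @examples
#' comprehensive_ranking(list(m1 = c(A = 1, B = 2), m2 = c(A = 2, B = 1)))
#' @export
comprehensive_ranking <- function(ranks) {
  if (is.matrix(ranks))
    ranks <- stats::setNames(lapply(seq_len(ncol(ranks)),
                                    function(j) ranks[, j]), colnames(ranks))
  if (length(ranks) < 2L) stop("need ranks from at least 2 methods")
  genes <- names(ranks[[1L]])
  for (m in ranks)
    if (!setequal(names(m), genes))
      stop("methods rank different gene sets")
  mat <- vapply(ranks, function(m) m[genes], numeric(length(genes)))
  rownames(mat) <- genes
  geo <- exp(rowMeans(log(mat)))
  ord <- genes[order(geo)]          # order() is stable: input order breaks ties
  structure(list(geo_rank = geo, order = ord, ranks = mat),
            class = "consensus_ranking")
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat("Consensus ranking (geometric mean of ",
      ncol(x$ranks), " method ranks):\n", sep = "")
  g <- x$geo_rank[x$order]
  cat(paste0("  ", format(seq_along(g)), ". ", format(names(g)), "  ",
             formatC(g, digits = 2, format = "f")), sep = "\n")
  invisible(x)
}

#' RefFinder-style consensus pipeline
#'
#' Runs the four standard stability methods the RefFinder tool aggregates -
#' comparative delta-Ct, geNorm stepwise ranking, ungrouped NormFinder and
#' BestKeeper (`sd_cp`) - on one Cq matrix and combines their ranks by
#' geometric mean. geNorm's tied terminal pair both receive rank 1 under the
#' default `"min"` tie policy; BestKeeper genes can alternatively be ranked
#' by descending index correlation (`bestkeeper_by = "index_r"`).
#'
#' @param cq A [cq_matrix()].
#' @param samples Optional sample subset.
#' @param ties Tie policy for the geNorm terminal pair (and any exact score
#'   ties): `"min"` (default) or `"consecutive"`.
#' @param bestkeeper_by `"sd"` (default) or `"index_r"`.
#' @param efficiency Amplification base for the relative-quantity transform.
#' @return A `consensus_ranking` whose `ranks` matrix has columns
#'   `delta_ct`, `genorm`, `normfinder`, `bestkeeper`.
#' @examples
#' reffinder_pipeline(bovine_pbmc_cq())
#' @export
reffinder_pipeline <- function(cq, samples = NULL,
                               ties = c("min", "consecutive"),
                               bestkeeper_by = c("sd", "index_r"),
                               efficiency = 2) {
  ties <- match.arg(ties)
  bestkeeper_by <- match.arg(bestkeeper_by)
  stopifnot(inherits(cq, "cq_matrix"))
  cq <- resolve_samples(cq, samples)
  rq <- relative_quantities(cq, efficiency = efficiency)
  genes <- colnames(cq$values)

  dct <- rank_from_scores(delta_ct_scores(cq), ties = ties)
  gn <- genorm_ranking(rq)
  # reported stepwise stability as the score: the terminal pair is a true
  # tie, everything else is strictly ordered along the exclusion path
  gn_rank <- rank_from_scores(gn$stability[genes], ties = ties)
  nf <- rank_from_scores(normfinder_ungrouped(rq)$stability, ties = ties)
  bk <- bestkeeper(cq)
  bk_scores <- if (bestkeeper_by == "sd") bk$stability
               else -stats::setNames(bk$index_cor$r, bk$index_cor$gene)
  bk_rank <- rank_from_scores(bk_scores[genes], ties = ties)

  comprehensive_ranking(list(delta_ct = dct[genes], genorm = gn_rank,
                             normfinder = nf[genes], bestkeeper = bk_rank))
}
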