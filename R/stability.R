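#' Fit a reference-gene stability analysis
#'
#' The package's central fitting function: runs the four expression-stability
#' algorithms (geNorm with its pairwise-variation analysis, NormFinder
#' grouped and ungrouped, BestKeeper, comparative delta-Ct) on one Cq matrix
#' and aggregates them into a consensus ranking. Returns a classed object
#' with `print`, `summary`, `coef`, `plot` and `simulate` methods.
#'
#' @param cq A [cq_matrix()] (or a plain samples x genes matrix, which is
#'   validated via [cq_matrix()]).
#' @param group Optional group labels overriding those carried by `cq`
#'   (one per sample). Used by grouped NormFinder and by the target-gene
#'   summaries.
#' @param samples Optional sample subset (id vector or group label).
#' @param efficiency Amplification base for the relative-quantity transform,
#'   scalar or per-gene named vector (default 2).
#' @param genorm_threshold Pairwise-variation cut-off for the optimal panel
#'   size (default 0.15).
#' @param ties Tie policy for consensus ranks, `"min"` (default) or
#'   `"consecutive"`; see [rank_from_scores()].
#' @return An object of class `refgene_stability` with components `cq`,
#'   `rq`, `genorm`, `vseries`, `normfinder` (grouped, or `NULL` for a
#'   single group), `normfinder_ungrouped`, `bestkeeper`, `delta_ct`,
#'   `consensus`, and `optimal_panel` (the top `optimal_n` consensus genes).
#' @examples
#' fit <- refgene_stability(bovine_pbmc_cq())
#' fit
#' summary(fit)
#' @export
refgene_stability <- function(cq, group = NULL, samples = NULL,
                              efficiency = 2, genorm_threshold = 0.15,
                              ties = c("min", "consecutive")) {
  ties <- match.arg(ties)
  if (!inherits(cq, "cq_matrix")) cq <- cq_matrix(as.matrix(cq), group)
  else if (!is.null(group)) cq <- cq_matrix(cq$values, group)
  cq <- resolve_samples(cq, samples)
  rq <- relative_quantities(cq, efficiency = efficiency)

  gn <- genorm_ranking(rq)
  vs <- pairwise_variation_series(rq, ranking = gn,
                                  threshold = genorm_threshold)
  nf_u <- normfinder_ungrouped(rq)
  nf_g <- if (nlevels(droplevels(cq$group)) >= 2L)
    normfinder_grouped(rq) else NULL
  bk <- bestkeeper(cq, efficiency = if (length(efficiency) == 1L)
    efficiency else 2)
  dct <- delta_ct_scores(cq)
  cons <- reffinder_pipeline(cq, ties = ties,
                             efficiency = efficiency)
  structure(list(cq = cq, rq = rq, genorm = gn, vseries = vs,
                 normfinder = nf_g, normfinder_ungrouped = nf_u,
                 bestkeeper = bk, delta_ct = dct, consensus = cons,
                 optimal_panel = cons$order[seq_len(vs$optimal_n)],
                 ties = ties),
            class = "refgene_stability")
}

#' @export
print.refgene_stability <- function(x, ...) {
  cat("Reference-gene stability analysis: ", nrow(x$cq$values),
      " samples, ", ncol(x$cq$values), " genes\n", sep = "")
  cat("geNorm best pair:     ", paste(x$genorm$final_pair, collapse = " = "),
      "  (M = ", formatC(x$genorm$stability[x$genorm$final_pair[1L]],
                         digits = 3, format = "f"), ")\n", sep = "")
  nf_best <- if (!is.null(x$normfinder)) x$normfinder else
    x$normfinder_ungrouped
  bb <- names(sort(nf_best$stability))[1L]
  cat("NormFinder best:       ", bb, "  (stability = ",
      formatC(nf_best$stability[bb], digits = 3, format = "f"), ")\n",
      sep = "")
  bk_best <- names(sort(x$bestkeeper$stability))[1L]
  cat("BestKeeper best:       ", bk_best, "  (SD[+/-CP] = ",
      formatC(x$bestkeeper$stability[bk_best], digits = 2, format = "f"),
      ")\n", sep = "")
  cat("consensus order:       ", paste(x$consensus$order, collapse = " > "),
      "\n", sep = "")
  cat("optimal panel (V < ", x$vseries$threshold, "): ",
      paste(x$optimal_panel, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Consolidated stability table
#'
#' One row per rank position with each method's gene and score, mirroring
#' the consolidated ranking tables of reference-gene studies.
#'
#' @param object A `refgene_stability` fit.
#' @param ... Unused.
#' @return A data.frame of class `summary.refgene_stability`.
#' @export
summary.refgene_stability <- function(object, ...) {
  k <- ncol(object$cq$values)
  fmt <- function(scores, digits = 3) {
    s <- sort(scores)
    paste0(names(s), " (", formatC(s, digits = digits, format = "f"), ")")
  }
  gn <- object$genorm
  gn_lab <- c(paste0(paste(gn$final_pair, collapse = "/"), " (",
                     formatC(gn$stability[gn$final_pair[1L]], digits = 3,
                             format = "f"), ")"),
              fmt(gn$stability[gn$ranking[-(1:2)]]), "-")
  nf <- if (!is.null(object$normfinder)) object$normfinder
        else object$normfinder_ungrouped
  cons <- object$consensus
  data.frame(
    rank = seq_len(k),
    genorm = gn_lab[seq_len(k)],
    normfinder = fmt(nf$stability),
    bestkeeper = fmt(object$bestkeeper$stability, digits = 2),
    delta_ct = fmt(object$delta_ct),
    consensus = paste0(cons$order, " (",
                       formatC(cons$geo_rank[cons$order], digits = 2,
                               format = "f"), ")"),
    stringsAsFactors = FALSE)
}

#' @export
coef.refgene_stability <- function(object, ...) {
  object$consensus$geo_rank
}

#' Plot a stability fit
#'
#' Two base-graphics panels: the geNorm average-M curve along the exclusion
#' path (left) and the pairwise-variation bars with the decision threshold
#' (right).
#'
#' @param x A `refgene_stability` fit.
#' @param ... Passed to [graphics::barplot()] for the V panel.
#' @return Invisibly, `x`.
#' @export
plot.refgene_stability <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(old))
  ex <- x$genorm$exclusion
  mcurve <- c(rev(ex$avg_m), x$genorm$stability[x$genorm$final_pair[1L]])
  labs <- c(rev(ex$excluded), paste(x$genorm$final_pair, collapse = "\n"))
  labs <- rev(labs)
  mcurve <- rev(mcurve)
  graphics::plot(seq_along(mcurve), mcurve, type = "b", pch = 19,
                 xaxt = "n", xlab = "", ylab = "average expression stability M",
                 main = "geNorm stepwise exclusion")
  graphics::axis(1, at = seq_along(mcurve), labels = labs, las = 2,
                 cex.axis = 0.8)
  graphics::barplot(x$vseries$v, las = 2, ylab = "pairwise variation V",
                    main = "optimal number of genes", ...)
  graphics::abline(h = x$vseries$threshold, lty = 2)
  invisible(x)
}

#' Simulate datasets resembling a fitted analysis
#'
#' Draws `nsim` synthetic Cq matrices from the moment-matched
#' [cq_sim_spec()] of the fitted data (same group sizes, baselines, group
#' shifts, loading and noise SDs).
#'
#' @param object A `refgene_stability` fit.
#' @param nsim Number of datasets.
#' @param seed Integer seed for reproducibility.
#' @param ... Unused.
#' @return A list of `nsim` [cq_matrix()] objects (length-1 list for
#'   `nsim = 1`).
#' @export
simulate.refgene_stability <- function(object, nsim = 1, seed = NULL, ...) {
  spec <- fit_sim_spec(object$cq)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  lapply(seq_len(nsim), function(i) simulate_cq(spec))
}
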