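#' Normalize target genes by a reference panel
#'
#' Computes per-sample relative expression of each target gene as its
#' relative quantity divided by the normalization factor (geometric mean of
#' the panel genes' relative quantities), then summarizes per group with
#' mean, SD, SE and the fold difference between the first group and each
#' other group.
#'
#' @param cq A [cq_matrix()] containing both targets and panel genes (use a
#'   combined matrix; targets and panel must not overlap).
#' @param targets Character vector of target gene ids.
#' @param panel Character vector of reference panel gene ids.
#' @param efficiency Amplification base (default 2).
#' @param samples Optional sample subset.
#' @return An object of class `normalized_expression`: list with
#'   `expression` (samples x targets relative expression), `summary`
#'   (data.frame of target, group, n, mean, sd, se) and `fold_difference`
#'   (targets x groups matrix of group-mean ratios relative to the first
#'   group).
#' @export
normalize_targets <- function(cq, targets, panel, efficiency = 2,
                              samples = NULL) {
  stopifnot(inherits(cq, "cq_matrix"))
  cq <- resolve_samples(cq, samples)
  if (length(intersect(targets, panel)))
    stop("targets and reference panel overlap: ",
         paste(intersect(targets, panel), collapse = ", "))
  missing <- setdiff(c(targets, panel), colnames(cq$values))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  rq <- relative_quantities(cq, efficiency = efficiency)
  nf <- normalization_factor(rq, panel)
  expr <- rq$values[, targets, drop = FALSE] / nf
  grp <- cq$group
  gs <- levels(droplevels(grp))
  summ <- do.call(rbind, lapply(targets, function(tg) {
    do.call(rbind, lapply(gs, function(g) {
      e <- expr[grp == g, tg]
      n <- length(e)
      data.frame(target = tg, group = g, n = n, mean = mean(e),
                 sd = stats::sd(e), se = stats::sd(e) / sqrt(n),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  gm <- vapply(gs, function(g)
    colMeans(expr[grp == g, , drop = FALSE]), numeric(length(targets)))
  gm <- matrix(gm, nrow = length(targets),
               dimnames = list(targets, gs))
  fold <- gm / gm[, 1L]
  structure(list(expression = expr, summary = summ,
                 fold_difference = fold, panel = panel),
            class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat("Normalized expression (panel: ",
      paste(x$panel, collapse = ", "), ")\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Contrast two reference panels on the same targets
#'
#' Normalizes the targets with a best and a worst candidate panel
#' side-by-side and flags targets whose between-group expression difference
#' reverses direction depending on the panel - the classic symptom of
#' normalizing with an unstable (condition-confounded) reference gene.
#'
#' @param cq A [cq_matrix()] containing targets and both panels.
#' @param targets Target gene ids.
#' @param best_panel,worst_panel Two reference panels (each disjoint from
#'   the targets).
#' @param efficiency Amplification base.
#' @param samples Optional sample subset.
#' @param margin Materiality threshold for calling a reversal: both panels'
#'   fold differences must deviate from 1 by at least this factor (default
#'   1.2, i.e. 20%) in opposite directions. Without a margin, sampling noise
#'   around a true fold of 1 would constantly trip the flag.
#' @return An object of class `panel_contrast`: list with `best`, `worst`
#'   (the two `normalized_expression` objects) and `reversal` (named logical
#'   per target; `TRUE` if any group's fold difference relative to the first
#'   group materially reverses direction between panels).
#' @export
panel_contrast <- function(cq, targets, best_panel, worst_panel,
                           efficiency = 2, samples = NULL, margin = 1.2) {
  stopifnot(margin >= 1)
  b <- normalize_targets(cq, targets, best_panel,
                         efficiency = efficiency, samples = samples)
  w <- normalize_targets(cq, targets, worst_panel,
                         efficiency = efficiency, samples = samples)
  fb <- b$fold_difference
  fw <- w$fold_difference
  rev_mat <- (fb >= margin & fw <= 1 / margin) |
             (fb <= 1 / margin & fw >= margin)
  reversal <- apply(rev_mat[, -1L, drop = FALSE], 1L, any)
  structure(list(best = b, worst = w, reversal = reversal),
            class = "panel_contrast")
}

#' @export
print.panel_contrast <- function(x, ...) {
  cat("Panel contrast\n  best panel:  ",
      paste(x$best$panel, collapse = ", "),
      "\n  worst panel: ", paste(x$worst$panel, collapse = ", "),
      "\n", sep = "")
  flagged <- names(x$reversal)[x$reversal]
  cat("direction reversals: ",
      if (length(flagged)) paste(flagged, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}
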