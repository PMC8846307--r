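#' Specify a synthetic Cq simulation
#'
#' Describes the additive model on the Cq (log-expression) scale that all
#' four stability methods implicitly assume:
#' `Cq[sample j of group g, gene i] = baseline_i + s_j + shift_ig + e_ij`
#' with per-sample loading offsets `s_j ~ N(0, sample_factor_sd^2)` shared
#' by all genes, group-by-gene shifts, and gene-specific Gaussian noise
#' `e ~ N(0, noise_sd_i^2)`. Known parameters make every method testable by
#' parameter recovery.
#'
#' @param n_per_group Named integer vector of group sizes (>= 2 each).
#' @param baseline_cq Named per-gene baseline Cq (cycles).
#' @param noise_sd Per-gene noise SD (cycles); scalar recycled.
#' @param group_shift Gene x group matrix of shifts (cycles), or `NULL`
#'   for none.
#' @param sample_factor_sd SD of the per-sample loading offset (cycles).
#' @return An object of class `cq_sim_spec`.
#' @examples
#' sp <- cq_sim_spec(c(a = 5, b = 5),
#'                   baseline_cq = c(g1 = 20, g2 = 25, g3 = 30),
#'                   noise_sd = 0.3)
#' simulate_cq(sp, seed = 1)
#' @export
cq_sim_spec <- function(n_per_group, baseline_cq, noise_sd = 0.3,
                        group_shift = NULL, sample_factor_sd = 0.5) {
  if (is.null(names(n_per_group)))
    names(n_per_group) <- paste0("group", seq_along(n_per_group))
  if (is.null(names(baseline_cq)))
    names(baseline_cq) <- paste0("gene", seq_along(baseline_cq))
  k <- length(baseline_cq)
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, k)
  if (length(noise_sd) != k) stop("one noise SD per gene required")
  names(noise_sd) <- names(baseline_cq)
  if (is.null(group_shift))
    group_shift <- matrix(0, k, length(n_per_group),
                          dimnames = list(names(baseline_cq),
                                          names(n_per_group)))
  if (!all(dim(group_shift) == c(k, length(n_per_group))))
    stop("group_shift must be genes x groups")
  dimnames(group_shift) <- list(names(baseline_cq), names(n_per_group))
  if (any(n_per_group < 2L)) stop("group sizes must be >= 2")
  if (any(noise_sd < 0) || sample_factor_sd < 0)
    stop("standard deviations must be non-negative")
  structure(list(n_per_group = n_per_group, baseline_cq = baseline_cq,
                 noise_sd = noise_sd, group_shift = group_shift,
                 sample_factor_sd = sample_factor_sd),
            class = "cq_sim_spec")
}

#' @export
print.cq_sim_spec <- function(x, ...) {
  cat("Cq simulation spec: ", sum(x$n_per_group), " samples (",
      paste(names(x$n_per_group), "=", x$n_per_group, collapse = ", "),
      "), ", length(x$baseline_cq), " genes\n", sep = "")
  cat("baselines ", paste(round(x$baseline_cq, 1), collapse = " "),
      "; noise SD ", paste(round(x$noise_sd, 2), collapse = " "),
      "; loading SD ", x$sample_factor_sd, "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic Cq matrix
#'
#' Draws one dataset from a [cq_sim_spec()]. Reproducible: the same spec and
#' seed always give the same matrix; the caller's random state is left
#' untouched when a seed is supplied.
#'
#' @param spec A [cq_sim_spec()].
#' @param seed Integer seed, or `NULL` to use the current random state.
#' @return A [cq_matrix()] with group labels from the spec. The generating
#'   spec is attached as attribute `"truth"`.
#' @export
simulate_cq <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cq_sim_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n <- sum(spec$n_per_group)
  k <- length(spec$baseline_cq)
  grp <- rep(names(spec$n_per_group), spec$n_per_group)
  s <- stats::rnorm(n, 0, spec$sample_factor_sd)
  eps <- matrix(stats::rnorm(n * k), n, k) %*% diag(spec$noise_sd, k)
  v <- matrix(spec$baseline_cq, n, k, byrow = TRUE) + s + eps +
    t(spec$group_shift[, grp, drop = FALSE])
  dimnames(v) <- list(paste0(grp, "_", stats::ave(seq_len(n), grp,
                                                  FUN = seq_along)),
                      names(spec$baseline_cq))
  out <- cq_matrix(v, group = grp)
  attr(out, "truth") <- spec
  out
}

#' Moment-matched simulation spec for a Cq dataset
#'
#' Fits the [cq_sim_spec()] parameters to an observed Cq matrix by moments:
#' per-gene group means give baselines and group shifts (deviations from the
#' gene's unweighted group-mean average); the loading SD is estimated from
#' the per-sample means after removing gene and group effects; per-gene
#' noise SDs from the residuals (loading contribution subtracted in
#' quadrature).
#'
#' @param cq A [cq_matrix()] with >= 2 groups.
#' @return A `cq_sim_spec` emulating the dataset's structure.
#' @examples
#' sp <- fit_sim_spec(bovine_pbmc_cq())
#' round(sp$baseline_cq, 1)
#' @export
fit_sim_spec <- function(cq) {
  stopifnot(inherits(cq, "cq_matrix"))
  v <- cq$values
  grp <- as.character(cq$group)
  gs <- unique(grp)
  gmeans <- vapply(gs, function(g) colMeans(v[grp == g, , drop = FALSE]),
                   numeric(ncol(v)))          # genes x groups
  baseline <- rowMeans(gmeans)
  shift <- gmeans - baseline
  fitted <- t(gmeans[, grp, drop = FALSE])    # samples x genes
  resid <- v - fitted
  sample_eff <- rowMeans(resid)
  sf_var <- max(0, stats::var(sample_eff))
  noise_var <- pmax(apply(resid, 2L, stats::var) - sf_var, 0.01 ^ 2)
  cq_sim_spec(
    n_per_group = vapply(gs, function(g) sum(grp == g), integer(1L)),
    baseline_cq = baseline,
    noise_sd = sqrt(noise_var),
    group_shift = shift,
    sample_factor_sd = sqrt(sf_var))
}

#' Simulation spec emulating the bundled bovine PBMC dataset
#'
#' [fit_sim_spec()] applied to [bovine_pbmc_cq()]: two groups of 15, ten
#' genes with the dataset's per-gene mean baselines (including the large
#' cold-vs-hot shift of HPRT1), moment-fitted noise SDs and loading SD.
#'
#' @return A `cq_sim_spec`.
#' @export
bovine_sim_spec <- function() {
  fit_sim_spec(bovine_pbmc_cq())
}
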