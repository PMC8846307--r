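#' Transform Cq values to relative quantities
#'
#' Applies the delta-Cq transform `q = E^(min(Cq) - Cq)` per gene, where the
#' minimum is taken over the (selected) samples and `E` is the assumed
#' amplification base (2 for perfect doubling). Each gene's highest-expressed
#' sample gets relative quantity 1 and all values lie in `(0, 1]`.
#'
#' The default `efficiency = 2` for every gene follows the usual convention
#' for stability input data; per-gene bases (e.g. from standard-curve slopes
#' via [efficiency_from_slope()], as `1 + pct/100`) may be supplied instead.
#'
#' @param cq A [cq_matrix()].
#' @param efficiency Single amplification base > 1, or a named vector with
#'   one base per gene.
#' @param samples Optional sample subset (see [subset_samples()]).
#' @return An object of class `rq_matrix`: list with `values` (samples x
#'   genes relative quantities), `efficiency` (named per-gene base) and
#'   `group` (factor carried over from `cq`).
#' @examples
#' cq <- bovine_pbmc_cq()
#' rq <- relative_quantities(cq)
#' max(rq$values[, "GAPDH"])   # exactly 1
#' @export
relative_quantities <- function(cq, efficiency = 2, samples = NULL) {
  stopifnot(inherits(cq, "cq_matrix"))
  cq <- resolve_samples(cq, samples)
  genes <- colnames(cq$values)
  if (length(efficiency) == 1L && is.null(names(efficiency)))
    efficiency <- stats::setNames(rep(efficiency, length(genes)), genes)
  if (!all(genes %in% names(efficiency)))
    stop("missing efficiency for gene(s): ",
         paste(setdiff(genes, names(efficiency)), collapse = ", "))
  efficiency <- efficiency[genes]
  if (any(efficiency <= 1))
    stop("amplification base must exceed 1")
  mins <- apply(cq$values, 2L, min)
  q <- t(efficiency ^ (mins - t(cq$values)))
  dimnames(q) <- dimnames(cq$values)
  structure(list(values = q, efficiency = efficiency, group = cq$group),
            class = "rq_matrix")
}

#' @export
print.rq_matrix <- function(x, ...) {
  cat("Relative-quantity matrix: ", nrow(x$values), " samples x ",
      ncol(x$values), " genes\n", sep = "")
  cat("amplification base: ",
      paste(unique(round(x$efficiency, 4)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# log2 relative quantities; exact form (minCq - Cq) * log2(E), avoiding a
# round trip through the exponential.
log2_rq <- function(rq) {
  stopifnot(inherits(rq, "rq_matrix"))
  log2(rq$values)
}

#' Convert a standard-curve slope to percent amplification efficiency
#'
#' For a dilution-series standard curve of Cq against log10 template amount,
#' the per-cycle amplification factor is `10^(-1/slope)`, so the efficiency
#' in percent is `(10^(-1/slope) - 1) * 100`. A slope of -3.3219
#' (= -1/log10(2)) corresponds to perfect doubling, 100%.
#'
#' @param slope Standard-curve slope in cycles per log10 dilution; must be
#'   negative.
#' @return Efficiency in percent.
#' @examples
#' efficiency_from_slope(-3.3219)  # 100.00
#' efficiency_from_slope(-3.30)    # 100.92
#' @export
efficiency_from_slope <- function(slope) {
  if (any(!is.finite(slope)) || any(slope >= 0))
    stop("standard-curve slope must be negative")
  (10 ^ (-1 / slope) - 1) * 100
}

#' Per-gene descriptive statistics of Cq values
#'
#' Arithmetic summaries per gene over a sample subset: mean, median, min,
#' max, quartiles, classical (n-1) standard deviation, and the coefficient
#' of variation `100 * sd / mean` in percent. These are the box-plot style
#' descriptives of raw Cq; the BestKeeper module computes its own (mean
#' absolute deviation based) dispersion separately.
#'
#' @param cq A [cq_matrix()].
#' @param samples Optional sample subset.
#' @return A data.frame with one row per gene.
#' @export
descriptive_stats <- function(cq, samples = NULL) {
  stopifnot(inherits(cq, "cq_matrix"))
  v <- select_rows(cq, samples)
  q <- t(apply(v, 2L, stats::quantile, probs = c(0.25, 0.5, 0.75)))
  n <- nrow(v)
  sds <- if (n > 1L) apply(v, 2L, stats::sd) else rep(0, ncol(v))
  means <- colMeans(v)
  data.frame(gene = colnames(v),
             n = n,
             mean = means,
             sd = sds,
             cv_pct = 100 * sds / means,
             min = apply(v, 2L, min),
             q25 = q[, 1L],
             median = q[, 2L],
             q75 = q[, 3L],
             max = apply(v, 2L, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify genes into expression tiers from mean Cq
#'
#' Mean Cq below 20 cycles is called abundant (`"high"`), between 20 and
#' 23.5 moderate (`"intermediate"`), and 23.5 or above low expression
#' (`"low"`). The two boundaries sit in the empty gaps between the natural
#' abundance clusters of typical PBMC reference panels; they are labels for
#' reporting only and feed no stability score.
#'
#' @param means Named numeric vector of per-gene mean Cq.
#' @param breaks Two increasing cut points, default `c(20, 23.5)`.
#' @return Named character vector of tiers.
#' @export
expression_tiers <- function(means, breaks = c(20, 23.5)) {
  stopifnot(length(breaks) == 2L, breaks[1L] < breaks[2L])
  if (!length(means)) return(stats::setNames(character(0), character(0)))
  tier <- ifelse(means < breaks[1L], "high",
                 ifelse(means < breaks[2L], "intermediate", "low"))
  stats::setNames(tier, names(means))
}
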