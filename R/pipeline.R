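#' Build a run configuration
#'
#' Collects the options of a full analysis run into a validated list. A
#' configuration can also be read from a YAML file with
#' [read_run_config()]; explicit arguments override file values.
#'
#' @param input `"bundled"` for the bovine PBMC dataset, or a path to a
#'   delimited Cq table (see [read_cq_table()]).
#' @param subset `"all"` or a group label to restrict the analysis to.
#' @param methods Character subset of
#'   `c("genorm", "normfinder", "bestkeeper", "delta_ct", "consensus")`.
#' @param normfinder_grouping `"groups"` (use the matrix's group labels),
#'   `"none"` (ungrouped), or a vector of custom labels.
#' @param genorm_threshold Pairwise-variation cut-off (default 0.15).
#' @param efficiency Amplification base, scalar or per-gene named vector.
#' @param out_dir Directory for report files.
#' @param quiet Suppress progress messages (logged to stderr).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = "bundled", subset = "all",
                       methods = c("genorm", "normfinder", "bestkeeper",
                                   "delta_ct", "consensus"),
                       normfinder_grouping = "groups",
                       genorm_threshold = 0.15, efficiency = 2,
                       out_dir = tempdir(), quiet = FALSE) {
  known <- c("genorm", "normfinder", "bestkeeper", "delta_ct", "consensus")
  if (!length(methods) || !all(methods %in% known))
    stop("unknown method(s): ",
         paste(setdiff(methods, known), collapse = ", "))
  if (!is.numeric(genorm_threshold) || genorm_threshold <= 0)
    stop("genorm_threshold must be > 0")
  structure(list(input = input, subset = subset, methods = methods,
                 normfinder_grouping = normfinder_grouping,
                 genorm_threshold = genorm_threshold,
                 efficiency = efficiency, out_dir = out_dir,
                 quiet = isTRUE(quiet)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param file Path to a YAML file whose keys match the arguments of
#'   [run_config()].
#' @param ... Overrides applied after reading.
#' @return A `run_config`.
#' @export
read_run_config <- function(file, ...) {
  vals <- yaml::read_yaml(file)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' Write per-method stability reports
#'
#' One comma-delimited file per method with columns `rank`, `gene`, `score`
#' (fixed 3 decimals, matching the conventional table precision). Existing
#' files are overwritten.
#'
#' @param results Named list of per-gene stability score vectors (lower =
#'   more stable), e.g. the components of a [refgene_stability()] fit.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_stability_report <- function(results, dir) {
  if (!length(results)) stop("no results to write")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(results), function(m) {
    scores <- results[[m]]
    if (!length(scores)) stop("empty gene list for method '", m, "'")
    s <- sort(scores)
    df <- data.frame(rank = seq_along(s), gene = names(s),
                     score = formatC(s, digits = 3, format = "f"),
                     stringsAsFactors = FALSE)
    path <- file.path(dir, paste0("stability_", m, ".csv"))
    utils::write.table(df, path, sep = ",", quote = FALSE,
                       row.names = FALSE)
    path
  }, character(1L))
  invisible(paths)
}

#' Run a configured stability analysis
#'
#' Loads the input, restricts to the requested subset, fits
#' [refgene_stability()], and writes one report per selected method plus a
#' consolidated ranking table. Progress and provenance (row/column counts,
#' options) are logged to stderr unless `quiet`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `refgene_stability` fit and the
#'   written `files`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!config$quiet) message("[refstab] ", ...)
  cq <- if (identical(config$input, "bundled")) bovine_pbmc_cq()
        else read_cq_table(config$input)
  if (!identical(config$subset, "all")) {
    if (!config$subset %in% levels(cq$group))
      stop("unknown group '", config$subset, "'; available: ",
           paste(levels(cq$group), collapse = ", "))
    cq <- subset_samples(cq, config$subset)
  }
  say("input: ", nrow(cq$values), " samples x ", ncol(cq$values),
      " genes; subset = ", config$subset)
  if (identical(config$normfinder_grouping, "none"))
    cq <- cq_matrix(cq$values, group = NULL)
  else if (!identical(config$normfinder_grouping, "groups"))
    cq <- cq_matrix(cq$values, group = config$normfinder_grouping)
  fit <- refgene_stability(cq, efficiency = config$efficiency,
                           genorm_threshold = config$genorm_threshold)
  results <- list()
  if ("genorm" %in% config$methods)
    results$genorm <- fit$genorm$stability
  if ("normfinder" %in% config$methods)
    results$normfinder <- if (!is.null(fit$normfinder))
      fit$normfinder$stability else fit$normfinder_ungrouped$stability
  if ("bestkeeper" %in% config$methods)
    results$bestkeeper <- fit$bestkeeper$stability
  if ("delta_ct" %in% config$methods)
    results$delta_ct <- fit$delta_ct
  if ("consensus" %in% config$methods)
    results$consensus <- fit$consensus$geo_rank
  files <- write_stability_report(results, config$out_dir)
  cons_path <- file.path(config$out_dir, "consolidated_ranking.csv")
  utils::write.table(summary(fit), cons_path, sep = ",", quote = TRUE,
                     row.names = FALSE)
  files <- c(files, consolidated = cons_path)
  say("wrote ", length(files), " report file(s) to ", config$out_dir)
  invisible(list(fit = fit, files = files))
}

#' Recompute the bundled dataset's published benchmarks
#'
#' Re-runs the full analysis on [bovine_pbmc_cq()] and compares a panel of
#' previously reported stability values for this dataset (geNorm M values
#' and pairwise variations, BestKeeper dispersion and correlations,
#' NormFinder stability, consensus scores, efficiency conversion, mean Cq)
#' against the freshly computed numbers.
#'
#' @param quiet Suppress the printed table.
#' @return A data.frame with `check`, `computed`, `reference`, `tolerance`
#'   and `pass`, invisibly when `quiet = FALSE`.
#' @examples
#' \donttest{reproduce_benchmarks(quiet = TRUE)}
#' @export
reproduce_benchmarks <- function(quiet = FALSE) {
  cq <- bovine_pbmc_cq()
  rq <- relative_quantities(cq)
  fit <- refgene_stability(cq)
  cold <- genorm_ranking(relative_quantities(subset_samples(cq, "cold_arid")))
  hot <- genorm_ranking(relative_quantities(subset_samples(cq, "hot_arid")))
  bk <- fit$bestkeeper
  d <- bk$descriptives
  computed <- c(
    fit$genorm$stability[fit$genorm$final_pair[1L]],
    fit$genorm$exclusion$avg_m[1L],
    unname(fit$vseries$v["V2:3"]),
    unname(fit$vseries$v["V3:4"]),
    cold$stability[cold$final_pair[1L]],
    hot$stability[hot$final_pair[1L]],
    d$sd_cp[d$gene == "GAPDH"],
    d$cv_pct[d$gene == "GAPDH"],
    d$min_xfold[d$gene == "GAPDH"],
    bk$pair_r["GAPDH", "RPL4"],
    bk$index_cor$r[bk$index_cor$gene == "RPS9"],
    bk$index_cor$r[bk$index_cor$gene == "HPRT1"],
    min(fit$normfinder$stability),
    fit$consensus$geo_rank["RPS9"],
    fit$consensus$geo_rank["HPRT1"],
    efficiency_from_slope(-3.30),
    mean(cq$values[, "EEF1A1"]))
  out <- published_benchmarks()
  out$computed <- unname(computed)
  out$pass <- abs(out$computed - out$reference) <= out$tolerance
  out <- out[, c("check", "computed", "reference", "tolerance", "pass")]
  if (!quiet) {
    print(transform(out, computed = round(computed, 4)), row.names = FALSE)
    return(invisible(out))
  }
  out
}
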