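#' Construct a validated Cq matrix
#'
#' A `cq_matrix` holds one quantification-cycle (Cq) value per sample and
#' gene, plus a group label per sample. It is the input container for every
#' stability method in the package. Technical replicates are assumed to have
#' been averaged upstream; missing values are rejected rather than imputed,
#' because all downstream scores are dispersion statistics that a silent
#' imputation would bias.
#'
#' @param values Numeric matrix, samples in rows and genes in columns, with
#'   row and column names. All Cq must be finite and within `[5, 45]` cycles
#'   (values outside that range almost always indicate a unit mix-up, e.g.
#'   relative quantities pasted where Cq were expected).
#' @param group Character or factor of group labels, one per sample (row).
#'   A single group is allowed; grouped analyses require every group to have
#'   at least two samples.
#' @return An object of class `cq_matrix`: a list with elements `values`
#'   (the matrix) and `group` (a factor named by sample).
#' @examples
#' m <- matrix(c(20, 21, 22, 30, 31, 32), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), c("geneA", "geneB")))
#' cq_matrix(m, group = c("a", "a", "b"))
#' @export
cq_matrix <- function(values, group = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (samples x genes)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample row names and gene column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (nrow(values) < 3L) stop("need at least 3 samples")
  if (ncol(values) < 2L) stop("need at least 2 genes")
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("missing or non-finite Cq at sample '", rownames(values)[bad[1L]],
         "', gene '", colnames(values)[bad[2L]], "'")
  }
  if (any(values < 5 | values > 45)) {
    bad <- which(values < 5 | values > 45, arr.ind = TRUE)[1L, ]
    stop("Cq out of admissible range [5, 45] at sample '",
         rownames(values)[bad[1L]], "', gene '", colnames(values)[bad[2L]],
         "' (", values[bad[1L], bad[2L]], "); Cq/RQ confusion?")
  }
  if (is.null(group)) group <- rep("all", nrow(values))
  if (length(group) != nrow(values))
    stop("'group' must have one label per sample")
  group <- factor(as.character(group), levels = unique(as.character(group)))
  if (anyNA(group)) stop("missing group label")
  names(group) <- rownames(values)
  structure(list(values = values, group = group), class = "cq_matrix")
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat("Cq matrix: ", nrow(x$values), " samples x ", ncol(x$values),
      " genes\n", sep = "")
  cat("genes: ", paste(colnames(x$values), collapse = ", "), "\n", sep = "")
  tab <- table(x$group)
  cat("groups: ", paste(names(tab), " (n=", tab, ")", sep = "",
                        collapse = ", "), "\n", sep = "")
  cat("Cq range: [", min(x$values), ", ", max(x$values), "]\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.cq_matrix <- function(x, ...) x$values

#' @export
dim.cq_matrix <- function(x) dim(x$values)

#' Subset the samples of a Cq matrix
#'
#' @param cq A [cq_matrix()].
#' @param samples Either a character vector of sample ids, a logical/integer
#'   index over rows, or a single group label (matched against the group
#'   factor first, then against sample ids).
#' @return A `cq_matrix` restricted to the selected samples.
#' @export
subset_samples <- function(cq, samples) {
  stopifnot(inherits(cq, "cq_matrix"))
  if (is.character(samples) && length(samples) == 1L &&
      samples %in% levels(cq$group)) {
    keep <- cq$group == samples
  } else if (is.character(samples)) {
    missing <- setdiff(samples, rownames(cq$values))
    if (length(missing))
      stop("unknown sample ids: ", paste(missing, collapse = ", "))
    keep <- samples
  } else {
    keep <- samples
  }
  cq_matrix(cq$values[keep, , drop = FALSE],
            group = as.character(cq$group[keep]))
}

# Resolve a `samples` argument shared by analysis functions: NULL means all.
resolve_samples <- function(cq, samples) {
  if (is.null(samples)) cq else subset_samples(cq, samples)
}

# Lenient row selection for descriptive summaries, where subsets below the
# container's 3-sample minimum are still meaningful.
select_rows <- function(cq, samples) {
  v <- cq$values
  if (!is.null(samples)) {
    if (is.character(samples) && length(samples) == 1L &&
        samples %in% levels(cq$group)) {
      v <- v[cq$group == samples, , drop = FALSE]
    } else {
      v <- v[samples, , drop = FALSE]
    }
  }
  if (!nrow(v)) stop("empty sample subset")
  v
}

#' Read a Cq table from delimited text
#'
#' Reads a comma- or tab-delimited table of Cq values. The default layout is
#' samples as rows: the first column holds sample ids, an optional column
#' literally named `group` holds group labels, and the remaining numeric
#' columns are genes. A genes-as-rows table is accepted via
#' `orientation = "genes"` (it is transposed after reading; group labels can
#' then only be supplied through `group`).
#'
#' @param file Path to the file (or a connection).
#' @param orientation `"samples"` (default; samples as rows) or `"genes"`.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param group Optional vector of group labels overriding any `group`
#'   column in the file.
#' @return A [cq_matrix()].
#' @export
read_cq_table <- function(file, orientation = c("samples", "genes"),
                          sep = NULL, group = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) {
    header <- readLines(file, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(file, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", fill = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate ids in first column: ",
         paste(unique(df[[1L]][duplicated(df[[1L]])]), collapse = ", "))
  ids <- df[[1L]]
  df <- df[, -1L, drop = FALSE]
  file_group <- NULL
  gcol <- which(names(df) == "group")
  if (length(gcol)) {
    file_group <- df[[gcol[1L]]]
    df <- df[, -gcol, drop = FALSE]
  }
  num <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(df),
                                     dimnames = list(NULL, names(df)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric Cq value '", df[bad[1L], bad[2L]], "' at row '",
         ids[bad[1L]], "', column '", colnames(num)[bad[2L]], "'")
  }
  rownames(num) <- ids
  if (orientation == "genes") {
    num <- t(num)
    file_group <- NULL
  }
  cq_matrix(num, group = if (is.null(group)) file_group else group)
}

#' Write a Cq matrix to delimited text
#'
#' Writes the samples-as-rows layout understood by [read_cq_table()]:
#' a `sample` id column, a `group` column, then one column per gene.
#'
#' @param cq A [cq_matrix()].
#' @param file Output path.
#' @param digits Number of decimal places (default 2, the usual instrument
#'   export precision).
#' @return Invisibly, `file`.
#' @export
write_cq_table <- function(cq, file, digits = 2) {
  stopifnot(inherits(cq, "cq_matrix"))
  df <- data.frame(sample = rownames(cq$values),
                   group = as.character(cq$group),
                   format(round(cq$values, digits), nsmall = digits,
                          trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(file)
}
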