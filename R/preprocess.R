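#' Omics tables
#'
#' An `omics_table` holds a feature x sample matrix of transcript counts or
#' protein intensities, sample group labels (e.g. basal / PA / TbPA), and a
#' kind tag. Missing values are `NA` in the matrix; a logical missing mask is
#' derived on demand.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   dimnames.
#' @param groups Character vector of group labels, one per sample.
#' @param kind `"transcript"` or `"protein"`.
#' @return An `omics_table`.
#' @export
omics_table <- function(values, groups, kind = c("transcript", "protein")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(colnames(values)) ||
      (nrow(values) > 0L && is.null(rownames(values)))) {
    stop("omics_table: values must have feature and sample dimnames", call. = FALSE)
  }
  if (length(groups) != ncol(values)) {
    stop("omics_table: one group label per sample required", call. = FALSE)
  }
  if (any(!nzchar(groups)) || anyNA(groups)) {
    stop("omics_table: group labels must be nonempty", call. = FALSE)
  }
  structure(list(values = values, groups = as.character(groups), kind = kind),
            class = "omics_table")
}

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf("<omics_table> %s: %d features x %d samples, groups: %s, %d missing\n",
              x$kind, nrow(x$values), ncol(x$values),
              paste(unique(x$groups), collapse = "/"), sum(is.na(x$values))))
  invisible(x)
}

#' Read an omics table from TSV
#'
#' Expects a TSV whose first column holds feature ids and whose header names
#' the samples, plus a two-column TSV (`sample`, `group`) mapping samples to
#' groups. Missing values may be encoded as `NA` or empty fields.
#'
#' @param path Values TSV path.
#' @param groups_path Sample-to-group TSV path.
#' @param kind `"transcript"` or `"protein"`.
#' @return An `omics_table`.
#' @export
read_omics_tsv <- function(path, groups_path, kind = c("transcript", "protein")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- as.character(df[[1]])
  gmap <- utils::read.delim(groups_path, check.names = FALSE)
  grp <- stats::setNames(as.character(gmap[[2]]), as.character(gmap[[1]]))
  missing_s <- setdiff(colnames(vals), names(grp))
  if (length(missing_s)) {
    stop(sprintf("no group label for sample(s): %s",
                 paste(missing_s, collapse = ", ")), call. = FALSE)
  }
  omics_table(vals, unname(grp[colnames(vals)]), kind)
}

#' Write an omics table to TSV
#'
#' @param table An `omics_table`.
#' @param path Values TSV path.
#' @param groups_path Optional path for the sample-to-group TSV.
#' @export
write_omics_tsv <- function(table, path, groups_path = NULL) {
  df <- data.frame(feature = rownames(table$values), table$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    utils::write.table(data.frame(sample = colnames(table$values),
                                  group = table$groups),
                       groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Discard genes with low total counts
#'
#' Removes transcript features whose summed raw counts across all samples
#' fall below `min_total` (default 10, the usual "fewer than 10 total reads"
#' prefilter); a feature with exactly `min_total` reads is kept. Row order is
#' preserved.
#'
#' @param table A transcript `omics_table` of raw counts.
#' @param min_total Minimum total count to keep a feature.
#' @return The filtered `omics_table`.
#' @export
filter_low_count_genes <- function(table, min_total = 10) {
  stopifnot(inherits(table, "omics_table"))
  if (table$kind != "transcript") {
    stop("filter_low_count_genes applies to transcript tables", call. = FALSE)
  }
  if (any(table$values < 0, na.rm = TRUE)) {
    stop("negative counts in transcript table", call. = FALSE)
  }
  if (nrow(table$values) == 0L) return(table)
  totals <- rowSums(table$values, na.rm = TRUE)
  table$values <- table$values[totals >= min_total, , drop = FALSE]
  table
}

#' Log2-transform intensities
#'
#' Applies `v -> log2(v + pseudocount)` to make skewed count/intensity
#' distributions symmetric; `NA` stays `NA`. A zero pseudocount with zero
#' values would produce `-Inf` and is an error.
#'
#' @param table An `omics_table` with nonnegative values.
#' @param pseudocount Nonnegative constant added before the log.
#' @return The transformed `omics_table`.
#' @export
log2_transform <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "omics_table"), pseudocount >= 0)
  v <- table$values
  if (any(v < 0, na.rm = TRUE)) stop("log2_transform: negative values", call. = FALSE)
  if (pseudocount == 0 && any(v == 0, na.rm = TRUE)) {
    stop("log2_transform: zero values with pseudocount 0 (log of 0)", call. = FALSE)
  }
  table$values <- log2(v + pseudocount)
  table
}

#' Keep proteins with enough valid values in every group
#'
#' A protein is retained iff its fraction of non-missing values is at least
#' `min_valid_fraction` within each sample group (the common "70% valid
#' values per group" rule for label-free proteomics).
#'
#' @param table A protein `omics_table`.
#' @param min_valid_fraction Minimum per-group non-missing fraction.
#' @return The filtered `omics_table`.
#' @export
filter_proteins_by_validity <- function(table, min_valid_fraction = 0.70) {
  stopifnot(inherits(table, "omics_table"))
  if (table$kind != "protein") {
    stop("filter_proteins_by_validity applies to protein tables", call. = FALSE)
  }
  groups <- unique(table$groups)
  for (g in groups) {
    if (sum(table$groups == g) == 0L) {
      stop(sprintf("group '%s' has zero samples", g), call. = FALSE)
    }
  }
  if (nrow(table$values) == 0L) return(table)
  keep <- rep(TRUE, nrow(table$values))
  for (g in groups) {
    cols <- table$groups == g
    frac <- rowMeans(!is.na(table$values[, cols, drop = FALSE]))
    keep <- keep & (frac >= min_valid_fraction)
  }
  table$values <- table$values[keep, , drop = FALSE]
  table
}

#' K-nearest-neighbor imputation of missing values
#'
#' Each missing cell is replaced by the mean of that sample's values over the
#' `k` nearest feature rows, with distance measured as Euclidean distance on
#' the columns both rows observe (normalized by the number of shared
#' columns, so rows with different missingness are comparable). Neighbors
#' must observe the column being imputed. Observed cells are never touched.
#'
#' @param table An `omics_table`.
#' @param k Number of neighbors (lowered with a warning if too few rows
#'   qualify).
#' @return The imputed `omics_table` (no missing values remain).
#' @export
knn_impute <- function(table, k = 10) {
  stopifnot(inherits(table, "omics_table"), k >= 1)
  v <- table$values
  if (!anyNA(v)) return(table)
  all_missing <- rownames(v)[rowSums(!is.na(v)) == 0L]
  if (length(all_missing)) {
    stop(sprintf("knn_impute: feature(s) with no observed values: %s",
                 paste(all_missing, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(v)
  if (k > n - 1L) {
    warning(sprintf("knn_impute: k lowered from %d to %d (only %d candidate rows)",
                    k, n - 1L, n - 1L))
    k <- n - 1L
  }
  out <- v
  for (i in which(rowSums(is.na(v)) > 0L)) {
    d <- rep(NA_real_, n)
    for (j in seq_len(n)) {
      if (j == i) next
      shared <- !is.na(v[i, ]) & !is.na(v[j, ])
      if (!any(shared)) next
      d[j] <- sqrt(sum((v[i, shared] - v[j, shared])^2) / sum(shared))
    }
    for (col in which(is.na(v[i, ]))) {
      cand <- which(!is.na(d) & !is.na(v[, col]))
      if (length(cand) == 0L) {
        stop(sprintf("knn_impute: no neighbor observes column '%s' for feature '%s'",
                     colnames(v)[col], rownames(v)[i]), call. = FALSE)
      }
      nb <- cand[order(d[cand], cand)][seq_len(min(k, length(cand)))]
      out[i, col] <- mean(v[nb, col])
    }
  }
  table$values <- out
  table
}

#' Z-score standardization of features
#'
#' Centers and scales each feature row to mean 0 and population (1/N)
#' standard deviation 1. Population sd is used so the transform is exactly
#' idempotent and test expectations are closed-form.
#'
#' @param table An `omics_table` without missing values.
#' @return The standardized `omics_table`.
#' @export
zscore <- function(table) {
  stopifnot(inherits(table, "omics_table"))
  v <- table$values
  if (anyNA(v)) stop("zscore: missing values present (impute first)", call. = FALSE)
  mu <- rowMeans(v)
  sd_pop <- sqrt(rowMeans((v - mu)^2))
  zero <- sd_pop < 1e-300
  if (any(zero)) {
    stop(sprintf("zscore: constant feature(s): %s",
                 paste(rownames(v)[zero], collapse = ", ")), call. = FALSE)
  }
  table$values <- (v - mu) / sd_pop
  table
}

#' Collapse an omics table to one value per feature
#'
#' Helper for GPR mapping: averages samples (optionally within one group)
#' into a single named vector, the per-condition abundance profile that
#' [map_to_reactions()] consumes.
#'
#' @param table An `omics_table`.
#' @param group Optional group label to restrict to.
#' @return Named numeric vector feature -> mean value (`NA` dropped).
#' @export
collapse_samples <- function(table, group = NULL) {
  v <- table$values
  if (!is.null(group)) {
    if (!group %in% table$groups) {
      stop(sprintf("no group '%s' in table", group), call. = FALSE)
    }
    v <- v[, table$groups == group, drop = FALSE]
  }
  rowMeans(v, na.rm = TRUE)
}
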