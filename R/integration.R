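#' Reaction activity vectors
#'
#' An `activity_vector` carries one unitless score per covered reaction.
#' Reactions without a GPR, or whose GPR cannot be resolved from the data,
#' are absent from the coverage — never silently zero.
#'
#' @param scores Named numeric vector reaction id -> score (finite).
#' @param provenance `"transcript"`, `"protein"` or `"integrated"`.
#' @return An `activity_vector`.
#' @export
activity_vector <- function(scores, provenance = c("transcript", "protein",
                                                   "integrated")) {
  provenance <- match.arg(provenance)
  if (length(scores) && (is.null(names(scores)) || any(!nzchar(names(scores))))) {
    stop("activity_vector: scores must be named by reaction id", call. = FALSE)
  }
  if (any(!is.finite(scores))) {
    stop("activity_vector: scores must be finite", call. = FALSE)
  }
  structure(list(scores = scores, provenance = provenance),
            class = "activity_vector")
}

#' @export
print.activity_vector <- function(x, ...) {
  cat(sprintf("<activity_vector> %s: %d reactions covered\n",
              x$provenance, length(x$scores)))
  invisible(x)
}

#' Coverage of an activity vector
#'
#' @param av An `activity_vector`.
#' @return Character vector of covered reaction ids.
#' @export
coverage <- function(av) names(av$scores)

#' Map gene or protein values onto reactions through GPR rules
#'
#' Evaluates each reaction's GPR with the measured values: a gene leaf takes
#' its value, `AND` the minimum of its children (all complex members are
#' needed), `OR` the maximum (the strongest isozyme suffices). Reactions
#' without a GPR, or unresolvable under the missing policy, are left out of
#' the coverage. Features in `feature_values` that match no GPR leaf are
#' collected in the `unmatched` attribute as a mapping log.
#'
#' @param model A `metabolic_model`.
#' @param feature_values Named numeric vector, gene/protein id -> value, in
#'   the same id namespace as the GPR leaves.
#' @param provenance Provenance tag for the result.
#' @param missing_policy Passed to [eval_gpr()]: `"ignore-or"` (default)
#'   drops missing leaves under `OR` but leaves `AND` unresolved; `"strict"`
#'   requires every leaf.
#' @return An `activity_vector` with attribute `unmatched`.
#' @export
map_to_reactions <- function(model, feature_values,
                             provenance = c("transcript", "protein"),
                             missing_policy = c("ignore-or", "strict")) {
  provenance <- match.arg(provenance)
  missing_policy <- match.arg(missing_policy)
  scores <- numeric(0)
  used <- character(0)
  for (r in model$reactions) {
    if (is.null(r$gpr)) next
    used <- c(used, gpr_genes(r$gpr))
    val <- eval_gpr(r$gpr, feature_values, missing_policy = missing_policy)
    if (!is.na(val)) scores[r$id] <- val
  }
  av <- activity_vector(scores, provenance)
  attr(av, "unmatched") <- setdiff(names(feature_values), unique(used))
  av
}

#' Principal component analysis by covariance eigen-decomposition
#'
#' Computes the covariance matrix of the input, its eigen-decomposition,
#' and the component scores. Components are sorted by descending eigenvalue
#' and signs are fixed deterministically: the largest-magnitude loading of
#' each component is made positive. Rank-deficient input is fine; a
#' zero-variance column is an error (standardize or drop it).
#'
#' @param x Numeric matrix, observations x variables (here: reactions x
#'   omics layers), no missing values.
#' @return A `pca_result`: `eigenvalues`, `loadings` (orthonormal columns),
#'   `variance_fraction`, `scores` (centered data projected on loadings).
#' @export
pca_cov <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("pca_cov: missing values", call. = FALSE)
  if (ncol(x) < 2L) stop("pca_cov: need at least 2 variables", call. = FALSE)
  if (nrow(x) < 3L) stop("pca_cov: need at least 3 observations", call. = FALSE)
  vars <- apply(x, 2, stats::var)
  if (any(vars < 1e-300)) {
    stop(sprintf("pca_cov: zero-variance column(s): %s",
                 paste(colnames(x)[vars < 1e-300], collapse = ", ")),
         call. = FALSE)
  }
  C <- stats::cov(x)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  load <- eg$vectors
  for (j in seq_len(ncol(load))) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) load[, j] <- -load[, j]
  }
  centered <- sweep(x, 2, colMeans(x))
  structure(list(eigenvalues = ev,
                 loadings = load,
                 variance_fraction = ev / sum(ev),
                 scores = centered %*% load),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' Fuse transcript and protein activity vectors by PCA
#'
#' Takes the reactions covered by both vectors, standardizes each layer
#' across reactions (z-score over the intersection, so the two layers are on
#' comparable scales), runs [pca_cov()] on the reactions x 2 matrix, and
#' collapses the first `n_components` component scores into a single
#' integrated score per reaction as the variance-fraction-weighted sum
#' `sum_c score_c * varfrac_c`. With perfectly correlated inputs the
#' integrated vector reproduces their common ranking.
#'
#' @param transcript_av,protein_av `activity_vector`s from
#'   [map_to_reactions()].
#' @param n_components Number of leading components to combine (default 2).
#' @return An integrated `activity_vector` with attribute `pca` (the
#'   `pca_result`).
#' @export
integrate_activity <- function(transcript_av, protein_av, n_components = 2) {
  common <- intersect(coverage(transcript_av), coverage(protein_av))
  if (length(common) == 0L) {
    stop("integrate_activity: no reaction is covered by both layers", call. = FALSE)
  }
  z <- function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s < 1e-300) stop("integrate_activity: constant layer", call. = FALSE)
    (v - mean(v)) / s
  }
  mat <- cbind(transcript = z(transcript_av$scores[common]),
               protein = z(protein_av$scores[common]))
  rownames(mat) <- common
  p <- pca_cov(mat)
  n_components <- min(n_components, ncol(mat))
  w <- p$variance_fraction[seq_len(n_components)]
  sc <- p$scores[, seq_len(n_components), drop = FALSE]
  integrated <- as.numeric(sc %*% w)
  names(integrated) <- common
  av <- activity_vector(integrated, "integrated")
  attr(av, "pca") <- p
  av
}

#' Rescale an integrated activity vector onto the iMAT threshold scale
#'
#' Applies the signed logarithm `s(x) = sign(x) * ln(1 + |x|)` (defined for
#' the signed PCA scores, odd, monotone), then an affine map anchoring the
#' `lower_q` quantile at `low` and the `upper_q` quantile at `high`, so the
#' HIGH/LOW classes of [classify_reactions()] correspond to the outer
#' quartiles by default.
#'
#' @param av An integrated `activity_vector`.
#' @param low,high Target threshold values (defaults -500 / +500).
#' @param lower_q,upper_q Anchored quantiles (defaults 0.25 / 0.75).
#' @return The rescaled `activity_vector`.
#' @export
to_threshold_scale <- function(av, low = -500, high = 500,
                               lower_q = 0.25, upper_q = 0.75) {
  stopifnot(inherits(av, "activity_vector"))
  if (av$provenance != "integrated") {
    stop("to_threshold_scale expects an integrated activity vector", call. = FALSE)
  }
  x <- av$scores
  if (length(x) < 2L || max(x) - min(x) < 1e-300) {
    stop("to_threshold_scale: constant activity vector", call. = FALSE)
  }
  s <- sign(x) * log1p(abs(x))
  qs <- stats::quantile(s, c(lower_q, upper_q), names = FALSE, type = 7)
  if (qs[2] - qs[1] < 1e-300) {
    stop("to_threshold_scale: degenerate quantiles", call. = FALSE)
  }
  slope <- (high - low) / (qs[2] - qs[1])
  out <- low + slope * (s - qs[1])
  activity_vector(stats::setNames(out, names(x)), "integrated")
}

#' Write an activity table as TSV
#'
#' @param model A `metabolic_model` (defines the reaction order).
#' @param transcript_av,protein_av,integrated_av,scaled_av Activity vectors
#'   (any may be `NULL`).
#' @param path Output TSV path.
#' @export
write_activity_tsv <- function(model, path, transcript_av = NULL,
                               protein_av = NULL, integrated_av = NULL,
                               scaled_av = NULL) {
  rids <- reaction_ids(model)
  pull <- function(av) if (is.null(av)) rep(NA_real_, length(rids)) else
    unname(av$scores[rids])
  df <- data.frame(reaction = rids,
                   transcript = pull(transcript_av),
                   protein = pull(protein_av),
                   integrated = pull(integrated_av),
                   scaled = pull(scaled_av))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
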