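#' Stoichiometric matrix
#'
#' Builds the sparse stoichiometric matrix S (metabolites x reactions):
#' entry (m, r) is the signed coefficient of metabolite m in reaction r,
#' negative for substrates. Row order follows the model's metabolite order,
#' column order the reaction order.
#'
#' @param model A `metabolic_model`.
#' @return A `dgCMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- metabolite_ids(model)
  rxn_ids <- reaction_ids(model)
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(model$reactions)) {
    st <- model$reactions[[k]]$stoichiometry
    i <- c(i, match(names(st), met_ids))
    j <- c(j, rep.int(k, length(st)))
    x <- c(x, unname(st))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' Write the stoichiometric matrix as TSV
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @export
write_stoichiometric_tsv <- function(model, path) {
  S <- as.matrix(stoichiometric_matrix(model))
  df <- data.frame(metabolite = rownames(S), S, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a flat elemental formula
#'
#' Accepts flat formulas such as `"C6H12O6"` or `"C10H17N3O6S"`: element
#' symbols (one uppercase letter, optional lowercase) each followed by an
#' optional integer count. Parenthesized groups are rejected — real
#' reconstruction formulas are flat and group expansion would make the
#' parser's behavior harder to pin down.
#'
#' @param formula Formula string; `""` returns an empty vector.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  if (!nzchar(formula)) return(stats::setNames(integer(0), character(0)))
  if (grepl("[()]", formula)) {
    stop(sprintf("formula '%s': parenthesized groups are not supported", formula),
         call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  pieces <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop(sprintf("formula '%s': cannot parse as element counts", formula),
         call. = FALSE)
  }
  els <- sub("[0-9]*$", "", pieces)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", pieces),
                           sub("^[A-Za-z]+", "", pieces), "1"))
  out <- tapply(cnt, els, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Element matrix of a model
#'
#' Rows are chemical elements (plus a `"charge"` pseudo-element when any
#' metabolite carries a charge), columns are metabolites. Metabolites with an
#' empty formula are reported in the `"unknown"` attribute and their columns
#' are NA, never silently zero.
#'
#' @param model A `metabolic_model`.
#' @return Numeric matrix elements x metabolites with attribute `unknown`
#'   (character vector of metabolite ids lacking a formula).
#' @export
element_matrix <- function(model) {
  met_ids <- metabolite_ids(model)
  parsed <- lapply(model$metabolites, function(m) parse_formula(m$formula))
  charges <- vapply(model$metabolites, `[[`, integer(1), "charge")
  elements <- sort(unique(unlist(lapply(parsed, names))))
  has_charge <- any(!is.na(charges))
  rows <- c(elements, if (has_charge) "charge")
  E <- matrix(0, nrow = length(rows), ncol = length(met_ids),
              dimnames = list(rows, met_ids))
  unknown <- character(0)
  for (k in seq_along(met_ids)) {
    p <- parsed[[k]]
    if (length(p) == 0L && !nzchar(model$metabolites[[k]]$formula)) {
      E[, k] <- NA_real_
      unknown <- c(unknown, met_ids[k])
      next
    }
    E[names(p), k] <- p
    if (has_charge) E["charge", k] <- if (is.na(charges[k])) 0 else charges[k]
  }
  attr(E, "unknown") <- unknown
  E
}

#' Check a reaction's elemental and charge balance
#'
#' For each element e the residual is `sum_m coeff(m) * count(e, m)`; a
#' reaction is mass- and charge-balanced iff all residuals are zero.
#' Exchange reactions are boundary pseudo-reactions and are skipped by
#' design (their residual is the transported species itself).
#'
#' @param model A `metabolic_model`.
#' @param rid Reaction id.
#' @return Named numeric vector element -> residual; a zero-length vector for
#'   exchange reactions.
#' @export
check_mass_balance <- function(model, rid) {
  rxn <- get_reaction(model, rid)
  if (rxn$is_exchange) return(stats::setNames(numeric(0), character(0)))
  E <- element_matrix(model)
  mets <- names(rxn$stoichiometry)
  unk <- intersect(mets, attr(E, "unknown"))
  if (length(unk)) {
    stop(sprintf("reaction '%s': unknown composition for metabolite(s) %s",
                 rid, paste(unk, collapse = ", ")), call. = FALSE)
  }
  res <- as.numeric(E[, mets, drop = FALSE] %*% rxn$stoichiometry)
  stats::setNames(res, rownames(E))
}

#' Residuals for every non-exchange reaction
#'
#' @param model A `metabolic_model`.
#' @return Named list reaction id -> residual vector (see
#'   [check_mass_balance()]); reactions touching metabolites of unknown
#'   composition are returned as `NA`.
#' @export
mass_balance_report <- function(model) {
  out <- list()
  for (r in model$reactions) {
    if (r$is_exchange) next
    out[[r$id]] <- tryCatch(check_mass_balance(model, r$id),
                            error = function(e) NA)
  }
  out
}
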