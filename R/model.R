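#' Metabolic model containers
#'
#' A `metabolic_model` is the in-memory form of a constraint-based model:
#' a metabolite table, a list of reactions (each with signed stoichiometry,
#' flux bounds in mmol gDW^-1 h^-1 and an optional GPR tree), and a single
#' maximization objective. Compartments follow the nine-letter convention
#' used by human reconstructions: cytosol `c`, extracellular `e`, Golgi `g`,
#' inner mitochondrial compartment `i`, lysosome `l`, mitochondria `m`,
#' nucleus `n`, endoplasmic reticulum `r`, peroxisome `x`.
#'
#' @name metabolic_model
NULL

COMPARTMENTS <- c("c", "e", "g", "i", "l", "m", "n", "r", "x")

#' Construct a metabolite
#'
#' @param id Unique metabolite identifier.
#' @param name Human-readable name (defaults to `id`).
#' @param compartment One-letter compartment code (see [metabolic_model]).
#' @param formula Flat elemental formula string such as `"C6H12O6"`; empty
#'   string if unknown.
#' @param charge Integer formal charge, or `NA` if unset.
#' @return A named list of class `metabolite`.
#' @export
metabolite <- function(id, name = id, compartment = "c", formula = "",
                       charge = NA_integer_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!compartment %in% COMPARTMENTS) {
    stop(sprintf("metabolite '%s': unknown compartment '%s' (must be one of %s)",
                 id, compartment, paste(COMPARTMENTS, collapse = ",")),
         call. = FALSE)
  }
  structure(list(id = id, name = name, compartment = compartment,
                 formula = formula, charge = as.integer(charge)),
            class = "metabolite")
}

#' Construct a reaction
#'
#' Stoichiometry is a named numeric vector: negative coefficients are
#' substrates, positive are products. Exchange reactions are boundary
#' pseudo-reactions touching a single metabolite, written in the uptake =
#' negative flux convention (`"M ->"`).
#'
#' @param id Unique reaction identifier.
#' @param stoichiometry Named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound Flux bounds (mmol gDW^-1 h^-1).
#' @param gpr A GPR rule string (parsed with [parse_gpr()]), a `gpr` object,
#'   or `NULL`/`""` for no gene association.
#' @param subsystem Free-text pathway label.
#' @param name Human-readable name.
#' @return A named list of class `reaction`; `is_exchange` is derived from
#'   the stoichiometry (exactly one metabolite).
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     gpr = NULL, subsystem = "", name = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stoichiometry <- unlist(stoichiometry)
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry)))) {
    stop(sprintf("reaction '%s': stoichiometry must be a named vector", id),
         call. = FALSE)
  }
  if (anyDuplicated(names(stoichiometry))) {
    stop(sprintf("reaction '%s': duplicated metabolite in stoichiometry", id),
         call. = FALSE)
  }
  if (any(stoichiometry == 0)) stoichiometry <- stoichiometry[stoichiometry != 0]
  if (!is.numeric(lower_bound) || !is.numeric(upper_bound) ||
      lower_bound > upper_bound) {
    stop(sprintf("reaction '%s': requires lower_bound <= upper_bound", id),
         call. = FALSE)
  }
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (!is.null(gpr) && !inherits(gpr, "gpr")) {
    stop(sprintf("reaction '%s': gpr must be a rule string or gpr object", id),
         call. = FALSE)
  }
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gpr = gpr,
                 is_exchange = length(stoichiometry) == 1L,
                 subsystem = subsystem),
            class = "reaction")
}

#' Construct and validate a metabolic model
#'
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param objective Reaction id of the (maximized) objective, or `NULL`.
#' @param id Model identifier.
#' @return A validated object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, objective = NULL,
                            id = "model") {
  m <- structure(list(id = id,
                      metabolites = metabolites,
                      reactions = reactions,
                      objective = objective),
                 class = "metabolic_model")
  validate_model(m)
}

#' Validate model invariants
#'
#' Checks id uniqueness, that every stoichiometry entry names a model
#' metabolite, bound sanity, and that the objective reaction exists. Returns
#' the model invisibly so it can be used in pipes; stops with a message
#' listing all offenders otherwise.
#'
#' @param model A `metabolic_model`.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  met_ids <- vapply(model$metabolites, `[[`, character(1), "id")
  rxn_ids <- vapply(model$reactions, `[[`, character(1), "id")
  errs <- character(0)
  if (anyDuplicated(met_ids)) {
    errs <- c(errs, paste0("duplicate metabolite ids: ",
                           paste(unique(met_ids[duplicated(met_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(rxn_ids)) {
    errs <- c(errs, paste0("duplicate reaction ids: ",
                           paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", ")))
  }
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoichiometry), met_ids)
    if (length(unknown)) {
      errs <- c(errs, sprintf("reaction '%s' references unknown metabolites: %s",
                              r$id, paste(unknown, collapse = ", ")))
    }
    if (r$lower_bound > r$upper_bound) {
      errs <- c(errs, sprintf("reaction '%s': lower_bound > upper_bound", r$id))
    }
  }
  if (!is.null(model$objective) && !model$objective %in% rxn_ids) {
    errs <- c(errs, sprintf("objective reaction '%s' not in model", model$objective))
  }
  if (length(errs)) {
    stop(paste0("invalid model '", model$id, "':\n  ",
                paste(errs, collapse = "\n  ")), call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions (%d exchanges)%s\n",
              x$id, length(x$metabolites), length(x$reactions),
              sum(vapply(x$reactions, `[[`, logical(1), "is_exchange")),
              if (is.null(x$objective)) "" else
                sprintf(", objective: %s", x$objective)))
  invisible(x)
}

metabolite_ids <- function(model) {
  vapply(model$metabolites, `[[`, character(1), "id")
}

#' Reaction and exchange accessors
#'
#' @param model A `metabolic_model`.
#' @return `reaction_ids()`: character vector in model order;
#'   `exchange_ids()`: ids of boundary (single-metabolite) reactions;
#'   `get_reaction()`: the `reaction` object with id `rid`.
#' @export
reaction_ids <- function(model) {
  vapply(model$reactions, `[[`, character(1), "id")
}

#' @rdname reaction_ids
#' @export
exchange_ids <- function(model) {
  rids <- reaction_ids(model)
  rids[vapply(model$reactions, `[[`, logical(1), "is_exchange")]
}

#' @rdname reaction_ids
#' @param rid Reaction id.
#' @export
get_reaction <- function(model, rid) {
  idx <- match(rid, reaction_ids(model))
  if (is.na(idx)) stop(sprintf("no reaction '%s' in model", rid), call. = FALSE)
  model$reactions[[idx]]
}

#' Modify flux bounds of one reaction
#'
#' @param model A `metabolic_model`.
#' @param rid Reaction id.
#' @param lower,upper New bounds; `NULL` leaves a bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, rid, lower = NULL, upper = NULL) {
  idx <- match(rid, reaction_ids(model))
  if (is.na(idx)) stop(sprintf("no reaction '%s' in model", rid), call. = FALSE)
  if (!is.null(lower)) model$reactions[[idx]]$lower_bound <- as.numeric(lower)
  if (!is.null(upper)) model$reactions[[idx]]$upper_bound <- as.numeric(upper)
  if (model$reactions[[idx]]$lower_bound > model$reactions[[idx]]$upper_bound) {
    stop(sprintf("reaction '%s': lower bound exceeds upper bound", rid),
         call. = FALSE)
  }
  model
}

bounds_matrix <- function(model) {
  cbind(lb = vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
        ub = vapply(model$reactions, `[[`, numeric(1), "upper_bound"))
}
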