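#' Classify reactions by activity score
#'
#' Maps a threshold-scale activity vector onto the three iMAT states:
#' score strictly above `high_threshold` is `HIGH`, strictly below
#' `low_threshold` is `LOW`, in between (inclusive) is `MODERATE`. Reactions
#' absent from the vector's coverage are `UNCOVERED`.
#'
#' @param av An `activity_vector` on the threshold scale.
#' @param model A `metabolic_model`.
#' @param low_threshold,high_threshold Class boundaries (defaults -500/+500).
#' @return A named character vector (one state per model reaction) of class
#'   `reaction_classification`.
#' @export
classify_reactions <- function(av, model, low_threshold = -500,
                               high_threshold = 500) {
  stopifnot(low_threshold < high_threshold)
  rids <- reaction_ids(model)
  states <- rep("UNCOVERED", length(rids))
  names(states) <- rids
  cov <- intersect(rids, coverage(av))
  sc <- av$scores[cov]
  states[cov] <- ifelse(sc > high_threshold, "HIGH",
                        ifelse(sc < low_threshold, "LOW", "MODERATE"))
  structure(states, class = "reaction_classification")
}

#' @export
print.reaction_classification <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = c("HIGH", "MODERATE", "LOW",
                                             "UNCOVERED")))
  cat("<reaction_classification>",
      paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' iMAT: maximize agreement between fluxes and activity classes
#'
#' Solves the iMAT mixed-integer program: maximize the number of HIGH
#' reactions carrying flux of magnitude at least `epsilon` (in either
#' direction if reversible) plus the number of LOW reactions carrying zero
#' flux, subject to steady state and the bounds. UNCOVERED and MODERATE
#' reactions are neither rewarded nor penalized.
#'
#' The solver is an exact depth-first branch-and-bound over the indicator
#' variables: fixing an indicator only tightens one reaction's bounds, so
#' each node is an LP feasibility check and the bound
#' `satisfied + remaining` prunes the tree. Satisfying branches are explored
#' first and ties resolve to the first optimum in a deterministic order; the
#' reported flux vector additionally minimizes total absolute flux within
#' the optimal indicator assignment, so results are reproducible.
#'
#' @param model A `metabolic_model`.
#' @param classification A `reaction_classification` (see
#'   [classify_reactions()]).
#' @param epsilon Minimum flux magnitude for a HIGH reaction to count as
#'   active (default 1.0, the original iMAT choice).
#' @param integer_tolerance Feasibility tolerance on the LP checks.
#' @return An `imat_solution`: `fluxes`, `objective` (number of satisfied
#'   indicators), `indicators` (named logical per HIGH/LOW reaction),
#'   `status`.
#' @export
imat <- function(model, classification, epsilon = 1.0,
                 integer_tolerance = 1e-6) {
  rids <- reaction_ids(model)
  stopifnot(all(rids %in% names(classification)))
  S <- as.matrix(stoichiometric_matrix(model))
  bnd <- bounds_matrix(model)
  lb0 <- bnd[, "lb"]; ub0 <- bnd[, "ub"]
  high <- which(unclass(classification)[rids] == "HIGH")
  low <- which(unclass(classification)[rids] == "LOW")
  ind_rxn <- c(high, low)
  ind_kind <- c(rep("HIGH", length(high)), rep("LOW", length(low)))
  k <- length(ind_rxn)

  feasible <- function(lb, ub) {
    if (any(lb > ub + 1e-12)) return(FALSE)
    sol <- solve_lp(numeric(length(rids)), S, rep(0, nrow(S)), lb, ub)
    sol$status == "optimal"
  }
  if (!feasible(lb0, ub0)) stop("iMAT: model is infeasible", call. = FALSE)

  best <- new.env(parent = emptyenv())
  best$value <- -1L
  best$assign <- NULL

  # assign[i] in {"fwd","bwd","zero","off"}; bounds carry the implied cuts
  recurse <- function(i, satisfied, assign, lb, ub) {
    if (satisfied + (k - i + 1L) <= best$value) return()
    if (i > k) {
      if (satisfied > best$value) {
        best$value <- satisfied
        best$assign <- assign
      }
      return()
    }
    r <- ind_rxn[i]
    if (ind_kind[i] == "HIGH") {
      if (ub[r] >= epsilon - integer_tolerance) {
        lb2 <- lb; lb2[r] <- max(lb[r], epsilon)
        if (feasible(lb2, ub)) {
          assign[i] <- "fwd"
          recurse(i + 1L, satisfied + 1L, assign, lb2, ub)
        }
      }
      if (lb[r] <= -epsilon + integer_tolerance) {
        ub2 <- ub; ub2[r] <- min(ub[r], -epsilon)
        if (feasible(lb, ub2)) {
          assign[i] <- "bwd"
          recurse(i + 1L, satisfied + 1L, assign, lb, ub2)
        }
      }
      assign[i] <- "off"
      recurse(i + 1L, satisfied, assign, lb, ub)
    } else {
      if (lb[r] <= integer_tolerance && ub[r] >= -integer_tolerance) {
        lb2 <- lb; ub2 <- ub; lb2[r] <- 0; ub2[r] <- 0
        if (feasible(lb2, ub2)) {
          assign[i] <- "zero"
          recurse(i + 1L, satisfied + 1L, assign, lb2, ub2)
        }
      }
      assign[i] <- "off"
      recurse(i + 1L, satisfied, assign, lb, ub)
    }
  }
  recurse(1L, 0L, character(k), lb0, ub0)

  # rebuild the bounds of the optimal assignment and pick the minimum-|v| flux
  lb <- lb0; ub <- ub0
  if (k > 0L) {
    for (i in seq_len(k)) {
      r <- ind_rxn[i]
      switch(best$assign[i],
             fwd = { lb[r] <- max(lb[r], epsilon) },
             bwd = { ub[r] <- min(ub[r], -epsilon) },
             zero = { lb[r] <- 0; ub[r] <- 0 },
             off = NULL)
    }
  }
  v <- min_total_flux(S, lb, ub)
  indicators <- if (k > 0L)
    stats::setNames(best$assign != "off", rids[ind_rxn]) else logical(0)
  structure(list(fluxes = stats::setNames(v, rids),
                 objective = best$value,
                 indicators = indicators,
                 epsilon = epsilon,
                 status = "optimal"),
            class = "imat_solution")
}

#' @export
print.imat_solution <- function(x, ...) {
  cat(sprintf("<imat_solution> %d of %d indicators satisfied (%s)\n",
              x$objective, length(x$indicators), x$status))
  invisible(x)
}

# minimum total |v| over {S v = 0, lb <= v <= ub} via variable splitting
min_total_flux <- function(S, lb, ub) {
  n <- ncol(S)
  A <- cbind(S, -S)
  lo <- c(pmax(lb, 0), pmax(-ub, 0))
  hi <- c(pmax(ub, 0), pmax(-lb, 0))
  sol <- solve_lp(rep(1, 2 * n), A, rep(0, nrow(S)), lo, hi)
  if (sol$status != "optimal") stop("min_total_flux: infeasible", call. = FALSE)
  sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
}

#' Extract the context-specific model from an iMAT solution
#'
#' Retains the reactions carrying flux above `flux_tolerance` in the iMAT
#' solution, plus all exchange reactions and the objective reaction (the
#' downstream medium step needs the boundary intact), then drops metabolites
#' no retained reaction touches.
#'
#' @param model The parent `metabolic_model`.
#' @param solution An `imat_solution`.
#' @param classification The `reaction_classification` used for the solve
#'   (kept for the record; extraction itself is flux-driven).
#' @param flux_tolerance Magnitude below which a flux counts as zero.
#' @return The extracted `metabolic_model`.
#' @export
extract_context_model <- function(model, solution, classification = NULL,
                                  flux_tolerance = 1e-6) {
  stopifnot(inherits(solution, "imat_solution"))
  if (solution$status != "optimal") {
    stop("extract_context_model: solution is not optimal", call. = FALSE)
  }
  keep <- vapply(model$reactions, function(r) {
    r$is_exchange || identical(r$id, model$objective) ||
      abs(solution$fluxes[r$id]) > flux_tolerance
  }, logical(1))
  rxns <- model$reactions[keep]
  used <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
  mets <- Filter(function(m) m$id %in% used, model$metabolites)
  out <- metabolic_model(mets, rxns, objective = model$objective,
                         id = paste0(model$id, "_context"))
  if (!is.null(out$objective) && !out$objective %in% reaction_ids(out)) {
    stop("extract_context_model: objective reaction was pruned", call. = FALSE)
  }
  out
}

#' Expression-derived flux bounds (exp2flux analog)
#'
#' Rescales each covered reaction's bounds by its activity: the upper bound
#' becomes `v_max * (score - min) / (max - min)` over the coverage, and the
#' lower bound its negative for reversible reactions (original `lb < 0`) or
#' zero otherwise. Uncovered reactions keep their original bounds.
#'
#' @param model A `metabolic_model`.
#' @param av An `activity_vector`.
#' @param v_max Flux scale of the most active reaction (mmol gDW^-1 h^-1).
#' @return The re-bounded `metabolic_model`.
#' @export
activity_to_bounds <- function(model, av, v_max = 1000) {
  sc <- av$scores
  if (length(sc) == 0L) return(model)
  rng <- range(sc)
  if (rng[2] - rng[1] < 1e-300) {
    stop("activity_to_bounds: constant activity vector", call. = FALSE)
  }
  for (k in seq_along(model$reactions)) {
    r <- model$reactions[[k]]
    if (!r$id %in% names(sc)) next
    cap <- v_max * (sc[[r$id]] - rng[1]) / (rng[2] - rng[1])
    model$reactions[[k]]$upper_bound <- cap
    model$reactions[[k]]$lower_bound <- if (r$lower_bound < 0) -cap else 0
  }
  model
}
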