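#' Flux balance analysis
#'
#' Maximizes the model objective subject to steady state (`S v = 0`) and the
#' flux bounds. With `loopless = TRUE` the optimal solution is post-processed
#' CycleFreeFlux-style: exchange fluxes and the objective flux are fixed at
#' their FBA values, every internal reaction is restricted to the sign of its
#' FBA flux, and total internal flux is minimized by LP. The result provably
#' contains no thermodynamically infeasible internal cycle: any steady-state
#' cycle supported on internal reactions with the solution's sign pattern
#' could be subtracted, strictly lowering the minimized norm. Use
#' [find_internal_cycle()] to verify the property on any flux vector.
#'
#' @param model A `metabolic_model` with an objective.
#' @param loopless Remove thermodynamically infeasible internal cycles.
#' @param tol Flux tolerance.
#' @return A `flux_result`: list with `fluxes` (named), `objective`,
#'   `status`, `loopless`.
#' @export
fba <- function(model, loopless = FALSE, tol = 1e-9) {
  if (is.null(model$objective)) stop("model has no objective", call. = FALSE)
  S <- as.matrix(stoichiometric_matrix(model))
  bnd <- bounds_matrix(model)
  rids <- reaction_ids(model)
  obj <- as.numeric(rids == model$objective)
  sol <- solve_lp(obj, S, rep(0, nrow(S)), bnd[, "lb"], bnd[, "ub"],
                  maximize = TRUE)
  if (sol$status != "optimal") {
    return(structure(list(fluxes = stats::setNames(rep(NA_real_, length(rids)), rids),
                          objective = NA_real_, status = sol$status,
                          loopless = loopless),
                     class = "flux_result"))
  }
  v <- stats::setNames(sol$x, rids)
  if (loopless) v <- cycle_free_flux(model, S, bnd, v, tol = tol)
  structure(list(fluxes = v, objective = unname(v[model$objective]),
                 status = "optimal", loopless = loopless),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf("<flux_result> status: %s, objective: %s%s\n", x$status,
              format(x$objective), if (isTRUE(x$loopless)) " (loopless)" else ""))
  invisible(x)
}

cycle_free_flux <- function(model, S, bnd, v, tol = 1e-9) {
  rids <- reaction_ids(model)
  is_ex <- vapply(model$reactions, `[[`, logical(1), "is_exchange")
  lb <- bnd[, "lb"]; ub <- bnd[, "ub"]
  obj <- numeric(length(rids))
  for (k in seq_along(rids)) {
    if (is_ex[k] || rids[k] == model$objective) {
      lb[k] <- ub[k] <- v[k]           # exchanges and objective pinned
    } else if (v[k] > tol) {
      lb[k] <- 0; ub[k] <- v[k]; obj[k] <- 1
    } else if (v[k] < -tol) {
      lb[k] <- v[k]; ub[k] <- 0; obj[k] <- -1
    } else {
      lb[k] <- ub[k] <- 0
    }
  }
  sol <- solve_lp(obj, S, rep(0, nrow(S)), lb, ub, maximize = FALSE)
  if (sol$status != "optimal") return(v)   # should not happen; keep FBA flux
  stats::setNames(sol$x, rids)
}

#' Search for a sign-matched internal cycle
#'
#' Tests the loopless contract on a flux vector: is there a nonzero
#' steady-state flux `w` supported only on internal (non-exchange) reactions
#' whose sign pattern matches `v`? Solved as an LP maximizing the matched
#' circulation with all exchanges closed.
#'
#' @param model A `metabolic_model`.
#' @param v Named flux vector (as from [fba()]).
#' @param tol Support tolerance on `v`.
#' @return `NULL` if no such cycle exists, otherwise a named flux vector `w`
#'   certifying the cycle.
#' @export
find_internal_cycle <- function(model, v, tol = 1e-6) {
  S <- as.matrix(stoichiometric_matrix(model))
  rids <- reaction_ids(model)
  is_ex <- vapply(model$reactions, `[[`, logical(1), "is_exchange")
  n <- length(rids)
  lb <- numeric(n); ub <- numeric(n); obj <- numeric(n)
  for (k in seq_len(n)) {
    if (is_ex[k] || abs(v[rids[k]]) <= tol) next   # closed
    if (v[rids[k]] > 0) { ub[k] <- 1; obj[k] <- 1 }
    else { lb[k] <- -1; obj[k] <- -1 }
  }
  if (all(obj == 0)) return(NULL)
  sol <- solve_lp(obj, S, rep(0, nrow(S)), lb, ub, maximize = TRUE)
  if (sol$status != "optimal" || sol$objective <= tol) return(NULL)
  stats::setNames(sol$x, rids)
}

#' Flux variability analysis at a fixed objective
#'
#' For every requested reaction, minimizes and maximizes its flux over the
#' polytope `{S v = 0, bounds, objective = value}` — two LPs per reaction.
#' `fixed_objective_value` is an absolute flux by default; with
#' `fraction = TRUE` it is interpreted as a fraction of the FBA optimum.
#'
#' @param model A `metabolic_model` with an objective.
#' @param fixed_objective_value Objective flux to pin (e.g. an experimentally
#'   measured biomass rate), or `NULL` to pin at the FBA optimum.
#' @param fraction Interpret `fixed_objective_value` as fraction of optimum.
#' @param reactions Reaction ids to analyze (default: all).
#' @return An `fva_result` data.frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, fixed_objective_value = NULL, fraction = FALSE,
                reactions = NULL) {
  if (is.null(model$objective)) stop("model has no objective", call. = FALSE)
  S <- as.matrix(stoichiometric_matrix(model))
  bnd <- bounds_matrix(model)
  rids <- reaction_ids(model)
  if (is.null(fixed_objective_value) || isTRUE(fraction)) {
    base <- fba(model)
    if (base$status != "optimal") stop("FVA: model is not solvable", call. = FALSE)
    fixed_objective_value <- if (is.null(fixed_objective_value)) base$objective
      else fixed_objective_value * base$objective
  }
  A <- rbind(S, as.numeric(rids == model$objective))
  rhs <- c(rep(0, nrow(S)), fixed_objective_value)
  # feasibility probe
  probe <- solve_lp(numeric(length(rids)), A, rhs, bnd[, "lb"], bnd[, "ub"])
  if (probe$status != "optimal") {
    stop(sprintf("FVA: objective value %g is infeasible", fixed_objective_value),
         call. = FALSE)
  }
  if (is.null(reactions)) reactions <- rids
  missing_r <- setdiff(reactions, rids)
  if (length(missing_r)) {
    stop(sprintf("FVA: unknown reaction(s): %s", paste(missing_r, collapse = ", ")),
         call. = FALSE)
  }
  res <- lapply(reactions, function(rid) {
    e <- as.numeric(rids == rid)
    lo <- solve_lp(e, A, rhs, bnd[, "lb"], bnd[, "ub"], maximize = FALSE)
    hi <- solve_lp(e, A, rhs, bnd[, "lb"], bnd[, "ub"], maximize = TRUE)
    c(lo$objective, hi$objective)
  })
  out <- data.frame(reaction = reactions,
                    min = vapply(res, `[[`, numeric(1), 1),
                    max = vapply(res, `[[`, numeric(1), 2))
  class(out) <- c("fva_result", "data.frame")
  out
}
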