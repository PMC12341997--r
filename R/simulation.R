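#' Growth medium definition
#'
#' A medium is a set of metabolite concentrations (mM) plus the culture
#' parameters needed to turn concentrations into uptake fluxes: culture
#' volume (L), biomass (gDW) and duration (h). Defaults of 1 for each
#' culture parameter make the flux numerically equal to the concentration.
#'
#' @param concentrations Named numeric vector metabolite id -> mM (>= 0).
#' @param volume_L,biomass_gDW,duration_h Positive culture parameters.
#' @return A `medium` object.
#' @export
medium <- function(concentrations, volume_L = 1, biomass_gDW = 1,
                   duration_h = 1) {
  if (length(concentrations) && is.null(names(concentrations))) {
    stop("medium: concentrations must be named by metabolite id", call. = FALSE)
  }
  if (any(concentrations < 0)) stop("medium: negative concentration", call. = FALSE)
  if (volume_L <= 0 || biomass_gDW <= 0 || duration_h <= 0) {
    stop("medium: volume, biomass and duration must be positive", call. = FALSE)
  }
  structure(list(concentrations = concentrations, volume_L = volume_L,
                 biomass_gDW = biomass_gDW, duration_h = duration_h),
            class = "medium")
}

#' Read a medium from TSV
#'
#' Two columns: metabolite id and concentration in mM.
#'
#' @param path TSV path.
#' @param ... Culture parameters passed to [medium()].
#' @return A `medium`.
#' @export
read_medium_tsv <- function(path, ...) {
  df <- utils::read.delim(path)
  medium(stats::setNames(as.numeric(df[[2]]), as.character(df[[1]])), ...)
}

#' Convert a concentration to an exchange flux
#'
#' `flux = concentration * volume / (biomass * duration)` — the
#' dimensional-analysis conversion from a medium concentration (mM =
#' mmol/L) to the flux unit mmol gDW^-1 h^-1: the culture volume holds
#' `C * V` mmol, available to `X` grams of cells over `t` hours.
#'
#' @param concentration_mM Concentration in mM.
#' @param volume_L Culture volume in liters.
#' @param biomass_gDW Cell dry weight in grams.
#' @param duration_h Duration in hours.
#' @return Flux in mmol gDW^-1 h^-1.
#' @export
concentration_to_flux <- function(concentration_mM, volume_L = 1,
                                  biomass_gDW = 1, duration_h = 1) {
  if (any(concentration_mM < 0)) stop("negative concentration", call. = FALSE)
  if (volume_L <= 0) stop("volume must be positive", call. = FALSE)
  if (biomass_gDW <= 0 || duration_h <= 0) {
    stop("biomass and duration must be positive", call. = FALSE)
  }
  concentration_mM * volume_L / (biomass_gDW * duration_h)
}

# exchange id for a metabolite: the exchange reaction consuming exactly it
exchange_for <- function(model, met_id) {
  for (r in model$reactions) {
    if (r$is_exchange && names(r$stoichiometry) == met_id) return(r$id)
  }
  NA_character_
}

#' Constrain a model's boundary to a medium
#'
#' Sets each medium metabolite's exchange lower bound to minus the converted
#' uptake flux; exchanges of metabolites absent from the medium get lower
#' bound 0 (no uptake). Secretion (upper) bounds are untouched. Medium
#' metabolites without a matching exchange are reported with a warning.
#'
#' @param model A `metabolic_model`.
#' @param med A [medium()].
#' @return The constrained model, with attribute `unmatched` listing medium
#'   metabolites that have no exchange in the model.
#' @export
apply_medium <- function(model, med) {
  stopifnot(inherits(med, "medium"))
  ex_map <- stats::setNames(
    vapply(names(med$concentrations), function(m) exchange_for(model, m),
           character(1)),
    names(med$concentrations))
  unmatched <- names(ex_map)[is.na(ex_map)]
  if (length(unmatched)) {
    warning(sprintf("apply_medium: no exchange for medium metabolite(s): %s",
                    paste(unmatched, collapse = ", ")))
  }
  fed <- unname(ex_map[!is.na(ex_map)])
  for (k in seq_along(model$reactions)) {
    r <- model$reactions[[k]]
    if (!r$is_exchange) next
    if (r$id %in% fed) {
      m <- names(r$stoichiometry)
      flux <- concentration_to_flux(med$concentrations[[m]], med$volume_L,
                                    med$biomass_gDW, med$duration_h)
      model$reactions[[k]]$lower_bound <- -flux
    } else {
      model$reactions[[k]]$lower_bound <- 0
    }
  }
  attr(model, "unmatched") <- unmatched
  model
}

#' Metabolic scenarios
#'
#' Builds one of the four canonical astrocyte scenarios:
#' `basal` (medium only); `ischemia` (oxygen and glucose uptake ramped from
#' 2.5 down to 0 mmol gDW^-1 h^-1); `PA` (basal plus palmitate uptake at
#' 0.208); `Tb_PA` (PA plus tibolone uptake at 0.07, i.e. 70 uM expressed
#' in mM). Species ids are configurable aliases so both toy and
#' reconstruction-derived models work.
#'
#' @param name One of `"basal"`, `"ischemia"`, `"PA"`, `"Tb_PA"`.
#' @param glucose,oxygen,palmitate,tibolone Metabolite ids in the model.
#' @param ramp_start,ramp_end,ramp_steps Ischemia ramp specification
#'   (defaults 2.5 -> 0 in 11 steps).
#' @param pa_uptake,tb_uptake Scenario uptake fluxes (mmol gDW^-1 h^-1).
#' @return A `scenario` object.
#' @export
scenario <- function(name = c("basal", "ischemia", "PA", "Tb_PA"),
                     glucose = "glc_e", oxygen = "o2_e",
                     palmitate = "pmt_e", tibolone = "tib_e",
                     ramp_start = 2.5, ramp_end = 0, ramp_steps = 11,
                     pa_uptake = 0.208, tb_uptake = 70e-3) {
  name <- match.arg(name)
  structure(list(name = name, glucose = glucose, oxygen = oxygen,
                 palmitate = palmitate, tibolone = tibolone,
                 ramp = seq(ramp_start, ramp_end, length.out = ramp_steps),
                 pa_uptake = pa_uptake, tb_uptake = tb_uptake),
            class = "scenario")
}

require_exchange <- function(model, met_id, what) {
  ex <- exchange_for(model, met_id)
  if (is.na(ex)) {
    stop(sprintf("scenario needs an exchange for %s species '%s'", what, met_id),
         call. = FALSE)
  }
  ex
}

#' Run a metabolic scenario
#'
#' Applies the medium, adds the scenario's exchange overrides and runs FBA
#' (one solve per ramp step for ischemia, one otherwise). The biomass
#' objective already set on the model is used throughout.
#'
#' @param model A `metabolic_model` with a biomass objective.
#' @param scen A [scenario()].
#' @param med A [medium()].
#' @param loopless Use loopless FBA.
#' @return A list of `flux_result` (length = ramp steps for ischemia, else
#'   1); for ischemia each element carries attribute `uptake` (the ramp
#'   value).
#' @export
run_scenario <- function(model, scen, med, loopless = FALSE) {
  stopifnot(inherits(scen, "scenario"))
  base <- apply_medium(model, med)
  if (scen$name == "basal") {
    return(list(fba(base, loopless = loopless)))
  }
  if (scen$name == "ischemia") {
    ex_glc <- require_exchange(base, scen$glucose, "glucose")
    ex_o2 <- require_exchange(base, scen$oxygen, "oxygen")
    return(lapply(scen$ramp, function(u) {
      m <- set_bounds(base, ex_glc, lower = -u)
      m <- set_bounds(m, ex_o2, lower = -u)
      r <- fba(m, loopless = loopless)
      attr(r, "uptake") <- u
      r
    }))
  }
  ex_pa <- require_exchange(base, scen$palmitate, "palmitate")
  m <- set_bounds(base, ex_pa, lower = -scen$pa_uptake)
  if (scen$name == "Tb_PA") {
    ex_tb <- require_exchange(m, scen$tibolone, "tibolone")
    m <- set_bounds(m, ex_tb, lower = -scen$tb_uptake)
  }
  list(fba(m, loopless = loopless))
}

#' Prediction accuracy against an experimental flux
#'
#' `accuracy = (1 - |predicted - experimental| / experimental) * 100`,
#' the ratio-of-difference statistic used to compare model biomass
#' predictions with measured rates. Reported to two decimals by
#' `format_accuracy()` with half-up rounding (values are snapped to 8
#' decimals first so e.g. an exact 96.875 prints as 96.88 despite binary
#' floating point).
#'
#' @param predicted_flux,experimental_flux Fluxes in the same unit;
#'   `experimental_flux` must be nonzero.
#' @return Accuracy percentage (full precision; format with
#'   [format_accuracy()]).
#' @export
prediction_accuracy <- function(predicted_flux, experimental_flux) {
  if (any(experimental_flux == 0)) {
    stop("prediction_accuracy: experimental flux must be nonzero", call. = FALSE)
  }
  (1 - abs(predicted_flux - experimental_flux) / experimental_flux) * 100
}

#' @rdname prediction_accuracy
#' @param accuracy Value from `prediction_accuracy()`.
#' @export
format_accuracy <- function(accuracy) {
  snapped <- round(accuracy, 8)
  halfup <- sign(snapped) * floor(abs(snapped) * 100 + 0.5) / 100
  sprintf("%.2f%%", halfup)
}

#' Write flux results as TSV
#'
#' @param result A `flux_result` or `fva_result`.
#' @param path Output TSV path.
#' @export
write_flux_tsv <- function(result, path) {
  df <- if (inherits(result, "fva_result")) {
    as.data.frame(result)
  } else {
    data.frame(reaction = names(result$fluxes), flux = unname(result$fluxes))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
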