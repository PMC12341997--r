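#' Find dead-end metabolites
#'
#' A metabolite is a dead end when, given the reaction directions allowed by
#' the bounds, no reaction can produce it or none can consume it. A reaction
#' with coefficient `c` for the metabolite can produce it if `c > 0` and the
#' upper bound is positive, or `c < 0` and the lower bound is negative;
#' consumption is the mirror image. Exchange reactions count as
#' producers/consumers like any other.
#'
#' @param model A `metabolic_model`.
#' @return Named character vector metabolite id -> tag, tag in
#'   `"no-production"`, `"no-consumption"`, `"orphan"` (neither).
#' @export
find_dead_end_metabolites <- function(model) {
  tol <- 1e-12
  prod <- cons <- stats::setNames(logical(length(model$metabolites)),
                                  metabolite_ids(model))
  for (r in model$reactions) {
    fwd <- r$upper_bound > tol
    bwd <- r$lower_bound < -tol
    for (m in names(r$stoichiometry)) {
      cc <- r$stoichiometry[[m]]
      if ((cc > 0 && fwd) || (cc < 0 && bwd)) prod[m] <- TRUE
      if ((cc < 0 && fwd) || (cc > 0 && bwd)) cons[m] <- TRUE
    }
  }
  bad <- !prod | !cons
  tags <- ifelse(!prod & !cons, "orphan",
                 ifelse(!prod, "no-production", "no-consumption"))
  stats::setNames(tags[bad], names(prod)[bad])
}

reaction_kind <- function(r) {
  if (r$is_exchange) return("exchange")
  if (grepl("exchange", r$subsystem, ignore.case = TRUE)) return("exchange")
  if (grepl("transport", r$subsystem, ignore.case = TRUE)) return("transport")
  # same species name in two compartments marks a transporter
  base <- sub("(_[a-z]|\\[[a-z]\\])$", "", names(r$stoichiometry))
  if (anyDuplicated(base)) "transport" else "metabolic"
}

# can metabolite m be produced (dir = 1) or consumed (dir = -1) at positive
# rate in `model`, optionally with some reactions closed?
can_carry <- function(S, lb, ub, met_row, dir, tol = 1e-6) {
  n <- ncol(S)
  # temporary boundary reaction: drain (m ->) for production, source for
  # consumption
  col <- numeric(nrow(S)); col[met_row] <- -dir
  A <- cbind(S, col)
  obj <- c(numeric(n), 1)
  sol <- solve_lp(obj, A, rep(0, nrow(S)), c(lb, 0), c(ub, 1e6),
                  maximize = TRUE)
  sol$status == "optimal" && sol$objective > tol
}

#' Gap filling against a universal reaction database
#'
#' Finds a minimum-weight set of database reactions whose addition lets
#' every dead-end metabolite of `model` both be produced and be consumed at
#' positive steady-state rate (each direction checked by an LP with a
#' temporary boundary reaction). Costs discourage patching holes with
#' transport or exchange reactions, following the fastGapFill weighting
#' idea. The search is an exact branch-and-bound over the inclusion
#' indicators; monotonicity (adding reactions never hurts) gives the
#' pruning bound.
#'
#' @param model A `metabolic_model`.
#' @param universal_db A `metabolic_model` sharing the metabolite id
#'   namespace (extra metabolites allowed).
#' @param weights Named numeric costs per reaction kind; default
#'   `c(metabolic = 1, transport = 10, exchange = 100)`.
#' @return A list: `dead_ends` (as [find_dead_end_metabolites()]), `added`
#'   (db reaction ids chosen), `weight` (their total cost), `unfillable`
#'   (dead-end metabolites no candidate set can fix), `model` (the augmented
#'   model).
#' @export
gap_fill <- function(model, universal_db,
                     weights = c(metabolic = 1, transport = 10, exchange = 100)) {
  dead <- find_dead_end_metabolites(model)
  if (length(dead) == 0L) {
    return(list(dead_ends = dead, added = character(0), weight = 0,
                unfillable = character(0), model = model))
  }
  # candidate reactions must only use metabolites known to model or db
  mids <- metabolite_ids(model)
  cand <- Filter(function(r) !r$id %in% reaction_ids(model) &&
                   all(names(r$stoichiometry) %in%
                         union(mids, metabolite_ids(universal_db))),
                 universal_db$reactions)
  cand_w <- vapply(cand, function(r) {
    kind <- reaction_kind(r)
    w <- weights[kind]
    if (is.na(w)) w <- max(weights)
    unname(w)
  }, numeric(1))
  # augmented metabolite set (db may introduce new species)
  new_mids <- setdiff(unique(unlist(lapply(cand, function(r)
    names(r$stoichiometry)))), mids)
  mets_aug <- c(model$metabolites,
                Filter(function(m) m$id %in% new_mids, universal_db$metabolites))
  all_mids <- vapply(mets_aug, `[[`, character(1), "id")

  build <- function(include) {
    rxns <- c(model$reactions, cand[include])
    S <- matrix(0, length(all_mids), length(rxns),
                dimnames = list(all_mids, vapply(rxns, `[[`, character(1), "id")))
    for (k in seq_along(rxns)) {
      S[names(rxns[[k]]$stoichiometry), k] <- rxns[[k]]$stoichiometry
    }
    list(S = S,
         lb = vapply(rxns, `[[`, numeric(1), "lower_bound"),
         ub = vapply(rxns, `[[`, numeric(1), "upper_bound"))
  }
  fixed_by <- function(include) {
    sys <- build(include)
    ok <- vapply(names(dead), function(m) {
      row <- match(m, all_mids)
      can_carry(sys$S, sys$lb, sys$ub, row, 1) &&
        can_carry(sys$S, sys$lb, sys$ub, row, -1)
    }, logical(1))
    names(dead)[ok]
  }

  with_all <- fixed_by(seq_along(cand))
  unfillable <- setdiff(names(dead), with_all)
  target <- with_all
  if (length(target) == 0L) {
    return(list(dead_ends = dead, added = character(0), weight = 0,
                unfillable = unfillable, model = model))
  }

  nb <- length(cand)
  best <- new.env(parent = emptyenv())
  best$weight <- Inf; best$set <- integer(0)
  # order candidates by increasing weight so cheap fixes are explored first
  ord <- order(cand_w)
  recurse <- function(pos, included, w) {
    if (w >= best$weight) return()
    if (pos > nb) {
      if (setequal(intersect(fixed_by(included), target), target)) {
        best$weight <- w; best$set <- included
      }
      return()
    }
    # optimistic check: include everything still undecided
    optimistic <- c(included, ord[pos:nb])
    if (!setequal(intersect(fixed_by(optimistic), target), target)) return()
    # early accept: if current inclusion already fixes everything, no need
    # to add more weight
    if (setequal(intersect(fixed_by(included), target), target)) {
      if (w < best$weight) { best$weight <- w; best$set <- included }
      return()
    }
    recurse(pos + 1L, included, w)                        # exclude first
    recurse(pos + 1L, c(included, ord[pos]), w + cand_w[ord[pos]])
  }
  recurse(1L, integer(0), 0)

  added_ids <- vapply(cand[best$set], `[[`, character(1), "id")
  aug <- if (length(best$set)) {
    used <- unique(unlist(lapply(cand[best$set], function(r)
      names(r$stoichiometry))))
    metabolic_model(c(model$metabolites,
                      Filter(function(m) m$id %in% setdiff(used, mids),
                             universal_db$metabolites)),
                    c(model$reactions, cand[best$set]),
                    objective = model$objective, id = model$id)
  } else model
  list(dead_ends = dead, added = added_ids,
       weight = if (is.finite(best$weight)) best$weight else NA_real_,
       unfillable = unfillable, model = aug)
}

close_exchanges <- function(model) {
  for (k in seq_along(model$reactions)) {
    if (model$reactions[[k]]$is_exchange) {
      model$reactions[[k]]$lower_bound <- 0
      model$reactions[[k]]$upper_bound <- 0
    }
  }
  model
}

#' Detect leak and siphon metabolites
#'
#' With every exchange bound closed to `[0, 0]`, a metabolite is a leak if
#' it can still be produced at positive rate (made "from nothing" — a mass
#' conservation violation) and a siphon if it can still be consumed at
#' positive rate ("into nothing"). Each metabolite is tested by one LP per
#' direction with a temporary drain/source reaction.
#'
#' @param model A `metabolic_model`.
#' @param tolerance Flux above which production/consumption counts.
#' @return List with character vectors `leaks` and `siphons`.
#' @export
find_leaks_siphons <- function(model, tolerance = 1e-6) {
  closed <- close_exchanges(model)
  S <- as.matrix(stoichiometric_matrix(closed))
  bnd <- bounds_matrix(closed)
  mids <- metabolite_ids(closed)
  leaks <- siphons <- character(0)
  for (i in seq_along(mids)) {
    if (can_carry(S, bnd[, "lb"], bnd[, "ub"], i, 1, tol = tolerance)) {
      leaks <- c(leaks, mids[i])
    }
    if (can_carry(S, bnd[, "lb"], bnd[, "ub"], i, -1, tol = tolerance)) {
      siphons <- c(siphons, mids[i])
    }
  }
  list(leaks = leaks, siphons = siphons)
}

#' Minimal leakage mode of a leak or siphon metabolite
#'
#' Returns a minimum-cardinality set of reactions that can jointly produce
#' (leak) or consume (siphon) the metabolite with all exchanges closed —
#' the smallest certificate of the mass-conservation violation. Exact
#' search: the support of a sparse (minimum total |v|) certificate seeds a
#' recursive branch-and-bound that, for each current support, tries closing
#' each member in turn; a branch dies when the leak disappears.
#'
#' @param model A `metabolic_model`.
#' @param metabolite_id A metabolite detected by [find_leaks_siphons()].
#' @param mode `"leak"` (production) or `"siphon"` (consumption).
#' @param tolerance Flux tolerance.
#' @return Character vector of reaction ids (minimum cardinality); attribute
#'   `flux` holds a certificate flux vector over those reactions.
#' @export
minimal_leakage_mode <- function(model, metabolite_id,
                                 mode = c("leak", "siphon"),
                                 tolerance = 1e-6) {
  mode <- match.arg(mode)
  dir <- if (mode == "leak") 1 else -1
  closed <- close_exchanges(model)
  S <- as.matrix(stoichiometric_matrix(closed))
  bnd <- bounds_matrix(closed)
  mids <- metabolite_ids(closed)
  rids <- reaction_ids(closed)
  row <- match(metabolite_id, mids)
  if (is.na(row)) stop(sprintf("no metabolite '%s'", metabolite_id), call. = FALSE)
  n <- length(rids)
  # boundary column forcing production/consumption of at least `demand`
  col <- numeric(nrow(S)); col[row] <- -dir
  demand <- max(tolerance * 10, 1e-3)

  certificate <- function(closed_set) {
    lb <- bnd[, "lb"]; ub <- bnd[, "ub"]
    lb[closed_set] <- 0; ub[closed_set] <- 0
    A <- cbind(S, col)
    # sparse certificate: minimize total |v| with the demand active
    Asplit <- cbind(A, -S)     # split only the reaction variables
    lo <- c(pmax(lb, 0), demand, pmax(-ub, 0))
    hi <- c(pmax(ub, 0), 1e6, pmax(-lb, 0))
    obj <- c(rep(1, n), 0, rep(1, n))
    sol <- solve_lp(obj, Asplit, rep(0, nrow(S)), lo, hi)
    if (sol$status != "optimal") return(NULL)
    v <- sol$x[seq_len(n)] - sol$x[n + 1L + seq_len(n)]
    v
  }

  v0 <- certificate(integer(0))
  if (is.null(v0)) {
    stop(sprintf("metabolite '%s' is not a %s", metabolite_id, mode),
         call. = FALSE)
  }
  best <- new.env(parent = emptyenv())
  best$support <- which(abs(v0) > tolerance)
  best$flux <- v0
  seen <- new.env(parent = emptyenv())
  recurse <- function(closed_set) {
    key <- paste0("k", paste(sort(closed_set), collapse = ","))
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    v <- certificate(closed_set)
    if (is.null(v)) return()
    supp <- which(abs(v) > tolerance)
    if (length(supp) < length(best$support)) {
      best$support <- supp; best$flux <- v
    }
    if (length(supp) <= 1L) return()
    for (r in supp) recurse(c(closed_set, r))
  }
  recurse(integer(0))
  out <- rids[best$support]
  attr(out, "flux") <- stats::setNames(best$flux[best$support], out)
  out
}

#' Balance a reaction (or pair) by adding candidate metabolites
#'
#' Given a reaction with a nonzero element residual, solves
#' `E_cand x = -residual` for coefficients of the candidate species (the
#' classic balancing set: protons, water, electrons), i.e. searches the null
#' space of the element matrix extended by the candidates. Both members of a
#' reactant/product pair are balanced independently; a reaction that no
#' candidate combination can balance is reported, not altered.
#'
#' @param model A `metabolic_model` whose metabolites carry formulas.
#' @param rxn_a,rxn_b Reaction ids; the pair should share at least one
#'   metabolite, as product in one and reactant in the other.
#' @param candidates Metabolite ids (with known formulas) allowed as
#'   balancing species.
#' @return A list: `model` (with adjusted stoichiometries), `report` — a
#'   data.frame with one row per reaction: `reaction`, `balanced`,
#'   `additions` (formatted as `"coef*met"`).
#' @export
balance_reaction_pair <- function(model, rxn_a, rxn_b,
                                  candidates = c("h_c", "h2o_c", "e_c")) {
  rids <- c(rxn_a, rxn_b)
  shared <- intersect(names(get_reaction(model, rxn_a)$stoichiometry),
                      names(get_reaction(model, rxn_b)$stoichiometry))
  if (length(shared) == 0L) {
    warning("balance_reaction_pair: the reactions share no metabolite")
  }
  E <- element_matrix(model)
  candidates <- intersect(candidates, colnames(E))
  candidates <- setdiff(candidates, attr(E, "unknown"))
  if (length(candidates) == 0L) {
    stop("balance_reaction_pair: no usable candidate metabolites", call. = FALSE)
  }
  Ec <- E[, candidates, drop = FALSE]
  rows <- list()
  for (rid in rids) {
    res <- check_mass_balance(model, rid)
    if (all(abs(res) < 1e-9)) {
      rows[[rid]] <- data.frame(reaction = rid, balanced = TRUE, additions = "")
      next
    }
    x <- tryCatch(qr.solve(Ec, -res), error = function(e) NULL)
    ok <- !is.null(x) && all(abs(Ec %*% x + res) < 1e-9)
    if (!ok) {
      rows[[rid]] <- data.frame(reaction = rid, balanced = FALSE,
                                additions = "")
      next
    }
    x <- round(x, 9)
    idx <- match(rid, reaction_ids(model))
    st <- model$reactions[[idx]]$stoichiometry
    for (j in seq_along(candidates)) {
      if (abs(x[j]) < 1e-12) next
      m <- candidates[j]
      st[m] <- (if (m %in% names(st)) st[[m]] else 0) + x[j]
    }
    st <- st[abs(st) > 1e-12]
    model$reactions[[idx]]$stoichiometry <- st
    model$reactions[[idx]]$is_exchange <- length(st) == 1L
    used <- which(abs(x) > 1e-12)
    rows[[rid]] <- data.frame(
      reaction = rid, balanced = TRUE,
      additions = paste(sprintf("%g*%s", x[used], candidates[used]),
                        collapse = " + "))
  }
  list(model = model, report = do.call(rbind, rows))
}

#' Full curation report
#'
#' Runs dead-end detection, gap filling and leak/siphon detection and
#' returns everything in one structure, mirroring the usual curation
#' workflow (report what remains rather than forcing resolution).
#'
#' @param model A `metabolic_model`.
#' @param universal_db Optional universal database for gap filling.
#' @param tolerance Flux tolerance for leak/siphon detection.
#' @return A `curation_report` list: `dead_ends`, `gap_fill` (or `NULL`),
#'   `leaks`, `siphons`.
#' @export
curate_model <- function(model, universal_db = NULL, tolerance = 1e-6) {
  gf <- if (is.null(universal_db)) NULL else gap_fill(model, universal_db)
  mdl <- if (is.null(gf)) model else gf$model
  ls <- find_leaks_siphons(mdl, tolerance)
  structure(list(dead_ends = find_dead_end_metabolites(model),
                 gap_fill = gf, leaks = ls$leaks, siphons = ls$siphons,
                 model = mdl),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("<curation_report> %d dead ends, %d leaks, %d siphons%s\n",
              length(x$dead_ends), length(x$leaks), length(x$siphons),
              if (is.null(x$gap_fill)) "" else
                sprintf(", %d reactions added", length(x$gap_fill$added))))
  invisible(x)
}
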