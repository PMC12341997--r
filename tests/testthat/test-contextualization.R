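test_that("classify_reactions applies the +/-500 thresholds strictly", {
  m <- diamond_model()
  av <- activity_vector(c(AB = 600, AC = -600, BD = 0, CD = 500),
                        "integrated")
  cls <- classify_reactions(av, m)
  expect_equal(unclass(cls)[["AB"]], "HIGH")
  expect_equal(unclass(cls)[["AC"]], "LOW")
  expect_equal(unclass(cls)[["BD"]], "MODERATE")
  expect_equal(unclass(cls)[["CD"]], "MODERATE")   # boundary is MODERATE
  expect_equal(unclass(cls)[["EX_A"]], "UNCOVERED")
  expect_error(classify_reactions(av, m, 500, -500), "low_threshold")
})

classification_of <- function(model, states) {
  cls <- rep("MODERATE", length(reaction_ids(model)))
  names(cls) <- reaction_ids(model)
  cls[names(states)] <- states
  structure(cls, class = "reaction_classification")
}

test_that("iMAT satisfies a single HIGH reaction on an open chain", {
  m <- chain_model(capacities = c(5, 5, 5))
  cls <- classification_of(m, c(R2 = "HIGH"))
  sol <- imat(m, cls)
  expect_equal(sol$objective, 1)
  expect_gte(abs(sol$fluxes[["R2"]]), 1)
  # steady state within tolerance
  S <- as.matrix(stoichiometric_matrix(m))
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-8)
})

test_that("iMAT with all reactions MODERATE settles at zero flux", {
  m <- chain_model()
  cls <- classification_of(m, c())
  sol <- imat(m, cls)
  expect_equal(sol$objective, 0)
  expect_equal(max(abs(sol$fluxes)), 0)
})

test_that("iMAT finds the trade-off between conflicting HIGH and LOW states", {
  # HIGH reaction downstream of a LOW one: only one indicator can win
  m <- chain_model(capacities = c(5, 5, 5))
  cls <- classification_of(m, c(R1 = "LOW", R2 = "HIGH", R3 = "HIGH"))
  sol <- imat(m, cls)
  expect_equal(sol$objective, 2)                  # both HIGH beat the one LOW
  expect_gte(sol$fluxes[["R2"]], 1)
})

imat_enumeration_oracle <- function(model, cls, epsilon = 1) {
  # exhaustive assignment enumeration, each checked by LP feasibility
  S <- as.matrix(stoichiometric_matrix(model))
  bnd <- bounds_matrix(model)
  rids <- reaction_ids(model)
  high <- which(unclass(cls)[rids] == "HIGH")
  low <- which(unclass(cls)[rids] == "LOW")
  options_of <- c(lapply(high, function(i) list(c(i, 1), c(i, 2), c(i, 0))),
                  lapply(low, function(i) list(c(i, 3), c(i, 0))))
  best <- 0L
  grids <- expand.grid(lapply(options_of, seq_along))
  if (nrow(grids) == 0) return(0L)
  for (g in seq_len(nrow(grids))) {
    lb <- bnd[, "lb"]; ub <- bnd[, "ub"]; sat <- 0L; ok <- TRUE
    for (j in seq_along(options_of)) {
      opt <- options_of[[j]][[grids[g, j]]]
      i <- opt[1]
      if (opt[2] == 1) { lb[i] <- max(lb[i], epsilon); sat <- sat + 1L }
      if (opt[2] == 2) { ub[i] <- min(ub[i], -epsilon); sat <- sat + 1L }
      if (opt[2] == 3) { lb[i] <- 0; ub[i] <- 0; sat <- sat + 1L }
      if (lb[i] > ub[i]) { ok <- FALSE; break }
    }
    if (!ok || sat <= best) next
    sol <- solve_lp(numeric(length(rids)), S, rep(0, nrow(S)), lb, ub)
    if (sol$status == "optimal") best <- sat
  }
  best
}

test_that("iMAT objective equals exhaustive enumeration on a toy network", {
  set.seed(99)
  for (rep in 1:5) {
    m <- make_toy_model(fixture_spec("random", n_reactions = 8,
                                     gpr_fraction = 0, seed = rep))
    rids <- setdiff(reaction_ids(m), exchange_ids(m))
    picks <- sample(rids, 5)
    cls <- classification_of(m, stats::setNames(
      c("HIGH", "HIGH", "HIGH", "LOW", "LOW"), picks))
    sol <- imat(m, cls)
    expect_equal(sol$objective, imat_enumeration_oracle(m, cls))
  }
})

test_that("extraction drops the unused LOW branch but keeps the chain", {
  m <- diamond_model()       # AB/BD planted, AC/CD decoy
  cls <- classification_of(m, c(AB = "HIGH", BD = "HIGH",
                                AC = "LOW", CD = "LOW"))
  sol <- imat(m, cls)
  ctx <- extract_context_model(m, sol, cls)
  expect_true(all(c("AB", "BD") %in% reaction_ids(ctx)))
  expect_false(any(c("AC", "CD") %in% reaction_ids(ctx)))
  expect_true(all(exchange_ids(m) %in% reaction_ids(ctx)))  # never pruned
  # orphaned metabolites removed
  expect_false("C" %in% metabolite_ids(ctx))
  # restriction property: extracted optimum <= parent optimum
  expect_lte(fba(ctx)$objective, fba(m)$objective + 1e-9)
  expect_equal(fba(ctx)$status, "optimal")
})

test_that("retained set equals recomputation from the stored flux vector", {
  set.seed(41)
  m <- make_toy_model(fixture_spec("random", n_reactions = 10,
                                   gpr_fraction = 0, seed = 41))
  rids <- setdiff(reaction_ids(m), exchange_ids(m))
  cls <- classification_of(m, stats::setNames(
    sample(c("HIGH", "LOW", "MODERATE"), length(rids), replace = TRUE), rids))
  sol <- imat(m, cls)
  ctx <- extract_context_model(m, sol, cls)
  oracle <- vapply(m$reactions, function(r) {
    r$is_exchange || r$id == m$objective ||
      abs(sol$fluxes[r$id]) > 1e-6
  }, logical(1))
  expect_setequal(reaction_ids(ctx), reaction_ids(m)[oracle])
})

test_that("extracted flux cone is a subset of the parent's", {
  m <- diamond_model()
  cls <- classification_of(m, c(AB = "HIGH", CD = "LOW"))
  ctx <- extract_context_model(m, imat(m, cls), cls)
  # sample feasible fluxes of the extracted model, check parent feasibility
  S_p <- as.matrix(stoichiometric_matrix(m))
  bnd_p <- bounds_matrix(m)
  rids_p <- reaction_ids(m)
  S_c <- as.matrix(stoichiometric_matrix(ctx))
  bnd_c <- bounds_matrix(ctx)
  rids_c <- reaction_ids(ctx)
  set.seed(7)
  for (i in 1:5) {
    obj <- stats::rnorm(length(rids_c))
    sol <- solve_lp(obj, S_c, rep(0, nrow(S_c)), bnd_c[, "lb"], bnd_c[, "ub"],
                    maximize = TRUE)
    v_p <- stats::setNames(numeric(length(rids_p)), rids_p)
    v_p[rids_c] <- sol$x
    expect_lt(max(abs(S_p %*% v_p)), 1e-8)
    expect_true(all(v_p >= bnd_p[, "lb"] - 1e-9 & v_p <= bnd_p[, "ub"] + 1e-9))
  }
})

test_that("activity_to_bounds rescales bounds monotonically", {
  m <- metabolic_model(
    list(metabolite("A"), metabolite("B")),
    list(reaction("EX_A", c(A = -1), -1000, 1000),
         reaction("rev", c(A = -1, B = 1), -1000, 1000),
         reaction("fwd", c(A = -1, B = 1), 0, 1000),
         reaction("EX_B", c(B = -1), 0, 1000)))
  av <- activity_vector(c(rev = 10, fwd = 2, EX_B = 0), "integrated")
  out <- activity_to_bounds(m, av, v_max = 100)
  r_rev <- get_reaction(out, "rev")
  expect_equal(c(r_rev$lower_bound, r_rev$upper_bound), c(-100, 100))
  r_fwd <- get_reaction(out, "fwd")
  expect_equal(r_fwd$lower_bound, 0)
  expect_equal(r_fwd$upper_bound, 100 * 2 / 10)
  # uncovered bounds untouched
  expect_equal(get_reaction(out, "EX_A")$lower_bound, -1000)
  # monotonicity: higher score -> wider interval
  expect_gte(r_rev$upper_bound, r_fwd$upper_bound)
  expect_error(activity_to_bounds(m, activity_vector(c(rev = 1, fwd = 1),
                                                     "integrated")),
               "constant")
})
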