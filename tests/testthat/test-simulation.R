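test_that("concentration_to_flux is C * V / (X * t)", {
  expect_equal(concentration_to_flux(1, 1, 1, 1), 1)
  expect_equal(concentration_to_flux(0.208, 1, 1, 1), 0.208)  # PA bound
  expect_equal(concentration_to_flux(10, 2, 4, 5), 10 * 2 / (4 * 5))
  # doubling duration halves flux
  expect_equal(concentration_to_flux(3, 1, 1, 2),
               concentration_to_flux(3, 1, 1, 1) / 2)
  expect_error(concentration_to_flux(1, 1, 0, 1), "biomass")
  expect_error(concentration_to_flux(1, 1, 1, -2), "duration")
})

test_that("apply_medium opens fed exchanges and closes the rest", {
  m <- make_astrocyte_mini()
  med <- astrocyte_medium()
  out <- apply_medium(m, med)
  expect_equal(get_reaction(out, "EX_glc_e")$lower_bound, -25)
  expect_lt(get_reaction(out, "EX_glu_e")$lower_bound, 0)
  # absent from medium: no uptake, secretion untouched
  expect_equal(get_reaction(out, "EX_pmt_e")$lower_bound, 0)
  expect_equal(get_reaction(out, "EX_pmt_e")$upper_bound, 1000)
  expect_equal(get_reaction(out, "EX_lac_e")$upper_bound, 1000)
  # idempotent
  out2 <- apply_medium(out, med)
  expect_equal(bounds_matrix(out2), bounds_matrix(out))
  # unmatched medium species warn and are reported
  med2 <- medium(c(glc_e = 1, unobtainium = 5))
  expect_warning(m2 <- apply_medium(m, med2), "unobtainium")
  expect_equal(attr(m2, "unmatched"), "unobtainium")
})

test_that("FBA matches analytic optima on chain and diamond", {
  expect_equal(fba(chain_model(c(4, 9, 2)))$objective, 2)     # bottleneck
  expect_equal(fba(chain_model(c(10, 10, 10)))$objective, 10)
  r <- fba(diamond_model())
  expect_equal(r$objective, 10)                               # 3 + 7
  # steady state and bounds hold
  m <- diamond_model()
  S <- as.matrix(stoichiometric_matrix(m))
  expect_lt(max(abs(S %*% r$fluxes)), 1e-9)
  bnd <- bounds_matrix(m)
  expect_true(all(r$fluxes >= bnd[, "lb"] - 1e-9 &
                  r$fluxes <= bnd[, "ub"] + 1e-9))
})

test_that("FBA objective agrees with the independent LP oracle", {
  for (m in list(diamond_model(), make_astrocyte_mini() |>
                   apply_medium(astrocyte_medium()))) {
    S <- as.matrix(stoichiometric_matrix(m))
    bnd <- bounds_matrix(m)
    obj <- as.numeric(reaction_ids(m) == m$objective)
    orc <- lp_oracle(list(list(obj = obj, A = S, rhs = rep(0, nrow(S)),
                               lb = bnd[, "lb"], ub = bnd[, "ub"],
                               maximize = TRUE)))[[1]]
    expect_equal(fba(m)$objective, orc$objective, tolerance = 1e-7)
  }
})

test_that("loopless FBA removes the cycle without losing yield", {
  m <- cycle_trap_model()
  plain <- fba(m)
  ll <- fba(m, loopless = TRUE)
  expect_equal(ll$objective, plain$objective, tolerance = 1e-9)
  cyc <- c("BC", "CD", "DB")
  expect_equal(max(abs(ll$fluxes[cyc])), 0, tolerance = 1e-9)
  # the contract itself: no sign-matched internal cycle remains
  expect_null(find_internal_cycle(m, ll$fluxes))
  # and a flux vector with the cycle pumped does violate it
  v_bad <- plain$fluxes
  v_bad[cyc] <- v_bad[cyc] + 5
  expect_false(is.null(find_internal_cycle(m, v_bad)))
})

test_that("FVA ranges behave on parallel paths and at the optimum", {
  m <- metabolic_model(
    list(metabolite("A"), metabolite("B")),
    list(reaction("EX_A", c(A = -1), -1000, 0),
         reaction("P1", c(A = -1, B = 1), 0, 10),
         reaction("P2", c(A = -1, B = 1), 0, 10),
         reaction("EX_B", c(B = -1), 0, 1000)),
    objective = "EX_B")
  # objective fixed at 10: each path can range over [0, 10]
  rr <- fva(m, fixed_objective_value = 10)
  expect_equal(rr[rr$reaction == "P1", c("min", "max")],
               data.frame(min = 0, max = 10), ignore_attr = TRUE)
  # at the model maximum every essential reaction collapses to a point
  rmax <- fva(m, fixed_objective_value = 20)
  expect_equal(rmax[rmax$reaction == "P1", ]$min, 10, tolerance = 1e-9)
  expect_equal(rmax[rmax$reaction == "P1", ]$max, 10, tolerance = 1e-9)
  expect_error(fva(m, fixed_objective_value = 21), "infeasible")
})

test_that("FVA matches a per-reaction LP oracle on a larger fixture", {
  m <- apply_medium(make_astrocyte_mini(), astrocyte_medium())
  target <- fba(m)$objective * 0.5
  rr <- fva(m, fixed_objective_value = target)
  S <- as.matrix(stoichiometric_matrix(m))
  bnd <- bounds_matrix(m)
  rids <- reaction_ids(m)
  A <- rbind(S, as.numeric(rids == m$objective))
  rhs <- c(rep(0, nrow(S)), target)
  probs <- list()
  for (rid in rids) {
    e <- as.numeric(rids == rid)
    probs[[length(probs) + 1]] <- list(obj = e, A = A, rhs = rhs,
                                       lb = bnd[, "lb"], ub = bnd[, "ub"],
                                       maximize = FALSE)
    probs[[length(probs) + 1]] <- list(obj = e, A = A, rhs = rhs,
                                       lb = bnd[, "lb"], ub = bnd[, "ub"],
                                       maximize = TRUE)
  }
  orc <- lp_oracle(probs)
  for (k in seq_along(rids)) {
    expect_equal(rr$min[k], orc[[2 * k - 1]]$objective, tolerance = 1e-7)
    expect_equal(rr$max[k], orc[[2 * k]]$objective, tolerance = 1e-7)
  }
  # FVA brackets the FBA flux at the same fixed objective
  A_fix <- fva(m, fixed_objective_value = fba(m)$objective)
  v <- fba(m)$fluxes
  expect_true(all(A_fix$min <= v[A_fix$reaction] + 1e-7))
  expect_true(all(A_fix$max >= v[A_fix$reaction] - 1e-7))
})

test_that("basal scenario equals manual apply_medium + fba", {
  m <- make_astrocyte_mini()
  med <- astrocyte_medium()
  res <- run_scenario(m, scenario("basal"), med)
  expect_length(res, 1)
  manual <- fba(apply_medium(m, med))
  expect_equal(res[[1]]$objective, manual$objective)
  expect_equal(res[[1]]$fluxes, manual$fluxes)
})

test_that("ischemia ramp is monotone and ends at zero", {
  m <- make_astrocyte_mini()
  res <- run_scenario(m, scenario("ischemia"), astrocyte_medium())
  objs <- vapply(res, `[[`, numeric(1), "objective")
  expect_length(objs, 11)
  expect_true(all(diff(objs) <= 1e-9))
  expect_equal(objs[11], 0, tolerance = 1e-9)
  expect_equal(attr(res[[1]], "uptake"), 2.5)
  expect_equal(attr(res[[11]], "uptake"), 0)
})

test_that("PA and Tb_PA scenarios set the uptake constants", {
  m <- make_astrocyte_mini()
  med <- astrocyte_medium()
  s_pa <- scenario("PA")
  expect_equal(s_pa$pa_uptake, 0.208)
  s_tb <- scenario("Tb_PA")
  expect_equal(s_tb$tb_uptake, 0.07)
  expect_equal(scenario("ischemia")$ramp[1], 2.5)
  res <- run_scenario(m, s_tb, med)
  expect_equal(res[[1]]$status, "optimal")
  # a model without the species errors by name
  expect_error(run_scenario(diamond_model(), s_pa, medium(c(A = 1))),
               "palmitate")
})

test_that("weakening an uptake never increases the optimum (property)", {
  set.seed(3)
  m <- apply_medium(make_astrocyte_mini(), astrocyte_medium())
  base_obj <- fba(m)$objective
  for (ex in c("EX_glc_e", "EX_glu_e", "EX_cys_e")) {
    lb0 <- get_reaction(m, ex)$lower_bound
    tight <- fba(set_bounds(m, ex, lower = lb0 / 2))$objective
    expect_lte(tight, base_obj + 1e-9)
  }
})

test_that("prediction accuracy reproduces the reference statistics", {
  expect_equal(format_accuracy(prediction_accuracy(0.33, 0.32)), "96.88%")
  expect_equal(format_accuracy(prediction_accuracy(0.37, 0.32)), "84.38%")
  expect_equal(prediction_accuracy(5, 5), 100)
  expect_equal(prediction_accuracy(0.33, 0.32), 100 * (1 - 0.01 / 0.32),
               tolerance = 1e-12)
  expect_error(prediction_accuracy(1, 0), "nonzero")
})

test_that("flux TSV writers emit readable tables", {
  m <- diamond_model()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_flux_tsv(fba(m), p1)
  df <- utils::read.delim(p1)
  expect_equal(df$flux[df$reaction == "EX_D"], 10)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_flux_tsv(fva(m, fixed_objective_value = 10), p2)
  df2 <- utils::read.delim(p2)
  expect_true(all(c("reaction", "min", "max") %in% names(df2)))
})
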