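test_that("dead-end detection tags production/consumption gaps", {
  # A -> B with no consumer of B and no exchange for it
  m <- metabolic_model(
    list(metabolite("A"), metabolite("B")),
    list(reaction("EX_A", c(A = -1), -10, 0),
         reaction("R1", c(A = -1, B = 1), 0, 10)))
  dead <- find_dead_end_metabolites(m)
  expect_equal(dead, c(B = "no-consumption"))
  # fully exchanged chain: no dead ends
  expect_length(find_dead_end_metabolites(chain_model()), 0)
})

test_that("dead-end detection equals a brute-force directional scan", {
  set.seed(17)
  m <- random_balanced_model(n_reactions = 20, seed = 17)
  # break it: delete a couple of reactions so gaps appear
  m2 <- metabolic_model(m$metabolites, m$reactions[-c(3, 7)],
                        objective = NULL, id = "broken")
  dead <- find_dead_end_metabolites(m2)

  # oracle: per-metabolite scan over all reactions and allowed directions
  mets <- metabolite_ids(m2)
  oracle <- character(0)
  for (met in mets) {
    can_p <- FALSE; can_c <- FALSE
    for (r in m2$reactions) {
      cc <- r$stoichiometry[met]
      if (is.na(cc)) next
      if ((cc > 0 && r$upper_bound > 0) || (cc < 0 && r$lower_bound < 0)) {
        can_p <- TRUE
      }
      if ((cc < 0 && r$upper_bound > 0) || (cc > 0 && r$lower_bound < 0)) {
        can_c <- TRUE
      }
    }
    if (!can_p || !can_c) oracle <- c(oracle, met)
  }
  expect_setequal(names(dead), oracle)
})

broken_chain_db <- function() {
  # model: EX_in -> A, A->B, C->D, D-> EX_out; missing link B->C is in the DB
  mets <- lapply(c("A", "B", "C", "D"), function(id)
    metabolite(id, compartment = "c", formula = "X"))
  model <- metabolic_model(
    mets,
    list(reaction("EX_A", c(A = -1), -10, 0),
         reaction("AB", c(A = -1, B = 1), 0, 10),
         reaction("CD", c(C = -1, D = 1), 0, 10),
         reaction("EX_D", c(D = -1), 0, 10)),
    objective = "EX_D")
  db <- metabolic_model(
    mets,
    list(reaction("BC", c(B = -1, C = 1), 0, 10),
         reaction("AD_shortcut", c(A = -1, D = 1), 0, 10)))
  list(model = model, db = db)
}

test_that("gap_fill adds exactly the missing link", {
  f <- broken_chain_db()
  res <- gap_fill(f$model, f$db)
  expect_setequal(names(res$dead_ends), c("B", "C"))
  expect_equal(res$added, "BC")
  expect_length(res$unfillable, 0)
  expect_length(find_dead_end_metabolites(res$model), 0)
})

test_that("gap_fill prefers the cheaper of two candidate fixes", {
  f <- broken_chain_db()
  # two ways to reconnect B and C; the transport-like one is penalized
  db <- metabolic_model(
    f$db$metabolites,
    list(reaction("BC_cheap", c(B = -1, C = 1), 0, 10),
         reaction("BC_costly", c(B = -1, C = 1), 0, 10,
                  subsystem = "transport")))
  # force different weights through explicit kinds: rename so kind detection
  # sees a transport (compartment-suffixed ids are not present here, so use
  # explicit weights instead)
  res <- gap_fill(f$model, db, weights = c(metabolic = 1, transport = 10,
                                           exchange = 100))
  expect_equal(res$added, "BC_cheap")
  expect_equal(res$weight, 1)
})

test_that("gap_fill weight equals the power-set-search optimum", {
  set.seed(55)
  f <- broken_chain_db()
  # database with several partially useful candidates
  mets <- lapply(c("A", "B", "C", "D", "E"), function(id)
    metabolite(id, compartment = "c", formula = "X"))
  db <- metabolic_model(
    mets,
    list(reaction("BE", c(B = -1, E = 1), 0, 10),
         reaction("EC", c(E = -1, C = 1), 0, 10),
         reaction("BC_direct", c(B = -1, C = 1), 0, 10,
                  subsystem = "transport"),
         reaction("CB_rev", c(C = -1, B = 1), 0, 10),
         reaction("DB", c(D = -1, B = 1), 0, 10)))
  weights <- c(metabolic = 1, transport = 10, exchange = 100)
  res <- gap_fill(f$model, db, weights = weights)

  # power-set oracle
  kinds <- vapply(db$reactions, gemctx:::reaction_kind, character(1))
  w_of <- unname(weights[kinds])
  dead <- names(find_dead_end_metabolites(f$model))
  best <- Inf
  for (mask in 0:(2^5 - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:4)) > 0)
    cand <- metabolic_model(mets,
                            c(f$model$reactions, db$reactions[idx]),
                            objective = f$model$objective)
    still_dead <- names(find_dead_end_metabolites(cand))
    if (length(intersect(dead, still_dead))) next
    best <- min(best, sum(w_of[idx]))
  }
  expect_equal(res$weight, best)   # BE + EC (weight 2) beats BC_direct (10)
  expect_setequal(res$added, c("BE", "EC"))
})

test_that("gap_fill reports unfillable gaps instead of failing", {
  f <- broken_chain_db()
  db_useless <- metabolic_model(f$db$metabolites,
                                list(reaction("AD", c(A = -1, D = 1), 0, 10)))
  res <- gap_fill(f$model, db_useless)
  expect_setequal(res$unfillable, c("B", "C"))
  expect_length(res$added, 0)
})

test_that("leak and siphon detection flags creation/destruction from nothing", {
  mets <- list(metabolite("A", formula = "X"), metabolite("B", formula = "X"))
  m_leak <- metabolic_model(
    mets, list(reaction("magic", c(A = 1), 0, 10),       # -> A internally? no:
               reaction("AB", c(A = -1, B = 1), 0, 10),
               reaction("EX_B", c(B = -1), 0, 10)))
  # "magic" is single-metabolite so it classifies as exchange; build a true
  # internal creator instead: 2A -> A + B net destroys A... use A -> 2A
  m_leak <- metabolic_model(
    mets, list(reaction("dup", c(A = 1, B = -1), 0, 10),
               reaction("AB", c(A = -1, B = 2), 0, 10),  # A -> 2B, B -> A+?:
               reaction("EX_B", c(B = -1), 0, 10)))
  # cycle: A -> 2B (AB), B -> A + ... net creation: A->2B then 2B->2A doubles A
  ls <- find_leaks_siphons(m_leak)
  expect_true(all(c("A", "B") %in% ls$leaks))

  # balanced fixtures are clean
  for (m in list(chain_model(), diamond_model(), random_balanced_model(16, 2))) {
    ls0 <- find_leaks_siphons(m)
    expect_length(ls0$leaks, 0)
    expect_length(ls0$siphons, 0)
  }

  # destroying reaction: 2A -> B with B -> A gives net consumption
  m_siphon <- metabolic_model(
    mets, list(reaction("shrink", c(A = -2, B = 1), 0, 10),
               reaction("BA", c(B = -1, A = 1), 0, 10),
               reaction("EX_A", c(A = -1), -10, 10)))
  ls2 <- find_leaks_siphons(m_siphon)
  expect_true("A" %in% ls2$siphons)
})

test_that("planted unbalanced reactions create leaks or siphons (property)", {
  set.seed(66)
  for (seed in 1:5) {
    m <- random_balanced_model(n_reactions = 12, seed = seed)
    ls0 <- find_leaks_siphons(m)
    expect_length(c(ls0$leaks, ls0$siphons), 0)
    # plant one mass-creating reaction closing a cycle back to the source:
    # P2 -> 2 S amplifies mass around the planted pathway
    bad <- reaction("planted_bad", c(P2 = -1, S = 2), 0, 10)
    m_bad <- metabolic_model(m$metabolites, c(m$reactions, list(bad)),
                             objective = m$objective)
    ls <- find_leaks_siphons(m_bad)
    expect_gt(length(c(ls$leaks, ls$siphons)), 0)
  }
})

leak_pair_model <- function() {
  # single offending internal pair: A -> 2B, B -> A (net creates B)
  metabolic_model(
    list(metabolite("A", formula = "X"), metabolite("B", formula = "X"),
         metabolite("C", formula = "X")),
    list(reaction("dbl", c(A = -1, B = 2), 0, 10),
         reaction("back", c(B = -1, A = 1), 0, 10),
         reaction("BC", c(B = -1, C = 1), 0, 10),
         reaction("EX_C", c(C = -1), 0, 10)))
}

test_that("minimal_leakage_mode returns a minimum-cardinality certificate", {
  m <- leak_pair_model()
  ls <- find_leaks_siphons(m)
  expect_true("B" %in% ls$leaks)
  mode <- minimal_leakage_mode(m, "B", "leak")
  expect_setequal(as.character(mode), c("dbl", "back"))

  # certificate property: the induced submodel still leaks
  sub <- metabolic_model(m$metabolites,
                         Filter(function(r) r$id %in% mode, m$reactions))
  expect_true("B" %in% find_leaks_siphons(sub)$leaks)

  # non-leaking metabolite errors
  m_ok <- chain_model()
  expect_error(minimal_leakage_mode(m_ok, "M1", "leak"), "not a leak")
})

test_that("minimal_leakage_mode cardinality equals exhaustive search", {
  # <= 8 reactions: compare against subset enumeration
  m <- metabolic_model(
    list(metabolite("A", formula = "X"), metabolite("B", formula = "X"),
         metabolite("C", formula = "X")),
    list(reaction("dbl", c(A = -1, B = 2), 0, 10),
         reaction("back", c(B = -1, A = 1), 0, 10),
         reaction("tri", c(A = -1, C = 3), 0, 10),      # bigger leak route
         reaction("cb", c(C = -1, B = 1), 0, 10),
         reaction("ba2", c(B = -2, A = 1), 0, 10),
         reaction("EX_B", c(B = -1), 0, 10)))
  ls <- find_leaks_siphons(m)
  expect_true("B" %in% ls$leaks)
  mode <- minimal_leakage_mode(m, "B", "leak")

  # oracle: smallest reaction subset whose induced submodel leaks B
  rids <- reaction_ids(m)
  best <- Inf
  for (mask in 1:(2^length(rids) - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_along(rids) - 1)) > 0)
    if (length(idx) >= best) next
    sub <- metabolic_model(m$metabolites, m$reactions[idx])
    if ("B" %in% find_leaks_siphons(sub)$leaks) best <- length(idx)
  }
  expect_equal(length(mode), best)
})

test_that("balance_reaction_pair restores zero residuals with candidates", {
  mets <- list(
    metabolite("glc_c", compartment = "c", formula = "C6H12O6"),
    metabolite("lac_c", compartment = "c", formula = "C3H6O3"),
    metabolite("pyr_c", compartment = "c", formula = "C3H4O3"),
    metabolite("h2o_c", compartment = "c", formula = "H2O"),
    metabolite("h_c", compartment = "c", formula = "H"),
    metabolite("e_c", compartment = "c", formula = ""))
  # pyr -> lac is missing 2 H; glc -> 2 pyr is missing 4 H (2 H2O + 2H? no:
  # C6H12O6 -> 2 C3H4O3 leaves H: 12-8=4, O: 6-6=0 -> 4 h_c on the right
  m <- metabolic_model(
    mets,
    list(reaction("GLYC", c(glc_c = -1, pyr_c = 2), 0, 10),
         reaction("LDH", c(pyr_c = -1, lac_c = 1), 0, 10),
         reaction("EX_glc", c(glc_c = -1), -10, 0)))
  out <- balance_reaction_pair(m, "GLYC", "LDH",
                               candidates = c("h_c", "h2o_c"))
  expect_true(all(out$report$balanced))
  expect_true(all(abs(check_mass_balance(out$model, "GLYC")) < 1e-9))
  expect_true(all(abs(check_mass_balance(out$model, "LDH")) < 1e-9))
  st <- get_reaction(out$model, "GLYC")$stoichiometry
  expect_equal(st[["h_c"]], 4)          # integer-linear-system solution
  st2 <- get_reaction(out$model, "LDH")$stoichiometry
  expect_equal(st2[["h_c"]], -2)
})

test_that("already balanced pairs are untouched; impossible ones reported", {
  m <- glc_lac_model()
  out <- balance_reaction_pair(m, "GLYCL", "GLYCL", candidates = "lac")
  expect_true(all(out$report$balanced))
  expect_equal(get_reaction(out$model, "GLYCL")$stoichiometry,
               get_reaction(m, "GLYCL")$stoichiometry)

  mets <- list(metabolite("a", formula = "C2"), metabolite("b", formula = "C1"),
               metabolite("h2o", formula = "H2O"))
  m2 <- metabolic_model(mets,
                        list(reaction("r", c(a = -1, b = 1), 0, 1),
                             reaction("r2", c(b = -1, a = 1), 0, 1)))
  out2 <- balance_reaction_pair(m2, "r", "r2", candidates = "h2o")
  expect_false(any(out2$report$balanced))   # water cannot supply carbon
})

test_that("random small imbalances over {H, H2O} match the linear-system oracle", {
  set.seed(88)
  for (rep in 1:10) {
    nh <- sample(-3:3, 1); nw <- sample(-2:2, 1)
    # build a product metabolite whose formula absorbs the planted imbalance
    h_cnt <- 4 + nh + 2 * nw; o_cnt <- 1 + nw
    if (h_cnt < 0 || o_cnt < 0) next
    f_prod <- paste0("C2", if (h_cnt > 0) paste0("H", h_cnt),
                     if (o_cnt > 0) paste0("O", o_cnt))
    mets <- list(metabolite("sub", formula = "C2H4O"),
                 metabolite("prd", formula = f_prod),
                 metabolite("h", formula = "H"),
                 metabolite("h2o", formula = "H2O"))
    m <- metabolic_model(mets,
                         list(reaction("r", c(sub = -1, prd = 1), 0, 1),
                              reaction("x", c(prd = -1, sub = 1), 0, 1)))
    out <- balance_reaction_pair(m, "r", "x", candidates = c("h", "h2o"))
    expect_true(all(out$report$balanced))
    st <- get_reaction(out$model, "r")$stoichiometry
    # oracle: solve E x = -residual exhaustively over small coefficients
    res <- check_mass_balance(m, "r")
    found <- NULL
    for (ch in -6:6) for (cw in -6:6) {
      if (abs(res[["H"]] + ch + 2 * cw) < 1e-9 &&
          abs(res[["O"]] + cw) < 1e-9 &&
          abs(res[["C"]]) < 1e-9) found <- c(h = ch, h2o = cw)
    }
    expect_false(is.null(found))
    got_h <- if ("h" %in% names(st)) st[["h"]] else 0
    expect_equal(got_h, unname(found["h"]), tolerance = 1e-9)
  }
})
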