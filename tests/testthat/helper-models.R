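# Shared fixture builders (code, not files: everything is reproducible)

# linear chain with an uptake and a secretion exchange
chain_model <- function(capacities = c(4, 9, 2)) {
  make_toy_model(fixture_spec("chain", capacities = capacities,
                              gpr_fraction = 0, seed = 1))
}

diamond_model <- function() {
  make_toy_model(fixture_spec("diamond", gpr_fraction = 0, seed = 1))
}

cycle_trap_model <- function() {
  make_toy_model(fixture_spec("cycle-trap", gpr_fraction = 0, seed = 1))
}

# 2 metabolites, 3 reactions; glucose -> 2 lactate with real formulas
glc_lac_model <- function() {
  metabolic_model(
    list(metabolite("glc", compartment = "c", formula = "C6H12O6"),
         metabolite("lac", compartment = "c", formula = "C3H6O3")),
    list(reaction("EX_glc", c(glc = -1), -10, 0),
         reaction("GLYCL", c(glc = -1, lac = 2), 0, 1000),
         reaction("EX_lac", c(lac = -1), 0, 1000)),
    objective = "EX_lac")
}

# random small mass-balanced network (single pseudo-element, all coeffs 1)
random_balanced_model <- function(n_reactions = 20, seed = 1) {
  make_toy_model(fixture_spec("random", n_reactions = n_reactions,
                              gpr_fraction = 0, seed = seed))
}

# a tiny omics table
tiny_table <- function(values, kind = "transcript",
                       groups = rep("g1", ncol(values))) {
  omics_table(values, groups, kind)
}
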