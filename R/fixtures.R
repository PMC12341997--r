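#' Synthetic fixture specification
#'
#' Describes a reproducible toy model plus omics generator run. The same
#' spec (including `seed`) always produces bit-identical outputs.
#'
#' Defaults state the emulated world: three treatment groups with 6
#' replicates each, transcript-protein correlation `rho = 0.6` (empirical
#' mRNA-protein correlations are moderate), log-normal abundances with
#' within-group noise sd 0.5 on the log2 scale, and 10% missing protein
#' intensities (label-free proteomics loses low-abundance peptides;
#' transcript counts are complete).
#'
#' @param topology `"chain"`, `"diamond"`, `"cycle-trap"` or `"random"`.
#' @param n_reactions Number of internal reactions (random topology).
#' @param capacities Capacities of the chain steps (chain topology).
#' @param gpr_fraction Fraction of internal reactions that receive a GPR.
#' @param noise_sd Within-group sd of log2 abundances.
#' @param rho Transcript-protein correlation on the log scale.
#' @param replicates Replicates per group.
#' @param missing_rate Missing-at-random rate for protein intensities.
#' @param seed Integer seed.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(topology = c("random", "chain", "diamond",
                                      "cycle-trap"),
                         n_reactions = 12, capacities = c(4, 9, 2),
                         gpr_fraction = 1.0, noise_sd = 0.5, rho = 0.6,
                         replicates = 6, missing_rate = 0.1, seed = 1) {
  topology <- match.arg(topology)
  stopifnot(n_reactions >= 4, rho >= 0, rho <= 1, noise_sd >= 0,
            missing_rate >= 0, missing_rate < 1, replicates >= 1)
  structure(list(topology = topology, n_reactions = n_reactions,
                 capacities = capacities, gpr_fraction = gpr_fraction,
                 noise_sd = noise_sd, rho = rho, replicates = replicates,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "fixture_spec")
}

pseudo_met <- function(id) metabolite(id, compartment = "c", formula = "X")

assign_gprs <- function(rxns, gpr_fraction) {
  # each selected reaction gets one of: single gene, 2-gene AND, 2-gene OR
  for (k in seq_along(rxns)) {
    if (rxns[[k]]$is_exchange) next
    if (stats::runif(1) > gpr_fraction) next
    base <- paste0("g_", rxns[[k]]$id)
    kind <- sample(c("single", "and", "or"), 1)
    rxns[[k]]$gpr <- switch(kind,
      single = parse_gpr(base),
      and = parse_gpr(paste(paste0(base, "_1"), "and", paste0(base, "_2"))),
      or = parse_gpr(paste(paste0(base, "_1"), "or", paste0(base, "_2"))))
  }
  rxns
}

#' Generate a toy metabolic model
#'
#' All topologies are elementally balanced by construction (every metabolite
#' carries the single pseudo-element formula `"X"`, all coefficients 1), so
#' leak/siphon detection is clean by design. `chain` has the analytic FBA
#' optimum `min(capacities)`; `diamond` has two parallel routes with
#' capacities 3 and 7 (optimum 10); `cycle-trap` adds a 3-reaction internal
#' cycle to a productive path for loopless tests; `random` builds two
#' parallel pathways (a planted one and a decoy) between a source and a
#' sink, tagged in attribute `planted`.
#'
#' @param spec A [fixture_spec()].
#' @return A `metabolic_model`; attributes: `planted` (reaction ids of the
#'   planted active subnetwork), `decoy`.
#' @export
make_toy_model <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  build <- switch(spec$topology,
                  chain = toy_chain(spec$capacities),
                  diamond = toy_diamond(),
                  `cycle-trap` = toy_cycle_trap(),
                  random = toy_random(spec$n_reactions))
  rxns <- assign_gprs(build$reactions, spec$gpr_fraction)
  m <- metabolic_model(build$metabolites, rxns, objective = build$objective,
                       id = paste0("toy_", spec$topology))
  attr(m, "planted") <- build$planted
  attr(m, "decoy") <- build$decoy
  m
}

toy_chain <- function(capacities) {
  n <- length(capacities)
  mids <- paste0("M", seq_len(n + 1L))
  mets <- lapply(mids, pseudo_met)
  rxns <- c(
    list(reaction("EX_in", stats::setNames(-1, mids[1]), -1000, 0)),
    lapply(seq_len(n), function(i) {
      reaction(paste0("R", i),
               stats::setNames(c(-1, 1), mids[c(i, i + 1L)]),
               0, capacities[i])
    }),
    list(reaction("EX_out", stats::setNames(-1, mids[n + 1L]), 0, 1000)))
  list(metabolites = mets, reactions = rxns, objective = "EX_out",
       planted = paste0("R", seq_len(n)), decoy = character(0))
}

toy_diamond <- function(cap_b = 3, cap_c = 7) {
  mets <- lapply(c("A", "B", "C", "D"), pseudo_met)
  rxns <- list(
    reaction("EX_A", c(A = -1), -1000, 0),
    reaction("AB", c(A = -1, B = 1), 0, cap_b),
    reaction("AC", c(A = -1, C = 1), 0, cap_c),
    reaction("BD", c(B = -1, D = 1), 0, 1000),
    reaction("CD", c(C = -1, D = 1), 0, 1000),
    reaction("EX_D", c(D = -1), 0, 1000))
  list(metabolites = mets, reactions = rxns, objective = "EX_D",
       planted = c("AB", "BD"), decoy = c("AC", "CD"))
}

toy_cycle_trap <- function() {
  mets <- lapply(c("A", "B", "C", "D"), pseudo_met)
  rxns <- list(
    reaction("EX_A", c(A = -1), -1000, 0),
    reaction("AB", c(A = -1, B = 1), 0, 10),
    reaction("EX_B", c(B = -1), 0, 1000),
    # 3-reaction internal cycle B -> C -> D -> B, capacity far above the path
    reaction("BC", c(B = -1, C = 1), 0, 1000),
    reaction("CD", c(C = -1, D = 1), 0, 1000),
    reaction("DB", c(D = -1, B = 1), 0, 1000))
  list(metabolites = mets, reactions = rxns, objective = "EX_B",
       planted = c("AB"), decoy = c("BC", "CD", "DB"))
}

toy_random <- function(n_reactions) {
  # two parallel pathways source -> sink; pathway 1 is the planted active
  # subnetwork. Both can carry steady-state flux by construction.
  len1 <- max(2L, floor(n_reactions / 2))
  len2 <- max(2L, n_reactions - len1)
  mids1 <- c("S", paste0("P", seq_len(len1 - 1L)), "T")
  mids2 <- c("S", paste0("Q", seq_len(len2 - 1L)), "T")
  mets <- lapply(unique(c(mids1, mids2)), pseudo_met)
  path_rxns <- function(mids, prefix, cap) {
    lapply(seq_len(length(mids) - 1L), function(i) {
      reaction(paste0(prefix, i),
               stats::setNames(c(-1, 1), mids[c(i, i + 1L)]),
               0, cap)
    })
  }
  rxns <- c(list(reaction("EX_S", c(S = -1), -1000, 0)),
            path_rxns(mids1, "act", 10),
            path_rxns(mids2, "dec", 10),
            list(reaction("EX_T", c(T = -1), 0, 1000)))
  list(metabolites = mets, reactions = rxns, objective = "EX_T",
       planted = paste0("act", seq_len(len1)),
       decoy = paste0("dec", seq_len(len2)))
}

#' Miniature astrocyte model
#'
#' A ~40-reaction model of the pathways central to astrocyte energy
#' metabolism: lumped glycolysis ending in lactate export, pyruvate
#' oxidation and a lumped TCA/oxidative phosphorylation branch, the
#' glutamate-glutamine cycle (uptake, glutamine synthetase, export),
#' glutathione synthesis, palmitate beta-oxidation and a tibolone
#' uptake/clearance pair, with a biomass (maintenance) objective that
#' requires glucose-derived carbon and ATP. Key currency metabolites
#' (glucose, lactate, glutamate, glutamine, glutathione, oxygen, CO2,
#' palmitate) carry real formulas so flux ratios such as the
#' glucose-to-lactate conversion are meaningful; cofactor pools are lumped
#' and unannotated.
#'
#' @return A `metabolic_model` with objective `BIOMASS`.
#' @export
make_astrocyte_mini <- function() {
  M <- function(id, comp, formula = "") metabolite(id, compartment = comp,
                                                   formula = formula)
  mets <- list(
    M("glc_e", "e", "C6H12O6"), M("glc_c", "c", "C6H12O6"),
    M("g6p_c", "c"), M("pyr_c", "c"), M("pyr_m", "m"),
    M("lac_c", "c", "C3H6O3"), M("lac_e", "e", "C3H6O3"),
    M("o2_e", "e", "O2"), M("o2_c", "c", "O2"), M("o2_m", "m", "O2"),
    M("co2_m", "m", "CO2"), M("co2_e", "e", "CO2"),
    M("atp_c", "c"), M("adp_c", "c"),
    M("nad_c", "c"), M("nadh_c", "c"), M("nad_m", "m"), M("nadh_m", "m"),
    M("coa_m", "m"), M("accoa_m", "m"),
    M("glu_e", "e", "C5H9NO4"), M("glu_c", "c", "C5H9NO4"),
    M("gln_c", "c", "C5H10N2O3"), M("gln_e", "e", "C5H10N2O3"),
    M("akg_m", "m"), M("nh4_e", "e"), M("nh4_c", "c"),
    M("gsh_c", "c", "C10H17N3O6S"), M("gsh_e", "e", "C10H17N3O6S"),
    M("cys_e", "e", "C3H7NO2S"), M("cys_c", "c", "C3H7NO2S"),
    M("gly_e", "e", "C2H5NO2"), M("gly_c", "c", "C2H5NO2"),
    M("pmt_e", "e", "C16H32O2"), M("pmt_c", "c", "C16H32O2"),
    M("tib_e", "e", "C21H28O2"), M("tib_c", "c", "C21H28O2"),
    M("h2o_c", "c", "H2O"))
  EX <- function(met, lb = 0, ub = 1000) {
    reaction(paste0("EX_", met), stats::setNames(-1, met), lb, ub,
             subsystem = "exchange")
  }
  R <- reaction
  rxns <- list(
    EX("glc_e"), EX("o2_e"), EX("lac_e"), EX("co2_e"), EX("glu_e"),
    EX("gln_e"), EX("gsh_e"), EX("cys_e"), EX("gly_e"), EX("nh4_e"),
    EX("pmt_e"), EX("tib_e"), EX("h2o_c", lb = -1000),
    R("GLCt", c(glc_e = -1, glc_c = 1), 0, 1000, "SLC2A1",
      subsystem = "transport"),
    R("HEX1", c(glc_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1), 0, 1000,
      "HK1 or HK2", subsystem = "glycolysis"),
    R("GLYC", c(g6p_c = -1, adp_c = -2, nad_c = -2,
                pyr_c = 2, atp_c = 2, nadh_c = 2), 0, 1000,
      "GAPDH and PKM", subsystem = "glycolysis"),
    R("LDH", c(pyr_c = -1, nadh_c = -1, lac_c = 1, nad_c = 1), -1000, 1000,
      "LDHA or LDHB", subsystem = "glycolysis"),
    R("LACt", c(lac_c = -1, lac_e = 1), -1000, 1000,
      "SLC16A1 or SLC16A3", subsystem = "transport"),
    R("PYRtm", c(pyr_c = -1, pyr_m = 1), 0, 1000, "MPC1 and MPC2",
      subsystem = "transport"),
    R("PDH", c(pyr_m = -1, coa_m = -1, nad_m = -1,
               accoa_m = 1, co2_m = 1, nadh_m = 1), 0, 1000,
      "PDHA1 and DLAT", subsystem = "TCA"),
    R("TCA", c(accoa_m = -1, nad_m = -3, adp_c = -1,
               coa_m = 1, co2_m = 2, nadh_m = 3, atp_c = 1), 0, 1000,
      "CS and IDH3A", subsystem = "TCA"),
    R("ETC", c(nadh_m = -1, o2_m = -0.5, adp_c = -2.5,
               nad_m = 1, atp_c = 2.5, h2o_c = 1), 0, 1000,
      "NDUFS1 and COX4I1", subsystem = "oxphos"),
    R("O2t", c(o2_e = -1, o2_c = 1), 0, 1000, subsystem = "transport"),
    R("O2tm", c(o2_c = -1, o2_m = 1), 0, 1000, subsystem = "transport"),
    R("CO2t", c(co2_m = -1, co2_e = 1), 0, 1000, subsystem = "transport"),
    R("NADHS", c(nadh_c = -1, nad_m = -1, nad_c = 1, nadh_m = 1), 0, 1000,
      "MDH1 and MDH2", subsystem = "shuttle"),
    R("GLUt", c(glu_e = -1, glu_c = 1), 0, 1000, "SLC1A2 or SLC1A3",
      subsystem = "transport"),
    R("GLNS", c(glu_c = -1, nh4_c = -1, atp_c = -1, gln_c = 1, adp_c = 1),
      0, 1000, "GLUL", subsystem = "glutamate"),
    R("GLNt", c(gln_c = -1, gln_e = 1), 0, 1000, "SLC38A3",
      subsystem = "transport"),
    R("GDH", c(glu_c = -1, nad_c = -1, akg_m = 1, nh4_c = 1, nadh_c = 1),
      0, 1000, "GLUD1", subsystem = "glutamate"),
    R("AKGDH", c(akg_m = -1, nad_m = -2, adp_c = -1,
                 co2_m = 2, nadh_m = 2, atp_c = 1), 0, 1000, "OGDH",
      subsystem = "TCA"),
    R("NH4t", c(nh4_e = -1, nh4_c = 1), 0, 1000, subsystem = "transport"),
    R("CYSt", c(cys_e = -1, cys_c = 1), 0, 1000, subsystem = "transport"),
    R("GLYt", c(gly_e = -1, gly_c = 1), 0, 1000, subsystem = "transport"),
    R("GSHS", c(glu_c = -1, cys_c = -1, gly_c = -1, atp_c = -2,
                gsh_c = 1, adp_c = 2), 0, 1000, "GCLC and GSS",
      subsystem = "glutathione"),
    R("GSHt", c(gsh_c = -1, gsh_e = 1), 0, 1000, "ABCC1",
      subsystem = "transport"),
    R("PMTt", c(pmt_e = -1, pmt_c = 1), 0, 1000, "CD36",
      subsystem = "transport"),
    R("FAOX", c(pmt_c = -1, coa_m = -8, nad_m = -7, adp_c = -1,
                accoa_m = 8, nadh_m = 7, atp_c = 1), 0, 1000,
      "CPT1A and ACADVL", subsystem = "beta-oxidation"),
    R("TIBt", c(tib_e = -1, tib_c = 1), 0, 1000, subsystem = "transport"),
    R("DM_tib", c(tib_c = -1), 0, 1000, subsystem = "demand"),
    R("ATPM", c(atp_c = -1, adp_c = 1), 0, 1000, subsystem = "maintenance"),
    R("BIOMASS", c(g6p_c = -0.3, atp_c = -3, glu_c = -0.1, cys_c = -0.02,
                   gly_c = -0.02, gsh_c = -0.01, adp_c = 3), 0, 1000,
      subsystem = "biomass"))
  metabolic_model(mets, rxns, objective = "BIOMASS", id = "astrocyte_mini")
}

#' DMEM/FBS-like fixture medium for the miniature astrocyte model
#'
#' Concentrations loosely follow high-glucose DMEM (25 mM glucose) with
#' serum-level amino acids; oxygen is effectively unconstrained. With unit
#' culture parameters, uptake bounds equal concentrations numerically.
#'
#' @return A [medium()].
#' @export
astrocyte_medium <- function() {
  medium(c(glc_e = 25, o2_e = 100, glu_e = 0.5, cys_e = 0.2, gly_e = 0.4,
           nh4_e = 0.5))
}

#' Simulate paired transcript and protein tables with known ground truth
#'
#' Genes attached (through the GPRs) to the planted-active reactions draw
#' their log2 abundance from a high component, all others from a low one;
#' each protein's log intensity mixes the gene's transcript deviation with
#' independent noise so that the transcript-protein correlation is `rho`.
#' Protein intensities are censored missing-at-random at `missing_rate`;
#' transcript counts are complete integers. Groups are basal / PA / TbPA
#' with `replicates` samples each.
#'
#' @param model A model from [make_toy_model()] (GPRs required).
#' @param spec The [fixture_spec()] used to build it.
#' @param mu_high,mu_low Mean log2 abundance of active / inactive genes.
#' @return List: `transcript` and `protein` (`omics_table`s), `truth`
#'   (planted reaction ids).
#' @export
simulate_omics <- function(model, spec, mu_high = 9, mu_low = 5) {
  stopifnot(inherits(spec, "fixture_spec"))
  planted <- attr(model, "planted")
  genes_of <- lapply(model$reactions, function(r) gpr_genes(r$gpr))
  names(genes_of) <- reaction_ids(model)
  all_genes <- sort(unique(unlist(genes_of)))
  if (length(all_genes) == 0L) stop("model has no GPRs", call. = FALSE)
  active_genes <- sort(unique(unlist(genes_of[planted])))
  set.seed(spec$seed + 1L)
  groups <- rep(c("basal", "PA", "TbPA"), each = spec$replicates)
  samples <- paste0(groups, "_", sequence(rep(spec$replicates, 3)))
  ng <- length(all_genes); ns <- length(samples)
  mu <- ifelse(all_genes %in% active_genes, mu_high, mu_low)
  e1 <- matrix(stats::rnorm(ng * ns, sd = spec$noise_sd), ng, ns)
  e2 <- matrix(stats::rnorm(ng * ns, sd = spec$noise_sd), ng, ns)
  t_log <- mu + e1
  p_log <- mu + spec$rho * e1 + sqrt(1 - spec$rho^2) * e2
  tvals <- round(2^t_log)
  pvals <- 2^p_log
  if (spec$missing_rate > 0) {
    drop <- matrix(stats::runif(ng * ns) < spec$missing_rate, ng, ns)
    # never censor a protein completely
    full <- rowSums(!drop) == 0L
    drop[full, 1] <- FALSE
    pvals[drop] <- NA_real_
  }
  dimnames(tvals) <- dimnames(pvals) <- list(all_genes, samples)
  list(transcript = omics_table(tvals, groups, "transcript"),
       protein = omics_table(pvals, groups, "protein"),
       truth = planted)
}
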