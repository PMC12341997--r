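---
title: "Methods: multi-omics contextualization of metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics contextualization of metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemctx)
```

## The problem

Genome-scale metabolic models (GEMs) describe a cell's metabolism as a
stoichiometric matrix $S$ over reactions with flux bounds, and predict flux
distributions by linear programming (flux balance analysis, FBA: maximize an
objective flux subject to $S v = 0$ and bounds). A generic human
reconstruction, however, contains far more reactions than any one cell type
uses. Context-specific extraction keeps only reactions supported by omics
measurements. Transcript abundance and protein abundance each carry part of
the evidence — transcripts with broad coverage but weak coupling to flux,
proteins closer to catalysis but sparser and noisier — so `gemctx` fuses
both layers into a single reaction-activity score before extraction, instead
of bounding reactions with either layer alone.

## Pipeline and model assumptions

1. **Preprocessing** (`filter_low_count_genes`, `log2_transform`,
   `filter_proteins_by_validity`, `knn_impute`, `zscore`). Transcript
   features with fewer than 10 total reads are dropped; proteins must have at
   least 70% valid values in every sample group; both layers are
   log2-transformed; remaining missing protein intensities are imputed with
   k-nearest-neighbor features (k = 10, Euclidean distance on shared observed
   columns). The variance-stabilizing normalization some proteomics
   pipelines apply is deliberately replaced by log2 + standardization: the
   downstream integration only needs symmetric, scale-free inputs, and the
   simpler transform is exactly testable. The per-group validity rule is
   interpreted as *fraction* ≥ 0.7 within each group (with 6 replicates this
   means ≥ 5 of 6), the only reading that generalizes across group sizes.
   `zscore` uses the population (1/N) standard deviation so the transform is
   exactly idempotent.

2. **GPR mapping** (`map_to_reactions`). Each reaction's gene-protein-
   reaction rule is evaluated with gene values substituted at the leaves:
   `AND` → min (all complex members are required), `OR` → max (the strongest
   isozyme suffices). This yields one $\mathbb{R}^n$ vector per omics layer,
   $n$ = number of reactions. A reaction with no rule, or whose rule cannot
   be resolved, is *uncovered* — absent from the vector, never silently
   zero. Under the default missing policy an unmeasured gene is ignored
   below `OR` but vetoes `AND` (a complex cannot be asserted present when a
   subunit is unmeasured).

3. **PCA fusion** (`integrate_activity`). The two activity vectors are
   z-scored across their common reactions (the two layers live on different
   scales; without standardization the covariance eigen-decomposition would
   be dominated by the wider one), assembled into a reactions × 2 matrix and
   decomposed via the covariance matrix (`pca_cov`, eigen-decomposition with
   a deterministic sign convention: the largest-magnitude loading of each
   component is positive). The integrated score is the
   variance-fraction-weighted sum of the first two component scores. Two
   genuinely open design points are resolved as follows and are
   configurable:
   * *Orientation*: PCA is run over reactions as observations and
     {transcript, protein} as the two variables — the only arrangement that
     returns one score per reaction.
   * *Scalarization*: with two retained components a rule is needed to
     collapse them to one score; weighting each component score by its
     explained-variance fraction is the least arbitrary choice (it reduces
     to plain PC1 when one component dominates, and is symmetric in the
     inputs).

4. **Threshold scaling** (`to_threshold_scale`). The extraction step
   classifies reactions against fixed thresholds of −500 and +500. PCA
   scores are signed and of arbitrary scale, so they are first compressed
   with the signed logarithm $s(x) = \mathrm{sign}(x)\,\ln(1+|x|)$ (a plain
   log is undefined for signed scores; $s$ is odd, monotone and fixes 0),
   then mapped affinely so the 25th/75th percentiles land exactly on the
   thresholds. HIGH and LOW therefore correspond to the outer quartiles by
   default; both quantiles and targets are parameters.

5. **Extraction** (`classify_reactions`, `imat`, `extract_context_model`,
   `activity_to_bounds`). Classification is strict (> +500 is HIGH,
   < −500 is LOW, boundaries are MODERATE). The iMAT program maximizes the
   number of HIGH reactions carrying at least $\varepsilon = 1$ flux (in
   either direction if reversible) plus LOW reactions carrying none;
   uncovered and MODERATE reactions are neither rewarded nor penalized. The
   extracted model keeps flux-carrying reactions plus all exchanges and the
   objective (the medium step downstream needs the boundary intact). The
   expression-to-bounds rescaling (an exp2flux-style step) is applied
   *after* extraction by default; both orders are supported because the
   source workflow does not pin one down. $\varepsilon = 1$ is the
   customary iMAT default; the tie among alternate MILP optima is broken
   deterministically (first optimum in a fixed search order, then the
   minimum-total-|v| flux within it), so extraction is reproducible.

6. **Curation** (`find_dead_end_metabolites`, `gap_fill`,
   `find_leaks_siphons`, `minimal_leakage_mode`, `balance_reaction_pair`).
   Dead ends are metabolites that no reaction can produce or none can
   consume under the current bounds. Gap filling selects a minimum-weight
   set of universal-database reactions making every fixable dead end able to
   carry steady-state flux in both directions; weights default to 1/10/100
   for metabolic/transport/exchange candidates, discouraging boundary
   patches. Leaks (producible with every exchange closed) and siphons
   (consumable from nothing) are mass-conservation violations; each is
   certified by an LP with a temporary drain or source, and
   `minimal_leakage_mode` finds a smallest reaction set reproducing the
   violation. Element balancing solves $E_c x = -\text{residual}$ over a
   candidate set (protons, water, electrons by default — the classic
   balancing species; the set is configurable because no canonical choice
   exists). A reaction that cannot be balanced is reported, not altered:
   curation reports what remains rather than forcing resolution.

7. **Simulation** (`apply_medium`, `fba`, `fva`, `run_scenario`,
   `prediction_accuracy`). Medium concentrations (mM) convert to uptake
   bounds via $\text{flux} = C \cdot V / (X \cdot t)$ with culture volume
   $V$ (L), biomass $X$ (gDW) and duration $t$ (h) as explicit parameters
   defaulting to 1 — the dimensional-analysis-forced form. Four scenarios
   are built in: basal; ischemia (oxygen and glucose uptake ramped 2.5 → 0
   mmol gDW⁻¹ h⁻¹, 11 steps by default since only the endpoints are
   specified); palmitate challenge (uptake 0.208); and tibolone
   pre-treatment plus palmitate (tibolone uptake 0.07 = 70 µM on the mM
   scale). FVA fixes the objective as an *absolute* equality (the use case
   is pinning biomass at an experimentally measured rate, e.g. 0.32); a
   fraction-of-optimum mode exists for convenience. The accuracy statistic
   is $(1 - |v_{pred} - v_{exp}|/v_{exp}) \times 100$, printed to two
   decimals with half-up rounding (values are snapped to 8 decimals first so
   an exact 96.875 prints as 96.88 despite binary floating point).

## Numerical choices

* **LP engine.** No linear-programming package is available in the target
  R environment, so the package ships a dense bounded-variable two-phase
  primal simplex (`solve_lp`) with Bland's anti-cycling rule. All problems
  here are tiny (tens of reactions), where a textbook dense implementation
  is fast and auditable. It is cross-checked in the test suite against an
  independent oracle (the HiGHS solver via scipy through the pre-installed
  Python) on random LPs, FBA instances and every FVA range.
* **iMAT as branch-and-bound.** Each iMAT indicator only tightens one
  reaction's bounds, so the MILP is solved exactly by depth-first
  branch-and-bound whose nodes are LP feasibility checks, with the bound
  "satisfied + remaining" for pruning. On every fixture up to 12 reactions
  the objective equals exhaustive enumeration over all indicator
  assignments.
* **Loopless FBA.** Instead of the big-M loop-law MILP, the FBA optimum is
  post-processed in the CycleFreeFlux style: exchange fluxes and the
  objective are pinned, each internal reaction is restricted to the sign of
  its FBA flux, and total internal |v| is minimized by LP. Any remaining
  sign-matched internal cycle could be subtracted from the solution,
  strictly lowering the minimized norm — a contradiction — so the result
  provably satisfies the loopless contract (no nonzero steady-state flux
  supported on internal reactions with the solution's sign pattern), which
  `find_internal_cycle` verifies directly in the tests. This avoids
  tuning a big-M constant and keeps the solver LP-only.
* **Tolerances.** Reduced-cost and ratio tolerances are 1e−9; flux support
  and leak tolerances 1e−6; steady state is verified to 1e−9 on all
  reported solutions. Degenerate inputs (constant activity vectors,
  zero-variance PCA columns, constant z-score rows, zero experimental flux)
  raise errors naming the offender rather than propagating NaN.

## What the synthetic data emulates — and what it does not

`fixture_spec`/`make_toy_model`/`simulate_omics` generate toy networks
(chain, diamond, a cycle trap for loopless tests, and random
parallel-pathway networks with a planted active subnetwork) plus paired
omics tables. The stated world: three treatment groups (basal, palmitate,
tibolone + palmitate) with 6 replicates each; log-normal abundances with
active genes at mean log2 intensity 9 and inactive at 5, within-group sd
0.5; transcript–protein correlation ρ = 0.6 (empirical mRNA–protein
correlations are moderate); 10% missing protein intensities at random;
transcript counts complete. Toy models are elementally balanced by
construction via single-pseudo-element formulas, so leak/siphon detection is
clean by design. `make_astrocyte_mini` is a ~40-reaction cartoon of
astrocyte metabolism (lumped glycolysis → lactate export, pyruvate
oxidation, TCA/oxidative phosphorylation, the glutamate–glutamine cycle,
glutathione synthesis, palmitate β-oxidation, a tibolone pair, and a
maintenance biomass objective that requires glucose-derived carbon, so the
ischemia ramp genuinely reaches zero).

A green test on these fixtures establishes that the algorithms are
implemented correctly at small scale. It does **not** establish anything
about reconstruction-scale behavior: real models have thousands of
reactions, incomplete and inconsistent GPR coverage (~50% is typical),
systematic rather than random proteomics missingness, and medium
compositions known only approximately. Reported reconstruction-scale
quantities (model size, leak/siphon counts, component variance splits,
absolute flux tables) are therefore outside what this package's tests can
or do claim.

## Known limitations

* The simplex is dense and unscaled; it is not intended for
  reconstruction-scale models (thousands of reactions), where a sparse
  industrial solver would be required.
* Gap filling and minimal leakage modes use exact combinatorial search,
  exponential in the worst case; they are designed for small candidate sets
  (tens), which the weighting scheme and the tests reflect.
* The SBML reader/writer covers the FBC v2 subset this workflow needs
  (species, bounds, gene associations, one maximization objective) and
  raises on anything else rather than dropping it silently.
* The per-condition collapse before GPR mapping is a mean over replicates;
  no differential-expression shrinkage is attempted.
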