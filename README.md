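# csif — four-state analysis of ligand-binding pathways from CPMG relaxation dispersion

`csif` resolves **conformational-selection (CS)** and **induced-fit (IF)**
ligand-binding pathways from ¹⁵N CPMG relaxation dispersion data. It is
built around a four-state exchange model of a protein that interconverts
between a closed ground state (1) and an open, binding-competent state (2),
and binds ligand either via the open state (CS: 1→2→4) or via a
ligand-associated closed intermediate (IF: 1→3→4). The package covers the
complete analysis chain used to dissect lactose binding to the
carbohydrate-recognition domain of human galectin-3 (galectin-3C), and a
synthetic-data generator that emulates that study so every stage is
testable end to end.

## What it computes

* **Forward models** — the Carver–Richards closed form for two-state
  exchange,

  R₂(1/τ) = R₂₀ + ½[k_ex − (1/τ) cosh⁻¹(D₊cosh η₊ − D₋cos η₋)],

  and a general N-state Bloch–McConnell propagator
  (`M = K − diag(R₂₀) − i diag(ω)`, ideal 180° pulses as complex
  conjugation) that simulates the finite CPMG train exactly as measured:
  `R₂eff = −log(I(T)/I(0))/T`.
* **Fitting** — residue-wise and global two-state fits of apo data with
  F-test model selection (`P < 0.01`); χ² grid search over the global
  parameters (k_on, ρ_off = k_off,3/k_off,4, ρ_close = k₂₁/k₄₃) followed by
  a global four-state Bloch–McConnell fit of all residues and ligand
  concentrations simultaneously, with δ₁ fixed, δ₄ constrained by the
  saturated-sample shift (δ_lac = p₃δ₃ + p₄δ₄), and Monte-Carlo parameter
  errors.
* **Kinetics** — microscopic rate constants under exact detailed balance,
  equilibrium populations, pathway fluxes from waiting-time sums
  (F_CS = [1/(k₁₂[P₁]) + 1/(k_on[P₂][L])]⁻¹ and the IF analogue), the
  CS→IF crossover concentration, and the Smoluchowski diffusion-limited
  on-rate k_on,D = 4πrDN_A×10³.

## Worked example

```r
library(csif)

# reference parameter set for lactose / galectin-3C at 301 K
rates <- galectin_rates()
print(rates)
#> Four-state microscopic rate constants:
#>   k12    =         34 s^-1      k21    =        735 s^-1
#>   k_on   =   1.72e+08 M^-1 s^-1
#>   k_off3 =  4.878e+05 s^-1      k_off4 =       1834 s^-1
#>   k34    =  2.103e+04 s^-1      k43    =       1709 s^-1
#>   cycle closure = 1

# how much of the binding flux runs through induced fit?
L <- free_ligand_at_saturation(rates, 0.76)
pathway_fluxes(rates, equilibrium_populations(rates, L), P_tot = 0.5e-3)
#> Pathway fluxes: F_CS = 0.003876 M/s, F_IF = 0.5759 M/s (IF share 99.3%)

flux_crossover(rates)     # CS -> IF switch at ~0.5 uM free ligand
#> [1] 5.085788e-07

diffusion_limited_kon(20e-10, 0.57e-9, 0.126e-9)  # ~1.05e10 M^-1 s^-1
#> [1] 10534162213
```

The IF share of the flux is ~74% at 4% saturation and ~99% at 76%
saturation: even though the open state binds ligand ~270-fold more tightly
(ρ_off), induced fit dominates because the bound protein opens four hundred
times faster than the apo protein (k₃₄ ≫ k₁₂).

A full synthetic round trip — generate a titration, fit it back, get
errors:

```r
design  <- study_design(seed = 1)            # 8 residues, 7 saturations, 14.1 T
dataset <- generate_titration_dataset(design)
fixed   <- list(k12 = 34, k21 = 735, Kd_macro = 223e-6,
                delta1 = setNames(as.list(dataset$truth$shifts$delta1),
                                  dataset$truth$shifts$residue),
                delta_lac = as.list(dataset$truth$delta_lac))
gs  <- grid_search_four_state(dataset, fixed)
fit <- fit_four_state_global(dataset, fixed, start = grid_top_starts(gs, 3))
fit <- monte_carlo_errors(fit, n_replicates = 100, seed = 1)
```

A thin command-line wrapper with subcommands `simulate-apo`,
`simulate-titration`, `fit-apo`, `fit-global`, `gridsearch` and `flux`
lives at `inst/cli/csif` (installed under `system.file("cli", "csif")`).

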