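---
title: "Resolving conformational-selection and induced-fit binding pathways from CPMG relaxation dispersion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving conformational-selection and induced-fit binding pathways from CPMG relaxation dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csif)
```

## The scientific problem

A protein that changes conformation upon ligand binding can do so along two
pathways. In *conformational selection* (CS) the ligand binds a pre-existing,
weakly populated open conformation; in *induced fit* (IF) it binds the
dominant closed conformation and then drives the conformational change. The
two pathways are not mutually exclusive: which one dominates is decided by
the reaction *flux* through each, not by the mere existence of an open
state. `csif` implements a four-state kinetic analysis of ¹⁵N CPMG
relaxation dispersion data that resolves both pathways and their fluxes,
developed around the lactose/galectin-3C system as the worked reference
case.

The four states are:

* state 1 — ligand-free, closed (ground state),
* state 2 — ligand-free, open (high-energy, binding-competent),
* state 3 — ligand-associated, closed (IF intermediate),
* state 4 — ligand-bound, open (final complex).

CS is the route 1→2→4, IF the route 1→3→4; there is no direct 1↔4 or 2↔3
exchange. Binding steps are pseudo-first-order with rate `k_on * [L]`, with
a single bimolecular `k_on` shared by both pathways.

## Model parameterization and derived rates

The fit has three global parameters: `k_on`, the off-rate ratio
`rho_off = k_off3/k_off4`, and the open→closed rate ratio `rho_close`.
Three further quantities are fixed inputs: the apo exchange rates `k12`,
`k21` (from two-state fits of apo data) and the macroscopic `Kd`.
`derive_rate_constants()` turns these six numbers into the seven
microscopic rate constants by imposing

1. `k43 = k21 / rho_close`,
2. detailed balance around the cycle 1-2-4-3-1, which fixes
   `k34/k43 = (k12/k21) * rho_off`,
3. the macroscopic affinity,
   `1/Kd = (k_on/k_off3) (1 + k34/k43)/(1 + k12/k21)`.

Two design choices deserve comment.

*The `rho_close` convention.* Both `k21/k43` and `k21/k34` appear as
definitions of `rho_close` in descriptions of this model. The package
defaults to `k21/k43`, which is the convention consistent with the
reference rate table (`735/1930 ≈ 0.38`, against a fitted value of 0.43;
`k21/k34` would give 0.027). Both conventions are available through the
`convention` argument of `four_state_params()`.

*Detailed balance is enforced exactly.* A thermodynamic cycle at
equilibrium must close; `rate_constants()` verifies the closure product to
`1e-10` by default. The rounded reference rate set
(`galectin_rates(balanced = FALSE)`) closes the cycle only to ~15% —
consistent with its two-significant-digit precision — and is stored with
the check disabled. All quantitative work uses the exactly balanced set
derived from the global parameter triple (`k_on = 172e6` M⁻¹s⁻¹,
`rho_off = 266`, `rho_close = 0.43`) with `k12 = 34` s⁻¹, `k21 = 735` s⁻¹
and `Kd = 223` µM. The `Kd` value is itself back-derived from the reference
rates (the directly measured calorimetric value is not part of the set);
it should be treated as a derived constant, not a measurement.

## Forward model of the CPMG experiment

Transverse magnetization of the four states evolves under the
Bloch–McConnell generator `M = K − diag(R20) − i diag(ω)`, where `K` is the
exchange matrix (pseudo-first-order in the free-ligand concentration), `ω`
holds the state resonance offsets (`Δω = Δδ·γ·B0`, shifts in ppm), and a
single exchange-free rate `R20` is shared by all four states of a residue
at a given field — the standard in-phase, single-quantum approximation with
an ideal, instantaneous 180° pulse modeled as complex conjugation.
Off-resonance effects and the relaxation-compensated pulse element are
handled experimentally, not modeled.

`simulate_dispersion()` propagates the echo train
`(τ/2 − 180° − τ/2)ⁿ` with `τ = 1/(2ν_cp)` and `n = 2 T_relax ν_cp`
(required to be an integer) and reports
`R2eff = −log(I(T)/I(0))/T` with `I` the summed real magnetization,
starting from magnetization proportional to the equilibrium populations —
exactly what the experiment's equilibration delay ensures. `T_relax`
defaults to 40 ms, a typical value for this experiment (the reference study
does not state its value); the default 17-point `ν_cp` grid spans 25–1000
Hz in multiples of 25 Hz so every echo count is exact.

Two numerical routes to `R2eff` are provided, and their relationship is a
deliberate part of the design:

* `carver_richards_r2()` — the two-state closed form. Internally the
  `cosh⁻¹` argument is evaluated with a complex-safe branch and an
  asymptotic expansion when `cosh(η₊)` would overflow.
* `bm_r2_asymptotic()` — the decay rate of the slowest mode of the
  numerical two-echo cycle propagator, a pure-R oracle independent of both
  the closed form and the compiled propagator.

The closed form agrees with the asymptotic propagator rate to machine
precision over the full slow/intermediate/fast parameter range — the test
suite asserts this over random draws. The *finite-train, endpoint-sampled*
`R2eff` of `simulate_dispersion()` additionally contains an amplitude term
of order `1/T_relax` that the asymptotic expressions omit; it is negligible
in fast exchange and stays within ~2% of the closed form in the regimes
probed experimentally, but grows in deep slow exchange with large minor
populations. For this reason the two-state fitters default to the
propagator likelihood (`method = "bm"`), which matches how the data —
measured or synthetic — are actually defined; `method = "cr"` selects the
closed form.

## Fitting protocol

The analysis proceeds in the same two stages as the experimental study.

**Apo stage.** `fit_two_state_residue()` fits each residue's curves (one or
both fields) with shared `k_ex`, `p_minor`, `|Δδ|` (sign is not
identifiable from CPMG alone and is left to auxiliary experiments) and a
per-field `R20`, by `1/σ²`-weighted Levenberg–Marquardt from a small
multi-start grid. `ftest_exchange_vs_flat()` compares against a flat model
at `P < 0.01`; `fit_two_state_global()` then ties residues reporting on the
same process to a single `(k_ex, p_minor)`.

A note on the F-test's operating characteristics: on data whose truth is
flat, the exchange alternative reaches its null through a degenerate
boundary (`Δδ → 0` makes `k_ex` and `p_minor` unidentifiable), so the
likelihood-ratio statistic is stochastically smaller than its nominal
reference distribution and the test rejects *less* often than 1% — it is
conservative. The test suite checks both facts: the F machinery attains the
nominal 1% on a regular nested linear pair, and the exchange-vs-flat
comparison does not exceed it.

**Titration stage.** `fit_four_state_global()` fits all residues and all
ligand concentrations simultaneously. Free parameters are exactly the three
globals plus, per residue, `δ2`, `δ3` and one `R20` (shared across
concentrations). `δ1` is fixed to the apo value; `δ4` is not free but
back-computed from the lactose-saturated observable
`δ_lac = p3 δ3 + p4 δ4`, evaluated with the saturated-limit partition
`p3:p4 = k43:k34` (the saturated sample is the limit `L → ∞`). Free-ligand
concentrations are recomputed from the mass balance at the fixed `Kd`
whenever the kinetics change.

The optimizer is a three-stage pipeline chosen for the roughness of the
χ² surface:

1. `grid_search_four_state()` profiles χ² (inner Levenberg–Marquardt over
   the residue-level parameters) on log-spaced grids covering `rho_off`
   30–1000, `rho_close` 0.001–1000 and `k_on` (8–300)×10⁶ M⁻¹s⁻¹. The
   surface is far sharper along `rho_close` than along the other axes, so
   that axis is sampled at half-decade steps. Grid ties are broken toward
   the lowest `k_on`, then the lowest `rho_off`.
2. From several low-χ² grid nodes with distinct `rho_close`
   (`grid_top_starts()`), a joint Levenberg–Marquardt over *all* free
   parameters (globals on the log scale). In practice this stage is highly
   basin-robust: it reaches the same optimum from widely separated nodes.
3. A short Nelder–Mead simplex refinement of the profiled objective around
   the optimum, followed by a final joint polish, accepted only if it
   lowers χ².

`monte_carlo_errors()` resimulates the best-fit curves with Gaussian noise
at the reported per-point σ, refits each replicate from the best-fit start,
and returns per-parameter standard deviations; 1000 replicates is the
convention for two-state fits and 500 for four-state fits. Replicate
non-convergence above 10% attaches a warning. The `k_on` dispersion is
heavy-tailed upward — the dispersion data lose sensitivity once binding
approaches the diffusion limit, a real feature of the experiment, so its
Monte-Carlo SD should be read as conservative.

## Kinetic post-analysis

From a balanced rate set the package computes equilibrium populations
(proportional to `1 : k12/k21 : k_on L/k_off3 : (k_on L/k_off3)(k34/k43)`),
pathway fluxes via waiting-time sums

F_CS = [1/(k12 [P1]) + 1/(k_on [P2][L])]⁻¹,
F_IF = [1/(k_on [P1][L]) + 1/(k34 [P3L])]⁻¹,

the IF flux share, the CS→IF crossover concentration (sign-change
bracketing on a log grid; the absence of a crossover is a valid, reported
outcome), and the Smoluchowski diffusion-limited on-rate
`k_on,D = 4π r D N_A × 10³`. For the reference system the IF share rises
from ~74% at 4% saturation to ~99% at 76% saturation, with a crossover in
the sub-micromolar range; `k_on,D ≈ 1.05×10¹⁰ M⁻¹s⁻¹`, some 60-fold above
the fitted `k_on`, as expected when binding requires a diffusive search
across the protein surface. Note that the low-concentration flux ratio is
delicately balanced — the two waiting-time sums differ by fractions of a
percent near the crossover — so the crossover location is very sensitive to
the input rates; with `rho_close = 0.381` (the rounded-table convention)
rather than 0.43 the crossover disappears entirely, with IF dominating at
all concentrations. Quantities like the flux share at experimental
saturations are robust to this choice at the level of a few percentage
points.

## The synthetic-data generator

`generate_apo_dataset()` and `generate_titration_dataset()` emulate the
design of the reference study: apo dispersion at 14.1 T and 18.8 T, seven
titration samples at 14.1 T at saturations 4, 8, 11, 21, 27, 30 and 75%,
eight reporting residues, 0.5 mM total protein (back-computed from the
published ligand loads and the derived `Kd`; the study's exact per-sample
concentrations are not in the main text), and Gaussian noise with
`SD = max(0.3 s⁻¹, 2% of R2)` — chosen so that recovery precision is
comparable to the reference parameter uncertainties. Ground-truth shifts
follow the physics of the system: `δ2` 0.5–3 ppm from `δ1`, `δ3` 0.1–1 ppm
on the same side, `δ4` within 0.2 ppm of `δ2` (open-state shifts with and
without ligand are similar). One master seed drives everything;
per-curve child seeds are derived from the curve identity, so a zero-ligand
titration sample is byte-identical to the apo generator's output.

What the generator does *not* emulate: peak overlap and integration errors,
off-resonance and pulse imperfections, temperature drift, R₁ρ/CEST-type
effects, scalar coupling and anti-phase coherences, or deviations from
Gaussian noise. Passing recovery tests on these fixtures therefore
demonstrates correctness of the estimator under the stated noise model, not
robustness to every systematic error of a real spectrometer.

## Numerical choices and degenerate inputs

* Weighted least squares uses `1/σ²` with σ taken from the data table.
* Log-scale parameters are clamped inside the optimizers (e.g. `k_ex` ≤
  e³⁰) so runaway steps stay finite; failed model evaluations return large
  residuals instead of raising, letting the optimizer retreat.
* Global-parameter bounds: `k_on` ∈ (10⁶, 10¹⁰) M⁻¹s⁻¹, `rho_off` ∈ (1,
  10⁴), `rho_close` ∈ (10⁻⁴, 10⁴) — generously enclosing the grid ranges.
* `free_ligand()` uses the closed-form quadratic root with a bisection
  fallback at `1e-12` relative tolerance.
* A `ν_cp` that does not give an integer echo count in `T_relax` is a
  schedule error, raised at construction.
* Zero ligand: fluxes are reported as 0 with a `zero_ligand` flag rather
  than dividing by zero; states 3 and 4 simply carry zero population.
* The test suite and the acceptance script scale problem sizes to run
  comfortably on a single CPU: Monte-Carlo replicate counts of 100–200
  (against defaults of 500–1000), 2–4 residue designs for the slower
  fitting tests, and the full 8-residue, 7-sample design for the headline
  recovery runs. The information a titration carries about `rho_off`
  depends noticeably on the drawn shift configuration, so the headline
  recovery experiment is run in triplicate (independent ground truths) and
  the recovered ratios are summarized by their geometric mean.

## Known limitations

* The in-phase single-quantum approximation ignores pulse imperfections;
  data acquired without relaxation compensation would need preprocessing.
* `R20` is assumed identical for the four states of a residue at a given
  field.
* The finite-train endpoint `R2eff` definition makes the closed-form
  likelihood (`method = "cr"`) slightly biased in slow exchange; the
  default propagator likelihood avoids this at modest cost.
* Only the flat-vs-exchange model comparison is built in; selection among
  alternative exchange topologies is out of scope.
* Fluxes are steady-state equilibrium quantities; transient kinetics
  (stopped-flow-type experiments) are not modeled.
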