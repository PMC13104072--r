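---
title: "Lumped kinetic modelling of hexane-2,3-diol pathway flux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lumped kinetic modelling of hexane-2,3-diol pathway flux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdokin)
```

## The modelling problem

Engineered *E. coli* strains convert glucose to hexane-2,3-diol (2,3-HDO)
through the chain

glucose → butyryl-CoA → butanal → 2,3-HDO,

where butyryl-CoA is supplied either by a fast PhaB-PhaJ route or a slower
reversal-β-oxidation (FadB) route, butyryl-CoA → butanal is catalysed by the
CoA-acylating aldehyde dehydrogenase PduP, and the final carboligation plus
reduction step is lumped into one reaction. In the parental strain,
endogenous thioesterases (TesB, YciA) additionally drain butyryl-CoA to
butyrate. The central scientific question the models address is whether
butyryl-CoA accumulation *inhibits* PduP: a plateauing product curve under a
fast inflow route, versus a steady rise under a slow one, is the fingerprint
this package quantifies with AIC model comparison.

`hdokin` implements four lumped ODE variants over the five species
(glucose, butyryl-CoA, butanal, butyrate, 2,3-HDO), all mass-conserving by
construction:

* `MR40_PHABJ` — parental strain: first-order steps with constants `Ka1`
  (glucose inflow, 1/h), `Km1` (PduP step), `Ka2` (thioesterase drain),
  `Ka3` (2,3-HDO formation).
* `DKO_PHABJ` — thioesterase double knockout; the drain is removed and the
  PduP step constant is renamed `Km2`.
* `DKO_PHABJ_INHIB` — as above but the PduP step follows the
  substrate-inhibition (Haldane) law v = Vmax·B/(Km + B + B²/Ki), with
  `Vmax` in mM/h and `Km`, `Ki` in mM. The flux is unimodal in B with its
  maximum at √(Km·Ki) and decays like Vmax·Ki/B at high B.
* `DKO_FADB_INHIB` — the inhibition model with the slower FadB inflow
  constant `Kb1`.

All concentrations are carried in mM. The stoichiometry of the lumped
glucose → butyryl-CoA step is 1:1 as written in the model equations; the
rate constants absorb the true stoichiometric and yield factors. The default
initial state converts 40 g/L glucose with the shipped molar-mass table
(180.16 g/mol → 222.02 mM) so that conservation is checkable in a single
unit. PduP's literature Km of 0.87 µM is stored as 8.7×10⁻⁴ mM; all rate
laws operate in mM.

### A documented inconsistency in the saturation example

The source analysis states that the PduP rate reaches 98% of Vmax "when the
concentration of butyryl-CoA reaches 4.35 mM", while 98% saturation under
V/Vmax = S/(Km+S) corresponds to S = 50·Km = 43.5 µM; 4.35 mM is 5000·Km and
gives 99.98%. The package implements only the general formula
(`saturation_fraction()`) and does not guess which number was intended; the
50·Km → 98.04% reading is the one used in the acceptance checks.

## Numerical integration

No general-purpose ODE solver package is assumed; the integrators live in
compiled code:

* **Dormand–Prince 5(4)** (adaptive explicit Runge–Kutta, FSAL) for the
  linear variants, with defaults rtol = 10⁻⁸ and atol = 10⁻¹⁰ mM.
* **A two-stage L-stable Rosenbrock scheme** (order 2, γ = 1 − 1/√2) for
  the substrate-inhibition variants. Their Jacobian has a single fast mode
  with slope ≈ Vmax/Km ≈ 10⁴ h⁻¹ whenever butyryl-CoA sits far below Km —
  for the FadB regime that is essentially the whole 96 h horizon — which
  stability-limits explicit methods to ~10⁵ steps. The system's Jacobian is
  lower triangular, so each Rosenbrock stage solves by forward
  substitution; the order conditions and the L-stability root
  γ² − 2γ + ½ = 0 were verified analytically during development, and the
  two integrators cross-validate each other to better than 10⁻⁶ relative in
  the test suite.

Tiny negative concentrations produced within tolerance (≤ 10⁻⁶ mM by
default) are clamped to zero; anything larger is an error, as is exhausting
the step budget (reported with the last good time). Both schemes preserve
linear invariants exactly, so total concentration is conserved to roundoff.

The linear (`DKO_PHABJ`) chain admits the exact Bateman solution
(`analytic_linear_chain()`), kept deliberately independent of the
integrator as an oracle; the degenerate equal-rates form is not implemented
and near-collisions (relative separation below 10⁻⁹) raise an error rather
than silently losing precision.

### Cumulative butyryl-CoA flux

`cumulative_flux()` returns the running integrals of butyryl-CoA production
(k·glucose) and consumption (PduP step plus drain). An early design used
trapezoidal quadrature on a 0.1 h grid; measurement showed that the
inhibition variants' outflow has a sub-minute initial boundary layer that
fixed-grid quadrature cannot resolve (errors up to 0.5 mM), so the
integrals are instead carried as auxiliary ODE states under the same error
control as the trajectory. The identity production − consumption = B(t)
then holds to roundoff, and the production integral is independently
checked against its closed form G₀(1 − e^(−kt)) in the tests. Because
"cumulative amount of butyryl-CoA" is ambiguous between the production
integral and the time integral of the pool, both are exposed
(`cumulative_flux()`, `butyryl_coa_exposure()`), and `percent_change()`
computes knockout-versus-parent comparisons under either reading.

## Fitting and model selection

`compute_rss()` integrates a variant and sums squared residuals at the
observation times; `aic()` implements AIC = n·ln(RSS/n) + 2k with no
small-sample correction, returning −∞ with a warning at RSS = 0 (possible
on noiseless synthetic data; such entries are dropped from comparisons).
The reported fits' n and k were never stated alongside the printed RSS/AIC
pairs; `infer_n_k()` recovers them by exhaustive integer search — (5, 1)
and (5, 2) are the unique solutions in n ∈ 3..10, k ∈ 0..5 — which fixes
the default observation grid at {0, 24, 48, 72, 96} h: the stated "24 to
96 h" points plus the t = 0 anchor. This is an inference, not a stated
fact.

`fit_params()` minimises the RSS over the free parameters with a bounded
derivative-free search on log-transformed values: Brent line search over
the full log-interval for one free parameter, otherwise Nelder–Mead
restarted from 8 seeded log-uniform draws with a final polish, upper bounds
enforced by a smooth penalty. Bounds default to [0, 10³] in each
parameter's unit (none are stated in the source analysis). Identical seeds
give bit-identical results. Integration failures at extreme restart draws
map to a large finite objective value so the simplex retreats rather than
aborts.

`staged_fit_protocol()` reproduces the staged fixing scheme: (1) fit the
parental model to butyrate + 2,3-HDO jointly (residuals weighted equally in
mM²; the source is silent on weighting and on whether the fit was joint or
sequential); (2) fix `Ka1`, `Ka3` and fit `Km2` to the knockout data;
(3) fix `Km` at 8.7×10⁻⁴ mM and fit `Vmax`, `Ki` of the inhibition model to
the same data, comparing stages 2 and 3 by AIC; (4) fix everything from
stage 3 and fit `Kb1` to the FadB data. Stage 3's free set {Vmax, Ki} with
Km fixed is the only reading consistent with both the k = 2 recovered from
the printed AIC and the fitted Km equalling the literature PduP value; the
free mask remains configurable. Comparisons whose runner-up sits within
ΔAIC < 2 are flagged inconclusive, per standard information-criterion
practice (the source uses plain min-AIC).

## The synthetic world

The fitted time courses exist only as figures and an unavailable
supplementary file, so `synthetic_data` generates datasets with known
ground truth. The stated world:

* observation grid {0, 24, 48, 72, 96} h;
* proportional Gaussian noise, cv = 0.05 with a 0.2 mM floor, truncated at
  zero — a typical spread for triplicate shake-flask measurements; the
  source states no noise model, so this is a declared assumption;
* fixture magnitudes echoing the measured order of magnitude without
  claiming to reproduce them: the knockout PhaB-PhaJ curve plateaus near
  25 mM at 96 h, the FadB curve rises steadily to ≈ 30 mM, and the parental
  strain reaches ≈ 24.9 mM 2,3-HDO with ≈ 30.5 mM butyrate.

The frozen fixture constants were calibrated once, by root-finding on the
noiseless model curves against those magnitudes, before any acceptance
outcome was observed, and are not revisited: shared `Ka1` = 0.05 h⁻¹ and
`Ka3` = 0.1 h⁻¹; parental `Km1` = 1.95×10⁻³, `Ka2` = 2.12×10⁻³ h⁻¹
(leaving a large accumulating butyryl-CoA pool, consistent with the
toxic-accumulation interpretation); inhibition truth `Vmax` = 9.54 mM/h
with the literature `Km` = 8.7×10⁻⁴ mM and fitted-value `Ki` = 2.6 mM;
FadB `Kb1` = 1.69×10⁻³ h⁻¹; and a linear-truth alternative
(`Km2` = 1.81×10⁻³ h⁻¹) for model-selection specificity checks.

What a green test does and does not establish: the generator draws from the
same model family the fits assume, with independent Gaussian noise. Real
fermentation data add replicate correlation, systematic calibration error,
volatilisation losses and model misspecification; recovery and selection
results here validate the *machinery*, not the biological conclusions. In
particular the source's fitted constants and its 61.4% cumulative
butyryl-CoA increase are not reproducible from the package (their inputs
are not machine-readable) and are deliberately not asserted anywhere. In
the synthetic world the parental and knockout fixtures share `Ka1`, so
their cumulative *production* integrals coincide; the knockout-versus-
parent contrast there shows up in the consumption split and the pool
exposure instead.

## Fermentation metrics

`ferm_metrics` reproduces every paired titer/yield/productivity report from
its stated inputs through a single molar-mass table (standard atomic
weights, two decimals). 152.2 mM × 118.17 g/mol gives 17.99 g/L against the
printed 17.98 — a 0.05% discrepancy attributable to molar-mass truncation
on the reporting side — so paired values are checked at 0.5% relative
rather than reverse-engineering the original constant. The yield
denominator (glucose consumed for bioreactor runs, initial medium glucose
for shake flasks) is always passed explicitly.

## Known limitations

* The four variants lump multi-enzyme segments into single reactions;
  the constants have no direct enzymological interpretation.
* No compartmentalisation, biomass coupling, or by-product routes beyond
  butyrate; the pentane-2,3-diol pathway has no ODE model (none is given).
* Stage-1 parameters other than `Ka1` are weakly identified from two
  product curves alone; the staged protocol propagates stage-1 estimates,
  and compensated biases (e.g. between `Vmax` and `Ki`, or between a
  biased `Vmax` and stage-4's `Kb1`) are expected at 5% noise.
* `Km` far below the data's concentration range is structurally
  near-unidentifiable; `recovery_experiment()` flags this case.
* AIC comparisons use the least-squares form without small-sample
  correction, mirroring the analysis being reproduced; with n = 5 an AICc
  would penalise the extra parameter much harder.
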