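---
title: "Modeling cytosolic copper homeostasis in budding yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cytosolic copper homeostasis in budding yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuflux)
```

## The model

`cuflux` models the cytosolic copper economy of exponentially growing
*Saccharomyces cerevisiae* as a 10-component, 25-reaction reaction network:

* apo and holo forms of the deficiency-sensing transcription factor
  (`aMAC`/`MAC`), the excess-sensing factor (`aACE`/`ACE`), the
  metallothionein (`aCUP`/`CUP`) and an aggregate pool of all other copper
  proteins (`aOTH`/`OTH`);
* the plasma-membrane importer (`CTR`);
* the labile, exchangeable cytosolic pool (`CU`).

Reactions fall into six classes: constant biosynthesis of the apo proteins,
catalyzed biosynthesis (metallothionein expression driven by holo-ACE,
importer expression driven by apo-MAC), two saturable import routes,
metalation/demetalation of the four protein pairs, and first-order growth
dilution of every component at α = 0.0033 min⁻¹ (210-minute doubling time).
Concentrations are μM, time is minutes. Copper bookkeeping assigns 4 Cu to
each holo transcription factor, 8 to the metallothionein, 1 to each
other-protein and to the labile pool.

```{r network}
net <- build_canonical_network()
net
table(net$reactions$class)
```

Two copper variables must not be confused. `COPPER` is the *effective
nutrient copper* seen by the import machinery — the medium concentration plus
a fixed offset that accounts for trace copper present even in unsupplemented
or chelator-treated medium. The seven study conditions (`MBCS` with a
membrane-impermeable chelator, and media supplemented with 0–250 μM copper)
map to effective `COPPER` of 1.2, 4, 14, 54, 104, 179 and 254 μM. `CU` is the
cytosolic labile pool, which homeostasis holds within roughly a factor of
four (0.27–1.2 μM) across that 200-fold nutrient range.

### Rate laws

Every reaction rate is written relative to the reference condition (`M10`):
a rate constant times dimensionless factors — substrate and catalyst
concentrations divided by their reference values, Michaelis saturation
`COPPER/(Km + COPPER)` for the two importers (Km = 2 and 35 μM), power-law
cooperativity in the labile pool for the metalations (exponents 0.62, 0.90,
1.1 and 1 for MAC, ACE, CUP, OTH — the Hill coefficients of the respective
titration curves), and a logistic ("soft Heaviside") factor
`1/(1 + exp(n_sens (Sen_sp − Sen)))` for the four reactions under
expression-level regulation.

## Stage 1: titration fits and axis recalibration

The transcription-factor metalation curves are characterized by a Hill
coefficient and a half-saturation point. A useful identity: a curve running
from 10% to 90% saturation over a concentration ratio *r* has
n = log 81 / log *r*; the MAC curve spans (2.8 nM, 3.1 μM) on the free-ion
activity axis, giving the strikingly sub-cooperative n ≈ 0.62 despite the
factor binding four coppers.

```{r hill}
hill_from_dynamic_range(3.1e-6, 2.8e-9)
kd_from_half_saturation(9.7e-20, 0.62)   # M^0.62 units
```

Free-ion activities are far below one atom per cell and are therefore
thermodynamic bookkeeping, not populations. The axis is recalibrated to the
cellular labile-pool scale by matching the reference condition's labile pool
(0.59 μM) to its free-ion activity (6.1e-19 M); the shape (Hill coefficient)
of each curve is invariant under this rescaling.

```{r recal}
anchor <- calibration_anchor()
signif(anchor$factor, 2)
default_hill_fits()$MAC
```

## Stage 2: per-condition concentrations

Measured quantities per condition are the copper content of three groups —
metallothionein-bound (8 Cu each), other-protein-bound (1 Cu each) and labile
— plus fractional occupancies for the CUP and OTH pools. Totals follow from
`total = holo + holo (1 − occ)/occ`:

```{r groups}
protein_from_copper(2.8, 8, 0.30)   # metallothionein at M10
protein_from_copper(0.67, 1, 0.30)  # other proteins at M10
```

The transcription factors are partitioned apo/holo by their recalibrated
titration curves; their totals are fixed by two anchors (apo-MAC = 0.37 μM at
the reference, and total cellular copper 5.5 μM at the chelated condition,
which calibrates the ACE total). Importer concentration follows apo-MAC with
the fixed ratio 0.29/0.37 ≈ 0.79, reflecting its MAC-driven expression.

The occupancy trajectories deserve a note: CUP occupancy rises from 0.10 at
`MBCS` to 0.67 at `M250` (the metallothionein both accumulates and fills),
while OTH occupancy is tied to the labile pool so that the other-protein pool
stays near its physiological loading. These fixture values interpolate the
printed anchors monotonically; they are inputs to, not outputs of, the
pipeline.

```{r conds}
conds <- assemble_condition_table()
conds[, c("condition", "copper", "CUP", "occ_cup", "OTH", "CU",
          "total_cell_cu")]
```

A magnitude check that free-ion activities cannot be populations, and that
μM-scale pools are comfortably so (cell volume 42 fL):

```{r atoms}
atoms_per_cell(1e-6)    # 1 uM  -> ~25,000 atoms
1 / atoms_per_cell(1e-18)  # 1e-18 M -> one atom per ~40 million cells
```

## Stage 3: steady-state fluxes from the pathway basis

At steady state the flux vector lies in the null space of the 10 × 25
stoichiometric matrix, which has nullity 15. The null space is re-expressed
as 15 *nonnegative* basic pathways — physically realizable routes from
synthesis/import to dilution — and the 15 independent fluxes are chosen as
the 10 dilutions, the 4 demetalations and the second import route. Dilution
fluxes follow directly from concentrations (α C); demetalation runs 100-fold
faster than holo dilution (metal exchange fast relative to growth); the first
importer's constant is set at the chelated anchor condition where the second
importer is off.

```{r pathways}
S <- stoichiometric_matrix(net)
ncol(S) - matrix_rank(S)
ref <- reference_from_conditions(conds)
rates <- steady_state_rate_table(conds, net, ref)
head(rates)
```

(The `MBCS`/`M0` conditions sit exactly at the all-first-importer anchor, so
the solved second-importer flux there is a floored zero; the pipeline warns
when flooring exceeds round-off.)

## Stage 4: apparent constants and logistic regulation

Dividing each condition's flux by its rate-law factors yields an apparent
rate constant per reaction per condition. Twenty-one reactions have
condition-invariant constants — for the exponent-matched metalations this is
an algebraic identity, machine-exact in practice — while four (`BACUP`,
`MCUPF`, `MOTHF`, `CUIN2`) trend systematically with copper and are assigned
logistic regulation in their sensed species (the labile pool for the first
three, nutrient `COPPER` for the second importer).

Classification uses two statistics over the seven-condition series: the
*spread* (max/min − 1 over positive entries, threshold 0.5) and the *maximum
drawdown* relative to the series range (threshold 0.25), which accepts
monotone-up-to-noise series without accepting systematically decreasing ones.

```{r calib}
kt <- apparent_rate_constants(rates, conds, net, ref)
cls <- classify_invariance(kt)
table(cls$class)
params <- consolidate_constants(cls, conds)
params$logistic$MCUPF
```

The logistic fit is a bounded Levenberg–Marquardt least-squares problem with
20 seeded multistarts. The plateau constant is bounded below by the largest
observed apparent constant (the logistic factor is < 1) and above by 20× it,
which keeps the search off the ridge where plateau and setpoint trade off
when no observation approaches saturation.

## Stage 5: dynamics

`cu_system()` assembles network, parameters and reference into an ODE system;
`integrate_system()` uses `deSolve::lsoda` with rtol 1e-8 / atol 1e-12 (the
100× demetalation makes the system stiff). Experiment definitions:

* **Anneal** (`anneal()`, `steady_state()`): integrate to t = 20,000 min,
  then polish with damped Newton iterations to residual < 1e-9 μM/min; warns
  if the polished state moved more than 2× from the integrated endpoint.
* **Recovery** (`perturb_component()`): after an instantaneous scaling of one
  component, the system has *recovered* at the first time all components stay
  within 1% of the pre-perturbation state for a sustained 50 min. Doubling
  the labile pool at the reference condition recovers in ≈ 700 min — several
  doubling times, because excess copper must be diluted through the slowly
  responding buffering pools.
* **Adjustment** (`step_nutrient()`): after a step in nutrient `COPPER`, each
  component's *adjustment time* is the first time it stays within 5% of the
  new steady state for 50 min. Stepping the reference condition to the
  highest condition, the metallothionein is the slowest pool (> 700 min).
* **Homeostatic slope** (`sweep_nutrient()`, `homeostatic_slope()`): the
  regression slope of the labile pool against nutrient copper over the 10–50
  μM window, in nM per μM. Knocking out the second importer (`knockout()`)
  both caps total cellular copper (≈ 10 vs ≈ 26 μM at the highest condition)
  and flattens this slope — the mutant is *more* homeostatic because the
  remaining importer saturates early.

```{r dynamics, eval = FALSE}
sys <- cu_system(net, params, ref, copper = 14)
ss <- anneal(sys, ref$concentrations)
p <- perturb_component(sys, ss$state, "CU", factor = 2)
p$recovery_time
plot_trajectory(p$trajectory, components = c("CU", "CUP"))
```

## Stage 6: synthetic ground truth

`generate_ground_truth()` draws a model instance within ±30% (log-uniform) of
the study-calibrated template and *derives* its rate constants so that the
drawn reference state is an exact fixed point; the construction further
guarantees that every fixed point of the drawn system lies on an exact
effective titration curve for the transcription factors, so the estimation
pipeline's curve-based partition inverts the truth exactly. The other six
conditions are solved by continuation. Draws are rejected (and resampled)
when the labile pool fails to increase with nutrient copper, any state is
non-positive, the second importer is not negligible at the chelated anchor,
or a logistic setpoint falls outside the window its sensed species actually
traverses — in that last case the emitted data would carry no setpoint
information and the recovery benchmark would be meaningless.

`emit_titration()` converts the truth's states into the measurement schema of
Stage 2, optionally with multiplicative lognormal noise (ICP-MS-like
proportional error); `run_estimation_pipeline()` chains Stages 2–4; and
`parameter_recovery_report()` scores recovery: at zero noise the invariant
constants round-trip to < 1e-6 relative and the trending set is identified
exactly; at 5% noise the median setpoint errors across seeds stay within 25%.

```{r synthetic, eval = FALSE}
truth <- generate_ground_truth(1)
parameter_recovery_report(truth, noise_cv = 0.05, seeds = 1:25)
```

The generator's scope is deliberately narrow: it validates the estimation
pipeline, not biology. It does not model instrument drift, chromatographic
artifacts, or biological replicate structure.

## Numerical choices, in one place

* Stiff integration: `lsoda`, rtol 1e-8, atol 1e-12; states clipped at 0.
* Steady states: integration bracket then damped Newton, tolerance 1e-9
  μM/min (1e-10 for ground-truth states).
* Jacobians: central finite differences, step 1e-6 relative.
* Logistic fits: `minpack.lm::nls.lm` on *relative* residuals (the matched
  objective for multiplicative measurement error, with a weight floor so
  structurally zero observations still penalize models predicting flux
  there), 20 seeded multistarts, maxiter 500, maxfev 5000, ftol 1e-12;
  converged fits preferred, best non-converged kept as a flagged fallback.
* Nonnegative pathway basis: row-reduction sweeps over several orderings,
  columns normalized to unit maximum; verified in tests against an
  independent double-description extreme-ray enumeration.
* All stochastic steps (jitter, noise, multistarts) save and restore the
  global RNG state and are deterministic given their seed.

## Limitations

* The aggregate other-protein pool hides heterogeneous kinetics behind one
  exponent and one occupancy trajectory.
* Logistic regulation is a surrogate for unmeasured expression dynamics; its
  sensitivity parameter is only weakly identified when the titration samples
  few points on the switch flank (the setpoint is pinned by any half-engaged
  condition, but steepness is not).
* The effective-COPPER offsets and the occupancy trajectories between printed
  anchors are fixture interpolations, not measurements.
* Steady-state flux inference assumes balanced exponential growth; transients
  in the underlying experiments are not modeled at the inference stage.
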