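# cuflux

Kinetic modeling of cytosolic copper homeostasis in budding yeast
(*Saccharomyces cerevisiae*).

## The scientific problem

Copper is both essential and toxic: cells must load cuproproteins while keeping
the exchangeable ("labile") cytosolic pool in the low-micromolar range across
orders-of-magnitude changes in nutrient supply. In yeast this balance is
maintained by a small regulatory circuit: the Mac1 transcription factor senses
copper deficiency and drives expression of the Ctr importers, the Ace1 factor
senses excess and drives expression of the Cup1 metallothionein, and the bulk
of cellular copper resides in a collective pool of other cuproproteins.

`cuflux` implements a complete, reproducible pipeline from published
measurements to a calibrated ordinary-differential-equation model of this
circuit:

1. **Titration analysis** — fit Hill cooperativity to transcription-factor
   metalation curves and recalibrate their ligand axis from free-ion activity
   to the cellular labile-pool scale.
2. **Condition estimation** — convert measured per-group copper concentrations
   (metallothionein-bound, other-protein-bound, labile) into apo and holo
   protein concentrations across a seven-condition nutrient-copper titration
   (`MBCS`, `M0`, `M10`, `M50`, `M100`, `M175`, `M250`).
3. **Pathway analysis** — decompose the null space of the 10-component,
   25-reaction stoichiometric matrix into nonnegative basic pathways and solve
   the steady-state flux of every reaction at every condition.
4. **Rate calibration** — back-calculate apparent rate constants, classify
   them as condition-invariant or trending, and fit a logistic (soft
   Heaviside) regulation law to the trending ones.
5. **Dynamics** — integrate the assembled stiff system: annealing to steady
   state, perturbation/recovery, nutrient-step, importer-knockout and
   nutrient-sweep experiments.
6. **Synthetic data** — generate titration datasets with known ground truth
   and score end-to-end parameter recovery.

The network couples ten components — apo/holo Mac1 (`aMAC`/`MAC`), apo/holo
Ace1 (`aACE`/`ACE`), apo/holo metallothionein (`aCUP`/`CUP`), an aggregate
apo/holo pool of other copper proteins (`aOTH`/`OTH`), the importer (`CTR`)
and the labile pool (`CU`) — through 25 reactions: biosynthesis, metalation,
demetalation, two import routes and first-order growth dilution of every
component.

## Worked example

From published anchors to a calibrated dynamical model:

```r
library(cuflux)

# 1. Transcription-factor titration fits (labile-pool axis, uM)
fits <- default_hill_fits()
fits$MAC
#> <cu_hill_fit> n = 0.62, [CU]_0.5 = 0.09382, Kd = 0.2306

# 2. Apo/holo concentrations across the nutrient-copper titration
conds <- assemble_condition_table()
conds[, c("condition", "copper", "aMAC", "MAC", "aCUP", "CUP", "CU",
          "total_cell_cu")]
#> # A tibble: 7 x 8
#>   condition copper  aMAC   MAC  aCUP    CUP    CU total_cell_cu
#>   <chr>      <dbl> <dbl> <dbl> <dbl>  <dbl> <dbl>         <dbl>
#> 1 MBCS         1.2 0.522  1.01 0.394 0.0438  0.27          5.5
#> 2 M0           4   0.407  1.12 0.675 0.153   0.48          7.58
#> 3 M10         14   0.37   1.16 0.817 0.35    0.59          9.70
#> 4 M50         54   0.320  1.21 0.917 0.75    0.8          13.8
#> 5 M100       104   0.294  1.23 1.02  1.25    0.95         18.4
#> 6 M175       179   0.273  1.25 1.11  1.81    1.1          23.5
#> 7 M250       254   0.261  1.27 1.11  2.25    1.2          27.3

# 3-4. Steady-state fluxes, apparent constants, invariance classification
net <- build_canonical_network()
ref <- reference_from_conditions(conds)
rates <- steady_state_rate_table(conds, net, ref)
kt <- apparent_rate_constants(rates, conds, net, ref)
params <- consolidate_constants(classify_invariance(kt), conds)
params
#> <cu_params> 21 invariant constants, 4 logistic reactions
#>   (BACUP, CUIN2, MCUPF, MOTHF)
params$logistic$MCUPF
#> <cu_logistic> k_inv = 0.4094, setpoint = 1.001 uM (CU), n = 2.354 /uM

# 5. Dynamics: anneal the reference condition, then double the labile pool
sys <- cu_system(net, params, ref, copper = 14)
ss <- anneal(sys, reference_from_conditions(conds)$concentrations)
ss
#> <cu_steady_state> residual = 1.61e-12 uM/min (converged)
#>    aMAC     MAC    aACE     ACE    aCUP     CUP    aOTH     OTH     CTR      CU
#> 0.36740 1.15953 0.99795 0.25664 0.79716 0.34098 1.53860 0.69473 0.29025 0.59891

p <- perturb_component(sys, ss$state, "CU", factor = 2)
c(p$returned, round(p$recovery_time))
#> returned: TRUE   recovery time: 701 min
```

Trajectories, nutrient sweeps, titration curves and apparent-constant profiles
all have `autoplot()`/`plot_*()` methods; fits and steady states have
`tidy()`/`glance()` methods.

## Units and conventions

Concentrations are μM, time is minutes, the growth rate is
α = 0.0033 min⁻¹ (210-min doubling). Copper bookkeeping weights are 4 Cu per
transcription-factor holo form, 8 per metallothionein, 1 per other-protein and
labile copper. `COPPER` denotes the effective nutrient copper seen by the
import machinery; `CU` the cytosolic labile pool.
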