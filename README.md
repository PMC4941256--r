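# cytokinetics

Age- and generation-structured simulation of proliferating cancer-cell
populations under drug treatment, with joint fitting of flow-cytometry and
time-lapse time courses, sequential two-drug combination analysis, and
Loewe-additivity isobolograms.

## The problem

Anticancer drugs perturb the cell cycle in ways a single growth-inhibition
number cannot resolve: cells may be *delayed* in a phase, *arrested* at a
checkpoint (and later released), or *killed*, and each effect can differ
between cells that have not yet divided since treatment start (generation 0)
and their descendants (generation 1, 2, ...). Flow cytometry (FC) measures
the percentage of cells in G1, S and G2M; time-lapse microscopy (TL) counts
live cells per division generation; a Coulter counter gives absolute cell
numbers. None of these streams alone identifies the underlying kinetics —
but a population model fitted jointly to all of them can decompose the
response into cytostatic (delay, block) and cytotoxic (death-rate)
components per phase and generation. The package is aimed at
quantitative-pharmacology and systems-biology groups analysing such
time-resolved cell-cycle perturbation experiments, e.g. for EGFR-inhibitor /
antimetabolite scheduling in pancreatic cancer cell lines.

## The model

Cells transit G1 → S → G2M and divide. The transit time of phase *p* is
gamma-distributed with mean *T̄ₚ* and coefficient of variation *CVₚ*. The
population is described by densities *n(t, a; p, g)* of cells with age *a*
in phase *p* and generation *g*, evolved by discrete-time transport: each
step a cohort ages by *v·Δt* and leaves its phase with the conditional
hazard implied by the gamma survival function. Drug effects are typed
**perturbation modules** acting on a phase, a set of generations and a time
window:

- **delay / synthesis inhibition** — the aging speed is multiplied by
  ∏(1 − dᵢπᵢ(t)); an S-phase delay *d* is identically a fractional
  reduction of the DNA synthesis rate;
- **block** — a fraction *p·π(t)* of each cohort arriving at the phase-exit
  checkpoint is arrested into a blocked pool;
- **recycle** — blocked cells resume at the downstream phase entry with
  first-order rate *r·π(t)*;
- **death** — cells are removed at rate *μ·π(t)* (per hour), with
  commitment windows expressed through step profiles;

where π(t) is a constant, step-window, sigmoid, or recovery (declining
sigmoid) activation profile. Division doubles the G2M exit flux into G1 of
the next generation. At each division the generation index increments;
generations above `maxGeneration` are lumped. A stochastic single-cell
microsimulator implements the same chain cell-by-cell and serves as a
brute-force cross-check of the deterministic engine.

Fitting minimizes an inverse-variance weighted least-squares objective over
the FC (percentage points), TL and count (log cells) streams, with
Latin-hypercube multi-start and Nelder-Mead refinement; uncertainty comes
from a residual bootstrap, and nested models are compared by F test.
Sequential treatments hand the full population state from the first drug's
model to the second's. Factorial SRB dose-response grids are analysed by
constrained 4-parameter-logistic ray fits and the Loewe Combination Index
CI = a/ICx(A) + b/ICx(B).

## Worked example

Simulate a 6 h pulse of gemcitabine (20 nM parameter set, shipped) on an
exponentially growing BxPC-3-like population:

```r
library(cytokinetics)
params <- shippedCellCycleParameters("bxpc3")
growthRate(params, dt = 0.5)$doublingTime
#> 22.66268

gem <- shippedModel("bxpc3_gemcitabine_20nM")
tr  <- simulatePopulation(params, list(gem), shippedSchedule("gemcitabine"),
                          simulationGrid(dt = 0.5, horizon = 96))
subset(tr@observables, time_h %in% c(0, 24, 48, 96),
       select = c(time_h, pct_G1, pct_S, pct_G2M, n_total))
#>  time_h pct_G1 pct_S pct_G2M n_total
#>       0  49.05 33.58   17.36    1000
#>      24  16.15 60.46   23.39    1327
#>      48  23.53 38.51   37.95    2692
#>      96  46.74 24.20   29.06   12415
```

The untreated population doubles every 22.7 h with a stationary
49/34/17 phase split. After the pulse, DNA synthesis is inhibited by 88%
and recovers with half-maximum at 18 h: by 24 h a semi-synchronized wave
has accumulated in S phase (60.5% vs 33.6% untreated), then progresses
through G2M and dissipates; by 96 h the treated culture has reached 12 415
cells against 18 844 untreated (34% growth inhibition). The same engine
drives synthetic-data generation (`generateDataset`), joint fitting
(`fitModel`, `uncertaintyIntervals`, `compareModels`), sequential
combinations (`simulateSequential`, `refitInteraction`) and isobologram
analysis (`generateSrbGrid`, `isoboleAnalysis`). A thin command-line
front-end is available via `runCli()` or `inst/cli/cytokinetics`.

See the methods vignette (`vignettes/cell-cycle-drug-response.Rmd`) for
the model assumptions, parameter semantics, numerical choices and
limitations.

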