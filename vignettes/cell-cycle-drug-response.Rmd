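---
title: "Decomposing cytostatic and cytotoxic drug effects with an age-structured cell-cycle model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing cytostatic and cytotoxic drug effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytokinetics)
```

## The population model

The package simulates a proliferating cell population as cohorts flowing
through G1, S and G2M and dividing. Two ingredients define the unperturbed
kinetics:

* **Phase transit-time law.** The time a cell spends in phase $p$ is a
  random variable $\tau_p \sim \Gamma(\bar T_p, CV_p)$, parameterized by
  its mean (hours) and coefficient of variation. The gamma family was
  chosen because it has strictly positive support, is closed under the
  (mean, CV) parameterization the field reports, and yields a closed-form
  survival function from which the engine derives per-age-bin exit
  hazards. Within the CV range of real cell lines (0.1–0.3) the fitted
  observables are insensitive to the exact family.
* **Generation structure.** Cells carry the number of divisions since
  treatment start. Generations $0..G$ (default $G = 5$) are explicit;
  divisions at $G$ re-enter $G$ (a self-renewing lump), adequate for
  horizons of about four generations.

The deterministic engine discretizes age in bins equal to the time step
(`SimulationGrid`, default $\Delta t = 0.5$ h). Each step, the cohort in
age bin $a$ of compartment $(p, g)$:

1. dies with probability $1 - e^{-\mu\Delta t}$ if a death module targets
   the compartment (blocked cells die at the same rate);
2. ages by $v\,\Delta t$, where $v = \prod_i (1 - d_i \pi_i(t)) \le 1$ is
   the composed slow-down of the active delay/synthesis-inhibition
   modules, and exits the phase with the conditional probability
   $1 - S_p(a + v\Delta t)/S_p(a)$ given by the gamma survival $S_p$;
3. is split at the checkpoint: a fraction $b\,\pi(t)$ of the exit flux
   enters the blocked pool, the rest moves to age 0 of the next phase;
   blocked pools drain at their recycling rate into the downstream phase
   (G1-arrested cells resume at S entry; G2M-arrested cells divide);
4. doubles on G2M exit and enters G1 of generation $g+1$.

This scheme is *exactly* the mean field of the single-cell chain
implemented by `microsimulate()`: a microsimulated cell draws
$\tau_p$, advances its phase age by $v\,\Delta t$ per step, crosses when
the age reaches $\tau_p$, and faces the same Bernoulli block, death and
recycling probabilities. The test suite exploits this: deterministic and
stochastic runs must agree within Monte-Carlo error on randomized
configurations, which certifies the transport discretization without
reference to any external discretization of the continuity equations.

**Initial condition.** Experiments start from exponentially growing
cultures, so `steadyStateInit()` computes the balanced-growth age/phase
distribution of the *discrete* chain: the per-step discount $z$ solves
$2\,G_{G1}(z)G_{S}(z)G_{G2M}(z) = 1$, with $G_p$ the generating function of
the number of steps spent in phase $p$; stationary bin densities are
$f_p z^i S_p(a_i)$. Because the eigenproblem is solved for the same
discretization the engine uses, an untreated simulation grows exponentially
from $t = 0$ to machine precision — there is no numerical transient, and
the doubling time reported with the trajectory is exact for the chain.

**Numerical behaviour.** The scheme is unconditionally positive and
conservative (checkpoint splits, recycling and divisions conserve or
exactly double flux). Its only bias is temporal quantization: a phase
transit costs $\lceil \tau/\Delta t\rceil$ steps, so each phase is credited
on average half a bin extra; at $\Delta t = 0.5$ h the doubling time of a
22 h cycle is overestimated by roughly 0.4 h. Because synthetic data are
generated and fitted on the same grid this bias cancels in all estimation
workflows; it only matters when comparing against continuous-time
analytics, and shrinks linearly with $\Delta t$.

## The perturbation grammar

A drug model is a list of typed modules, each with a phase, a set of
generations (0-based; empty = all), a magnitude and a time profile:

| effect | magnitude | semantics |
|---|---|---|
| `delay` | fraction in [0,1] | multiplies aging speed by $1-d\pi(t)$ |
| `synthesis_inhibition` | fraction | same mechanics; named for S phase, where transit speed *is* the DNA synthesis rate |
| `block` | probability | per-cohort arrest at the phase-exit checkpoint |
| `recycle` | rate (1/h) | first-order release of a blocked pool |
| `death` | rate (1/h) | removal to a cumulative dead count |

Delay is interpreted as a *fractional slow-down of transit speed* rather
than as a fraction of cells delayed: the two readings are
indistinguishable in FC percentages but the speed reading matches the
known biochemistry of S phase (a 0.88 S delay equals an 88% reduction of
the DNA synthesis rate) and composes naturally — simultaneous delays
multiply on speed.

Profiles take values in $[0,1]$: `constant`, `step_window`
($[on, off)$), `sigmoid` (logistic rise; the default steepness 1.366 h
makes the 10%→90% rise span 6 h, a shape choice — only half-maximum times
are constrained by data), and `recovery` (logistic decline from 1 to a
`floor`, used for the gradual release of DNA-synthesis inhibition, with
half-maximum at 18 h in the shipped gemcitabine sets; residual long-term
delays are encoded as separate step modules so each generation can keep
its own plateau). Module clocks are anchored to the drug's exposure
interval: `during` and `all` modules count time from drug start, `post`
modules from washout, so the same YAML file is valid in single-drug and
sequential schedules. At washout, `during` modules switch off and `post`
modules switch on instantaneously.

Dead cells leave the live pool immediately and are excluded from all three
observables (FC debris gating assumed); blocked cells count in their phase
of arrest and in their generation's TL count. Death rates apply to both
in-transit and blocked cells of the targeted compartments, since arrested
cells are among those reported dying.

## The synthetic-data generator

`generateDataset()` emulates the replicate structure of the motivating
experiments: three independent FC experiments, five TL wells, triplicate
absolute counts; FC sampled every 24 h and TL every 6 h over 0–96 h by
default. Noise defaults (`noiseModel()`: 2.5 percentage points additive on
FC, renormalized to 100; lognormal CV 0.08 on TL counts, 0.05 on absolute
counts, 0.07 on SRB survival fractions) are nominal values chosen once to
match the scatter of published replicate error bars. The generator does
*not* emulate DNA-histogram deconvolution error structure, lineage-tracking
mistakes, well-to-well growth heterogeneity, or correlated noise across
generations within a well — so passing recovery tests demonstrate
identifiability under idealized replicate noise, not robustness to those
real-data pathologies.

The unperturbed cycling parameters shipped for the two cell lines
(`shippedCellCycleParameters`) are documented nominal values
($T_c \approx 22$ h BxPC-3-like, 26 h Capan-1-like); the published
originals are not printed in the available text. Model files whose
magnitudes are likewise nominal carry the `_nominal` suffix; all other
shipped magnitudes are the published best-fit values.

## Fitting

The objective is a weighted sum of squared residuals across streams: FC in
percentage points, TL and counts on $\log(\text{cells}+1)$ (which makes
the objective invariant to count rescaling), each residual divided by its
standard error. Two weighting modes exist:

* `replicate` (default): each observation weighted by its own replicate
  SD — the natural choice for estimation;
* `pooled`: every observation of a stream weighted by the stream's RMS SD.
  Per-point SDs estimated from 3–5 replicates are noisy; they make
  standardized residuals heavy-tailed and inflate the size of the
  nested-model F test (empirically to ~0.2 at nominal 0.05). Pooling
  restores homoscedastic Gaussian residuals per stream, and the F test
  then holds its size. Model-comparison workflows should use it.

A `minCount` detection floor drops TL/count observations whose mean is
below a few cells: a time-lapse field cannot score a generation that holds
no cells, and near-empty log-scale observations carry almost no noise yet
would count toward the residual degrees of freedom.

Optimization is multi-start — Latin-hypercube starts within the declared
bounds plus the model's current values — with Nelder-Mead (Brent for one
parameter) refinement of the best starts on a logit-transformed scale, so
bounds are respected smoothly. Profile *time* parameters (half-max, window
edges) are snapped to a 3 h grid, reflecting that such times are only
reported and identifiable at coarse resolution. Parameters whose modules
are inactive everywhere on the observation window are auto-fixed with a
warning. Uncertainty intervals come from a residual bootstrap (resampling
standardized residuals within streams, refitting locally, percentile
2.5–97.5); this is the package's own choice of uncertainty analysis.
Nested models are compared by an F test on the weighted SSE with
$(\Delta k,\, n - k_{full})$ degrees of freedom at $\alpha = 0.05$,
supporting incremental model building (add a checkpoint module only when
it significantly improves the joint fit).

## Sequential combinations and interaction

`simulateSequential()` runs one continuous simulation: the full population
state — age-binned densities, blocked pools, generation indices — carries
across the second drug's start exactly. During the inter-treatment gap
both drugs' post-treatment modules run concurrently. At the second drug's
start, first-drug modules addressing the same (effect, phase, generation
set) are superseded by default (`policy = "supersede"`); `"error"` raises
on such overlaps and `"compose"` lets them multiply. The exact-key overlap
criterion is deliberate: partial generation overlaps are composed rather
than silently truncated.

`refitInteraction()` frees a chosen subset of the second drug's parameters
against combination data and reports, per parameter, the single-drug value
and interval next to the combination estimate and its bootstrap interval;
a parameter is called *changed* when the two intervals are disjoint —
a conservative mirror of highlighting practice in published model tables.

## Isobologram analysis

Factorial SRB grids are analysed per ray: drug A's dose-response at each
fixed drug-B dose (and vice versa) is fitted with a constrained 4PL
(bottom ≥ 0, top ≤ 1, slope > 0, Levenberg-Marquardt with a bounded
quasi-Newton fallback), inverted in closed form at the target inhibition
(IC30, IC50), and each iso-effective pair $(a, b)$ is scored with the
Loewe Combination Index $a/\mathrm{IC}_x^A + b/\mathrm{IC}_x^B$.
Inversions outside the tested dose range are flagged `extrapolated`;
levels outside a ray's fitted asymptotes are reported unreachable rather
than extrapolated. CI uncertainty is bootstrapped over replicate plates.
`loeweAdditiveSurface()` constructs the exact additive null surface for
two Hill curves with a common slope, used to verify that the pipeline
centres at CI = 1 under additivity.

## Problem sizes used by the test suite

The shipped tests certify the engine against the microsimulator on ten
randomized instances of $5\times2000$ cells at $\Delta t = 0.5$ h over
48 h; parameter-recovery fits use $\Delta t = 1.5$ h, 8 Latin-hypercube
starts and three seeded noise replicates per scenario (a parameter passes
when it falls inside the published bracket in the majority of replicates);
F-test calibration uses 200 null replicates of a reduced TL+count design
at $\Delta t = 2$ h. These sizes are the package's chosen compromise
between Monte-Carlo resolution and a test suite that runs in minutes;
all of them scale up by changing the grid and replicate arguments.

## Known limitations

* No pharmacokinetics: concentration is a label selecting a parameter
  set, not a dynamic variable; no spatial structure, cell-size dynamics
  or molecular state.
* The discrete-time hand-off of exits to the next step makes all
  transitions resolve at $\Delta t$ granularity; choose
  $\Delta t \lesssim$ 1/10 of the shortest phase mean.
* Whether dying S-phase cells linger in the DNA histogram is unresolved
  experimentally; the package removes them instantly, which slightly
  lowers %S under strong cytotoxicity relative to a lingering
  interpretation.
* The per-cell-per-hour reading of published death-rate columns is an
  interpretation; absolute cells/h readings would change only the scale
  of fitted death magnitudes, not the mechanics.
* Time-lapse observables assume field totals of live cells per
  generation, not lineage-restricted counts.
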