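---
title: "Screening bursting neuron models for multistability of rest states and bursting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening bursting neuron models for multistability of rest states and bursting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstscan)
```

## The problem

Conductance-based models of bursting neurons are routinely screened by
brute force: a grid over key parameters (here the leak reversal
potential and seven maximal conductances, the leak conductance
$g_{\mathrm{leak}}$ among them) is simulated case by case and each
trace is classified as silent, tonic spiking, bursting or irregular.
Direct integration only reveals the attractor the chosen initial
condition happens to fall into.  When a stable rest state coexists
with the bursting rhythm, a transient perturbation can silence the
cell permanently — a real concern for pacemaker cells such as the
heartbeat interneurons of the leech, the system this kind of database
screening was developed for.

`burstscan` implements the analysis layer that upgrades such a
database with stationary-state information, organized as five stages:

1. **Settle and classify** (`settle()`, `classifyRegime()`): integrate
   400 s with a stiff implicit Radau IIa method of order 5, discard
   the first 200 s, detect spikes as local maxima of $V$ above
   $-10\,$mV, and apply the inter-spike-interval rules (all ISIs
   $<1\,$s: tonic; any ISI $\ge 1\,$s: bursting statistics; CV of the
   burst period $>5\%$: irregular).
2. **Continue the rest state** (`continueBranch()`): one-parameter
   pseudo-arclength continuation of stationary states in
   $g_{\mathrm{leak}}$, started from the equilibrium reached by direct
   integration at $20\,$nS, with fold (LP) and Andronov–Hopf (AH)
   detection and `hyp`/`dep` labeling of stable intervals (split at
   $-35\,$mV).
3. **Scan the bursting range** (`scanBurstingRange()`): step
   $g_{\mathrm{leak}}$ outward in 1 nS increments, settling each probe
   from the endpoint of the last accepted bursting trajectory, and on
   each transition refine tenfold down to $10^{-4}\,$nS.  The
   carry-over of initial conditions makes the scan track the bursting
   attractor itself through coexistence regions.
4. **Intersect and classify** (`coexistenceRanges()`,
   `classifyScenario()`, `prevalenceOfMultistability()`): overlap the
   stable stationary intervals with the bursting range, map the
   resulting multiset of coexisting-regime sets onto the ten canonical
   arrangements A–J, and measure the prevalence of multistability as
   the covered fraction of the bursting range.
5. **Perturb the half-center oscillator** (`runPerturbation()`):
   couple two cells by reciprocal inhibition, run 100 s, reset one
   cell to a stable rest state while blocking the synapses for 5 s,
   restore them for another 100 s, and decide whether functional
   alternating bursting (both CVs $<5\%$, relative phase in
   $[0.45, 0.55]$) recovers.

`runCase()`/`runCohort()` chain the stages and `resultsStore()`
persists the two tables of the database extension (stationary states;
bifurcation values), keyed by case id.

## Units and tunable parameters

All quantities use mV, nS, nF, nA and seconds.  The defaults encode
the standard protocol:

| parameter | default | where | why |
|---|---|---|---|
| integration tolerances | rel $10^{-9}$, abs $10^{-12}$ | `integrateModel()` | stiff spiking systems; pointwise error well under classifier resolution |
| sampling interval | 1 ms | `integrateModel()` | $\ge 100$ samples per spike at typical widths; classification is insensitive to halving it |
| settling | 400 s, discard 200 s | `settle()` | transients of slow bursters die out within the discarded half |
| spike threshold | $-10$ mV | `detectSpikes()` | separates spikes from subthreshold oscillation in these models |
| burst gap | 1 s | `burstStatistics()` | ISI split between tonic and bursting |
| irregularity bound | CV period $>5\%$ (strict) | `classifyRegime()` | regular-burster criterion |
| robustness bounds | CV period $<5\%$, CV IBI $<10\%$ | `isRobustBurster()` | robust-burster filter |
| continuation steps | max 0.02 nS, min $10^{-12}$ nS, 4000 points | `continueBranch()` | follows branches of tens of nS through folds within the point budget |
| bifurcation localization | $10^{-8}$ nS | `detectBifurcations()` | far below the scanner's $10^{-4}$ nS precision |
| scan refinement | 1 nS start, $10^{-4}$ nS precision | `scanBurstingRange()` | five tenfold levels per direction |
| HCO protocol | 100 + 5 + 100 s | `runPerturbation()` | standard reset-perturbation timing |

## Numerical design

**Integrator.**  The contract is an implicit stiff method of order at
least 5 with dense output; `deSolve::radau` (Radau IIa, order 5) is
used, with compiled right-hand sides for the long settling runs and an
interpreted reference path (the two agree to solver tolerance; this is
tested).  Error behavior is pinned by closed-form problems (pure
decay; a stiff forced linear system) and tolerance monotonicity
checks.

**Continuation.**  The corrector solves the bordered system
$\{f(y,p) = 0,\ t\cdot(u - u_{\mathrm{pred}}) = 0\}$ with Newton
iterations to $\lVert f\rVert < 10^{-10}$; the predictor is the secant
through the last two points, so folds are traversed.  Steps adapt by
halving on failure and growing 1.4-fold after easy successes, clamped
to $[10^{-12}, 0.02]$.  Jacobians are analytic wherever the model can
supply them — the declarative gating structure differentiates in
closed form, as do all surrogate models — with a central
finite-difference fallback (agreement tested to $10^{-5}$ relative).

**Test functions.**  A fold is flagged by a sign change of
$\prod_i \lambda_i$ and a Hopf point by a sign change of
$\prod_{i<j}(\lambda_i + \lambda_j)$, a symmetric function that
survives eigenvalue reordering in higher-dimensional systems.
Crossings are localized by bisection along the curve (midpoint
prediction, correction perpendicular to the local secant) to a
parameter gap below $10^{-8}$ nS.  A Hopf candidate whose crossing
pair has imaginary part below $10^{-4}$ is a neutral saddle and is
discarded.  Coincident candidates are reported individually.

**Branch termination and clipping.**  Continuation runs into negative
parameter values when the curve does (stable depolarized states can
persist past $g_{\mathrm{leak}} = 0$ and fold back); reported stable
intervals are clipped to $[0, \infty)$.  The branch stops at the point
budget, on corrector failure at the minimal step, when the parameter
exceeds 25 nS moving outward, or below a floor of $-5$ nS — wide
enough for the fold-back geometry while keeping monotone branches
finite.  The stable interval containing the branch start is reported
as unbounded above, reflecting the screening assumption that a large
enough leak conductance always yields a stable hyperpolarized rest
state.

**Labeling conventions.**  Stable arcs are numbered along the branch
(`hyp1` contains the start); an arc straddling $-35$ mV is split at
the crossing so the hyp/dep invariant stays exact.  Burst onsets are
first spikes, ends are last spikes, so period = duration + interburst
interval holds identically; the coefficient of variation uses the
sample standard deviation ($n-1$), and a lone period has CV 0 by
convention.  ISIs of exactly 1 s count as burst gaps (the complement
of "smaller than 1 s"); the 5% and 10% CV comparisons are strict.
The relative phase of a half-center oscillator is measured from burst
onsets — the most robust markers — as the mean position of one cell's
onsets within the other's cycles, with the window $[0.45, 0.55]$
inclusive up to a $10^{-9}$ floating-point guard.

**Degenerate inputs.**  Empty spike trains are valid (silent);
a single spike in a 200 s window also classifies as silent; burst
statistics require at least two bursts and raise an
insufficient-cycles error otherwise; zero-width bursting ranges make
the prevalence undefined (error); single-point interval contacts are
excluded from prevalence but reportable as diagnostics
(`keep_points = TRUE`).

**Plateau traces.**  The robust-burster filter must exclude
plateau-like bursting, which the classification literature leaves
undefined.  The operational rule here: a trace that does spike, but
also dwells above the spike threshold continuously for more than 1 s
with at most one detected maximum in that window (a dome crest rather
than a spike cluster), is `plateau_like`.  Spikeless traces are silent
regardless of their potential — a depolarized rest state
(excitability block) is a silent regime.

## The surrogate models

The published kinetics of the eight leech-interneuron currents live in
an external model definition that this package does not reproduce;
the declarative format (`modelSpec()`, `readModelSpec()`) accepts them
as a plug-in configuration, and an explicitly synthetic template with
the right structure ships in
`inst/extdata/leech_hn_synthetic_template.yaml`.  All shipped tests
instead run on surrogate systems with independent ground truth:

- `makeFoldModel()`, `makeHopfModel()`: normal forms with exact LP/AH
  locations and, post-Hopf, a limit cycle of amplitude
  $\sqrt{\mu - \mu_c}$.
- `makeRelaxationModel()`: a FitzHugh–Nagumo-type relaxation
  oscillator whose Hopf point is recomputed by an eigenvalue-scan
  oracle on the root-solved equilibrium.
- `makeMinimalBurster()`: a three-dimensional fast–slow burster — a
  cubic (Hindmarsh–Rose-type) fast subsystem with a slow linear
  recovery variable — mapped onto membrane-potential units
  ($V = 20x - 20$ mV, 1 s $= 50$ fast-time units) so the $-10$ mV and
  $-35$ mV thresholds apply, with the leak-like parameter entering the
  drive as $I = 1.65 - 0.05\,g$.  Along $g$ it shows regular two- to
  four-spike bursting from the domain edge $g = 0$ up to the
  disappearance of the bursting attractor, a single equilibrium branch
  (the cubic is monotone, so the branch has no folds) whose
  hyperpolarized rest state stabilizes at an Andronov–Hopf point
  *below* that disappearance — hence a genuine window of
  bursting/rest coexistence at the top of the bursting range, the
  bistability the screening pipeline exists to find.  The coefficients
  were chosen once, at generation time, to satisfy exactly this
  structure, and the construction is verified by oracles rather than
  trusted: the manifest's Hopf location is recomputed from the
  closed-form equilibrium at every construction, and the
  bursting-range endpoints are re-derived in the tests by
  `denseBoundaryOracle()`, a uniform $10^{-5}$ nS carry-over sweep
  with full settling runs.
- `makeBursterHCO()` / `hcoFixture()`: two surrogate bursters coupled
  by graded reciprocal inhibition.  The `"recovered"` fixture is a
  symmetric bistable pair with strong slow inhibition, where the
  partner's bursting kicks a reset cell back out of its rest basin;
  the `"both_at_rest"` fixture is an asymmetric pair whose second cell
  is monostable at rest and bursts only under network drive, so
  resetting the endogenous cell strands both at rest.  Protocol
  initial conditions are the endpoint of a 150 s warmup from a
  standard asymmetric state (one cell active, one near rest), the same
  recipe used to seed database simulations.
- `makeSpikeTrace()`: piecewise-smooth voltage traces with prescribed
  spike timing (parabolic spikes, peak 0 mV, baseline $-50$ mV) for
  classifier tests; jittered variants are seeded and bitwise
  reproducible, and their expected CV is computed from the generated
  onsets, not assumed.

What the surrogates deliberately do **not** emulate: the
ten-dimensional state space, multiple fold-back branches, `hyp2`/`dep`
intervals and tristability of the real interneuron model, spike-shape
realism, channel noise, or temperature dependence.  Passing tests
therefore demonstrate that the machinery — integration contract,
continuation and test functions, carry-over scanning, interval
algebra, taxonomy, protocol bookkeeping — is correct on systems with
known answers; they do not reproduce the biological database's cohort
statistics, which require the external kinetics and a multi-cpu-day
sweep.  The taxonomy classifier is exercised on constructed interval
fixtures realizing all ten arrangements, because no single
three-dimensional surrogate can.

## Problem sizes used by the shipped tests

The test and acceptance runs use the full protocol where it is the
contract (400 s settles and $10^{-4}$ nS precision in the scanner
checks; 100 + 5 + 100 s in the protocol checks) and scaled-down
variants where only the mechanics are under test (60 s settles and
$10^{-1}$ nS precision in the cohort-workflow tests; shortened phases
in the protocol bookkeeping tests).  Dense oracles are evaluated on
windows around the boundaries they check ($\pm 3\times10^{-4}$ nS at
$10^{-5}$ nS resolution) rather than over the whole axis.  Grid
cardinalities are verified by streamed enumeration of the full
10,485,760-row product with the exclusion predicate applied in chunks.

## A worked example

```{r example, eval = FALSE}
m <- makeMinimalBurster(g = 3)

# stage 1: settle and classify at the original conductance
reg <- classifyRegime(settle(m, c(-10, 0, 2)))
isRobustBurster(reg)

# stage 2: equilibrium branch from the rest state at 20 nS
m20 <- setModelPar(m, 20)
eq <- findEquilibrium(m20, finalState(settle(m20, c(-10, 0, 2))))
br <- continueBranch(m20, eq)
bifs <- detectBifurcations(br, m20)
ivs <- stableIntervals(br, bifs)

# stage 3: bursting range with attractor carry-over
rng <- scanBurstingRange(m, start_g = 3, y0 = c(-10, 0, 2))

# stages 4-5: coexistence, scenario, prevalence
cx <- coexistenceRanges(ivs, rng)
classifyScenario(cx)
prevalenceOfMultistability(rng, cx)
```

## Known limitations

- One-parameter continuation of equilibria only: no continuation of
  periodic orbits, two-parameter curves or codimension-2 points, so
  the bursting range must come from direct integration (the scanner),
  not from limit-cycle continuation.
- The scanner reports the first transition it encounters at each
  refinement level; if a sliver of irregularity interrupts an
  otherwise bursting range, the range ends there by construction
  (matching the stepping protocol it implements).
- Near a chaotic boundary the CV-based irregularity call applies to a
  finite 200 s window; the boundary is exact for the procedure, not
  an invariant manifold of the flow.
- The results store is a two-table CSV-backed relational store with
  idempotent transactional writes; it targets reproducibility, not
  concurrent multi-process writes.
- The half-center protocol supports the single documented perturbation
  (reset one cell, block synapses 5 s); parameter sweeps over synaptic
  strengths are out of scope.
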