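# burstscan

Bifurcation-based screening of bursting neuron models for
multistability of rest states and bursting.

## The problem

Brute-force databases of conductance-based neuron models classify each
parameter set ("case") by integrating it from a handful of initial
conditions — which only ever reveals the attractor those initial
conditions fall into. When a stable rest state coexists with the
bursting rhythm, a transient perturbation can silence the cell
permanently, a serious failure mode for pacemaker neurons such as the
heartbeat interneurons screened by such databases. `burstscan` is for
computational neuroscientists who want to upgrade this kind of
database with stationary-state information and detect such coexistence
systematically rather than by luck of the initial condition.

The package implements, as reusable tested components:

- **Declarative models** — single-compartment Hodgkin–Huxley-type
  neurons (`modelSpec()`, YAML configs) and two-cell half-center
  oscillators coupled by reciprocal inhibition (`assembleHCO()`), with
  analytic Jacobians derived from the gating structure; plus
  deterministic enumeration of screening grids (`gridSpec()`,
  `countGrid()`).
- **Stiff integration** — implicit Radau IIa of order 5
  (via deSolve), relative tolerance 10⁻⁹, absolute 10⁻¹²; the standard
  settling protocol integrates 400 s and analyzes the last 200 s
  (`settle()`).
- **Trace classification** — spikes are local maxima of V above
  −10 mV; all inter-spike intervals < 1 s ⇒ tonic spiking; any
  ISI ≥ 1 s ⇒ burst statistics; CV of the burst period > 5% ⇒
  irregular. Robust bursters additionally need CV(IBI) < 10%
  (`classifyRegime()`, `isRobustBurster()`).
- **Equilibrium continuation** — pseudo-arclength continuation of
  stationary states in the leak conductance g_leak from the rest state
  at 20 nS, with fold (LP: sign change of ∏λᵢ) and Andronov–Hopf
  (AH: sign change of ∏_{i<j}(λᵢ+λⱼ)) detection localized to 10⁻⁸ nS,
  and stable intervals labeled hyp/dep by the −35 mV rule
  (`continueBranch()`, `detectBifurcations()`, `stableIntervals()`).
- **Bursting-range scanning** — the iterative tenfold step-refinement
  protocol (1 nS down to 10⁻⁴ nS) with endpoint carry-over, so the
  scan tracks the bursting attractor through coexistence regions
  (`scanBurstingRange()`), plus a dense carry-over oracle for
  verification (`denseBoundaryOracle()`).
- **Multistability analysis** — interval intersection into coexistence
  ranges, the ten-class scenario taxonomy A–J, prevalence of
  multistability over the bursting range, and the 2×-mean
  outlier-adjusted cohort summary (`coexistenceRanges()`,
  `classifyScenario()`, `prevalenceOfMultistability()`,
  `summarizePrevalence()`).
- **Half-center perturbation protocol** — 100 s coupled, 5 s with one
  cell reset (not clamped) to a stable rest state and synapses
  blocked, 100 s restored; recovery means both cells burst with
  CV < 5% at relative phase 0.45–0.55 (`runPerturbation()`).
- **Results store** — the two-table database extension (stationary
  states; bifurcation values) keyed by case id, with idempotent
  transactional writes and exact float round trips (`resultsStore()`).

Every stage is testable without the external leech-interneuron
kinetics through surrogate systems with independent ground truth: fold
and Hopf normal forms, a relaxation oscillator, a minimal fast–slow
endogenous burster whose bursting range genuinely overlaps its stable
rest state, and half-center fixtures with oracle-verified perturbation
outcomes (`makeFoldModel()`, `makeHopfModel()`, `makeRelaxationModel()`,
`makeMinimalBurster()`, `hcoFixture()`, `makeSpikeTrace()`).

## A worked example

The full per-case workflow on the surrogate burster at its original
conductance g = 3 nS:

```r
library(burstscan)
m <- makeMinimalBurster(g = 3)

classifyRegime(settle(m, c(-10, 0, 2)))
#> <regimeLabel>  bursting
#> <burstStats>  33 bursts, period 6.106 s (CV 8.3e-05), IBI 5.459 s (CV 8.63e-05)

m20 <- setModelPar(m, 20)
eq  <- findEquilibrium(m20, finalState(settle(m20, c(-10, 0, 2))))
br  <- continueBranch(m20, eq)
bifs <- detectBifurcations(br, m20)
ivs  <- stableIntervals(br, bifs)
bifs[[1]]; ivs[[1]]
#> <bifurcationPoint AH1>  AH at parameter 7.2441895
#> <stableInterval hyp1>  [7.24419, Inf] nS, V ~ -48 mV

rng <- scanBurstingRange(m, start_g = 3, y0 = c(-10, 0, 2))
rng
#> <burstingRange>  [0.000000, 7.624500] nS (precision 0.0001), beyond edges: domain_edge / irregular

cx <- coexistenceRanges(ivs, rng)
cx[[1]]; classifyScenario(cx)
#> <coexistenceRange>  [7.24419, 7.6245] nS: {bursting, hyp1}
#> <scenarioClass A>  bursting+hyp1
prevalenceOfMultistability(rng, cx)
#> [1] 0.04988005
```

Reading: the case bursts robustly (period ≈ 6.1 s, CV ≈ 0.01%); its
hyperpolarized rest state (≈ −48 mV) is stable for
g_leak ≥ 7.244 nS (an Andronov–Hopf point), while the bursting
attractor persists from the domain edge g = 0 up to 7.6245 nS — so on
[7.244, 7.625] nS bursting and rest coexist (scenario A), covering
about 5% of the bursting range. A cell parked at g = 7.4 nS can
therefore be switched permanently between bursting and silence by a
transient input.

The half-center configuration protects against exactly that switch:

```r
fx   <- hcoFixture("recovered")
warm <- integrateModel(fx$model, fx$y0, fx$warmup)
eqr  <- findEquilibrium(makeMinimalBurster(7.45), bursterEquilibrium(7.45))
runPerturbation(fx$model, finalState(warm), eqr, which_cell = 1)
#> <hcoOutcome>  recovered; pre: bursting/bursting | post: bursting/bursting (phase 0.474)
```

After one cell is reset into its rest state, the partner's bursting
pulls it back out of the rest basin and balanced anti-phase bursting
resumes (relative phase 0.474). The `"both_at_rest"` fixture shows the
dysfunctional alternative, where both cells end stranded at rest.

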