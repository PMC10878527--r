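---
title: "A mechanistic model of VEGFR1, VEGFR2 and NRP1 trafficking in endothelial cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanistic model of VEGFR1, VEGFR2 and NRP1 trafficking in endothelial cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegfrtraffic)
```

## The biological system and the model

Vascular endothelial growth factor receptors VEGFR1 and VEGFR2 and the
co-receptor Neuropilin-1 (NRP1) are not static residents of the endothelial
cell surface: they are continuously internalized into Rab4a/5a early
endosomes, sorted there towards degradation, direct ("fast") Rab4a-dependent
recycling, or transfer into Rab11a recycling endosomes for a slower return
route, while new receptors are synthesized at a constant rate and inserted
into the plasma membrane. Where a receptor sits determines whether it can see
extracellular ligand, which phosphatases it meets, and which signals it can
initiate, so the trafficking rate constants are not nuisance parameters —
they are the mechanism.

`vegfrtraffic` implements this system as a deterministic mass-action ODE
model. The molecular state space is built from three receptor species and
two ligand-independent coupling interactions: VEGFR1 and VEGFR2 homodimerize
reversibly, and NRP1 binds VEGFR1 (in monomer or dimer form) directly;
VEGFR2 does not couple to NRP1 without ligand, and an NRP1 is only carried
into a complex by a VEGFR1. That yields exactly eight molecules or
molecular complexes

```
R1, R2, N1, R1R1, R2R2, R1N1, R1R1N1, R1R1N1N1
```

each present on the surface and in the two endosomal compartments, plus a
cumulative degraded pool per complex: a 32-entry state. Rule expansion
produces 85 mass-action reactions: 3 zeroth-order production reactions, 40
first-order trafficking/degradation reactions (internalization `k_int`,
fast recycling `k_rec4`, inter-endosomal transfer `k_4to11`, slow recycling
`k_rec11`, degradation `k_deg`, each applied to all 8 complexes), and 21
coupling plus 21 uncoupling reactions (7 reversible rules instantiated in
each of the three live compartments). Complexes traffic at the rates of
their constituent receptors: anything containing VEGFR1 — including all
VEGFR1–NRP1 species — uses VEGFR1's constants, VEGFR2-only species use
VEGFR2's, and the NRP1 monomer uses NRP1's. Degraded pools only receive
inflow; they are excluded from all whole-cell aggregates.

Coupling rate constants are defined per membrane area
((molecules/µm²)⁻¹ s⁻¹) and divided by the area of the compartment in which
the reaction occurs, so the same biophysical affinity acts more strongly in
the small endosomal membranes than at the plasma membrane. Defaults:
surface area 1000 µm² (which maps a base constant of 10⁻⁴ to a per-cell
constant of 10⁻⁷), endosomal areas 100 µm² each; uncoupling `kd` = 0.01 s⁻¹
for all three bond types, VEGFR1–NRP1 base coupling 8×10⁻⁴
(molecules/µm²)⁻¹ s⁻¹, homodimer couplings 10⁻⁴. The endosomal areas and
homodimer coupling strengths are configuration with documented defaults
rather than measured quantities; every analysis function accepts a modified
`traffic_params()` object.

### Statistical factors and detailed balance

With homodimerization written as `kc·[M]²` (so `K_d = kd/kc` in receptor
units), microscopic consistency fixes the statistical factors of the mixed
rules: NRP1 binding a VEGFR1 dimer has two free sites (factor 2) and one
free site on `R1R1N1` (factor 1); the doubly-occupied complex releases NRP1
with factor 2; and a free VEGFR1 binding the vacant dimerization site of an
`R1N1` sees one specific partner, i.e. the full pairwise association rate,
factor 2 relative to `kc`. Under these factors every assembly route to a
complex yields the same equilibrium level (detailed balance), which the test
suite verifies by relaxing the coupling-only ODE against the closed-form
equilibrium. An alternative convention with factor 1 on the `R1N1 + R1`
rule is sometimes written down, but it makes the equilibrium level of
`R1R1N1` depend on the order of bond formation, which is unphysical for
independent binding sites; we therefore use the consistent factor set.

## Calibration

The 18 free parameters (15 trafficking constants, 3 production rates) are
estimated against a 24-observation HUVEC dataset, eight per receptor:

* absolute surface receptor counts: 1,800 / 4,900 / 68,000 per cell for
  VEGFR1 / VEGFR2 / NRP1;
* surface percentage of total receptor: 10 / 51 / 74 %;
* whole-cell fold change after Rab4a+Rab11a double knockdown: 1.0 (no
  detectable change), simulated as an 80% reduction of `k_rec4` and
  `k_rec11` for 48 h;
* whole-cell fold-change time courses under cycloheximide (CHX), simulated
  by setting all production rates to zero.

The CHX band intensities are not available as numbers, so the time-course
targets are reconstructed from the measured kinetics: exponential decay
with a 45-minute half-life for VEGFR1, an 82.5-minute half-life for VEGFR2
(midpoint of the reported 75–90 minute range), and no turnover for NRP1,
sampled at 1, 2, 4, 8 and 24 h (the experiment's span; the exact grid is
configurable).

The cost is the sum of squared relative residuals — each observation scaled
by its observed value — which puts counts (10³–10⁵ molecules) and fold
changes (order 1) on a comparable footing. The residual denominator
carries a detection floor of 0.01: band densitometry cannot quantify below
about a percent of the control band, so the reconstructed CHX target of
2⁻³² at 24 hours is compared at the floor rather than dividing by a number
that carries no information. Without the floor the late CHX rows create
cliffs that trap most optimization starts far from the data.

The optimizer is Levenberg–Marquardt (`minpack.lm::nls.lm`) run in log₁₀
parameter space with box constraints at the bounds [10⁻⁶, 10⁻¹] s⁻¹, from
starting points drawn log-uniformly within the bounds; 100 starts for the
full calibration. The three production rates are not free parameters of
the outer optimization: every residual evaluation re-solves them (the
"inner production loop") so that the steady-state surface counts match the
measured surface densities exactly — and because all VEGFR1-carrying
complexes traffic at VEGFR1's rates while VEGFR2 never couples to the
others, the VEGFR1 and VEGFR2 production rates have exact closed forms and
only NRP1's requires a one-dimensional numeric solve.

`summarize_fits()` forms the consensus as the per-parameter log-space
median (geometric mean also reported) over the *successful* starts:
converged runs whose final cost shows the data are actually reproduced
(default threshold `max(1, 3 × best cost)`; cost 1 corresponds to an
average relative residual around 20%, the scale of replicate blot
variability). Runs stranded in distant local minima carry no parameter
information, and including them rails the component-wise medians at the
bounds. Identifiability is diagnosed by the correlation between log
initial guesses and log optimized values.

A finding worth stating plainly: with the CHX targets reconstructed as
pure exponentials, the 24 observations identify the quantities they
anchor directly — the surface percentages, the intracellular pools, and
the whole-cell decay half-lives — but leave several individual rate
constants free. Fast-cycling solutions (large `k_int` with
correspondingly large recycling) reproduce a mono-exponential whole-cell
decay exactly as well as slow-cycling ones, because the lag phase that
would distinguish them is absent from an exact exponential. The
internalization rates of VEGFR2 and NRP1, the Rab11a-return rates, and the
VEGFR1 recycling:degradation ratio therefore scatter over decades across
equally good fits, and their ensemble medians reflect the starting
distribution more than the data. The shipped [huvec_params()] is the
lowest-cost reference fit (which reproduces every observation to well
under a percent) rather than the ensemble median, and its weakly
identified entries are flagged in its documentation.

## Numerical design

* **Right-hand side.** The network is compiled to index/stoichiometry
  arrays evaluated by a small C core under `deSolve::lsoda` (stiff-capable),
  with rtol 10⁻⁸ and atol 10⁻⁶ molecules by default; a pure-R evaluator
  with the identical rate laws backs the analytic Jacobian and the tests.
* **Steady states.** Rather than integrating to a large horizon, the
  default solver is a pseudo-transient continuation: damped implicit-Euler
  steps `(I/Δt − J)δ = f` with the analytic mass-action Jacobian, columns
  scaled by pool size, and Δt adapted so that the iteration becomes full
  Newton (quadratic) near the solution. Long stiff integration in
  expanding chunks remains as a fallback, with a Newton polish after each
  chunk. We chose this over integration-only because rate constants
  spanning [10⁻⁶, 10⁻¹] s⁻¹ produce relaxation times up to ~10⁸ s during
  multistart exploration, where integration alone is both slow and
  inaccurate. Convergence demands a residual below 10⁻⁸ of the production
  flux; where double-precision conditioning makes that unreachable, a
  state is accepted only once the iteration stalls and every species' net
  rate is below 10⁻⁶ of its gross turnover — a drift that is physically
  negligible (far below one molecule per day on any pool).
* **Inner production solve.** A joint Newton on the 24 live states plus
  the 3 production rates (stationarity plus surface-target equations),
  verified by polishing the steady state at the returned rates; on failure
  a log-log outer Newton (elasticity formulation, steps clamped to 2
  natural-log units, with a damped fixed-point fallback) takes over.
  Achieved surface counts are required within 10⁻⁴ relative of target,
  and are typically exact to 10⁻⁸.
* **Half-lives.** Whole-cell half-lives are read from protocol
  trajectories by log-linear interpolation between bracketing timepoints.
* **Ties and degenerate inputs.** Zero production gives the empty steady
  state; production with no route to degradation is reported as
  non-convergent rather than silently diverging; zero controls are
  rejected in normalization.

## The synthetic-data generator

`draw_ground_truth()` draws trafficking constants log-uniformly within the
calibration bounds and solves production rates against plausible surface
densities (the measured HUVEC values by default), rejecting infeasible
draws. `generate_measurements()` runs the full measurement pipeline on the
truth — steady state, biotin-split surface/total readouts, CHX chase,
double knockdown — and multiplies each observation by log-normal noise
with mean 1 and a constant coefficient of variation (default 0.15),
emulating western-blot densitometry: strictly positive, roughly constant
CV, normalized to loading controls and to the untreated/time-zero
condition. `generate_biotin_split()` emulates the equal-volume
eluate/flow-through design of the surface-labeling assay. Everything is
bit-reproducible from `(truth, seed)`.

What the generator does *not* emulate: replicate-level structure (gels as
random effects), band saturation or background subtraction, receptor pools
in secretory transit, and any ligand-dependent process. Parameter-recovery
results on synthetic data therefore demonstrate identifiability of the
estimation machinery under the model's own assumptions, not robustness to
the full messiness of blot data.

## Sensitivity analyses

Local sensitivities are one-at-a-time forward differences at +5%
(the protocol the experimental analysis used; not central differences),
reported as %Δoutput / %Δparameter at the re-equilibrated steady state.
The global scan varies each parameter over a log-spaced multiplier grid
spanning 10⁻² to 10²× the optimum (9 points by default, always anchored at
multiplier 1) and records the calibration cost and all 24 dataset-matched
predictions, re-running the CHX and knockdown protocols at each point.
When a trafficking constant is scanned the production rates are re-solved,
mirroring the calibration; when a production rate is scanned it is held at
its edited value. Parameters are varied one at a time; joint variation is
out of scope.

Two signatures are worth knowing. First, the surface *percentage* of a
receptor is invariant to its own production rate (production rescales all
pools together in the linear submodel), while absolute surface counts are
not — and increasing `k_deg` raises the surface percentage while lowering
the absolute surface count, because degradation drains the endosomal pools
preferentially. Second, with VEGFR1–NRP1 coupling on, NRP1 outputs respond
to VEGFR1 parameters and NRP1's total shows hyperlinear (>1) sensitivity
to its own production: the VEGFR1–NRP1 complex degrades at VEGFR1's much
faster rate, so extra NRP1 shifts the NRP1:complex ratio and lowers NRP1's
aggregate degradation. Setting the coupling to zero removes both effects,
which the test suite asserts.

## Transport-rate analysis

At steady state, overall transport rates (rate constant × pool, in
receptors/cell/s) balance per compartment: internalization against synthesis
plus recycling at the surface; Rab4a inflow against degradation plus both
recycling routes; Rab4a→Rab11a transfer against Rab11a recycling.
`compute_fluxes()` tabulates these, `surface_residence_half_life()` returns
ln 2 / `k_int`, and `recycling_degradation_ratio()` returns
(`k_rec4` + `k_4to11`) / `k_deg` — a rate-constant ratio, per the
interpretation "for every receptor degraded, r are recycled"; the
corresponding flux ratio can be formed from the flux table when wanted.
Closed-form dimerization equilibria (`equilibrium_dimer_fraction()`,
`equilibrium_r1n1()`) provide independent checks of the network's coupling
arithmetic, and `estimate_chq_inhibition()` infers the single inhibition
fraction f in `k_deg → (1−f)·k_deg` from a chloroquine accumulation series
by least squares, holding all other parameters fixed.

## Problem sizes and reproducibility

The shipped reference set (`huvec_params()`) is the lowest-cost fit of a
100-start calibration run with seed 1. The test suite and the acceptance
script use reduced desk-scale settings — 20 starts for the in-lab dataset
fit and 10 starts for the synthetic parameter-recovery experiment — which
preserve the data-anchored consensus quantities while keeping a full run
in minutes on one core. All randomness (start draws, noise) is governed
by explicit seeds.

## Known limitations

* No ligand binding or signaling: this is the unliganded trafficking
  network, the prerequisite for ligand studies rather than their
  replacement.
* Secretory transit (ER/Golgi) is collapsed into direct surface insertion.
* Several rate constants are weakly constrained by these data (the
  Rab11a-return rates, the VEGFR2 and NRP1 internalization rates, and the
  split of VEGFR1 endosomal outflow between recycling and degradation);
  the calibration section explains why, and the initial-final correlation
  diagnostics flag them. Quantities derived purely from those constants
  inherit the uncertainty.
* The knockdown mapping ("80% reduction of the relevant parameters") is
  ambiguous about whether Rab4a depletion also slows Rab4a→Rab11a
  transfer; the default leaves `k_4to11` unscaled, and
  `perturbation(..., rab4_scales_transfer = TRUE)` provides the
  alternative.
* Whether the experimental consensus used medians or geometric means of
  the optimization ensemble is ambiguous in the source material; the
  package computes the log-space median by default and reports both.
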