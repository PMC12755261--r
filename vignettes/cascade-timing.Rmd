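---
title: "Timing precision of gene-activation cascades: model, theory, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing precision of gene-activation cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascadeclock)
```

## The process being modelled

A cascade of `N` genes activates sequentially: gene 1 is induced at `t = 0`;
the instant its product first reaches an activation threshold, gene 2
switches on; and so forth until the last product crosses its threshold,
triggering the downstream event. The quantity of interest is the
first-passage time (FPT) `T` of that final crossing, and in particular its
relative variability `CV_T² = var(T)/⟨T⟩²` — the precision of the molecular
timer.

Each gene product is a continuous concentration evolving as a burst–dilution
hybrid process: bursts arrive in a Poisson stream at rate `k_i` while the
gene is active, each adds an amount drawn from a burst-size distribution
with moments `⟨b_i⟩` and `⟨b_i²⟩`, and between bursts the level decays
deterministically at the shared dilution rate `γ` (growth dilution; active
degradation is assumed negligible on the relevant time scales, as for most
bacterial proteins). Activation is a step function of the upstream level.
Because every newly activated gene starts from level zero, the `N` stage
times are independent and the total FPT is their sum — a fact the package
exploits (stage-decomposed simulation) and also verifies (a fully coupled
multi-gene simulator is kept solely as a cross-validation oracle; the two
modes must be statistically indistinguishable, and the test suite checks
this with two-sample Kolmogorov–Smirnov tests at n = 10⁴).

### Assumptions and what they exclude

* Step (all-or-none) activation, not graded Hill-type activation.
* Intrinsic noise only: no cell-to-cell variability in growth rate,
  resources or cell-cycle stage. Real single-cell data contain such
  extrinsic components, which correlate stages and bound the achievable
  precision from below; nothing here captures that.
* Concentrations are continuous (bursts can be fractional); molecular
  discreteness matters only through the burst-size second moment.
* One dilution rate for all proteins.

## Moments and the small-noise FPT theory

From the generator of the hybrid process, the first two moments of an
active gene obey linear ODEs (`moment_rhs()`), solved in closed form by

* mean: `x̄ (1 − e^{−γt})`, with steady state `x̄ = k⟨b⟩/γ`,
* variance: `(⟨b²⟩/2⟨b⟩) x̄ (1 − e^{−2γt})`,

so the stationary protein noise is `CV² = ⟨b²⟩/(2⟨b⟩ x̄)` — fixed by the
burst statistics and the steady state alone. `integrate_moments()`
re-derives these numerically (deSolve `lsoda`, tolerances 1e-10; the suite
requires sup-norm agreement below 1e-6, including a stiff fast-dilution
case with tolerances tightened to 1e-12).

The small-noise approximation linearizes timing fluctuations around the
mean trajectory: the mean stage time is the deterministic saturation time
`(1/γ) ln 1/(1−α)` at relative threshold `α = X/x̄`, and the protein
variance at the crossing, divided by the squared slope of the mean
trajectory, gives the stage FPT variance. Summing stages yields the cascade
formulas quoted in the README. The approximation is trustworthy for
thresholds well separated from both 0 and the steady state; the simulator
quantifies its error (the suite pins relative deviations below 25% for
`α ∈ [0.4, 0.7]` at the default parameterization, and observed deviations
in that band are in fact a few percent). Near the extremes the formula
overestimates the noise, so analytic optima should be read as approximate
locations, confirmed by simulation.

## Threshold optimization

At fixed mean FPT the per-gene thresholds trade off against each other
through `Π(1−α_i) = e^{−γ⟨T⟩}`. The constrained minimizer satisfies the
equal-tension identity `CV_i/(1−α_i*) = const`, giving the closed form
`α_n* = 1 − e^{−γ⟨T⟩/N} Π_i (CV_n/CV_i)^{1/N}`. A gene whose noise is too
large relative to the geometric mean of all `N` noises would need a
negative threshold; the inclusion interval
`e^{−(N−1)γ⟨T⟩/N} < CV_n/(ΠCV_i)^{1/N} < e^{γ⟨T⟩/N}` makes this precise,
reducing for `N = 2` to the three-regime classification
(`gene1_only` / `coupled` / `gene2_only`) by `CV₂/CV₁` versus `e^{±γ⟨T⟩}`.
Dilution is what opens the coupling window: as `γ⟨T⟩ → 0` it collapses to
the single point 1, and splitting the timing task can never help.

Design choices that were genuinely open:

* **Exclusion procedure.** The stationarity conditions say only that an
  over-noisy gene cannot satisfy the identity; they do not prescribe an
  algorithm. `optimal_thresholds_general()` iterates: solve the closed
  form, drop the worst violator (the most negative `α*`, i.e. the noisiest
  gene relative to the current geometric mean), re-solve on the remainder.
  The least-noisy gene can never be dropped (its `α*` is always the
  largest), so the iteration terminates with a non-empty set. A gene
  landing exactly at `α* = 0` is reported as excluded — a degenerate
  boundary case consistent with the two-gene boundary regimes.
* **Boundary ties.** `CV₂/CV₁` exactly at `e^{±γ⟨T⟩}` classifies as the
  adjacent single-gene regime; the coupled formulas produce `α* = 0` there,
  so optima are continuous across the boundary (tested).
* **Symmetric interface.** Internally one threshold can be eliminated
  through the mean constraint, but which one is arbitrary; the public
  `fpt_stats_cascade()` takes all `N` thresholds and treats them
  symmetrically.

For identical genes the optimum is the equal split `α = 1 − e^{−γ⟨T⟩/N}`,
with noise `CV₁² N (e^{2γ⟨T⟩/N} − 1)/(γ⟨T⟩)²`. Relaxing the fixed mean,
the per-stage optimal relative time solves the transcendental equation
`(1 − x)e^{2x} = 1`. The root is unique in (0, 1): `x = 0` is the trivial
root, the function rises with slope 1 just above it, and it equals −1 at
`x = 1`; `uniroot` on the bracket `(1e-9, 1 − 1e-9)` with tolerance 1e-15
gives `x* = 0.79681…` (residual below 1e-12, asserted). The minimum noise
simplifies algebraically to `CV₁²/(N x*(1 − x*)) ≈ 6.18 CV₁²/N`; the
commonly quoted prefactor 6.181 corresponds to evaluating at the root
rounded to three decimals, and the package returns the full-precision value
(≈ 6.177 CV₁²/N) while its tests check both conventions.

## The simulator

`simulate_stage_fpt()` is event-driven and exact: exponential inter-burst
waits, analytic decay `e^{−γΔt}` between events (no Euler step exists to
refine), and crossing checks only at burst instants — rigorous because the
level is non-increasing between bursts; the comparison is inclusive
(`level ≥ X`). Replicates exceeding an event cap (default 10⁷ bursts) raise
an explicit did-not-cross error rather than truncating silently; the cap is
this package's policy for pathological parameterizations (thresholds at or
above what the process can plausibly reach), not part of the model.
Reproducibility comes from R's global RNG: the compiled core draws through
R's RNG, so `set.seed()` — applied once per ensemble in
`sample_fpt_ensemble()` — makes ensembles bit-identical; execution is
sequential, and summaries (plug-in `CV_T²` with a delta-method standard
error propagated from sample central moments up to order four) are
recomputable from the stored replicates.

### Burst-size conventions

The geometric family is defined on support {0, 1, 2, …} with mean `m`
(second moment `m(2m + 1)`); zero-size bursts are legal no-op events. This
zero-inclusive convention is the package default because it is the only
geometric convention that admits burst means below 1, which the two-gene
regime study needs (`⟨b₂⟩ = 0.625` gives `CV₂/CV₁ = 0.5` exactly). The
shifted convention on {1, 2, …} (`geometric1`, second moment `2m² − m`) is
provided for comparison; at equal mean it is less dispersed, so it lowers
`CV₁²` and every noise prediction downstream. Sampler moments are tested
against the declared formulas at 10⁶ draws within four standard errors.

## Study conditions and what the generator does not emulate

The built-in fixtures (`cascade_fixture()`) fix the conditions under which
all quantitative claims are made: `γ = 0.05 min⁻¹`, geometric bursts of
mean 4, steady states of 800 (single-gene threshold sweep) or 1000 (all
multi-gene studies), mean FPTs of 10 or 40 min, and publication-scale
replicate counts of 10⁵–2×10⁵. The test suite and the default
`run_experiment()` runs use 10³–10⁵ replicates chosen so each check
resolves its effect within Monte-Carlo error while the whole suite stays
desk-scale; `full = TRUE` restores the publication-scale counts. Passing
tests demonstrate internal consistency of theory and simulation under
intrinsic noise only — they say nothing about extrinsic variability,
graded activation, or low-copy discreteness in real cells.

## Known limitations

* The small-noise mean `(1/γ)ln 1/(1−α)` carries a few-percent bias at
  moderate thresholds that grows toward both ends of (0, 1); simulated and
  analytic optima therefore differ slightly in location.
* FPT noise formulas overestimate near `α → 0` and `α → 1`; exact FPT
  distributions for the bursty process are out of scope.
* Genes are silenced only by exclusion (threshold 0); partial or leaky
  activation is not modelled.
* All theory assumes `0 < α < 1`; thresholds above the steady state can be
  simulated (crossings still occur via fluctuations) but have no analytic
  counterpart here.
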