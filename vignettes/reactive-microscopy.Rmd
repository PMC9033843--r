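---
title: "Reactive microscopy in silico: models, estimators and controllers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reactive microscopy in silico: models, estimators and controllers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`reactoscope` is a hardware-free testbed for *reactive* microscopy
experiments: experiments whose acquisition plan changes while they run, in
response to what the images show. The package provides the three layers such
an experiment needs — an event engine, a simulated microscope with ground
truth, and the analysis/estimation/control stack that closes the loop — so
that designs can be debugged, benchmarked and regression-tested before any
time on a real instrument is spent.

## The event model

An experiment is a main acquisition loop. Each frame acquires the channels
due at that frame, runs the online analysis hooks (segmentation, tracking,
quantification), then evaluates the triggers of all registered events and
applies the effects of those that fire:

```{r}
library(reactoscope)
ev <- Event("warn-crowding",
            trigger = function(s) nrow(s@tracks$pos1$cells) > 100,
            effect  = function(s, scope) {
              logRecord(s@logger, "user", "field of view crowded",
                        frame = s@frameIndex, severity = "warning")
              s
            },
            recurrence = "once")
```

Semantics are deliberately strict so that runs are reproducible:

* **Ordering.** Effects of simultaneously-true triggers run in registration
  order. Triggers are evaluated only after all analysis hooks of the frame
  have completed.
* **Events can create events.** An effect may register new events; they are
  evaluated from the next frame, never within the frame that created them.
* **Fault isolation.** An effect that throws is logged as an error and the
  remaining effects and frames continue; failures surface through the
  pluggable notifier rather than aborting the experiment.
* **Sequential-equivalent execution.** Everything runs on one thread; there
  is no within-frame interleaving to reason about. Identical configuration
  and master seed replay identical event sequences and numeric outputs,
  because every stochastic module draws from its own labelled RNG stream
  derived from the master seed.

## The virtual sample and microscope

The ground truth is a monolayer of elliptical cells (a data.frame, one row
per cell) with exponential area growth, division at an area threshold with
binomial partitioning of molecules, centroid jitter with overlap relaxation,
a light-driven gene-expression state, a decaying membrane-dye level, and an
irreversible recombination switch.

The camera model is standard: expected pixel value inside a cell is
`background + gain × exposure × signal`, with optional Poisson shot noise
(mean = expected intensity) and additive Gaussian read noise. Brightfield is
rendered as dark cell interiors on a bright background with a radial edge
gradient, which makes Otsu-threshold segmentation well posed. DMD
stimulation masks are blurred with a Gaussian point-spread (`bleedPsfSigma`,
default 2 px) before dosing, so targeting a cell leaks some light onto its
neighbours — the reason stimulation masks are eroded.

Two geometry choices matter for observability and are deliberate:

* Overlap relaxation separates cells by 2 % beyond their *bounding circles*
  (not their mean radii). Freshly divided daughters are aligned along the
  mother's major axis, and a mean-radius criterion would let them touch and
  merge into a single connected component — threshold segmentation cannot
  split touching cells, and watershed splitting is out of scope.
* Segmentation discards components touching the image border: a clipped
  cell's centroid and area are biased by an amount that grows with the
  clipped fraction, which would corrupt tracking.

## Gene expression: one birth–death stage with an input delay

Both the "average cell" and the "single cell" model share one structure:

$$\frac{dP}{dt} = b_0 + k\,u(t-\tau) - \gamma P$$

with binary activation `u` per 6-min measurement interval (a 1000-ms
saturating pulse maps to `u = 1` for its interval, consistent with the fast
photocycle of light-gated transcription factors), a deterministic delay
`τ` dominated by fluorophore maturation, and measured fluorescence
`y = αP + ε`, `ε ~ N(0, σ²)`. The stochastic version is the birth–death
process with the same rates, simulated either event-by-event (exact SSA) or
one interval at a time using the exact conditional law
`Binomial(n, e^{-γΔ}) + Poisson(b/γ (1 - e^{-γΔ}))`.

Defaults (used wherever a scenario does not override them):

| parameter | default | unit | rationale |
|---|---|---|---|
| `gamma` | ln2/90 | 1/min | degradation + dilution at a ~90-min generation time |
| `tau` | 36 | min | reporter maturation delay |
| `k` | 0.25 | molecules/min | full-light stationary mean ≈ 32 molecules |
| `b0` | 0.01 | molecules/min | small dark leak |
| `alpha` | 100 | a.u./molecule | one calibration constant for render and filter |
| `sigmaMeas` | 50 | a.u. | ~0.5 molecule of measurement noise |

These are simulator settings, not inferred biological constants: the
quantitative calibration of the system this simulator is patterned on is not
reproduced here, only its structure and time scales.

A one-stage model was chosen over an mRNA+protein cascade because every
behaviour the control stack relies on — delayed response, exponential
relaxation, Poisson-like copy-number noise — is already present, and a
second stage would add parameters that nothing downstream identifies.

## State estimation

**Population level.** A scalar Kalman filter tracks the deterministic model.
The delay is handled by *input buffering*: the filter stores the activations
applied over the last `τ` minutes and reads the oldest entry during
prediction, so the filter itself stays a textbook linear-Gaussian recursion.
The default process noise is the exact conditional variance of the
underlying birth–death step (binomial survival + Poisson production), i.e.
the linear-noise increment — no tuning constant.

**Single-cell level.** The master equation truncated to copy numbers
`0..N` (finite state projection) with an absorbing sink collecting the mass
that leaks past `N`; the default `N` is 8× the maximal stationary mean and
the leak is monitored (`sum(p) + leaked = 1` to 1e−9 between measurement
updates). Propagation is the matrix exponential of the truncated generator;
because inputs are binary, one pair of kernels (light on / light off) per
interval length serves every cell and every candidate control profile, which
is what makes hundred-cell single-cell control affordable. The measurement
update multiplies by the Gaussian likelihood `N(y; αn, σ²)`, renormalises,
and resets the leak; a measurement more than 10 SD from the whole support
falls back to the prior with a warning. At division a daughter's
distribution is the binomial thinning of the parent's — a modelling choice,
not a claim about the original system's filter.

**Fitting.** For fixed `(γ, τ)` the model response is linear in
`(P₀, b₀, k)`, so calibration profiles `τ` on a 3-min grid, optimises `γ`
in one dimension, and solves the rest by linear least squares. No
multistart, no local minima in the linear block. Identifiability requires at
least two distinct light profiles; the shipped characterisation design uses
three over 10 h (a sustained step for the plateau, an induction block
followed by darkness for a clean decay phase that pins down `γ`, and
alternating pulses for the delay). A 3–4 h design is genuinely too short to
identify `γ = ln2/90` to 10 % under 5 % noise — that is a property of the
physics, not of the optimiser.

## Control

**Adaptive exposure.** If the measured mean cell fluorescence is below
`target − deadband` the exposure increases by a constant step, above
`target + deadband` it decreases, clamped to hardware bounds, independently
per field of view. The shipped preset (setpoint 3000 a.u., deadband
150 a.u., step 5 ms, dye half-life ~2.8 h) starts from an exposure
calibrated at setup, as an experimenter would; the deadband and step trade
off reaction speed against limit-cycle amplitude, with the step sized at
roughly three times the per-frame signal drift.

**Receding-horizon MPC.** Every 6 min the controller enumerates all `2^H`
binary pulse sequences over a 24-min horizon (`H = 4`), predicts the
response, sums the cost against the target, applies the first input of the
minimiser, and repeats. The population controller predicts the Kalman mean
and uses squared deviations; the single-cell controller propagates each
cell's FSP distribution (sharing kernel products along the candidate-prefix
tree) and uses the expected absolute deviation. Ties break toward less total
light, then lexicographically off-first — a photo-toxicity-minimising,
deterministic rule.

One design point deserves emphasis. With `τ = 36 min` (six intervals) and a
four-interval horizon, an input chosen now has *no effect* inside a naive
`t+1..t+H` prediction window: every candidate would predict the same
trajectory, every tie would break to "off", and no controller could ever
act. The receding horizon is therefore *delay-compensated*: the estimate is
first rolled `τ` ahead on the already-committed input buffer, and candidates
are scored over the window `t+τ+1 .. t+τ+H` where they actually act.

**Open loop** runs the same receding-horizon optimisation entirely on the
model before the experiment and applies the resulting profile to all cells.

## The strategy-comparison scenario

The `mpc_comparison` preset compares open-loop, population-feedback and
single-cell-feedback control on 100 stochastically simulated cells over 30
intervals, with per-cell performance defined as the time-averaged absolute
deviation of the true fluorescence from target. Three of its generator
settings are the conditions that make the comparison meaningful, and they
are fixed design, not tuning:

* **A destabilised reporter** (`γ = ln2/30`, `k = 0.6`, target 1500 a.u.).
  With the default 90-min half-life, a 3-h run is a pure unreachable
  transient: every strategy saturates at full light and the comparison is
  vacuous. The fast-turnover reporter is the desk-scale counterpart of the
  many-hour experiments the design is modelled on.
* **Cell-to-cell variability**: each cell carries a lognormal expression
  capacity (CV 0.35) scaling its production rates, while all controllers use
  one nominal model. A shared light input cannot compensate variability
  between cells; per-cell feedback can. Without it the cells are i.i.d. and
  a population controller is already per-cell near-optimal.
* **A batch ("day") factor** (CV 0.15) on the whole experiment's expression
  capacity. Feedback has value only under model uncertainty: with a perfect
  model and no disturbances, open loop is optimal by construction. The batch
  factor represents ordinary calibration drift between the day a model is
  fitted and the day it is used.

Under these conditions single-cell feedback beats both alternatives in the
paired per-cell sign test at p < 0.01 across seeds, and the median per-cell
deviation orders single-cell < population ≤ open-loop. The population-vs-
open-loop margin is small and not sign-test significant — population
feedback corrects only the shared batch error, which is a minor part of any
single cell's deviation. The acceptance test gates that pair on the median
ordering accordingly.

## Targeting and recombination

Ring targeting adds any track whose centroid enters a fixed annulus;
targeting is permanent. Islet selection visits candidates in deterministic
order (descending distance to the nearest targeted cell, ties by track id)
and accepts a candidate only if it is farther than `dMin` from every
targeted cell's centroid *at the moment of selection* — cells drift
afterwards, and the separation constraint is not re-enforced retroactively.
Targeted tracks are stimulated with the union of their eroded masks for 1 s
every 6 min until the end of the experiment; a targeted track absent from a
frame is skipped and logged (tracking-loss accounting).

Ground-truth recombination is Bernoulli per effective stimulation
(`pRec = 0.9` for doses above threshold), irreversible, with the reporter
rising linearly to plateau after a delay and the growth rate reduced from
the same moment. Endpoint classification thresholds final reporter
fluorescence at the midpoint between basal and plateau; because
recombination times are quantised to stimulation ticks and the ramp is
deterministic, a cell's endpoint fluorescence sits a discrete distance from
the threshold and classification agrees exactly with what the ground-truth
recombination times predict. Cells recombining within `delay + ramp/2` of
the endpoint are *expected* to read below threshold — the same
late-recombiner tail seen in real endpoint distributions.

## Numerical choices and degenerate inputs

* Deterministic trajectories use the exact piecewise closed form (inputs are
  piecewise constant), so there is no integration error; `dt` must divide
  the interval and `τ` must sit on the `dt` grid.
* FSP kernels come from `Matrix::expm` on the dense truncated generator;
  probability vectors are clipped at zero after each product (roundoff) and
  the conservation identity is asserted in tests at 1e−9.
* The assignment step of tracking is an exact shortest-augmenting-path
  solver on the standard padded cost matrix (births/deaths as dummy
  moves, gate at `maxDisp`); it is cross-checked against exhaustive
  permutation search in the tests.
* Empty stimulation masks deliver zero dose; erosion that would empty a mask
  falls back to the single centroid pixel so a targeted cell always receives
  light; an all-off fallback profile is returned if an FSP predictive
  distribution has lost all its mass.
* Zero-frame experiments produce headers-only tables and a valid log.

## Problem sizes

The shipped presets run on one CPU in well under their budgets: the
adaptive-exposure benchmark (2 fields × 50 cells × 60 frames, two arms)
in ~20 s; the characterisation fit (3 × 51 time points, 21-point delay
grid) in ~2 s; the strategy comparison (100 cells × 30 intervals × 3
strategies, FSP truncation N ≈ 210) in ~10 s; the ring-targeting experiment
(25 cells growing to ~45, 60 frames, 320×320 px) in ~25 s. These sizes were
chosen as the smallest at which each effect is comfortably resolved.

## What passing tests do and do not show

The simulator emulates: monolayer growth and division, maturation-delayed
stochastic expression, dye decay, camera noise, DMD bleed-through, tracking
at moderate density, and cell-to-cell plus batch variability. It does not
emulate: real bright-field texture (the threshold segmenter would not
survive real images; the original systems use trained neural segmenters),
optical PSF/defocus/stage drift, mRNA dynamics or cell-cycle structure,
crowding beyond gentle contact, or mechanistic photocycles. Green tests
therefore validate the *logic and numerics* of the reactive stack — event
semantics, filters against oracles, controller optimality against
enumeration, targeting bookkeeping against ground truth — and the
qualitative phenomenology, not any quantitative claim about a particular
organism or instrument.
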