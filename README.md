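# reactoscope

Reactive microscopy experiments — experiments whose acquisition plan changes
*while they run*, in response to what the images show — are hard to develop:
debugging a closed-loop design on a real microscope burns days of instrument
time and live samples on what are usually software bugs. `reactoscope` is a
hardware-free R implementation of the full reactive stack, aimed at people
who build such experiments (optogenetic single-cell control, adaptive
imaging, targeted recombination) and want to design, test and benchmark the
control logic entirely in software.

The package provides:

* an **event engine**: experiments are a main acquisition loop plus events,
  each a *trigger* (predicate over the experiment state) and an *effect*
  (action on the state or the hardware handle). Effects run in registration
  order, may register new events (visible from the next frame), and are
  fault-isolated; everything is logged as structured JSONL and replays
  identically from a master seed;
* a **virtual microscope**: a growing, dividing monolayer of cells with
  light-inducible gene expression (maturation delay τ), a decaying membrane
  dye, a Poisson/Gaussian camera, and DMD illumination with Gaussian
  bleed-through — plus per-frame ground truth for oracle-based testing;
* **online image analysis**: Otsu segmentation of the synthetic brightfield,
  exact globally-minimal assignment tracking, per-cell mean-intensity
  quantification, SNR, and mask erosion for precise single-cell targeting;
* **estimation and control**: a Kalman filter for the "average cell" model
  and a finite-state-projection (FSP) Bayesian filter per cell for the
  stochastic model; a constant-step adaptive exposure controller; and
  receding-horizon model predictive control (MPC) at the population and
  single-cell level, with open-loop precomputation as the baseline;
* **targeting strategies**: ring-region targeting, islet selection with a
  minimum-separation constraint, scheduled 1-s/6-min stimulation of all
  targeted tracks, and endpoint recombination phenotyping.

## The models in brief

Gene expression is a one-stage birth–death process with a deterministic
input delay,

    dP/dt = b0 + k·u(t − τ) − γ·P,        y = α·P + N(0, σ²),

with binary light activation `u` per 6-min interval (a 1000-ms pulse
saturates its interval). The population controller propagates the mean with
a Kalman filter and minimises Σ(ŷ − r)² over all 2^H binary light sequences
of a 24-min horizon; the single-cell controller propagates each cell's FSP
distribution p(n) (truncated master equation with tracked leak mass) and
minimises Σ E|α·n − r|. Because inputs act only after τ, the horizon is
delay-compensated: candidates are scored on the window `t+τ+1 … t+τ+H` where
they take effect. See `vignettes/reactive-microscopy.Rmd` for the full
account.

## Worked example

The adaptive-exposure benchmark: two fields of view of ~50 dye-stained cells
whose red signal decays with a ~2.8-h half-life, imaged every 3 min for 60
frames. A reactive event measures the mean cell fluorescence after every
acquisition and nudges the exposure by ±5 ms toward a 3000 a.u. setpoint;
a control arm runs the identical sample at constant exposure.

```r
library(reactoscope)
cfg <- validateConfig(system.file("extdata", "adaptive_exposure.yaml",
                                  package = "reactoscope"))
res <- runExperiment(cfg)
str(res$summary)
#> List of 5
#>  $ time_avg_measured_after_settle: num 2865
#>  $ target                        : num 3000
#>  $ constant_decay_fraction       : num 0.506
#>  $ final_snr_adaptive            : num 51.7
#>  $ final_snr_constant            : num 28.2
```

Reading: the controller holds the measured mean at 2865 a.u. (4.5 % under
the 3000 a.u. setpoint — it trails the decay at the lower deadband edge),
while the constant-exposure arm loses 50.6 % of its signal; at the final
frame the adaptive arm's signal-to-noise ratio (mean cell / mean background
intensity) is 51.7 against 28.2 for the constant arm. Per-frame measurements
and exposures are in `res$adaptive$exposureLog`, the per-cell track table in
`res$trackTable`.

The other shipped presets run the same way:
`characterization.yaml` (three-group calibration data; refits the model with
the delay profiled on a 3-min grid and recovers τ = 36 min),
`mpc_comparison.yaml` (open-loop vs population vs single-cell MPC on 100
matched stochastic cells) and `recombination.yaml` (ring targeting with
eroded-mask DMD stimulation and endpoint phenotyping). A thin CLI wraps
them:

```sh
Rscript inst/scripts/reactoscope run inst/extdata/characterization.yaml seed=3
Rscript inst/scripts/reactoscope validate myconfig.yaml
Rscript inst/scripts/reactoscope report out/
```

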