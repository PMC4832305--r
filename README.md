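# mtrack — nanometre-precision tracking of dynamic microtubule ends

Microtubules are 25-nm-wide polymers of 8-nm tubulin subunits whose growing
ends must often be located in fluorescence movies far more precisely than
the pixel size (~120 nm) or the point spread function (σ_PSF ≈ 135 nm)
allow at first sight — and at the low signal-to-noise ratios (SNR 2–3)
typical when free labelled tubulin raises the background. `mtrack` is for
people who build or use microtubule end-tracking assays and need to know,
quantitatively, how tracking precision depends on their imaging choices.

The package provides the full characterization loop:

- **Simulation** — a stochastic 13-protofilament lattice (3-start B
  lattice, 8 nm subunits) grows with mean speed `v_g` and tip diffusion
  `D_p` (net subunits per frame ~ Normal(v_g·Δt·n_pf/d, 2·D_p·Δt·(n_pf/d)²)),
  maintains a linear tip taper of extent `TL`, bends thermally as a clamped
  cantilever (tip SD `σ_LD`), and is rendered by model convolution:
  Gaussian PSFs on each labelled subunit, exposure-weighted for
  incorporation during the exposure, plus Poisson photon noise, camera
  gain and offset. Every movie carries its exact ground-truth end
  position.
- **Tracking** — per frame: Wiener + Wallis filtering (segmentation only),
  backbone refinement, a predictive polymerizing/depolymerizing state
  machine with hysteresis proposing the new end, and a sub-pixel 2D
  least-squares fit of a Gaussian *wall-end* model
  `I = bg + A·exp(−v²/2σ²)·Φ(−u/σ_end)` to the raw image; the end is the
  half-maximum of the axial edge. A free-`σ_end` variant measures tip
  taper via `σ_end = √(σ_PSF² + σ_PF²)`.
- **Evaluation** — axial/lateral offset (accuracy) and precision (SD) vs
  ground truth with bootstrap errors, two-box SNR measurement,
  single-emitter localization theory
  (`σ² = (s² + a²/12)/N + 8πs⁴b²/(a²N²)`, with EMCCD excess noise as
  `N → N/1.4²`), and an image-averaging precision calculator.

## Worked example

```r
library(mtrack)

cfg   <- mt_config(n_frames = 50)                 # baseline: v_g 11 nm/s,
movie <- simulate_movie(cfg, seed = 21,           # D_p 271 nm²/s, LR 0.2,
                        snr_target = 3)           # pixel 120 nm, 200 ms
track <- track_movie(movie)
project_errors(track, movie$truth)
```

```
mt_errors over 50 frames (nm):
  axial   offset   -4.77 +/- 3.83   precision   27.28 +/- 2.36
  lateral offset   -0.26 +/- 1.31   precision    9.53 +/- 0.83
  axial rmse   27.42
```

At a measured SNR of 3 the end of this growing, wiggling microtubule is
recovered in every frame with ~27 nm axial and ~10 nm lateral precision
and an offset of a few nm — sub-pixel by a factor of ~4 and accurate to
about half a tubulin subunit. `averaging_precision(40,
135, 300)` shows why that matters: ~300 such end-aligned images average
down to 8 nm, single-subunit localization.

Parameter studies run through `sweep_runner()` /
`imaging_sweep_conditions()`; a thin command-line interface
(`inst/cli/mtrack.R`) exposes `simulate`, `track`, `snr`, `evaluate` and
`sweep` subcommands over TIFF movies, YAML configs and CSV tracks.

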