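---
title: "Methods: simulated LED-PIV of pulsatile flow in a compliant aneurysm phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated LED-PIV of pulsatile flow in a compliant aneurysm phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aaapiv)
```

## What this package models

`aaapiv` is a desk-scale re-creation of a bench experiment: pulsatile flow
through a compliant, idealized abdominal-aortic-aneurysm (AAA) phantom,
driven by a hybrid mock circulatory loop and imaged with a pulsed-LED
particle image velocimetry (PIV) system. Every stage that on the bench is
hardware — the piston pump, the pressure-regulated chamber, the camera, the
seeded fluid — is replaced here by a tested, parameterized simulation, so
that the downstream image-processing and hemodynamic analyses can be
exercised end to end against known ground truth.

The chain is:

1. **Geometry** — an axisymmetric lumen: a 20 mm parent vessel with a
   cosine-profiled fusiform bulge (aspect ratio L/d = 2.9, dilation ratio
   D/d = 1.9, 250 mm total length, 1.8 mm wall).
2. **Flow** — a parameterized pump waveform per amplitude case (FL/FM/FH),
   represented by Fourier harmonics; the analytic Womersley solution turns
   the harmonics into a radially resolved velocity field.
3. **Loop** — a discrete-time simulation of the hybrid unit: a 3-element
   Windkessel law computes the setpoint from the latest (delayed) flow
   measurement, a PID-regulated chamber tracks it under actuator slew
   limits, and a lumped-compliance phantom stores flow; channels are logged
   at 5 kHz.
4. **Imaging** — double-exposure frame pairs of advected tracer particles
   under four pulse-width/pulse-separation settings, with background,
   wall-glare and sensor-noise models, and per-pair ground truth.
5. **PIV** — background subtraction, percentile rescale, CLAHE, Gaussian
   smoothing; active-contour wall segmentation; three-pass FFT
   cross-correlation (128/64/32 px, 50% overlap) with window deformation;
   three-criterion vector validation.
6. **Metrics** — phase statistics, velocity-fluctuation RMS, vorticity,
   wall deformation and pressure-strain modulus, and the axisymmetric
   flow-rate integral used to cross-check PIV against the flow sensor.

## Flow model and its assumptions

The inlet waveform is built from two lobes: a half-sine systolic ejection
whose duration (systolic fraction) is solved so the time-averaged
|velocity| matches the case target, and a brief negative lobe (8% of peak,
0.08 s) representing valve-closure regurgitation. The waveform is then
scaled so the peak velocity matches the case target exactly. Zero diastolic
flow is assumed between the dip and the next ejection. This reproduces the
tabulated peak/mean velocities and hence the target Reynolds and
Womersley numbers, but it is *not* an in-vivo Doppler shape; harmonic
content beyond what these two lobes imply is absent.

The velocity field in the straight inlet region is the rigid-tube Womersley
solution evaluated per harmonic, with each harmonic's amplitude fixed by
flow-rate matching (so the cross-sectional integral reproduces the
waveform by construction; the implementation verifies <0.1% closure with 12
harmonics). Assumptions: fully developed axial flow, rigid walls, Newtonian
fluid. The rigid-wall assumption is the main idealization — the real
phantom wall moves by 1–3% of its diameter over the cycle. Consequently
synthetic images carry *no* radial velocity and no entrance effects; tests
passing on these sequences say nothing about flow development or
fluid–structure interaction on a real rig.

Womersley's Bessel function of complex argument `i^{3/2} α√k` is evaluated
by its power series. For the largest argument used by default (α = 14.3,
12 harmonics → |z| ≈ 50) worst-case cancellation amplifies rounding by
about `e^{0.3|z|} ≈ 1e6` on 1e-16 terms, leaving ~1e-10 relative accuracy —
orders of magnitude below every tolerance in the package.

## Loop simulation

The Windkessel capacitor pressure is advanced with the trapezoidal rule,
which is exact to second order and unconditionally stable for this linear
ODE; a guard rejects steps coarser than 1% of the relaxation time R_d·C.
The chamber is modeled as a rate-limited integrator (the solenoid valves
meter air from a 3 kPa pressure line and a −0.5 kPa vacuum line; their
authority is expressed as slew limits in Pa/s) under PID control with
clamping anti-windup. Gains (kp = 400 s⁻¹, ki = 4000 s⁻², kd = 0) were
chosen once for stable millisecond-scale tracking at the 5 kHz control
rate; a bench controller's gains are rig-specific. The flowmeter delay
(such clamp-on meters calibrate between 20 and 26 ms) defaults to 23 ms and is
applied to the logged flow channels; the Windkessel setpoint law consumes
the delayed measurement, as on the bench.

A 25 kHz anti-aliasing cutoff, as quoted for such sensor chains, exceeds
the Nyquist frequency of the 5 kHz logs; the package therefore exposes the low-pass as a
configurable option (default 25 Hz in the flow-balance analysis) rather
than hard-coding an unrealizable value.

The nominal chamber tuning range (0–40 mmHg) is not reproduced by the tabulated Windkessel parameters with zero ground
pressure; P0 is exposed in `wk3_params` and the range is treated as a
tuning target, not an assertion.

## Synthetic imaging

Particles are seeded as a Poisson process over the lumen area (default
7 mm⁻², ~12 per final 32 px window — standard PIV practice; bench seeding
densities are rarely reported) and uniformly across a 1.5 mm light sheet with a
Gaussian intensity profile (σ = thickness/4). Spots are Gaussian with
σ = 0.65 px (≈2.6 px e⁻² diameter); motion during the LED pulse is drawn as
a 3-sample streak; pulse energy scales linearly with pulse width, so the
10 µs settings are half as bright as the 20 µs ones. Background = offset +
smooth gradient + a bright band hugging the wall contour. Because the
compliant wall moves over the cycle, the glare band is *not* static between
acquisitions: the band position is jittered per pair (σ = 2 px; frozen
within a pair, since the wall barely moves in 400 µs). This matters: a
perfectly static band is removed exactly by mean-background subtraction,
which would make near-wall windows look unrealistically clean; the
fluctuating residual reproduces the unreliable near-wall behavior reported
on the bench. Sensor noise is Poisson-like shot noise (Gaussian
approximation) plus Gaussian read noise (σ = 4 counts), clipped to 12 bits.

The pair cadence defaults to period/25 = 32 ms (a 31 ms cadence, as
sometimes quoted for this acquisition rate, does not divide the 0.8 s
cycle evenly; the value is configurable).

## PIV engine choices

* Correlation windows are zero-mean and unweighted; the sub-pixel peak is a
  three-point Gaussian fit per axis; SNR is the first-to-second peak ratio
  with a 3×3 exclusion zone.
* Between passes the validated field is interpolated bilinearly to a dense
  predictor, which is **tapered linearly to zero within half a window of
  the lumen boundary** (distance transform of the mask). Without the taper,
  constant extrapolation carries the core displacement into the boundary
  layer, the warped near-wall particles acquire bimodal residuals, and
  near-wall vectors lock unpredictably onto either population. With it the
  predictor respects no-slip and near-wall vectors converge. Frame B is
  warped by the predictor with Catmull-Rom bicubic interpolation.
* The segmented lumen contour is also used to mask the images themselves
  (pixels outside the lumen set to zero) before correlation, and windows
  with more than 50% out-of-lumen coverage emit no vector.
* Validation: a vector is invalid if a component is >5 global SD from the
  global mean, or the normalized 3×3 median residual exceeds 3 (with 0.1 px
  regularization), or SNR < 1.25. Invalid vectors are replaced by the mean
  of valid neighbors and flagged; reported invalid rates are
  pre-replacement. Replaced vectors are excluded when two fields are
  *compared* (illumination difference maps): an interpolated value is not a
  measurement.
* CLAHE uses 8×8 tiles with the contrast limit of the underlying
  implementation's convention (limit = 2), and the frames are padded by
  edge replication to tile-divisible sizes; the smoothing σ is 1 px. These
  conditioning constants are rig-specific; all are exposed in
  `preprocess_config`.

## Wall segmentation

Each wall edge is an open snake: one row coordinate per column, climbing
the smoothed vertical-gradient magnitude under a second-difference
smoothness penalty via a semi-implicit (Cholesky-factored) update. This
exploits the near-horizontal wall orientation in both regions of interest
and is initialized from the analytic mask (standing in for the manual
initialization used on the bench). Convergence is declared below 0.02 px
maximum displacement; non-convergence raises a condition carrying the last
contour. The transverse extent Y(x) feeds the deformation metric
δ(x,t) = Y(x,t) − Y(x,t₀), normalized by Y(x,t₀) for the circular sections
of the idealized model.

## Problem sizes and determinism

The default imaging window is a 540×560 px region over the straight inlet
segment at the reference 24.6 px/mm image scale — large enough for three
correlation passes starting at 128 px and for the 8–12 mm flow-integration
band, while keeping a full 25-pair cycle tractable on one CPU. One cycle
(25 pairs) is rendered per run; a bench acquisition averages ~25 cycles, so
bench-scale phase-statistics magnitudes are emulated, not reproduced. All stochastic
stages consume explicit seeds and the pipeline is byte-reproducible for a
fixed configuration and seed.

## Known limitations

* Rigid-tube Womersley ground truth: no radial velocities, no bulge
  recirculation in the synthetic images; vorticity and fluctuation metrics
  are exercised on analytic and constructed fields instead.
* The patient-specific phantom is out of scope (no geometry is available
  to model); its tabulated dimensionless numbers are internally
  inconsistent (no single diameter reproduces both the Reynolds and
  Womersley values) and are not asserted anywhere.
* The loop simulation is lumped: no wave propagation, no valve dynamics
  beyond the fixed regurgitation dip.
* Reference distensibility values for silicone aortic phantoms
  (2–4.3×10⁵ N m⁻²) cannot be tied to one case/pressure pairing; the
  package recovers the modulus it was configured with, demonstrating the
  method rather than a particular number.
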