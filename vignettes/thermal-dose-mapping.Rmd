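---
title: "Thermal dose mapping from PRF MR thermometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal dose mapping from PRF MR thermometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrthermodose)
```

This vignette explains the models behind `mrthermodose`, the parameters
that matter, and the design decisions taken where the underlying procedure
left the details open.

## The measurement model

PRF thermometry exploits the temperature dependence of the water proton
resonance frequency, about α = −0.01 ppm/°C. In a gradient-echo acquisition
with echo time TE at field strength B₀, a temperature change ΔT at a pixel
shifts its phase by

$$\Delta\varphi = 2\pi\,\gamma\,B_0\,\alpha\,10^{-6}\,\Delta T\,T_E,$$

with γ = 42.577 MHz/T. At the default 1.5 T and TE = 15 ms this is
−0.0602 rad/°C, so heating *lowers* the phase and the reconstruction maps a
negative phase change to a positive ΔT.

`reconstruct_delta_t()` implements the inverse:

1. **Baseline phase** is the circular mean of the first
   `baseline_frame_count` phase frames (default: all pre-heating frames of
   a synthetic series). Averaging several frames reduces the phase noise of
   the reference; the circular mean (argument of the summed unit phasors)
   is immune to wrap seams, where an arithmetic mean of stored phase values
   would not be.
2. **Phase differences** are formed as `Arg(exp(i(φ_t − φ_ref)))`, the
   complex-difference formulation. It yields the same value as subtracting
   stored phase maps modulo 2π but cannot produce spurious ±2π jumps at the
   ±π seam.
3. **Temporal unwrapping** (`unwrap_temporal()`): frame-to-frame increments
   are wrapped into (−π, π] and cumulatively summed per pixel. This is
   exact whenever the true per-frame step is strictly inside (−π, π]; at
   620 ms per frame a step of π would require heating faster than
   ~80 °C/s, far beyond the regime of interest. No spatial (2-D)
   unwrapping is performed — per-frame steps are small, spatial gradients
   need not be.
4. Division by the PRF factor gives ΔT per pixel per frame.

No B₀-drift reference correction is applied. Over the few minutes of a run
drift is small compared with the effects of interest; a reference-ROI
correction is a possible future extension.

## Masking, ROI and smoothing

Low-magnitude pixels carry essentially random phase. `noise_mask()`
excludes every pixel whose mean baseline magnitude is below
`factor × S_air` (default factor 3.7), where `S_air` is the mean magnitude
over a user-supplied air region. The mask is evaluated once, on the mean of
the baseline magnitude frames, rather than per frame: one static pixel set
keeps the dose integral over a fixed domain, at the cost of not tracking
pixels that lose signal mid-run (those appear as phase noise in the
temperature curves instead).

`apply_roi()` restricts analysis to a kidney region of interest — a
polygon in pixel coordinates or a boolean raster. Polygon rasterization
keeps pixels whose centres lie inside the polygon under the even-odd rule.
Coordinates are 1-based (row, col) with pixel centres at integer
coordinates, the R matrix convention.

`smooth_temperature()` applies an averaging filter of odd width (default
3 × 3) to each ΔT frame. The filter is *mask-aware*: each kept pixel
becomes the mean of the kept pixels in its in-frame neighbourhood, with the
divisor renormalized accordingly. Zero-padding instead would bias values
toward zero exactly at the lesion rim and the mask boundary — the region
whose dose is being thresholded. Excluded pixels pass through unchanged and
contribute nothing.

The pipeline order is mask → ROI → smooth ΔT → dose. Whether smoothing is
applied at all is a switch (`smooth` in `experiment_config()`), since a
defensible pipeline could also accumulate dose on raw ΔT; smoothing before
dose accumulation is the default because the dose exponential amplifies
positive noise excursions asymmetrically.

## Thermal dose and critical area

`cem43()` accumulates cumulative equivalent minutes at 43 °C:

$$\mathrm{CEM}_{43} = \sum_k \Delta t_{\min}\, R^{\,43 - T_k}, \qquad
R = \begin{cases} 0.5 & T \ge 43\,^\circ\mathrm{C} \\
0.25 & 39 \le T < 43\,^\circ\mathrm{C} \\ \text{(no accrual)} & T < 39\,^\circ\mathrm{C}\end{cases}$$

with absolute temperature `T = baseline + ΔT` and `Δt` the acquisition time
per dynamic image (TA = 0.62 s by default) — the real elapsed time each
frame represents, not the pulse-sequence TR. The breakpoint, both R values,
the 39 °C accrual floor and the 120-min critical threshold are all explicit
fields of `dose_params()`; the defaults are the standard convention for
this dose model. Two consequences worth knowing:

* holding a pixel at exactly 43 °C accrues clock time (R⁰ = 1);
* one degree above the breakpoint doubles the rate (60 min at 44 °C =
  120 CEM43), which is how the critical threshold is validated in closed
  form.

`critical_area()` counts kept pixels with CEM43 **strictly** above the
threshold ("exceeded" is read as >, not ≥) and multiplies by the pixel
area from the acquisition geometry, `(FOV_r/N_r)·(FOV_c/N_c)` — 1.82 mm²
for the default 235 × 259 mm² FOV and 174 × 192 matrix. The hottest pixel
is the kept argmax of the per-pixel temporal maximum of ΔT, ties broken in
row-major order, and its full time course is returned.

## The synthetic scene

`simulate_temperature()` integrates a single-slice 2-D heat equation with
an explicit finite-difference scheme:

$$\frac{\partial T}{\partial t} = D\,\nabla^2 T
 + s(\mathbf r)\,A\,[\text{laser on}]
 - k_I\,I\,(T - T_{\mathrm{irr}})\,[\text{cavity}]
 - k_t\,(T - T_0)\,[\text{tissue}]$$

* **Geometry.** `scene_preset()` builds a circular fluid cavity inside a
  parenchyma annulus inside a clamped bath. The cavity disc area equals the
  measured mean collecting-space volume (0.95 cm³ "calyx", 8.86 cm³
  "pelvis") divided by the 4 mm slice thickness. The fiber tip sits at the
  cavity centre, so in the small cavity it is inherently closer to the
  tissue wall — the geometric mechanism by which small cavities are more
  dangerous.
* **Source.** An isotropic Gaussian (σ = 5 mm) with peak rate
  `source_amplitude_K_per_s` at the calibration power (30 W), scaled
  linearly with the protocol's power. The default amplitude of 4 K/s was
  fixed once by requiring the 30 W / 10 ml/min calyx preset to drive the
  cavity past the 43 °C breakpoint within 10 s of laser-on and to
  reproduce the qualitative flow-rate safety thresholds (no critical dose
  at ≥ 70 ml/min at 30 W, at lower rates at 14 W), and is not tuned
  per experiment.
* **Cooling.** Irrigation is a Newtonian sink toward the 22.1 °C irrigant
  at rate `k_I·I` with `k_I` = 0.004 s⁻¹ per (ml/min) — the minimal model
  that is monotone in the flow rate, since no flow physics is available.
  Tissue loses heat through the slice to the 37 °C bath at
  `k_t` = 0.005 s⁻¹. Blood perfusion is deliberately absent: the emulated
  preparation is ex vivo.
* **Burn-in.** Before frame 0 the scene is integrated for 60 s with the
  laser off, so the baseline frames show the steady irrigation-on state
  (the experimental protocol likewise rinses before acquiring). Without
  it, strong irrigation produces a cooling transient *during* the baseline
  frames that contaminates the phase reference.
* **Stability.** The explicit scheme requires
  `dt ≤ min(pixel)²/(4D)`; the constructor rejects configurations that
  violate the bound and names the maximum admissible step. Default
  `dt` = 0.05 s against a bound of ≈ 3.25 s at the default pitch.
* **Floor.** Temperatures cannot fall below the coldest reservoir in the
  scene — the irrigant — and the ground-truth container validates that
  floor rather than an arbitrary offset below baseline.

`encode_mr_series()` applies the forward PRF model pixelwise, gives the
object a uniform magnitude (default 100), surrounds it with a near-zero
"air" border (so every synthetic frame has a well-defined `S_air`), and
adds i.i.d. Gaussian noise to the real and imaginary channels from a single
seeded generator; output is bit-for-bit reproducible per seed.

**What the simulator does and does not emulate.** It reproduces pulsed
heating, diffusion, flow-rate-dependent cooling, cavity-size effects,
complex noise and an air background — enough to exercise every pipeline
stage and the qualitative trends (area non-increasing in irrigation,
non-decreasing in power, larger in the small cavity). It does not model
advection or turbulence of the irrigant, boiling, stone fragments, motion
or susceptibility artifacts, k-space/EPI effects, or 3-D heat transport.
Passing end-to-end tests therefore validates the *analysis chain* and the
direction of parameter effects, not absolute agreement with any particular
ex vivo measurement — the published areas from such experiments depend on
raw data that are not publicly deposited, and are used here only as trend
anchors.

## Reproducibility and problem sizes

All randomness enters through integer seeds: one per encode call, and in
sweeps a per-cell seed derived arithmetically from `base_seed`, so any cell
can be rerun in isolation. Runs write a JSON provenance record containing
every scalar parameter, the seed, and the scene masks as flat indices;
rerunning a config reproduces byte-identical summary rows.

The test suite and the acceptance script run the end-to-end analyses on
64 × 64 scenes at the native pixel pitch with 90 s of simulated time, and
the noiseless round-trip check on the full 174 × 192 raster with 60–100
frames; these sizes were chosen as the smallest at which the cavity
geometry, the air border and the trend structure are all well resolved.

## Known limitations

* The magnitude threshold is the only artifact defence; runs contaminated
  by bulk motion or air ingress must be flagged manually
  (`qc_excluded` in `experiment_config()`), mirroring how such runs are
  excluded in practice.
* Dose uses `baseline + ΔT` with a constant baseline; regions whose true
  absolute temperature differs from the assumed baseline (e.g. fluid
  pre-cooled by irrigation) inherit that offset, a limitation shared by
  any ΔT-only thermometry.
* No spatial unwrapping, multi-echo or referenceless reconstruction, fat
  suppression, or motion correction.
* The DICOM interchange format is not read or written; the portable
  container (`write_series()`/`read_series()`: per-frame TSV rasters plus
  a JSON sidecar) is the supported on-disk form.
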