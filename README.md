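# mrthermodose

Quantifying thermal tissue damage in the kidney during Ho:YAG laser
lithotripsy from dynamic MR thermometry.

During endoscopic laser fragmentation of urinary-tract stones the laser
deposits heat into the irrigated collecting space, and the surrounding renal
parenchyma can be damaged if irrigation does not carry that heat away fast
enough. Proton-resonance-frequency (PRF) MR thermometry images this process:
the water resonance shifts by about −0.01 ppm per °C, so the phase of a
dynamic gradient-echo series encodes the temperature change of every pixel.
`mrthermodose` turns such a magnitude/phase series into a per-pixel thermal
dose map and a single clinically interpretable number — the tissue area
whose dose exceeds the critical damage threshold.

The package is aimed at researchers analysing intrarenal (or other
intracavitary) laser-heating experiments under MR monitoring, and at anyone
who wants a fully synthetic, reproducible test bed for a PRF → dose → area
pipeline.

## The model

**PRF thermometry.** For echo time TE and field strength B₀, a temperature
change ΔT changes the gradient-echo phase by

    Δφ = 2π · γ · B₀ · α · 10⁻⁶ · ΔT · TE,      α ≈ −0.01 ppm/°C

with γ = 42.577 MHz/T. The reconstruction references each frame to the
circular mean of the pre-heating baseline frames through the complex product
z·conj(z_ref) (no wrap seams at ±π), unwraps the phase differences along
time, and divides by the PRF factor.

**Masking and smoothing.** Pixels whose signal magnitude S is below
3.7 × the mean air signal (S < 3.7·S_air) carry unusable phase and are
removed; analysis is further restricted to a kidney region of interest, and
a mask-aware 3 × 3 averaging filter suppresses phase noise.

**Thermal dose.** Each pixel's temperature history is converted to
cumulative equivalent minutes at 43 °C:

    CEM43 = Σ Δt · R^(43 − T),   R = 0.5 (T ≥ 43 °C), 0.25 (39 ≤ T < 43 °C)

with no accrual below 39 °C. Doses above 120 equivalent minutes damage most
tissues, including renal parenchyma; the headline result of a run is the
area (n_pixels × pixel area) with CEM43 > 120 min, plus the location and
time course of the hottest pixel.

**Synthetic test bed.** A finite-difference heat model of a fluid-filled
renal cavity (small "calyx" and large "pelvis" presets) with a pulsed
Gaussian source at the fiber tip, Newtonian irrigation cooling proportional
to the flow rate, and diffusion into the surrounding parenchyma, is encoded
into noisy complex MR frames with the acquisition geometry above — so the
entire chain can be validated without scanner data.

## Worked example

A simulated 30 W application (t_on/t_off = 10/5 s, three applications) in a
calyx-sized cavity at the lowest irrigation rate of the study grid,
10 ml/min:

```r
library(mrthermodose)

scene <- scene_preset("calyx", irrigation_ml_per_min = 10)
cfg <- experiment_config(protocol = laser_protocol(30, 10, 5),
                         scene = scene, duration_s = 90,
                         noise_sd = 2, seed = 1, fiber_site = "calyx")
run <- run_experiment(cfg)
run
#> Experiment run 'run'
#> Critical area: 260.5 mm^2 (143 px); hottest pixel (32, 32), max dT 50.1 C
run$mask
#> Pixel mask: 732 of 4096 pixels kept
#>   noise: removed 960
#>   roi: removed 2404
```

143 of the analysed pixels accumulated more than 120 equivalent minutes at
43 °C; at 1.82 mm² per pixel that is a critical damage area of 260.5 mm²
around the fiber tip, whose hottest pixel peaked 50.1 °C above baseline.
Raising the irrigation rate shrinks this area monotonically (it reaches zero
at 70–100 ml/min in this configuration), lowering the power to 14 W shrinks
it, and the large-cavity "pelvis" preset yields a smaller area than the
calyx at identical settings.

`run_sweep()` executes the full factorial of powers × pulse protocols ×
irrigation rates × cavity presets × replicates with deterministic per-cell
seeds, and `summarize_sweep()` pivots the per-run rows into a mean ± SD
table by irrigation rate. A thin command-line front end with `simulate`,
`analyze` and `sweep` subcommands is installed at
`inst/scripts/thermodose.R`.

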