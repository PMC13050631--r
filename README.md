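# densemp

Locally low-rank denoising for 2D spiral cine DENSE cardiac MRI, with
Marchenko–Pastur singular-value thresholds calibrated by Monte-Carlo
simulation for gridding-correlated noise — plus everything needed to
validate it end to end on an analytic numerical phantom: spiral k-space
simulation, coil pre-whitening, adjoint NUFFT reconstruction,
phase-cycle/coil combination, phase unwrapping, and circumferential
strain (E<sub>cc</sub>) analysis with AHA segmental statistics.

The package is aimed at cardiac MR physicists and image-analysis
researchers who want a tested, reusable implementation of
random-matrix-theory denoising for displacement-encoded MRI, and a
ground-truth phantom against which displacement and strain pipelines can
be verified exactly.

## The method in brief

Cine DENSE data form a 6D complex array
(N<sub>x</sub>, N<sub>y</sub>, N<sub>ch</sub>, N<sub>ph</sub>,
N<sub>pc</sub>, N<sub>enc</sub>). Overlapping 3×3 spatial patches
(non-spatial dimensions taken whole) are reshaped into real "Casorati-like"
matrices under the dimension grouping (x, y, ch) | (ph, enc, pc), with real
and imaginary parts concatenated. For an i.i.d. Gaussian p×q matrix the
eigenvalues of BBᵀ/q lie in [a, b] with

a = σ²(1 − √γ)², b = σ²(1 + √γ)², γ = p/q (p ≤ q),

the Marchenko–Pastur law. Spiral gridding correlates the image-domain
noise, shifting those bounds to [a_B, b_B]. The chain

b̂_B = (b_B/b) · (b/a) · (a/a_B) · â_B

recovers the noise ceiling per patch: b/a is closed-form, â_B is the
smallest Gram eigenvalue of the data patch itself, and the two ratios are
estimated once per acquisition geometry from 10 noise-only simulated
reconstructions (`calibrate_ratios()`), stored in a key-addressed lookup
table. Singular values below s\* = √(q·b̂_B) are hard-thresholded and the
overlapping denoised patches averaged. Denoised images then flow through
phase-cycle subtraction, coil combination, unwrapping, u = Δφ/(2π·k_e),
and Green–Lagrange strain mapping.

See `vignette("denoising-methods")` for the full model, the calibration
design, the phantom's motion/signal model, and validation conditions.

## Worked example

A complete phantom study — simulate, calibrate thresholds, reconstruct,
denoise, analyse strain — at a reduced 64² size (about a minute):

```r
library(densemp)

pc <- phantom_config(grid_size = 64, fov_mm = 128, n_phases = 10,
                     n_coils = 8, epicardial_radius_mm = 30,
                     endocardial_radius_mm = 14)
cfg <- run_config(phantom = pc, target_snr = 25, n_mc = 10, seed = 1,
                  smooth_sigma = 0.6)
run <- run_pipeline(cfg)
print(run)
```

```
dense_run (paired non-denoised / denoised results)
  injected k-space sigma: 7.213 (target apparent SNR 25)
              metric non_denoised     denoised
1              nrmse   0.14619070  0.074157788
2       apparent_snr  25.00883887 46.214230842
3        phase_snr_x  14.36251000 38.815593869
4        phase_snr_y   6.55070173 18.047461272
5    scan_efficiency   0.05582330  0.103156765
6 mean_abs_ecc_error   0.01011077  0.006482838
```

Reading the table: the injected k-space noise was calibrated so the
non-denoised apparent magnitude SNR lands at the requested operating
point (25, the high-resolution in vivo regime). Denoising halves the NRMSE
against the noise-free reference reconstruction, raises apparent magnitude
SNR and phase SNR, and reduces the mean absolute error of the E<sub>cc</sub>
strain map against the phantom's analytic ground truth. The calibrated
bound-ratio table is also part of the run:

```r
print(run$ratio_table)
#> ratio_table (62 x 62 locations, n_mc = 10)
#>   key: spiral_64_128_4_805|N64|dims8-10-2-3|patch3x3s1|xych|ri1|wh1
#>   mean r_upper = 1.0103, mean r_lower = 0.9981 (p = 144, q = 60)
```

Per-segment strain-time curves and tables:

```r
plot(run$denoised$segments)
write_strain_csv(run, "strain.csv")
write_metrics_csv(run, "metrics.csv")
```

A thin command-line wrapper with `simulate` / `calibrate` / `run` /
`report` subcommands is installed at `inst/cli/densemp.R`.

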