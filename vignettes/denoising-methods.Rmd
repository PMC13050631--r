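---
title: "Locally low-rank denoising of spiral cine DENSE: model, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locally low-rank denoising of spiral cine DENSE: model, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densemp)
```

# The problem

Cine DENSE (Displacement ENcoding with Stimulated Echoes) MRI encodes
myocardial tissue displacement into the image phase, from which
circumferential strain ($E_{cc}$) is computed. Because the stimulated echo
carries only a fraction of the equilibrium magnetization, DENSE is
SNR-starved, and the problem worsens at high spatial resolution and at low
field. A cine DENSE acquisition, however, is highly redundant: the same
anatomy is observed across coils, cardiac phases, phase-cycling
acquisitions, and displacement encodings. `densemp` exploits that
redundancy with patch-based locally low-rank denoising, with the noise
threshold derived from random-matrix theory and corrected, by Monte-Carlo
calibration, for the noise correlations that non-Cartesian (spiral)
reconstruction introduces.

# Noise model and the eigenvalue threshold

For a $p \times q$ ($p \le q$) matrix of i.i.d. zero-mean Gaussian entries
with variance $\sigma^2$, the eigenvalues $\lambda$ of
$Y = \tfrac{1}{q} X X^T$ follow the Marchenko–Pastur (MP) law with density

$$ p(\lambda \mid \sigma^2, \gamma) =
   \frac{\sqrt{(b - \lambda)(\lambda - a)}}{2 \pi \gamma \lambda \sigma^2},
   \qquad a \le \lambda \le b, $$

supported on $a = \sigma^2 (1 - \sqrt{\gamma})^2$,
$b = \sigma^2 (1 + \sqrt{\gamma})^2$, $\gamma = p/q$
(`mp_bounds()`, `mp_pdf()`). Singular-value components of a noisy matrix
whose eigenvalues fall below the upper bound are attributable to noise and
can be removed.

Image-domain noise after a non-Cartesian reconstruction is *not* i.i.d.:
the gridding/adjoint transform correlates neighbouring samples. For a
correlated Gaussian matrix $B = \Sigma^{1/2} X$ the spectrum is still
compactly supported, but its bounds $a_B = \sigma^2 L(\gamma, \Sigma)$ and
$b_B = \sigma^2 U(\gamma, \Sigma)$ depend on the covariance, which is
impractical to obtain analytically for a given spiral and patch geometry.
Two observations rescue the approach:

1. the *ratios* $b_B/b$ and $a/a_B$ are fixed for a given acquisition
   geometry, patch spec and reconstruction path, so they can be estimated
   once by simulation; and
2. $a_B$ can be estimated per patch from the data itself, as the smallest
   eigenvalue of the patch's scaled Gram matrix (real patches from smooth
   anatomy are rank-deficient in these groupings, so the smallest
   eigenvalue sits at the noise floor).

The chain
$$ \hat b_B = \frac{b_B}{b} \cdot \frac{b}{a} \cdot \frac{a}{a_B} \cdot \hat a_B, $$
with $b/a = (1+\sqrt\gamma)^2 / (1-\sqrt\gamma)^2$ known in closed form,
then yields the patch's noise eigenvalue ceiling, and
$s^\ast = \sqrt{q\,\hat b_B}$ the singular-value cutoff
(`threshold_from_data()`). The chain is exact when $\hat a_B = a$ and both
ratios are 1, which is one of the package's invariant tests.

## Monte-Carlo calibration

`calibrate_ratios()` draws `n_mc` (default 10) noise-only k-space
realizations with unit coil covariance (the pipeline pre-whitens first),
pushes each through *the same* reconstruction code path as the data, and
measures, for every patch location, the extreme eigenvalues of the
noise-only Casorati matrix against MP bounds computed from that
realization's empirical image-domain variance $\sigma^2_{\mathrm{eff}}$
(measured per real/imaginary component from the reconstructed noise image
itself, which makes the table independent of reconstruction scaling
conventions). Ratios are averaged per patch location — gridded noise is
not perfectly stationary — with the table's global means available as a
fallback (`ratio_fallback`). Tables are keyed by a calibration string
(trajectory identity, matrix and data dimensions, patch spec, whitening
flag); `denoise_volume()` refuses a table whose key does not match, and
`cached_ratio_table()` persists tables under key-addressed files, so the
expensive simulation runs once per protocol.

Design choices worth noting:

* **Orientation.** Groupings can give $p > q$; the package normalises with
  $\gamma = \min/\max$ and forms the Gram matrix over the smaller
  dimension, scaling by the larger (`eigen_spectrum()`).
* **$\hat a_B$ estimator.** The single smallest eigenvalue by default; a
  trimmed variant (mean of the 3 smallest) is available via `trimmed =
  TRUE` for robustness.
* **Degenerate aspect ratio.** $\gamma = 1$ makes $b/a$ undefined; the
  package raises an error instructing a non-square grouping.
* **Scale freedom.** The ratios are invariant to the calibration noise
  level; the tests verify a table at $\sigma = 2$ reproduces one at
  $\sigma = 1$.

# The 6D patch and Casorati-like matrix

Images are carried as a 6D complex array
$(N_x, N_y, N_{ch}, N_{ph}, N_{pc}, N_{enc})$. Overlapping $p_x \times
p_y$ spatial patches (default $3 \times 3$, stride 1; non-spatial
dimensions taken whole; interior-only, no padding) are reshaped into a
real 2D matrix by partitioning the six dimensions into two groups — the
spatial pair always together — and stacking real over imaginary parts on
the side holding the spatial dimensions (configurable). Axis order within
each side is fixed: canonical $(x, y, ch, ph, pc, enc)$, fast to slow. The
reshaping is an exact bijection, tested for all four groupings. The
default grouping $(x, y, ch)\,|\,(ph, enc, pc)$ and default $3\times3$
patch are the combination that attains the lowest phantom NRMSE in the
package's ablation test, consistent with the larger patches and
alternative groupings losing locality or redundancy.

Each Casorati matrix is hard-thresholded at $s^\ast$ (singular values
$\le s^\ast$ zeroed, retained values unchanged; an optional `"soft"` rule
subtracts the cutoff), reshaped back, and overlapping patches are averaged
with uniform weights per pixel coverage count. With the cutoff forced to
zero the machinery reproduces its input exactly, which isolates the
accumulate/average bookkeeping in a test.

# The synthetic phantom

No deposited DENSE raw data exist for this problem, so validation runs on
an analytic phantom (`phantom_config()`, `render_dense_images()`) built to
make every downstream quantity exactly checkable:

* **Motion.** A contracting, twisting annulus: material point $(R,
  \Theta)$ maps to $r = R(1 - c(t) w(R))$, $\theta = \Theta + \tau(t)$,
  plus a rigid bulk translation, all sharing one smooth systole/diastole
  time course. The transmural weighting $w(R)$ falls linearly from 1 at
  the endocardium to $1 - 0.25$ at the epicardium, so the endocardium
  strains more, as in a real ventricle. Because the map is axisymmetric,
  the circumferential Green–Lagrange strain is closed-form,
  $E_{cc} = (\lambda^2 - 1)/2$ with $\lambda = r/R$; the radial map is an
  invertible quadratic, so the Eulerian displacement a DENSE phase image
  encodes is also exact. Defaults (peak contraction 0.18, twist 6 deg,
  translation (2, 1) mm, peak at 40 % of the cycle) give a peak mid-wall
  $E_{cc} \approx -0.16$, typical of a healthy mid-ventricular slice.
* **Signal.** Per encoding (phase reference, x, y) and phase cycle, the
  pixel is a stimulated echo with phase
  $\phi_{bg} + 2\pi k_e u_{x|y}$ ($k_e = 0.10$ cycles/mm), whose sign
  alternates across the two phase cycles, plus a static, cycle-invariant
  artifact (T1-recovery) echo anchored at the end-diastolic annulus, both
  under a smooth shared background phase — so complex cycle subtraction
  cancels the artifact exactly and reference-encoding subtraction removes
  the background phase exactly. The stimulated echo decays exponentially
  over the cycle (`t1_decay_per_phase`), reproducing the lower apparent
  SNR of late cardiac phases.
* **Coils and noise.** Gaussian-profile ring coils with smooth phase and
  an AR(1) Toeplitz coil noise covariance; complex Gaussian k-space noise
  with that covariance, i.i.d. across samples. The injected
  $\sigma$ is *calibrated* to a requested apparent magnitude SNR
  (default 25, the high-resolution operating point), accounting for the
  object's own ringing floor in the background ROI, rather than
  hard-coded.

What the phantom deliberately does not emulate: through-plane motion and
dephasing (the 0.08 cycles/mm dephasing frequency is carried as metadata
only), off-resonance and fat signal, realistic electromechanics, or
view-sharing. Passing tests therefore demonstrate correctness of the
method's mechanics and direction-of-effect on ideal spiral data, not
in vivo performance.

# Reconstruction

The forward model (`forward_sample()`) is an exact type-2 nonuniform DFT
of the coil-weighted images at the spiral sample locations; the
reconstruction (`adjoint_nufft_recon()`) is the exact adjoint with an
analytic ramp density compensation (weights $\propto |k|$, floored at half
the radial Nyquist spacing, normalised to sum to one so a centred delta
reconstructs to peak 1). The trajectory is a uniform-density Archimedean
spiral with $n_{turns} = N/(2 N_{sp})$ so the combined interleaves meet
radial Nyquist; the azimuthal sample count defaults to the Nyquist arc
length and a design below 85 % of it errors unless explicitly allowed.
An exact (matrix) transform was chosen over an approximate gridding kernel
because at validation problem sizes it is affordable, makes the
forward/adjoint inner-product identity hold to machine precision, and
still exhibits the gridding-induced noise correlation the threshold
calibration exists to absorb; the calibration is defined against whatever
reconstruction path is used, and shares one code path with it. Multicoil
noise is pre-whitened by the inverse Cholesky factor of the empirical coil
covariance (`estimate_prewhitener()`), with coil sensitivities transformed
into the same basis for combination. Gradient-delay and off-resonance
corrections are exposed as pass-through hooks (`correction_hooks()`), as
their internals are scanner-specific.

# Strain analysis

After denoising: complex cycle subtraction (`combine_phase_cycles()`),
phase-preserving coil combination $\sum_c S_c^\ast I_c / \sum_c |S_c|^2$
(`coil_combine()`), phase-difference to the reference encoding,
quality-guided region-growing unwrapping with a temporal-consistency pass
anchored at the zero-displacement first frame (`unwrap_phase()`), and
$u = \Delta\phi / (2\pi k_e)$ (`phase_to_displacement()`).

The encoded displacement is Eulerian — the displacement of the tissue
currently at each pixel relative to its reference position — so
`compute_ecc()` estimates the *inverse* deformation gradient
$G = \partial X/\partial x = I - \nabla u$ on the pixel grid
(mask-normalised Gaussian-smoothed central differences), inverts it per
pixel to $F$, forms $E = (F^T F - I)/2$, and projects on the
circumferential direction at the recovered reference position
$X = x - u$. Rigid motion gives exactly zero strain in this formulation,
and the analytic phantom provides the oracle for everything else.
Six equal 60-degree sectors about the ventricular centre, labelled in the
AHA mid-cavity order from a configurable angular reference, yield
per-segment per-frame means and SDs (`segment_stats()`); empty segments
are reported missing, not zero.

Numerical choices: derivative smoothing defaults to 1 px (at the native
1.2 mm resolution); Green–Lagrange strain is the default with an
engineering-strain flag; masks with fewer than a handful of interior
pixels trigger a warning and stronger smoothing; disconnected mask regions
unwrap independently with a warning.

# Validation conditions and problem sizes

The full high-resolution protocol (128$^2$ matrix over 156 mm, 24 coils,
20 phases, 2784 readout points on 4 interleaves) is the package default.
The test-suite and the acceptance script run a scaled replica chosen to
keep the suite fast while preserving the quantities that drive the
method's behaviour:

* 64$^2$ matrix over 128 mm (2 mm pixels), 8 coils, 10 phases, 2 cycles,
  3 encodings; spiral at the azimuthal-Nyquist default;
* annulus radii 14–30 mm, so the wall is ~8 px thick — the same wall
  sampling as the high-resolution protocol (10 mm / 1.2 mm);
* strain-derivative smoothing held constant in *physical* units
  (1.2 mm, i.e. 0.6 px at the 2 mm fixture): at coarser pixels a 1 px
  kernel would smooth more anatomy in mm terms and change what the strain
  estimator measures;
* apparent magnitude SNR operating point 25, with noise-level calibration
  as above; Monte-Carlo calibration at the spec's 10 realizations;
* the grouping/patch-size ablation runs at 48$^2$ with 6 coils and
  8 phases.

The identity-reconstruction check (Cartesian FFT of fully sampled i.i.d.
noise must give bound ratios near 1) uses the full-size Casorati
dimensions (432 x 120) on a small patch grid, since the MP law is
asymptotic in the matrix dimensions, not the image size.

# Known limitations

* The exact NDFT scales quadratically; full 128$^2$/24-coil runs are
  minutes-scale, and a kernel-based NUFFT would be the natural extension
  for routine use (the calibration-key mechanism already isolates the
  reconstruction path so a different gridder only requires recalibration).
* Thresholds assume the patch's smallest Gram eigenvalue sits at the
  noise floor; for patches whose signal rank approaches $\min(p, q)$ the
  threshold inflates and denoising weakens (conservative failure mode).
* The phase unwrapper is quality-guided region growing; pathological
  aliasing (displacements far beyond $1/(2 k_e)$ between neighbouring
  pixels) would need the more elaborate spatiotemporal unwrappers used by
  clinical DENSE tools.
* Segmental statistics use fixed sectors about a fixed centre rather than
  material sectors tracked with the tissue; with the phantom's modest
  translation the mixing across sector borders is small, but it is a
  convention, shared between the compared pipelines.
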