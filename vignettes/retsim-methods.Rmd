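---
title: "Simulating AOSLO image capture of the cone mosaic: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating AOSLO image capture of the cone mosaic: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(retsim)
```

retsim produces synthetic video frames of the human cone photoreceptor
mosaic as they would be captured by an adaptive-optics scanning laser
ophthalmoscope (AOSLO), together with exact ground truth for every quantity
an image-processing algorithm might try to recover: cone positions, sizes
and reflectances; the eye-motion trace sample by sample, with every
microsaccade, drift period and tremor parameter labelled; the residual
wavefront; and the noise seed. This vignette explains each model in the
pipeline, the defaults and their units, the numerical choices, and what the
generator does *not* emulate.

## 1. The self-organised cone mosaic

Cone positions come from the Gray-Scott reaction-diffusion system, a
two-species model (`u`, `v`) whose kinetics

$$\partial u/\partial t = D_u \nabla^2 u - u v^2 + f (1 - u), \qquad
  \partial v/\partial t = D_v \nabla^2 v + u v^2 - (f + k)\, v$$

self-organise, for suitable feed/kill rates, into a pseudo-hexagonal array
of round spots — cells pack without gaps or overlap and without assuming a
hexagonal scaffold. The spot recipe is `Du = 0.14`, `Dv = 0.06`,
`f = 0.035`, `k = 0.065`, integrated by explicit Euler with `dt = 1` on a
`300 x 300` grid for 20,000 steps (`gs_state()`, `step_gray_scott()`); as a
stability rule of thumb, spots stay round while `Du >= 2 Dv`, and the
integrator aborts with the step index if a coefficient choice diverges.
Making `Dv` increase with radius produces a foveated mosaic whose spacing
grows away from the centre.

Numerical choices the model itself does not dictate:

* **Laplacian and boundary.** 5-point stencil; periodic boundary by
  default (no edge artefacts in the cropped interior), zero-flux for
  foveated runs so the pattern is not toroidal.
* **Seeding.** `u = 1, v = 0` everywhere (a fixed point) with a small
  central square at `u = 0.5, v = 0.25` plus ±0.02 uniform noise; the
  pattern grows outward from the centre.
* **Extended bounding box.** Patterns are generated on a grid larger than
  the field that is used and `rd_cone_positions()` keeps only the central
  80% in each dimension, so detected centres are free of boundary effects.
* **Peak detection.** Spot centres are strict 3x3 local maxima of the
  final `v` field above a relative threshold, refined to sub-pixel accuracy
  by separable quadratic fits. Shallow, still-forming spots can carry twin
  maxima; peaks closer than half the median nearest-neighbour distance are
  merged to their midpoint. Any method accurate to half a pixel would do as
  well — nothing downstream depends on this choice.

### Scaling to human geometry

The dimensionless pattern is scaled so its mean nearest-neighbour spacing
matches a cone-density model at the requested eccentricity. Density
$\rho$ converts to spacing via $s = (2\rho/\sqrt{3})^{-1/2}$; note this $s$
is the hexagonal *row* spacing ($\sqrt{3}/2$ times the centre-to-centre
distance), so its algebraic inverse is $\rho = \sqrt{3}/(2 s^2)$. The
embedded density table (cones/mm², 0.5-10 degrees, log-linearly
interpolated) is an approximate in-vivo model on the lower side of
histological counts, consistent with densities measured from adult AOSLO
images away from the foveal centre; it is deliberately user-overridable
(`cone_density(table = ...)`) and its absolute accuracy is not something
any of the package's tests depend on. Angular conversion uses 288 um/deg
for a 24 mm schematic eye, scaled linearly by axial length — a longer eye
squeezes the same retinal spacing into a smaller visual angle.

### Cone parameters

Each cone is a Gaussian blob with parameters (mu_x, mu_y, sigma_x, sigma_y,
theta, A). Widths follow the Marcuse estimate of the fundamental-mode field
radius of a step-index waveguide, $w = a(0.65 + 1.619 V^{-3/2} + 2.879
V^{-6})$, with the core radius from an approximate histological
inner-segment diameter (`2.2 + 0.55 * ecc` um) and default indices
`n_core = 1.39`, `n_clad = 1.34` (both configurable). The rendered Gaussian
uses `sigma = w / sqrt(2)` — the field-amplitude profile — rather than the
strict intensity profile (`w / 2`); reflective imaging of waveguiding cones
sits between the two conventions and the chosen one keeps rendered cone
FWHMs close to what AOSLO images of the corresponding eccentricities show.
The single-mode Gaussian approximation is good inside ~3 degrees and
acceptable to ~7; beyond that real cones become multimodal and this
generator underestimates their structural complexity.

Reflectances are `Normal(1, 0.2)` clipped at zero, multiplied by a smooth
random modulation field (Gaussian correlation length 15 arcmin, relative
sd 0.3, normalised to unit mean) that reproduces the patchy large-scale
brightness of real mosaics. No reflectance statistics are printed for the
instrument being emulated, so these are explicit stand-ins chosen to look
right; both knobs are arguments of `assign_reflectances()`. A per-cone
reflectance-versus-time callback can replace the static `A` when simulating
bleaching or intrinsic signals; the scanned-beam arrival time at each cone
is then the sampling time.

The analytic retina is `R(x, y) = sum_i A_i exp(-(a dx^2 + 2 b dx dy +
c dy^2))` with the standard rotated-Gaussian coefficients; `render_retina()`
evaluates it exactly at pixel centres, so rendering is linear in `A` and
translation-equivariant by construction.

## 2. Fixational eye movements

`generate_eye_trace()` builds a trace at 1 kHz from three components:

| component | parameter | default (mean, sd) | convention |
|---|---|---|---|
| microsaccade | amplitude | 30, 3 arcmin | trace displacement |
| microsaccade | interval | 1.0, 0.5 s | onset to onset |
| tremor | centre frequency | 65, 7.5 Hz | Gaussian band centre |
| tremor | bandwidth | 25, 2.5 Hz | Gaussian FWHM |
| tremor | amplitude | 0.08, 0.03 arcmin | segment RMS |
| drift | amplitude | 6.5, 0.7 arcmin | peak displacement from segment start |

Every per-event parameter is drawn fresh from its normal distribution
(truncated at zero) and logged in the event table, so parameter-recovery
studies can compare what a motion-extraction algorithm measures against
what was drawn.

Drift is synthesised from random spectral phases with a $1/f^2$ power
spectrum; tremor is white noise filtered by a Gaussian magnitude profile
and superimposed on drift. Microsaccades are ballistic: a raised-cosine
velocity profile (smooth, monotone displacement, zero velocity at both
ends) whose peak velocity follows the main sequence `v_peak = c * A^m` with
`m = 1` and `c = 70 /s`, giving ~29 ms durations at the default amplitude.
The literature supports log-log linearity but pins down neither constant;
both are arguments.

Two choices deserve flagging:

* **Interval truncation.** Intervals are redrawn when outside
  `[0.2, 1.8] s` — a *symmetric* window about the 1.0 s mean. A one-sided
  floor at 0.2 s would inflate the realised mean by ~6%, which would be
  visible to any algorithm validated against the configured value; the
  symmetric window enforces the minimum separation while preserving the
  mean exactly.
* **Centering.** Real fixation keeps gaze near the target, but whether
  microsaccades or drift do the correcting is debated. Here, whenever gaze
  exceeds half the containment radius (default bounds 60 arcmin), the next
  microsaccade points centre-ward with 15-degree Gaussian jitter; otherwise
  directions are uniform. This guarantees the trace never strays further
  than the bounds plus one microsaccade, without imposing statistics on
  drift.

## 3. Raster scan and desinusoiding

The fast (horizontal) scanner is resonant, so the beam position across a
line is sinusoidal and time-uniform samples are spatially compressed at the
line edges; the slow (vertical) scanner is a sawtooth with a flyback
fraction (default 5%) during which no samples are taken. Only the central
80% (duty cycle) of the forward sweep maps to image columns, as in real
systems. Defaults — 15.6 kHz line rate, 512 lines and samples, hence
~28.9 Hz frames — are typical-AOSLO stand-ins, not measurements of any
particular instrument, and every constant is an argument of
`scan_config()`.

Eye displacement is linearly interpolated at each sample time and added to
the scan position; this is what turns a mid-frame microsaccade into the
characteristic intra-frame shear or stretch. `desinusoid()` resamples each
line from time-uniform to space-uniform abscissae by cubic spline against
the sine position — the identical operation applied to real detector
streams — and the sine used for desinusoiding may deliberately differ
(phase, duty) from the one used for generation, to emulate calibration
error. Desinusoiding remaps space only; the non-uniform *temporal* sampling
of eye motion across a line is a property of the raw stream and is
preserved.

Noise is additive Gaussian, by default applied to the raw sample stream
before desinusoiding (mean 0, sd 2% of signal full scale — the real
instrument's noise figures are not published, so this is a plausible
default). If noise is instead added after desinusoiding it must itself be
warped: desinusoiding gives noise a non-flat column-variance profile, and
adding unwarped noise to a desinusoided frame would be statistically wrong
near the line edges. `add_noise(stage = "post_with_warp")` does the warp.

## 4. Double-pass confocal optics

PSFs come from the pupil function by discrete Fourier transform:
`PSF = |FT(A(rho) exp(i 2 pi W / lambda))|^2`, where `W` is a sum of ANSI
single-index Zernike polynomials (coefficients in um RMS) and `A` is the
pupil amplitude, optionally Gaussian-apodized to model the optical
Stiles-Crawford effect. Defaults: 7.2 mm pupil, 840 nm, diffraction-limited
(the validation figures use 5 mm to match a dilated adult pupil).

Capture of one sample follows the confocal sequence: multiply the retina by
the beam-centred input PSF (illumination), convolve with the output PSF
(re-imaging onto the pinhole), multiply by the pinhole transmission (unit
disc, default diameter 1 Airy unit, anti-aliased rim), and sum (detector
integration). While the PSFs are constant over a frame this collapses
algebraically to a single correlation with the *effective kernel*
`K = PSF_in . (PSF_out (x) pinhole)`; `capture_frame_fast()` uses that
identity and agrees with the explicit per-sample path to FFT round-off
(~1e-15 in practice, tested at 1e-6). Limits behave as confocal theory
requires: a point pinhole gives `K = PSF_in . PSF_out`, whose transfer
function is the autocorrelation of the single-pass OTF (the classic
double-pass statement); a wide-open pinhole degrades `K` to `PSF_in` alone.
Input and output PSFs are equal by default but may differ.

**Sampling rule.** The analytic retina is rendered on a fine grid at
`output pixel / oversample`; `oversample >= 2` is enforced and 4 is the
default — frames rendered at 4x differ from 10x renders by well under 1% of
frame energy, and the difference falls monotonically with the factor.
**Edges.** The retina is rendered with a guard band covering the kernel
half-width plus the actual gaze excursion of the run; a beam that would
read outside it is an error, never a wraparound.

## 5. End-to-end runs and determinism

`generate_dataset()` chains the stages and returns frames, raw streams and
the full ground truth; a single integer seed fixes the entire run, and
identical configurations are bit-identical. The reference frame is the same
pipeline with motion, aberrations and noise disabled (diffraction-limited,
scan-free-of-motion), so with all three flags off every frame *equals* the
reference — a property the test suite asserts exactly. Disabling one
degradation at a time changes only its own signature (pixel variance for
noise, intra-frame geometry for motion, spectral attenuation for blur).
For display, `intensity_scale()` linearly scales and clips so that an exact
pixel fraction saturates (default 10%, matching the saturated fraction of
the real detector gain being emulated).

## 6. Validation metrics

Packing regularity uses three statistics over interior cones — Voronoi
neighbour count, nearest-neighbour distance, vertex angle (the angle at a
cone between its nearest neighbour and their closest common Voronoi
neighbour) — each summarised as sd/mean (sd/60 degrees for the angle), so a
perfect hexagonal lattice scores exactly zero on all three. Choices the
statistics leave open: *strict adjacency* counts only Voronoi edges of
positive length (a square lattice then has 4 neighbours, not 8 through the
degenerate corners); *border cells* — any cell clipped by the analysis
window or reaching outside the convex hull of the points — are excluded
from sampling, since some of their true neighbours are missing;
*closest common neighbour* minimises the summed distance to the pair, ties
to the smaller index. A uniform-random mosaic of equal cone count (no
minimum-spacing constraint) provides the fully irregular reference; the
self-organised mosaics score far below it on all three metrics.

Spectral validation computes a Hann-windowed, radially averaged power
spectrum in cycles/degree. The modal cone-spacing frequency (Yellott's
ring) is the spectrum's peak above a low-frequency exclusion of
max(2 bins, 10 c/deg); the 10 c/deg floor skips the band occupied by the
reflectance-modulation field (correlation length 15 arcmin), which
otherwise outweighs the MTF-attenuated ring at small eccentricities, while
the ring itself stays between ~15 and ~60 c/deg over the modelled range.

## 7. Problem sizes used in the tests

The shipped tests run the full printed recipe (300 x 300, 20,000 steps) for
the packing and spectral checks; capture-path equivalence and oversampling
convergence use 40-48 px frames with 4 arcmin kernels, where the properties
under test are scale-free; eye-movement statistics use 60-1100 s traces
(1000+ events) at the 1 kHz default rate. These sizes were chosen so the
whole suite exercises every pipeline stage at full fidelity while staying
quick enough to run habitually.

## 8. What passing tests do and do not show

The generator reproduces the *statistical* structure of cone images —
packing geometry between hexagonal and random, plausible spectra, realistic
motion distortion and noise — with exact ground truth. It does not emulate:
rod intrusion between cones (rising beyond ~4 degrees and a known confound
for labelling); multimodal cone profiles beyond ~7 degrees; blood-vessel
shadows; anisoplanatism (a single PSF is applied across the field, a
coarse approximation beyond ~2 degrees); 3-D sectioning or multiply
scattered light (split-detection and dark-field geometries); and AO
control-loop dynamics (aberrations enter as per-frame Zernike tables, not
as closed-loop residuals). Algorithms validated purely on these synthetics
should therefore expect some degradation on real data at large
eccentricities and near vasculature.
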