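---
title: "Localizing fixed dipole emitters with astigmatic imaging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing fixed dipole emitters with astigmatic imaging: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipoleloc)
```

## The problem

In single molecule localization microscopy (SMLM) performed at cryogenic
temperature, fluorophores cannot rotate: each emitter behaves as a *fixed
dipole*. Two things change relative to room-temperature SMLM. First, the
image of a fixed dipole is not a Gaussian-like spot — it is an
orientation-dependent, generally asymmetric interference pattern, and for a
tilted dipole the apparent center of that pattern moves laterally as the
emitter defocuses. Second, cryostats force long-working-distance air
objectives with numerical apertures around 0.7, so the patterns are smooth
and a defocused tilted dipole is nearly indistinguishable from a laterally
shifted one. Fitting a Gaussian, or fitting the correct model with the
defocus unknown, can therefore be biased by tens of nanometers — ruinous at
the 1 nm precision scale that the high cryogenic photon yields
(N ~ 5×10^5 per emitter) would otherwise allow.

`dipoleloc` implements the remedy studied in this package's benchmarks:
introduce *deliberate weak vertical astigmatism* so the PSF ellipticity
encodes the sign and magnitude of the defocus, assume the dipole orientation
is available (e.g. from polarized excitation), and estimate position and
defocus jointly, `ξ = (x, y, d)`, by maximum likelihood under the Poisson
pixel model. The package provides the vectorial PSF model, a seeded forward
simulator, the fitter, Fisher-information/Cramér-Rao-bound (CRB)
calculators, and ensemble benchmarking utilities that compare the achieved
precision against the bound.

## Image formation model

A dipole with inclination `θ` (0 = optical axis) and azimuth `φ` sits at the
water/air interface (`n1 = 1.33` sample, `n2 = 1` immersion) in the focal
plane of an aplanatic air objective (NA 0.7, 60×, tube lens f = 180 mm,
emission λ = 680 nm). The back-focal-plane field is assembled from the
standard angular-spectrum treatment of dipole radiation at a planar
interface:

* pupil radius ρ ∈ [0, 1] maps to the air-side polar angle via
  `n2 sin θ2 = NA·ρ`; Snell's law gives the sample-side angle θ1;
* the dipole far field is decomposed into s/p components at θ1 and
  multiplied by the Fresnel transmission coefficients `t_s(θ1)`, `t_p(θ1)`
  (all angles are subcritical because NA < n2 < n1, so the field is real);
* the stationary-phase Jacobian `n2 cos θ2 / (n1 cos θ1)` of the
  angular-spectrum continuation and the aplanatic apodization
  `1/√(cos θ2)` are applied;
* after the objective the field is transverse, so two Cartesian components
  suffice (the axial information lives in the radial p-component).

Aberrations enter as a pupil phase `exp(i 2π W/λ)` with
`W = Σ_j w_j Z_j` expanded in *orthonormal* (unit-RMS) Zernike polynomials
with Noll indexing. In this convention the RMS wavefront error of a single
mode equals `|w_j|`, so coefficients carry nanometers; the standard
astigmatism used throughout is `w6 = 0.11 λ ≈ 74.8 nm` RMS. The defocus `d`
is a continuous model parameter, not a Zernike coefficient: by default it is
applied as the exact air-side axial phase `(2π/λ) n2 d cos θ2`
(`defocus_model = "exact_air"`), with `"exact_sample"` and a paraxial
pure-Z4 `"zernike"` variant available for comparison. The exact phase,
rather than the paraxial Z4, is what reproduces the measured ~1.3–1.4 μm
separation of the two astigmatic line foci for this calibration
(`astigmatic_foci_separation()` computes it by a defocus scan of the
second-moment widths).

The image-plane field is the Fourier transform of the pupil field. With all
lateral quantities expressed in object space, the transform kernel reduces
to `exp(-i (2π NA/λ)(x u + y v))`; the quadratic phase prefactor of the
exact Fresnel integral is dropped because it cancels in the normalized
intensity. The intensity is sampled on a subpixel grid (*oversampling*: 9
per pixel axis for simulation, 3 for fitting — the classic
accuracy/speed compromise), summed into 108.3 nm camera pixels, and
normalized to unit sum over the computed 17 × 17 ROI. An emitter shift
`(x, y)` is a pure coordinate shift of the continuous intensity, applied as
a pupil tilt inside the same transform.

## Numerical evaluation

Pupil integrals are midpoint sums on a 128 × 128 cell-centered Cartesian
grid. Two details matter for clean `O(h²)` convergence: cells cut by the
aperture rim are weighted by their exact area coverage (an anti-aliased
aperture), and the Zernike phase at those rim cells is evaluated at the
radially clamped coordinate so the phase has no spurious jump across the
rim. With these, refining 128 → 256 pupil samples changes normalized PSF
pixels by less than 10⁻⁴ of the peak, and further refinement is not
measurable against any quantity the package reports; 128 is the default
(`pupil_samples` in `optical_config()`).

The transform from pupil to image grid is evaluated as two complex matrix
products (BLAS), not an FFT: arbitrary subpixel positions and grids then
need no interpolation or padding, and at 17 × 17 × oversampling scale the
products are faster than padding-based FFTs. `psf_renderer()` precomputes
the pupil field and kernels for a fixed (orientation, aberration, optics)
context, so one render costs two products per field component — a few
milliseconds — which is what the simulator, the Fisher calculator and the
table builder use.

The *fit* objective must be evaluated hundreds of times per frame, so it
uses a precomputed lookup table of the continuous intensity (lateral
spacing pixel/9, defocus planes every 25 nm over ±900 nm) interpolated by
separable Catmull–Rom cubics in `(x, y, d)` — the same strategy as
spline-PSF fitters in the SMLM literature. The interpolant is an explicit
piecewise polynomial, so the objective gradient is exact for the tabulated
model; agreement with the direct Fourier model is ~10⁻⁶ relative and is
gated by a test. Positions outside the tabulated box (|x|, |y| > 250 nm,
|d| > 850 nm) are clamped with a quadratic penalty so the unconstrained
optimizer is pushed back into the domain; ground-truth positions
(|x|, |y| ≤ 108 nm, |d| ≤ 500 nm) sit well inside.

## Forward simulator

`simulate_frames()` draws ground truth and renders frames under the Poisson
camera model:

* positions uniform in the central 216 × 216 nm of the ROI (about 2 × 2
  pixels), defocus fixed or cycled over a grid (the benchmark grid is −500
  to 500 nm in 100 nm steps);
* expected counts `ν_k = N_eff · PSF_k + b²` per pixel, where `b` is the
  *standard deviation* of the Poisson background — parameterizing its mean
  as `b²` is the only reading that makes a Poisson background with standard
  deviation `b` and a fitted "mean background `b²`" simultaneously true;
* observed counts `z_k ~ Poisson(ν_k)` independently per pixel;
* under polarized excitation the photon yield couples to orientation:
  `N_x = N_max sin²θ cos²φ`, `N_y = N_max sin²θ sin²φ`,
  `N_eff = N_max sin²θ` (an axial dipole is never excited). The coupling is
  off by default — the headline benchmarks deliver `N = 5×10⁵` photons
  regardless of orientation — and `excitation_coupling = TRUE` enables it.
* `orientation = "random"` draws hemisphere-uniform directions
  (`θ = arccos U`), the measure a rigid label with no preferred orientation
  produces; `"uniform_angles"` is available as an alternative.

Every stack is bit-reproducible from its seed; child seeds per frame (and
per condition/repetition in ensembles) are derived and recorded, so any
subset can be regenerated independently.

What the simulator deliberately omits — and what passing benchmarks
therefore do not establish for real data: camera read noise, gain and
offset (pure photon counting is assumed), spatially varying background,
emitter depth below the interface (the dipole sits at the focal plane, so
no depth-dependent aberration), overlapping emitters, blinking or
photobleaching kinetics, and aberrations beyond the supplied Zernike
coefficients. The PSF mass falling outside the computed ROI is
renormalized into it, consistently between simulation and fitting.

## Estimation

Per frame, the pipeline mirrors a practical workflow:

1. background mean `b²` estimated as the mean of a signal-free frame
   (`estimate_background()`);
2. photon number estimated by summing background-corrected pixels
   (`estimate_neff()`);
3. starting values drawn at random — `(x, y)` uniform in a 2 × 2 pixel box
   about the ROI center, `d` uniform in (−500, 500) nm — and refined by a
   non-linear least-squares fit (`least_squares_init()`);
4. the Poisson negative log-likelihood, recentred on the saturated model so
   its scale is O(pixels) and the optimizer's relative termination test is
   scale-free, is minimized by unconstrained BFGS with the exact gradient
   of the tabulated model (`mle_localize()`); failed optimizations are
   retried with fresh random starts (3 by default) and flagged if still
   unsuccessful, with counts reported so ensembles are auditable.

The `ln(z_k!)` likelihood term is constant in the parameters and dropped.
A `likelihood = "normalized"` mode divides data and model by the total
detected photons — the recipe used on normalized images — which rescales
the objective without moving its minimizer; the two modes agree on the
estimate to optimizer tolerance (test-gated). When the supplied orientation
is itself an estimate, `orientation_input = "noisy"` perturbs it per frame
with Gaussian errors (defaults 2° in each angle; 4°/2° is the asymmetric
variant reflecting the harder inclination measurement — both quoted as
standard deviations, the reading consistent with the benchmark figure
captions). Modes that fit `θ` or `(θ, φ)` as well use the direct Fourier
model with numerical gradients, since a lookup table per orientation would
defeat its purpose; angles are optimized unconstrained and wrapped into
`θ ∈ [0, π/2]`, `φ ∈ [0, 2π)` afterwards using the antipodal equivalence
of dipole emission.

## Fisher information and the Cramér-Rao bound

For the Poisson pixel model the Fisher information over `ξ = (x, y, d)` is
`I = Σ_k (∂ν_k/∂ξ)ᵀ(∂ν_k/∂ξ)/ν_k`. The derivatives are central difference
quotients (1 nm lateral, 2 nm defocus steps; halving the steps moves
entries by < 0.5%, test-gated), evaluated on the oversampling-9 model that
also generates the data. Pixels with expected counts below 10⁻¹² photons
are excluded — they carry no photons and the 1/ν weight is undefined at
zero. `crb()` reports the square roots of the diagonal of `I⁻¹`;
degenerate conditions fail loudly naming the unidentifiable parameter
(an axial dipole without astigmatism at focus cannot encode `d`; an axial
dipole under excitation coupling yields no photons at all). The bound
treats `N_eff` and `b²` as known constants, matching the three-parameter
`ξ`; it therefore slightly understates the uncertainty of the practical
pipeline, which estimates both from data.

## Benchmarks and their scale

`run_ensemble()` executes a condition — orientation, defocus grid, photon
budget, background, astigmatism, fit configuration, repetitions — with a
per-(grid point, repetition) seed hierarchy, and `precision_bias()` reduces
it to the bias `μ` (mean error) and precision `σ` (sample standard
deviation of the error, n−1 denominator) per parameter, with standard
errors `σ/√n` and `σ/√(2(n−1))`. `crb_comparison()` forms `σ/√CRB` with a
configurable ceiling, flagging ratios so far below 1 that an unbiased
estimator could not produce them. The test suite runs the benchmark grid
(θ ∈ {π/2, π/3, π/6}, φ = π/4, 11 defocus values, b ∈ {0, 100}) at 500
repetitions per point: at that size the sampling error of `σ̂` is 3.2%, so
the 1.15 attainment ceiling sits several standard errors above perfect
attainment and the check probes the estimator rather than the Monte Carlo
noise. The headline precision checks (σ_x below 2 nm at b = 100 and below
6 nm at b = 300) use 100-frame ensembles; calibration quantities (wavefront
RMS, pixel size, foci separation, CRB floor) are deterministic.

One benchmark deserves a caveat. In the original study, fitting *without*
astigmatism produced lateral biases up to ~50 nm for tilted dipoles at
large defocus, attributed to the optimizer being trapped by the
near-degeneracy between ±d (whose patterns are point reflections of each
other, displaced by tens of nm for a tilted dipole). In this
implementation the profiled likelihood over defocus for those conditions
is unimodal, and the tight-tolerance exact-gradient optimizer essentially
never gets trapped: the no-astigmatism bias measures ~1 nm, not ~50 nm,
even though the model reproduces the underlying pattern displacement
(~70 nm between the ±d hypotheses at d = ±500 nm). The effect is thus an
optimizer property, not a model property, and we chose not to degrade the
optimizer to reproduce it; the corresponding acceptance check is expected
to fail and says so honestly.

## Design decisions that were genuinely open

* **Zernike units.** The only calibration anchor (w6 = 0.11λ ↔ ~75 nm RMS)
  is consistent only with unit-RMS polynomials and length-unit
  coefficients; that convention is adopted everywhere.
* **Defocus convention.** `d` is an axial displacement phase, not a static
  Z4 coefficient; the exact air-side form is the default because it
  reproduces the printed foci separation, and the alternatives remain
  selectable.
* **Background parameterization.** Mean `b²`, standard deviation `b` (see
  above).
* **Raw-count likelihood by default.** Normalizing the image makes the
  counts non-integer and the factorial term ill-defined; on raw counts the
  same minimizer is obtained with a statistically conventional objective.
  The normalized variant is retained and test-gated for equivalence.
* **Lookup-table fit model.** Chosen over per-iteration Fourier sums purely
  for speed; equivalence to the direct model is enforced by tests rather
  than assumed.
* **Orientation error magnitudes** are standard deviations in degrees
  (2°/2° and 4°/2°), the reading consistent between the text and figure
  captions of the source protocols.

## Limitations

Beyond the simulator omissions listed above: the model assumes the
astigmatism (and any other supplied aberration) is known exactly, as for a
calibrated setup; orientation-fitting modes are provided but slow (direct
model per iteration) and, consistent with the benchmarks, substantially
less precise than supplying an orientation estimate; the CRB calculator
covers `ξ = (x, y, d)` only, not the orientation angles; and nothing here
addresses the upstream SMLM steps (detection, segmentation, drift) — the
fitter consumes single-emitter ROI stacks.
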