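# dipoleloc

Bias-free localization of fixed fluorescence dipole emitters under low-NA
astigmatic imaging — the regime of cryogenic single molecule localization
microscopy (cryo-SMLM).

At cryogenic temperature fluorophores cannot rotate, so each emitter is a
**fixed dipole**: its image is an orientation-dependent interference pattern
whose apparent center shifts laterally with defocus. With the long-distance
air objectives (NA ≈ 0.7) that cryostats force, a defocused tilted dipole is
nearly indistinguishable from a laterally shifted one, and naive fitting is
biased by tens of nanometers — while the high cryogenic photon yields
(N ≈ 5·10⁵) would in principle allow ~1 nm precision. `dipoleloc`
implements the astigmatic-imaging remedy: weak vertical astigmatism
(Zernike Z6, w₆ = 0.11 λ ≈ 75 nm RMS) encodes the defocus in the PSF
ellipticity, the dipole orientation (θ, φ) is supplied (e.g. from polarized
excitation, with yields N_x = N_max sin²θ cos²φ, N_y = N_max sin²θ sin²φ),
and the position and defocus ξ = (x, y, d) are estimated jointly by maximum
likelihood under the Poisson pixel model

&nbsp;&nbsp;ν_k = N_eff · PSF_k(x, y, d; θ, φ) + b²,&nbsp;&nbsp;
z_k ~ Poisson(ν_k),

with the vectorial dipole PSF computed from the back-focal-plane field of a
dipole at the water/air interface (Fresnel s/p transmission, aplanatic
apodization, orthonormal Zernike aberrations, exact air-side defocus
phase). The precision benchmark is the Cramér-Rao bound
Var(ξ̂_k) ≥ (I⁻¹)_kk with I = Σ_k (∂ν_k/∂ξ)ᵀ(∂ν_k/∂ξ)/ν_k.

The package provides, as composable tidyverse-style functions:

* `psf_image()`, `bfp_field()`, `image_field()`, `psf_renderer()` — the
  vectorial PSF model (`zernike_polynomial()`, `build_wavefront()` for the
  aberration basis; `astigmatic_foci_separation()` for calibration);
* `simulate_frames()`, `sample_ground_truth()`, `render_frame()` — the
  seeded Poisson camera simulator (TIFF + CSV export via `write_frames()`);
* `mle_localize()`, `fit_frames()`, `estimate_background()`,
  `estimate_neff()`, `least_squares_init()` — the least-squares-initialized
  MLE fitter (fast spline-table model with exact gradients);
* `fisher_matrix()`, `crb()`, `crb_grid()` — Fisher information and CRB;
* `ensemble_condition()`, `run_ensemble()`, `precision_bias()`,
  `crb_comparison()`, `roi_size_sweep()` — seeded benchmarking with
  `tidy()`/`glance()`/`autoplot()` methods;
* a thin command-line wrapper (`inst/cli/dipoleloc`, subcommands
  `psf | simulate | fit | crb | benchmark`) over `cli_dispatch()`.

## Worked example

Simulate five frames of an inclined dipole (θ = π/3, φ = π/4) at 150 nm
defocus with 5·10⁵ photons and background standard deviation b = 100, then
fit position and defocus with the true orientation supplied:

```r
library(dipoleloc)
cfg   <- optical_config()                                   # NA 0.7, 60x, 680 nm
astig <- zernike_coefficients(astigmatism_rms_nm = 0.11 * 680)

sim  <- simulate_frames(5, defocus = 150, orientation = c(pi/3, pi/4),
                        cfg, astig, acquisition_params(background_sd = 100),
                        seed = 42)
fits <- fit_frames(sim, cfg, astig, background_mean = 100^2, seed = 42)
dplyr::select(fits, x_nm, y_nm, d_nm, fit_x_nm, fit_y_nm, fit_d_nm, fit_converged)
#> # A tibble: 5 × 7
#>    x_nm   y_nm  d_nm fit_x_nm fit_y_nm fit_d_nm fit_converged
#>   <dbl>  <dbl> <dbl>    <dbl>    <dbl>    <dbl> <lgl>
#> 1  89.6   4.12   150     91.2     4.96     143. TRUE
#> 2  94.4  51.1    150     94.9    51.7      146. TRUE
#> 3 -46.2 -78.9    150    -46.7   -78.3      167. TRUE
#> 4  71.4  33.9    150     72.8    33.5      144. TRUE
#> 5  30.6  44.3    150     29.9    46.1      146. TRUE
```

True positions (drawn uniformly in the central 2 × 2 pixels) are recovered
to a nanometer or two laterally and ~10–20 nm in defocus — consistent with
the bound for this condition. The bound itself:

```r
crb_grid(pi/2, pi/4, c(-300, 0, 300), coeffs = astig)
#> # A tibble: 3 × 8
#>   theta   phi  d_nm  n_eff background_sd sqrt_crb_x_nm sqrt_crb_y_nm
#>   <dbl> <dbl> <dbl>  <dbl>         <dbl>         <dbl>         <dbl>
#> 1  1.57 0.785  -300 500000             0         0.653         0.470
#> 2  1.57 0.785     0 500000             0         0.539         0.539
#> 3  1.57 0.785   300 500000             0         0.470         0.653
```

Sub-nanometer lateral bounds, with the x/y asymmetry mirroring in d — the
signature of the two astigmatic line foci. Larger studies run through
`run_ensemble()`; `tidy()` returns per-condition bias/precision tables with
the matching bound, `autoplot()` draws them.

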