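#' Optical system description
#'
#' Immutable description of the microscope: air objective observing a dipole in
#' an aqueous sample through a cryostat-compatible low-NA system, tube lens,
#' and sCMOS sampling. Defaults describe a 60x/0.7 air objective (3 mm focal
#' length via the 180 mm tube lens), red emission at 680 nm, and 6.5 um camera
#' pixels, i.e. 108.3 nm pixels in object space.
#'
#' @param numerical_aperture Objective NA (must be < both refractive indices).
#' @param n_sample Refractive index of the sample medium (water, 1.33).
#' @param n_immersion Refractive index on the collection side (air, 1.0).
#' @param magnification Lateral magnification (tube focal length / objective
#'   focal length).
#' @param tube_focal_length_mm Tube lens focal length in mm.
#' @param wavelength_nm Emission wavelength in nm.
#' @param camera_pixel_um Physical camera pixel pitch in um.
#' @param defocus_model How the fitted defocus `d` (nm) enters the pupil phase:
#'   `"exact_air"` (default) applies `(2 pi / lambda) n2 d cos(theta2)` — an
#'   axial displacement on the air side; `"exact_sample"` uses
#'   `n1 d cos(theta1)`; `"zernike"` uses the paraxial pure-Z4 equivalent.
#' @param pupil_samples Pupil sampling per axis used by model evaluations.
#' @return Object of class `optical_config`. The derived field
#'   `object_pixel_nm` is exactly `camera_pixel_um * 1000 / magnification`.
#' @export
#' @examples
#' cfg <- optical_config()
#' cfg$object_pixel_nm  # 108.33 nm
optical_config <- function(numerical_aperture = 0.7,
                           n_sample = 1.33,
                           n_immersion = 1.0,
                           magnification = 60,
                           tube_focal_length_mm = 180,
                           wavelength_nm = 680,
                           camera_pixel_um = 6.5,
                           defocus_model = c("exact_air", "exact_sample", "zernike"),
                           pupil_samples = 128) {
  defocus_model <- match.arg(defocus_model)
  num <- list(numerical_aperture = numerical_aperture, n_sample = n_sample,
              n_immersion = n_immersion, magnification = magnification,
              tube_focal_length_mm = tube_focal_length_mm,
              wavelength_nm = wavelength_nm, camera_pixel_um = camera_pixel_um)
  for (nm in names(num)) {
    x <- num[[nm]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      stop("`", nm, "` must be a single positive finite number")
    }
  }
  if (numerical_aperture >= n_immersion) {
    stop("numerical aperture (", numerical_aperture,
         ") must be smaller than the immersion index (", n_immersion,
         "): an air objective cannot collect beyond the unity aperture angle")
  }
  if (numerical_aperture >= n_sample) {
    stop("numerical aperture must be smaller than the sample index")
  }
  structure(c(num, list(
    object_pixel_nm = camera_pixel_um * 1000 / magnification,
    defocus_model = defocus_model,
    pupil_samples = as.integer(pupil_samples)
  )), class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<optical_config> NA %.2f, %gx, f_tube %g mm, lambda %g nm\n",
    "  n_sample %.3f | n_immersion %.3f | camera px %.2f um -> %.2f nm object px\n",
    "  defocus model: %s, pupil %d x %d\n"),
    x$numerical_aperture, x$magnification, x$tube_focal_length_mm, x$wavelength_nm,
    x$n_sample, x$n_immersion, x$camera_pixel_um, x$object_pixel_nm,
    x$defocus_model, x$pupil_samples, x$pupil_samples))
  invisible(x)
}

#' Emitter state: position, defocus and dipole orientation
#'
#' @param x,y Lateral position in nm, object space, relative to the ROI center
#'   (x increases rightward, y upward).
#' @param d Defocus in nm (axial offset from the nominal focal plane).
#' @param theta Inclination angle in radians, in `[0, pi/2]` (0 = along the
#'   optical axis).
#' @param phi Azimuthal angle in radians, wrapped into `[0, 2 pi)`; irrelevant
#'   to the PSF when `theta = 0`.
#' @return Object of class `dipole_state`.
#' @export
dipole_state <- function(x = 0, y = 0, d = 0, theta = pi / 2, phi = 0) {
  for (nm in c("x", "y", "d", "theta", "phi")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number")
    }
  }
  if (theta < 0 || theta > pi / 2 + 1e-12) {
    stop("`theta` must lie in [0, pi/2]")
  }
  phi <- phi %% (2 * pi)
  structure(list(x = x, y = y, d = d, theta = min(theta, pi / 2), phi = phi),
            class = "dipole_state")
}

#' @export
print.dipole_state <- function(x, ...) {
  cat(sprintf("<dipole_state> x %.1f nm, y %.1f nm, d %.1f nm, theta %.3f rad, phi %.3f rad\n",
              x$x, x$y, x$d, x$theta, x$phi))
  invisible(x)
}

#' Acquisition parameters for the forward simulator
#'
#' @param n_max Photon budget at parallel dipole/excitation-polarization
#'   alignment (default 5e5). With `excitation_coupling = FALSE` this photon
#'   number is delivered to the PSF regardless of orientation; with coupling on
#'   the detected photons follow `N_eff = n_max * sin(theta)^2`.
#' @param background_sd Standard deviation `b` of the Poisson background in
#'   photons; the per-pixel background mean is `b^2` so that its Poisson
#'   standard deviation is exactly `b`.
#' @param roi_px ROI edge length in (odd) pixels, default 17.
#' @param oversampling Subpixels per camera pixel per axis used when rendering
#'   expected images (default 9).
#' @param excitation_coupling Logical; orientation-dependent photon yield.
#' @return Object of class `acquisition_params`.
#' @export
acquisition_params <- function(n_max = 5e5, background_sd = 0, roi_px = 17,
                               oversampling = 9, excitation_coupling = FALSE) {
  if (!is.numeric(n_max) || n_max <= 0) stop("`n_max` must be positive")
  if (!is.numeric(background_sd) || background_sd < 0) stop("`background_sd` must be >= 0")
  if (roi_px < 1 || roi_px %% 2 != 1) stop("`roi_px` must be a positive odd integer")
  if (oversampling < 1 || oversampling != round(oversampling)) {
    stop("`oversampling` must be an integer >= 1")
  }
  structure(list(n_max = n_max, background_sd = background_sd,
                 roi_px = as.integer(roi_px), oversampling = as.integer(oversampling),
                 excitation_coupling = isTRUE(excitation_coupling)),
            class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf("<acquisition_params> N_max %g, b %g (bg mean %g/px), ROI %d px, oversampling %d, excitation coupling %s\n",
              x$n_max, x$background_sd, x$background_sd^2, x$roi_px, x$oversampling,
              if (x$excitation_coupling) "on" else "off"))
  invisible(x)
}

#' Fit configuration
#'
#' Controls which parameters are estimated and how the dipole orientation is
#' supplied to the fitter.
#'
#' @param fitted_parameters One of `"xyd"` (default: position + defocus with
#'   orientation supplied), `"xydt"` (additionally fit theta, phi supplied), or
#'   `"xydtp"` (fit both angles).
#' @param orientation_input `"exact"` (true orientation supplied), `"noisy"`
#'   (supplied orientation perturbed by Gaussian errors with the standard
#'   deviations below), or `"none"` (no orientation knowledge; only valid
#'   when both angles are fitted, starting angles drawn at random).
#' @param sigma_theta_deg,sigma_phi_deg Orientation error standard deviations
#'   in degrees for `orientation_input = "noisy"`; perturbed theta is clipped
#'   to `[0, pi/2]`.
#' @param oversampling Model oversampling during fitting (default 3, a
#'   speed/accuracy compromise; simulation uses 9).
#' @param start_d_range Interval (nm) for the random defocus starting value.
#' @param start_xy_halfwidth_nm Half-width of the random lateral starting box
#'   about the ROI center (default 108.33 nm ~ a 2 x 2 pixel region).
#' @param likelihood `"raw"` (default): Poisson likelihood on raw counts;
#'   `"normalized"`: data and model both divided by the total detected photons
#'   (same optimum up to the dropped factorial term; kept for comparison).
#' @param max_restarts Fresh random restarts after optimizer failure.
#' @param d_sanity_nm Fits with `|d|` beyond this window are flagged.
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(fitted_parameters = c("xyd", "xydt", "xydtp"),
                       orientation_input = c("exact", "noisy", "none"),
                       sigma_theta_deg = 2, sigma_phi_deg = 2,
                       oversampling = 3,
                       start_d_range = c(-500, 500),
                       start_xy_halfwidth_nm = 6.5e3 / 60,
                       likelihood = c("raw", "normalized"),
                       max_restarts = 3,
                       d_sanity_nm = 1500) {
  fitted_parameters <- match.arg(fitted_parameters)
  orientation_input <- match.arg(orientation_input)
  likelihood <- match.arg(likelihood)
  stopifnot(length(start_d_range) == 2, start_d_range[1] < start_d_range[2])
  structure(list(fitted_parameters = fitted_parameters,
                 orientation_input = orientation_input,
                 sigma_theta_deg = sigma_theta_deg, sigma_phi_deg = sigma_phi_deg,
                 oversampling = as.integer(oversampling),
                 start_d_range = as.numeric(start_d_range),
                 start_xy_halfwidth_nm = start_xy_halfwidth_nm,
                 likelihood = likelihood,
                 max_restarts = as.integer(max_restarts),
                 d_sanity_nm = d_sanity_nm),
            class = "fit_config")
}

#' @export
print.fit_config <- function(x, ...) {
  cat(sprintf("<fit_config> fit %s | orientation %s%s | oversampling %d | %s likelihood\n",
              x$fitted_parameters, x$orientation_input,
              if (x$orientation_input == "noisy")
                sprintf(" (sd theta %g deg, phi %g deg)", x$sigma_theta_deg, x$sigma_phi_deg) else "",
              x$oversampling, x$likelihood))
  invisible(x)
}
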