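# Vectorial image formation for a fixed dipole at a water/air interface,
# collected by a low-NA aplanatic air objective.
#
# Pupil radius rho in [0,1] maps to the air-side angle via n2 sin(theta2) =
# NA * rho; Snell's law links the sample-side angle (n1 sin(theta1) =
# n2 sin(theta2)). Because NA < n2 < n1, all collected rays are subcritical and
# the Fresnel coefficients are real. The back-focal-plane field of the dipole
# combines the s/p far-field projections at theta1, the Fresnel transmissions
# t_s, t_p, the stationary-phase Jacobian n2 cos(theta2) / (n1 cos(theta1)) of
# the angular-spectrum continuation across the interface, and the aplanatic
# 1/sqrt(cos(theta2)) apodization of the sine-condition objective. Constant
# prefactors are dropped throughout: they cancel in the normalized intensity.

pupil_geometry <- function(cfg, grid) {
  na <- cfg$numerical_aperture; n1 <- cfg$n_sample; n2 <- cfg$n_immersion
  rho <- sqrt(pmin(grid$u^2 + grid$v^2, 1))
  sin_t2 <- na * rho / n2
  cos_t2 <- sqrt(pmax(1 - sin_t2^2, 0))
  sin_t1 <- n2 * sin_t2 / n1
  cos_t1 <- sqrt(pmax(1 - sin_t1^2, 0))
  ts <- 2 * n1 * cos_t1 / (n1 * cos_t1 + n2 * cos_t2)
  tp <- 2 * n1 * cos_t1 / (n1 * cos_t2 + n2 * cos_t1)
  amp <- (n2 * cos_t2 / (n1 * cos_t1)) / sqrt(cos_t2)
  phi_p <- atan2(grid$v, grid$u)
  list(grid = grid, rho = rho, sin_t1 = sin_t1, cos_t1 = cos_t1,
       cos_t2 = cos_t2, ts = ts, tp = tp, amp = amp,
       cos_phi = cos(phi_p), sin_phi = sin(phi_p), phi_p = phi_p)
}

# s/p decomposition of the dipole far field, Fresnel-transmitted and mapped to
# Cartesian pupil components. The field is transverse after collimation, so the
# axial component is identically zero and the dipole's z-information lives in
# the radial (p) component.
bfp_components <- function(theta, phi, geom) {
  dp <- sin(theta) * geom$cos_t1 * cos(geom$phi_p - phi) - cos(theta) * geom$sin_t1
  ds <- sin(theta) * sin(geom$phi_p - phi)
  ep <- geom$tp * dp * geom$amp
  es <- geom$ts * ds * geom$amp
  w <- geom$grid$weight
  ex <- (ep * geom$cos_phi - es * geom$sin_phi) * w
  ey <- (ep * geom$sin_phi + es * geom$cos_phi) * w
  list(x = ex, y = ey)
}

#' Back-focal-plane field of a fixed dipole emitter
#'
#' Computes the vectorial electric field in the objective's back focal plane
#' for a dipole with orientation `(theta, phi)` emitting at the sample/air
#' interface, up to a constant factor (absorbed later by the intensity
#' normalization). The field is real for the subcritical collection geometry
#' used here and transverse after collimation (`z` component zero).
#'
#' @param theta,phi Dipole inclination and azimuth in radians.
#' @param cfg An [optical_config].
#' @param grid A [pupil_grid] (defaults to `cfg$pupil_samples` per axis).
#' @return Object of class `pupil_field`: list with numeric matrices `x`, `y`,
#'   `z` (zero), the `grid`, the geometry (`geom`) and `cfg`.
#' @export
bfp_field <- function(theta, phi, cfg = optical_config(),
                      grid = pupil_grid(cfg$pupil_samples)) {
  if (theta < 0 || theta > pi / 2 + 1e-12) stop("`theta` must lie in [0, pi/2]")
  geom <- pupil_geometry(cfg, grid)
  f <- bfp_components(theta, phi, geom)
  structure(list(x = f$x, y = f$y, z = matrix(0, grid$n, grid$n),
                 grid = grid, geom = geom, cfg = cfg,
                 theta = theta, phi = phi),
            class = "pupil_field")
}

# Pupil phase advance per nm of defocus (radians/nm), per the configured model.
defocus_phase_rate <- function(cfg, geom) {
  k <- 2 * pi / cfg$wavelength_nm
  switch(cfg$defocus_model,
    exact_air = k * cfg$n_immersion * geom$cos_t2,
    exact_sample = k * cfg$n_sample * geom$cos_t1,
    zernike = {
      # paraxial pure-Z4 equivalent of the air-side axial phase
      w4_per_nm <- -cfg$numerical_aperture^2 / (4 * sqrt(3) * cfg$n_immersion)
      k * w4_per_nm * wavefront_on_pupil(zernike_coefficients(`4` = 1), geom$grid)
    })
}

#' Propagate a pupil field to the image plane
#'
#' Evaluates the Fourier integral from the pupil to arbitrary image-plane
#' coordinates as a discrete midpoint sum, applying the aberration phase
#' `exp(i 2 pi W / lambda)` and the defocus phase inside the integral.
#' Coordinates are expressed in object space (image coordinates divided by the
#' magnification); with tube focal length `f = M * f_obj` and pupil radius
#' `f_obj * NA`, the transform kernel reduces to
#' `exp(-i (2 pi NA / lambda) (x u + y v))` on normalized pupil coordinates.
#' The quadratic phase prefactor of the exact Fresnel integral is dropped: it
#' cancels in the normalized intensity. Lateral emitter displacement is
#' equivalent to shifting the image coordinates.
#'
#' @param pupil A `pupil_field` from [bfp_field()].
#' @param wavefront_nm Aberration wavefront in nm on the pupil grid (matrix
#'   from [build_wavefront()]), or `NULL` for none.
#' @param x_nm,y_nm Numeric vectors of object-space image coordinates (nm); the
#'   field is evaluated on their outer grid.
#' @param defocus_nm Defocus in nm, applied as a pupil phase per
#'   `cfg$defocus_model`.
#' @return List with complex matrices `x`, `y`, `z` of size
#'   `length(x_nm) x length(y_nm)`.
#' @export
image_field <- function(pupil, wavefront_nm = NULL, x_nm, y_nm, defocus_nm = 0) {
  stopifnot(inherits(pupil, "pupil_field"))
  if (length(x_nm) == 0 || length(y_nm) == 0) stop("empty image coordinate vector")
  cfg <- pupil$cfg; grid <- pupil$grid
  if (is.null(wavefront_nm)) wavefront_nm <- matrix(0, grid$n, grid$n)
  if (!all(dim(wavefront_nm) == c(grid$n, grid$n))) {
    stop("wavefront grid (", paste(dim(wavefront_nm), collapse = "x"),
         ") does not match the pupil grid (", grid$n, "x", grid$n, ")")
  }
  k <- 2 * pi / cfg$wavelength_nm
  # the pupil field already carries the (anti-aliased) aperture weighting
  phase <- exp(1i * (k * wavefront_nm + defocus_nm * defocus_phase_rate(cfg, pupil$geom)))
  a <- 2 * pi * cfg$numerical_aperture / cfg$wavelength_nm
  kx <- exp(-1i * a * outer(x_nm, grid$axis))
  kyT <- exp(-1i * a * outer(grid$axis, y_nm))
  scale <- grid$du2
  list(x = (kx %*% (pupil$x * phase) %*% kyT) * scale,
       y = (kx %*% (pupil$y * phase) %*% kyT) * scale,
       z = matrix(0 + 0i, length(x_nm), length(y_nm)))
}

# Intensity on an (xs, ys) object-space grid for a stack of defocus values,
# reusing the Fourier kernels across the stack. Returns array [x, y, d].
psf_intensity_stack <- function(theta, phi, cfg, coeffs, xs, ys, ds,
                                grid = pupil_grid(cfg$pupil_samples)) {
  geom <- pupil_geometry(cfg, grid)
  fld <- bfp_components(theta, phi, geom)
  W <- wavefront_on_pupil(coeffs, grid)
  k <- 2 * pi / cfg$wavelength_nm
  static_phase <- exp(1i * k * W)
  px0 <- fld$x * static_phase
  py0 <- fld$y * static_phase
  rate <- defocus_phase_rate(cfg, geom)
  a <- 2 * pi * cfg$numerical_aperture / cfg$wavelength_nm
  kx <- exp(-1i * a * outer(xs, grid$axis))
  kyT <- exp(-1i * a * outer(grid$axis, ys))
  out <- array(0, c(length(xs), length(ys), length(ds)))
  for (i in seq_along(ds)) {
    ph <- exp(1i * ds[i] * rate)
    ex <- kx %*% (px0 * ph) %*% kyT
    ey <- kx %*% (py0 * ph) %*% kyT
    out[, , i] <- Re(ex)^2 + Im(ex)^2 + Re(ey)^2 + Im(ey)^2
  }
  out
}

# Sum os x os subpixel blocks into camera pixels.
bin_subpixels <- function(m, os) {
  if (os == 1) return(m)
  roi <- nrow(m) / os
  a <- array(m, c(os, roi, os * roi))
  s1 <- colSums(a)                       # (roi, os*roi)
  b <- array(s1, c(roi, os, roi))
  colSums(aperm(b, c(2, 1, 3)))          # (roi, roi)
}

# Object-space subpixel center coordinates for an odd ROI. The ROI center is
# the center of the middle pixel; positions are continuous nm offsets from it.
subpixel_centers <- function(roi_px, os, pixel_nm) {
  n <- roi_px * os
  (seq_len(n) - (n + 1) / 2) * pixel_nm / os
}

#' Normalized pixel-integrated PSF of a fixed dipole
#'
#' Computes the intensity of the dipole image on a subpixel grid (oversampling
#' the camera pixels), sums subpixels into camera pixels, and normalizes so the
#' ROI sum is exactly 1. The matrix is indexed `[x, y]`: the first index
#' increases with x (rightward), the second with y (upward).
#'
#' @param state A [dipole_state] (position, defocus, orientation).
#' @param cfg An [optical_config].
#' @param coeffs [zernike_coefficients] of static aberrations (defocus is the
#'   separate continuous parameter `state$d`).
#' @param roi_px Odd ROI edge length in pixels (default 17).
#' @param oversampling Subpixels per pixel per axis (default 9 as used for
#'   simulation; fitting uses 3).
#' @param grid Optional [pupil_grid].
#' @return `roi_px x roi_px` matrix of class `psf_image` summing to 1, with
#'   attributes `pixel_nm`, `roi_px`, `state`.
#' @export
#' @examples
#' psf <- psf_image(dipole_state(theta = pi / 2), optical_config(),
#'                  zernike_coefficients(`6` = 74.8))
#' sum(psf)  # exactly 1
psf_image <- function(state, cfg = optical_config(),
                      coeffs = zernike_coefficients(),
                      roi_px = 17, oversampling = 9,
                      grid = pupil_grid(cfg$pupil_samples)) {
  stopifnot(inherits(state, "dipole_state"))
  if (roi_px %% 2 != 1 || roi_px < 1) stop("`roi_px` must be odd and positive")
  if (oversampling < 1 || oversampling != round(oversampling)) {
    stop("`oversampling` must be an integer >= 1")
  }
  px <- cfg$object_pixel_nm
  s <- subpixel_centers(roi_px, oversampling, px)
  fine <- psf_intensity_stack(state$theta, state$phi, cfg, coeffs,
                              s - state$x, s - state$y, state$d, grid)[, , 1]
  img <- bin_subpixels(fine, oversampling)
  img <- img / sum(img)
  structure(img, class = c("psf_image", "matrix"),
            pixel_nm = px, roi_px = as.integer(roi_px), state = state)
}

#' @export
print.psf_image <- function(x, ...) {
  cat(sprintf("<psf_image> %d x %d px (%.2f nm px), sum %.6f, max %.4g\n",
              nrow(x), ncol(x), attr(x, "pixel_nm"), sum(x), max(x)))
  invisible(x)
}

#' Axial separation of the two astigmatic line foci
#'
#' With vertical astigmatism the x- and y- line foci lie at different defocus
#' values; their separation calibrates the strength of the astigmatism. The
#' defocus axis is scanned, the second-moment widths of the intensity along x
#' and along y are computed at each step, and the distance between the two
#' width minima (refined by a three-point parabola) is returned.
#'
#' @param cfg An [optical_config].
#' @param coeffs [zernike_coefficients]; must contain a nonzero Z6 term.
#' @param theta,phi Dipole orientation used for the scan (default in-plane,
#'   `theta = pi/2`, `phi = pi/4`).
#' @param d_range Scan range in nm (default +/- 1500).
#' @param d_step Scan step in nm (default 10).
#' @param window_halfwidth_nm Half-width of the evaluation window (default
#'   1350 nm, i.e. 25 pixels) so defocused patterns stay inside.
#' @param oversampling Sampling density of the window (default 3 per pixel).
#' @return Separation of the two line foci in nm.
#' @export
astigmatic_foci_separation <- function(cfg = optical_config(),
                                       coeffs = zernike_coefficients(`6` = 0.11 * 680),
                                       theta = pi / 2, phi = pi / 4,
                                       d_range = c(-1500, 1500), d_step = 10,
                                       window_halfwidth_nm = 1350,
                                       oversampling = 3) {
  if (!("6" %in% names(coeffs)) || coeffs[["6"]] == 0) {
    if (length(coeffs) == 0 || !("6" %in% names(coeffs))) return(0)
  }
  if (coeffs[["6"]] == 0) return(0)
  ds <- seq(d_range[1], d_range[2], by = d_step)
  step_nm <- cfg$object_pixel_nm / oversampling
  s <- seq(-window_halfwidth_nm, window_halfwidth_nm, by = step_nm)
  stack <- psf_intensity_stack(theta, phi, cfg, coeffs, s, s, ds)
  width2 <- function(marginal) {
    tot <- sum(marginal)
    mu <- sum(s * marginal) / tot
    sum((s - mu)^2 * marginal) / tot
  }
  wx <- apply(stack, 3, function(im) width2(rowSums(im)))
  wy <- apply(stack, 3, function(im) width2(colSums(im)))
  argmin_refined <- function(w) {
    i <- which.min(w)
    if (i == 1 || i == length(w)) {
      stop("no interior width minimum in the defocus scan range [",
           d_range[1], ", ", d_range[2], "] nm; widen `d_range`")
    }
    # three-point parabolic refinement
    num <- w[i - 1] - w[i + 1]
    den <- w[i - 1] - 2 * w[i] + w[i + 1]
    ds[i] + 0.5 * d_step * num / den
  }
  abs(argmin_refined(wx) - argmin_refined(wy))
}

#' Fast PSF renderer for a fixed imaging context
#'
#' Returns a closure `function(x, y, d, normalize = TRUE)` rendering
#' pixel-integrated, ROI-normalized PSFs for one fixed (orientation,
#' aberration, optics) context with precomputed pupil fields and Fourier
#' kernels. The emitter shift `(x, y)` and the defocus `d` enter as a single
#' combined pupil phase, so a render costs two BLAS products per field
#' component. Used by the simulator, the Fisher calculator and the fit-table
#' builder, where thousands of renders share one context; agrees with
#' [psf_image()] to machine precision.
#'
#' @inheritParams psf_image
#' @param theta,phi Dipole orientation in radians.
#' @return A function of `(x, y, d, normalize)` returning a
#'   `roi_px x roi_px` matrix.
#' @export
psf_renderer <- function(theta, phi, cfg, coeffs, roi_px = 17, oversampling = 9,
                         grid = pupil_grid(cfg$pupil_samples)) {
  geom <- pupil_geometry(cfg, grid)
  fld <- bfp_components(theta, phi, geom)
  W <- wavefront_on_pupil(coeffs, grid)
  k <- 2 * pi / cfg$wavelength_nm
  static_phase <- exp(1i * k * W)
  px0 <- fld$x * static_phase
  py0 <- fld$y * static_phase
  rate <- defocus_phase_rate(cfg, geom)
  a <- 2 * pi * cfg$numerical_aperture / cfg$wavelength_nm
  s <- subpixel_centers(roi_px, oversampling, cfg$object_pixel_nm)
  kx <- exp(-1i * a * outer(s, grid$axis))
  kyT <- t(kx)
  au <- a * grid$u
  av <- a * grid$v
  function(x = 0, y = 0, d = 0, normalize = TRUE) {
    ph <- exp(1i * (d * rate + x * au + y * av))
    ex <- kx %*% (px0 * ph) %*% kyT
    ey <- kx %*% (py0 * ph) %*% kyT
    img <- bin_subpixels(Re(ex)^2 + Im(ex)^2 + Re(ey)^2 + Im(ey)^2, oversampling)
    if (normalize) img / sum(img) else img
  }
}
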