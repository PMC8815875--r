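#' Expected pixel counts of the Poisson imaging model
#'
#' `nu_k = n_eff * PSF_k(x, y, d; theta, phi) + b^2` for every ROI pixel.
#'
#' @param state A [dipole_state].
#' @param cfg An [optical_config].
#' @param coeffs [zernike_coefficients].
#' @param n_eff Detected photons delivered to the PSF.
#' @param background_mean Background mean per pixel (`b^2`).
#' @param roi_px,oversampling ROI size and model oversampling (9 as in
#'   simulation; the bound describes the data-generating model).
#' @param renderer Optional prebuilt [psf_renderer] for this context.
#' @return `roi_px x roi_px` matrix of expected counts.
#' @export
expected_pixels <- function(state, cfg = optical_config(),
                            coeffs = zernike_coefficients(),
                            n_eff = 5e5, background_mean = 0,
                            roi_px = 17, oversampling = 9, renderer = NULL) {
  if (is.null(renderer)) {
    renderer <- psf_renderer(state$theta, state$phi, cfg, coeffs,
                             roi_px = roi_px, oversampling = oversampling)
  }
  n_eff * renderer(state$x, state$y, state$d) + background_mean
}

#' Fisher information matrix over (x, y, d) for Poisson pixels
#'
#' `I = sum_k (d nu_k / d xi)^T (d nu_k / d xi) / nu_k` with the partial
#' derivatives approximated by central difference quotients (default steps
#' 1 nm laterally, 2 nm in defocus). Pixels with expected counts below
#' `floor` carry no photons and are excluded from the sum (the 1/nu weight is
#' undefined at zero).
#'
#' @inheritParams expected_pixels
#' @param step_xy_nm,step_d_nm Central-difference steps.
#' @param floor Smallest expected count admitted to the information sum.
#' @return 3x3 symmetric matrix with rows/columns `x`, `y`, `d` (units
#'   photons/nm^2), class `fisher_matrix`.
#' @export
fisher_matrix <- function(state, cfg = optical_config(),
                          coeffs = zernike_coefficients(),
                          n_eff = 5e5, background_mean = 0,
                          roi_px = 17, oversampling = 9,
                          step_xy_nm = 1, step_d_nm = 2,
                          floor = 1e-12, renderer = NULL) {
  if (step_xy_nm <= 0 || step_d_nm <= 0) stop("difference steps must be positive")
  if (is.null(renderer)) {
    renderer <- psf_renderer(state$theta, state$phi, cfg, coeffs,
                             roi_px = roi_px, oversampling = oversampling)
  }
  nu0 <- n_eff * renderer(state$x, state$y, state$d) + background_mean
  pm <- function(dx = 0, dy = 0, dd = 0) {
    n_eff * renderer(state$x + dx, state$y + dy, state$d + dd)
  }
  derivs <- list(
    x = (pm(dx = step_xy_nm) - pm(dx = -step_xy_nm)) / (2 * step_xy_nm),
    y = (pm(dy = step_xy_nm) - pm(dy = -step_xy_nm)) / (2 * step_xy_nm),
    d = (pm(dd = step_d_nm) - pm(dd = -step_d_nm)) / (2 * step_d_nm)
  )
  keep <- nu0 >= floor
  info <- matrix(0, 3, 3, dimnames = list(c("x", "y", "d"), c("x", "y", "d")))
  for (i in 1:3) for (j in i:3) {
    info[i, j] <- info[j, i] <-
      sum((derivs[[i]] * derivs[[j]] / nu0)[keep])
  }
  structure(info, class = c("fisher_matrix", "matrix"))
}

#' Cramér-Rao lower bounds from a Fisher matrix
#'
#' The variance of any unbiased estimator of `(x, y, d)` is bounded below by
#' the diagonal of the inverse Fisher matrix; this returns the corresponding
#' standard-deviation bounds in nm.
#'
#' @param info A 3x3 Fisher matrix from [fisher_matrix()].
#' @param condition_tol Reciprocal condition number below which the matrix is
#'   treated as singular.
#' @return Named numeric vector `sqrt_crb_x`, `sqrt_crb_y`, `sqrt_crb_d` (nm).
#' @export
crb <- function(info, condition_tol = 1e-12) {
  stopifnot(is.matrix(info), all(dim(info) == c(3, 3)))
  ev <- eigen(info, symmetric = TRUE)
  if (min(ev$values) <= condition_tol * max(abs(ev$values), 1e-300)) {
    worst <- which.max(abs(ev$vectors[, which.min(ev$values)]))
    stop("Fisher matrix is singular or indefinite: parameter '",
         c("x", "y", "d")[worst],
         "' is not identifiable in this condition (condition number ",
         format(max(ev$values) / max(min(ev$values), 0), digits = 3), ")")
  }
  v <- diag(solve(info))
  stats::setNames(sqrt(v), c("sqrt_crb_x", "sqrt_crb_y", "sqrt_crb_d"))
}

#' Cramér-Rao bound over a grid of imaging conditions
#'
#' Convenience wrapper evaluating [fisher_matrix()] + [crb()] across a defocus
#' grid for one orientation/photon/background condition, reusing the rendering
#' context. With excitation coupling the photon number per condition is
#' `n_photons * sin^2(theta)`.
#'
#' @param theta,phi Dipole orientation (radians).
#' @param defocus Numeric vector of defocus values (nm).
#' @param n_photons Detected photons (`N_eff`, or `N_max` under coupling).
#' @param background_sd Background standard deviation `b` (mean `b^2`).
#' @param coeffs,cfg Aberrations and optics.
#' @param excitation_coupling Couple photon yield to orientation.
#' @param x,y Lateral evaluation point (default ROI center).
#' @inheritParams fisher_matrix
#' @return Tibble: condition columns plus `sqrt_crb_x_nm`, `sqrt_crb_y_nm`,
#'   `sqrt_crb_d_nm`.
#' @export
#' @examples
#' crb_grid(pi / 2, pi / 4, defocus = c(-200, 0, 200),
#'          coeffs = zernike_coefficients(`6` = 74.8))
crb_grid <- function(theta, phi, defocus = seq(-500, 500, by = 100),
                     n_photons = 5e5, background_sd = 0,
                     coeffs = zernike_coefficients(),
                     cfg = optical_config(),
                     excitation_coupling = FALSE,
                     x = 0, y = 0, roi_px = 17, oversampling = 9,
                     step_xy_nm = 1, step_d_nm = 2) {
  n_eff <- if (excitation_coupling) n_photons * sin(theta)^2 else n_photons
  if (n_eff <= 0) {
    stop("no photons are detected for theta = ", format(theta),
         " under excitation coupling; the Fisher matrix is singular")
  }
  renderer <- psf_renderer(theta, phi, cfg, coeffs,
                           roi_px = roi_px, oversampling = oversampling)
  rows <- purrr::map(defocus, function(d) {
    info <- fisher_matrix(dipole_state(x, y, d, theta, phi), cfg, coeffs,
                          n_eff = n_eff, background_mean = background_sd^2,
                          roi_px = roi_px, oversampling = oversampling,
                          step_xy_nm = step_xy_nm, step_d_nm = step_d_nm,
                          renderer = renderer)
    b <- crb(info)
    tibble::tibble(theta = theta, phi = phi, d_nm = d, n_eff = n_eff,
                   background_sd = background_sd,
                   sqrt_crb_x_nm = b[["sqrt_crb_x"]],
                   sqrt_crb_y_nm = b[["sqrt_crb_y"]],
                   sqrt_crb_d_nm = b[["sqrt_crb_d"]])
  })
  dplyr::bind_rows(rows)
}
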