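#' Orientation-dependent photon yield under polarized excitation
#'
#' For alternating excitation with x- and y-polarized light the absorption
#' probability scales with the squared cosine of the angle between the
#' excitation field and the dipole axis, giving detected photon numbers
#' `N_x = N_max sin^2(theta) cos^2(phi)`, `N_y = N_max sin^2(theta) sin^2(phi)`
#' and a total `N_eff = N_x + N_y = N_max sin^2(theta)`. A dipole along the
#' optical axis (`theta = 0`) is not excited at all.
#'
#' @param theta,phi Dipole orientation in radians (vectorized).
#' @param n_max Photon budget at parallel alignment.
#' @return A tibble with columns `theta`, `phi`, `n_x`, `n_y`, `n_eff`.
#' @export
#' @examples
#' excitation_yield(c(pi / 2, 0), c(0, 0), 5e5)
excitation_yield <- function(theta, phi, n_max = 5e5) {
  if (any(n_max <= 0)) stop("`n_max` must be positive")
  tibble::tibble(
    theta = theta, phi = phi,
    n_x = n_max * sin(theta)^2 * cos(phi)^2,
    n_y = n_max * sin(theta)^2 * sin(phi)^2,
    n_eff = n_max * sin(theta)^2
  )
}

#' Draw ground-truth emitter states for an ensemble
#'
#' Positions are i.i.d. uniform in the central 216 x 216 nm of the ROI
#' (about 2 x 2 pixels). Defocus is either a fixed value or a grid cycled
#' across frames. Orientation is either fixed, or `"random"` — uniform over
#' the upper hemisphere in solid angle (`theta = acos(U)`), the measure a
#' randomly oriented rigid label would produce; `"uniform_angles"` draws
#' `theta` uniformly in `[0, pi/2]` instead.
#'
#' @param n Number of frames.
#' @param defocus Defocus in nm: scalar or grid vector (cycled over frames).
#' @param orientation Either `c(theta, phi)` in radians, `"random"`, or
#'   `"uniform_angles"`.
#' @param acq [acquisition_params]; supplies `n_max` and whether the photon
#'   yield is coupled to the orientation. With coupling off, `n_eff = n_max`
#'   for every frame.
#' @param xy_halfwidth_nm Half-width of the central position box (108 nm).
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @return Tibble with columns `frame`, `x_nm`, `y_nm`, `d_nm`, `theta_rad`,
#'   `phi_rad`, `n_x`, `n_y`, `n_eff`.
#' @export
sample_ground_truth <- function(n, defocus = 0, orientation = c(pi / 2, 0),
                                acq = acquisition_params(),
                                xy_halfwidth_nm = 108, seed = NULL) {
  if (n < 1) stop("`n` must be >= 1")
  draw <- function() {
    x <- stats::runif(n, -xy_halfwidth_nm, xy_halfwidth_nm)
    y <- stats::runif(n, -xy_halfwidth_nm, xy_halfwidth_nm)
    d <- rep_len(defocus, n)
    if (is.character(orientation)) {
      mode <- match.arg(orientation, c("random", "uniform_angles"))
      theta <- if (mode == "random") acos(stats::runif(n)) else stats::runif(n, 0, pi / 2)
      phi <- stats::runif(n, 0, 2 * pi)
    } else {
      theta <- rep_len(orientation[1], n)
      phi <- rep_len(orientation[2], n)
    }
    yield <- excitation_yield(theta, phi, acq$n_max)
    n_eff <- if (acq$excitation_coupling) yield$n_eff else rep(acq$n_max, n)
    tibble::tibble(frame = seq_len(n), x_nm = x, y_nm = y, d_nm = d,
                   theta_rad = theta, phi_rad = phi,
                   n_x = yield$n_x, n_y = yield$n_y, n_eff = n_eff)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Render one simulated camera frame
#'
#' Expected counts are `nu_k = n_eff * PSF_k(x, y, d; theta, phi) + b^2` per
#' pixel — the PSF normalized over the computed ROI window, plus the Poisson
#' background whose mean `b^2` gives it standard deviation `b` — and the
#' observed frame draws each pixel independently from `Poisson(nu_k)`.
#'
#' @param gt One-row ground-truth tibble (or list) with `x_nm`, `y_nm`,
#'   `d_nm`, `theta_rad`, `phi_rad`, `n_eff`.
#' @param cfg An [optical_config].
#' @param coeffs [zernike_coefficients].
#' @param acq [acquisition_params].
#' @param renderer Optional prebuilt [psf_renderer] closure for this
#'   orientation/aberration context (rebuilt per call otherwise).
#' @param expected_only If `TRUE`, return the expected counts (no noise).
#' @return Integer (or numeric, if `expected_only`) `roi_px x roi_px` matrix.
#' @export
render_frame <- function(gt, cfg = optical_config(),
                         coeffs = zernike_coefficients(),
                         acq = acquisition_params(), renderer = NULL,
                         expected_only = FALSE) {
  if (is.null(renderer)) {
    renderer <- psf_renderer(gt$theta_rad, gt$phi_rad, cfg, coeffs,
                             roi_px = acq$roi_px, oversampling = acq$oversampling)
  }
  nu <- gt$n_eff * renderer(gt$x_nm, gt$y_nm, gt$d_nm) + acq$background_sd^2
  stopifnot(all(nu >= 0))
  if (expected_only) return(nu)
  matrix(stats::rpois(length(nu), as.numeric(nu)), nrow(nu), ncol(nu))
}

#' Simulate a seeded stack of frames with ground truth
#'
#' Draws ground truth, renders every frame with Poisson shot noise and
#' background, and returns a tibble carrying the frames as a list-column.
#' Bit-identical reproducible from `(parameters, seed)`: a per-frame child
#' seed is derived from `seed` and recorded.
#'
#' @inheritParams render_frame
#' @param n Number of frames.
#' @param defocus,orientation Passed to [sample_ground_truth()].
#' @param seed Integer master seed.
#' @return Tibble: ground-truth columns, `seed`, and list-column `frame_px`
#'   of integer count matrices.
#' @export
#' @examples
#' sim <- simulate_frames(3, defocus = 0, orientation = c(pi / 2, pi / 4),
#'                        acq = acquisition_params(background_sd = 100),
#'                        coeffs = zernike_coefficients(`6` = 74.8), seed = 7)
#' sim$frame_px[[1]][9, 9]
simulate_frames <- function(n, defocus = 0, orientation = c(pi / 2, 0),
                            cfg = optical_config(),
                            coeffs = zernike_coefficients(),
                            acq = acquisition_params(), seed = 1) {
  gt <- sample_ground_truth(n, defocus, orientation, acq, seed = seed)
  child <- withr::with_seed(seed + 1L, sample.int(.Machine$integer.max - 1L, n))
  fixed_orient <- !is.character(orientation)
  renderer <- if (fixed_orient) {
    psf_renderer(gt$theta_rad[1], gt$phi_rad[1], cfg, coeffs,
                 roi_px = acq$roi_px, oversampling = acq$oversampling)
  } else NULL
  frames <- purrr::map(seq_len(n), function(i) {
    r <- if (fixed_orient) renderer else NULL
    withr::with_seed(child[i],
                     render_frame(gt[i, ], cfg, coeffs, acq, renderer = r))
  })
  gt$seed <- child
  gt$frame_px <- frames
  gt
}
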