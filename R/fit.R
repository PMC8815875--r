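#' Estimate the mean background level from a signal-free frame
#'
#' A-priori estimator for the background mean `b^2`: the arithmetic mean of
#' all pixels of an image containing no fluorophore signal.
#'
#' @param dark_frame Matrix of counts without emitter signal.
#' @return Scalar background mean estimate (photons/pixel).
#' @export
estimate_background <- function(dark_frame) {
  if (!is.matrix(dark_frame) && !is.numeric(dark_frame)) stop("`dark_frame` must be numeric")
  mean(dark_frame)
}

#' Estimate the detected photon number from a frame
#'
#' Sums the background-corrected pixels: `sum_k (z_k - background_mean)`.
#' Negative totals (possible in very dim frames) are clipped to `minimum`
#' with a warning.
#'
#' @param frame Matrix of observed counts.
#' @param background_mean Background mean per pixel (`b^2`).
#' @param minimum Clip floor for the estimate.
#' @return Scalar photon-number estimate.
#' @export
estimate_neff <- function(frame, background_mean = 0, minimum = 1) {
  if (background_mean < 0) stop("`background_mean` must be >= 0")
  est <- sum(frame) - length(frame) * background_mean
  if (est < minimum) {
    warning("photon-number estimate ", format(est, digits = 4),
            " clipped to ", minimum)
    est <- minimum
  }
  est
}

# Direct-model (Fourier-sum) expected-count closure for a fixed optics context
# where the orientation may vary per evaluation (angle-fitting modes).
direct_model_context <- function(cfg, coeffs, roi_px, oversampling,
                                 grid = pupil_grid(cfg$pupil_samples)) {
  geom <- pupil_geometry(cfg, grid)
  W <- wavefront_on_pupil(coeffs, grid)
  k <- 2 * pi / cfg$wavelength_nm
  static_phase <- exp(1i * k * W)
  rate <- defocus_phase_rate(cfg, geom)
  a <- 2 * pi * cfg$numerical_aperture / cfg$wavelength_nm
  s <- subpixel_centers(roi_px, oversampling, cfg$object_pixel_nm)
  kx <- exp(-1i * a * outer(s, grid$axis))
  kyT <- t(kx)
  au <- a * grid$u; av <- a * grid$v
  function(x, y, d, theta, phi) {
    fld <- bfp_components(theta, phi, geom)
    ph <- exp(1i * (d * rate + x * au + y * av)) * static_phase
    ex <- kx %*% (fld$x * ph) %*% kyT
    ey <- kx %*% (fld$y * ph) %*% kyT
    img <- bin_subpixels(Re(ex)^2 + Im(ex)^2 + Re(ey)^2 + Im(ey)^2, oversampling)
    img / sum(img)
  }
}

# Wrap an arbitrary direction into the canonical ranges theta in [0, pi/2],
# phi in [0, 2 pi), using the antipodal equivalence of dipole emission.
canonical_orientation <- function(theta, phi) {
  vz <- cos(theta)
  vx <- sin(theta) * cos(phi)
  vy <- sin(theta) * sin(phi)
  if (vz < 0) { vx <- -vx; vy <- -vy; vz <- -vz }
  nrm <- sqrt(vx^2 + vy^2 + vz^2)
  th <- acos(min(1, max(-1, vz / nrm)))
  ph <- atan2(vy, vx) %% (2 * pi)
  c(theta = th, phi = ph)
}

#' Poisson negative log-likelihood of a frame under the dipole PSF model
#'
#' Computes `-sum_k [z_k ln(nu_k) - nu_k]` with
#' `nu_k = n_eff * PSF_k(x, y, d; theta, phi) + background_mean`. The
#' `ln(z_k!)` term is a constant in the parameters and is dropped (flagged in
#' the `"factorial_dropped"` attribute). `likelihood = "normalized"`
#' reproduces the normalized-image variant — data and model both divided by
#' the total detected photons — which has the same minimizer.
#'
#' @param frame Observed count matrix.
#' @param x,y,d,theta,phi Model parameters (nm, nm, nm, rad, rad).
#' @param cfg,coeffs Optics and aberrations.
#' @param n_eff,background_mean Photon number and background mean (estimates).
#' @param oversampling Model oversampling (3 during fitting).
#' @param likelihood `"raw"` or `"normalized"`.
#' @return Scalar negative log-likelihood (up to the dropped constant).
#' @export
negative_log_likelihood <- function(frame, x, y, d, theta, phi,
                                    cfg = optical_config(),
                                    coeffs = zernike_coefficients(),
                                    n_eff, background_mean = 0,
                                    oversampling = 3,
                                    likelihood = c("raw", "normalized")) {
  likelihood <- match.arg(likelihood)
  model <- direct_model_context(cfg, coeffs, nrow(frame), oversampling)
  nu <- n_eff * model(x, y, d, theta, phi) + background_mean
  nu <- pmax(nu, 1e-12)
  z <- as.numeric(frame)
  out <- if (likelihood == "raw") {
    -sum(z * log(nu) - nu)
  } else {
    tot <- sum(z)
    -sum((z / tot) * log(nu / tot) - nu / tot)
  }
  attr(out, "factorial_dropped") <- TRUE
  out
}

# Random starting values: (x, y) uniform in a 2x2 pixel box about the ROI
# center, d uniform in the configured interval. Uses the current RNG stream.
draw_start <- function(fit_cfg) {
  c(stats::runif(2, -fit_cfg$start_xy_halfwidth_nm, fit_cfg$start_xy_halfwidth_nm),
    stats::runif(1, fit_cfg$start_d_range[1], fit_cfg$start_d_range[2]))
}

#' Non-linear least-squares initialization for the maximum-likelihood fit
#'
#' Minimizes `sum_k (z_k - nu_k)^2` by quasi-Newton descent from a random
#' start — `(x, y)` uniform in a 2 x 2 pixel region about the center, `d`
#' uniform in `start_d_range` — and returns the optimum, which seeds the MLE.
#'
#' @param frame Observed count matrix.
#' @param table A [psf_table] for the frame's orientation context.
#' @param n_eff,background_mean Photon number and background-mean estimates.
#' @param fit_cfg A [fit_config].
#' @param start Optional explicit starting values `c(x, y, d)` (otherwise
#'   drawn from the current RNG stream).
#' @return List with `par` (c(x, y, d)), `value`, `convergence`, `start`.
#' @export
least_squares_init <- function(frame, table, n_eff, background_mean,
                               fit_cfg = fit_config(), start = NULL) {
  if (is.null(start)) start <- draw_start(fit_cfg)
  obj <- table_objective(table, frame, n_eff, background_mean, "ssq")
  res <- stats::optim(start, obj$fn, obj$gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  list(par = res$par, value = res$value, convergence = res$convergence,
       start = start)
}

# one complete LSQ -> MLE attempt for the 3-parameter table path
fit_attempt_xyd <- function(frame, table, n_eff, background_mean, fit_cfg) {
  start <- draw_start(fit_cfg)
  ls <- least_squares_init(frame, table, n_eff, background_mean, fit_cfg, start)
  # "normalized" mode: data and model divided by the total detected photons
  # (the recipe used on normalized images); rescales the objective without
  # moving its minimizer
  scl <- if (fit_cfg$likelihood == "normalized") 1 / sum(frame) else 1
  obj <- table_objective(table, frame, n_eff, background_mean, "nll",
                         scale = scl)
  res <- tryCatch(
    stats::optim(ls$par, obj$fn, obj$gr, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-8)),
    error = function(e) NULL)
  list(res = res, start = start)
}

# one LSQ -> MLE attempt fitting angles too, on the direct Fourier model
fit_attempt_angles <- function(frame, model, n_par, orient_start,
                               n_eff, background_mean, fit_cfg) {
  start3 <- draw_start(fit_cfg)
  start <- c(start3, orient_start[seq_len(n_par - 3)])
  z <- as.numeric(frame)
  mk_nu <- function(p) {
    th <- if (n_par >= 4) p[4] else orient_start[1]
    ph <- if (n_par >= 5) p[5] else orient_start[2]
    as.numeric(n_eff * model(p[1], p[2], p[3], th, ph) + background_mean)
  }
  ssq <- function(p) { nu <- mk_nu(p); sum((z - nu)^2) }
  nll <- function(p) { nu <- pmax(mk_nu(p), 1e-12); -sum(z * log(nu) - nu) }
  ls <- stats::optim(start, ssq, method = "BFGS",
                     control = list(maxit = 300, reltol = 1e-9))
  res <- tryCatch(
    stats::optim(ls$par, nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-8)),
    error = function(e) NULL)
  list(res = res, start = start)
}

#' Maximum-likelihood localization of one ROI frame
#'
#' Estimates `(x, y, d)` — optionally also the dipole inclination or both
#' orientation angles — by unconstrained quasi-Newton minimization of the
#' Poisson negative log-likelihood, started from a non-linear least-squares
#' fit with randomized starting values. Failed optimizations are retried with
#' fresh random starts up to `fit_cfg$max_restarts` times.
#'
#' @param frame Observed count matrix (square, odd size).
#' @param orientation `c(theta, phi)` in radians: the (estimated) dipole
#'   orientation. Under `orientation_input = "noisy"` it is perturbed by the
#'   configured Gaussian errors before being supplied to the model (the
#'   perturbed value is what a real orientation measurement would deliver).
#'   For angle-fitting modes it provides the starting values; with
#'   `orientation_input = "none"` random starting angles are drawn.
#' @param cfg,coeffs Optics and aberrations (assumed known, as for a
#'   calibrated astigmatic setup).
#' @param fit_cfg A [fit_config].
#' @param n_eff Photon-number estimate; `NULL` to estimate from the frame.
#' @param background_mean Background mean `b^2`; `NULL` with `dark_frame`
#'   supplied estimates it, otherwise 0.
#' @param dark_frame Optional signal-free frame for background estimation.
#' @param table Optional prebuilt [psf_table] (3-parameter fits); built on
#'   the fly when absent.
#' @param seed Optional seed for the random starting values.
#' @return One-row tibble: estimates `x_nm`, `y_nm`, `d_nm` (and `theta_rad`,
#'   `phi_rad` when fitted), `nll`, `converged`, `n_restarts`, `d_flagged`,
#'   starting values, `n_eff_used`, `background_used`, `runtime_s`.
#' @export
mle_localize <- function(frame, orientation, cfg = optical_config(),
                         coeffs = zernike_coefficients(),
                         fit_cfg = fit_config(),
                         n_eff = NULL, background_mean = NULL,
                         dark_frame = NULL, table = NULL, seed = NULL) {
  t0 <- proc.time()[3]
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
      mle_localize(frame, orientation, cfg, coeffs, fit_cfg, n_eff,
                   background_mean, dark_frame, table, seed = NULL)))
  }
  roi_px <- nrow(frame)
  if (is.null(background_mean)) {
    background_mean <- if (!is.null(dark_frame)) estimate_background(dark_frame) else 0
  }
  if (is.null(n_eff)) n_eff <- estimate_neff(frame, background_mean)

  model_orient <- orientation
  if (fit_cfg$orientation_input == "noisy") {
    model_orient <- c(
      min(max(orientation[1] + stats::rnorm(1, 0, fit_cfg$sigma_theta_deg * pi / 180), 0), pi / 2),
      (orientation[2] + stats::rnorm(1, 0, fit_cfg$sigma_phi_deg * pi / 180)) %% (2 * pi))
  }

  n_par <- switch(fit_cfg$fitted_parameters, xyd = 3L, xydt = 4L, xydtp = 5L)
  if (n_par == 3L) {
    if (is.null(table)) {
      table <- psf_table(model_orient[1], model_orient[2], cfg, coeffs,
                         roi_px = roi_px,
                         fit_oversampling = fit_cfg$oversampling)
    }
    runner <- function() fit_attempt_xyd(frame, table, n_eff, background_mean, fit_cfg)
  } else {
    if (fit_cfg$orientation_input == "none") {
      model_orient <- c(acos(stats::runif(1)), stats::runif(1, 0, 2 * pi))
    }
    model <- direct_model_context(cfg, coeffs, roi_px, fit_cfg$oversampling)
    runner <- function() fit_attempt_angles(frame, model, n_par, model_orient,
                                            n_eff, background_mean, fit_cfg)
  }

  attempt <- runner()
  restarts <- 0L
  while ((is.null(attempt$res) || attempt$res$convergence != 0) &&
         restarts < fit_cfg$max_restarts) {
    restarts <- restarts + 1L
    attempt <- runner()
  }
  res <- attempt$res
  converged <- !is.null(res) && res$convergence == 0
  par <- if (!is.null(res)) res$par else rep(NA_real_, n_par)
  out <- tibble::tibble(
    x_nm = par[1], y_nm = par[2], d_nm = par[3],
    nll = if (!is.null(res)) res$value else NA_real_,
    converged = converged, n_restarts = restarts,
    d_flagged = is.finite(par[3]) && abs(par[3]) > fit_cfg$d_sanity_nm,
    start_x_nm = attempt$start[1], start_y_nm = attempt$start[2],
    start_d_nm = attempt$start[3],
    n_eff_used = n_eff, background_used = background_mean,
    runtime_s = proc.time()[3] - t0)
  if (n_par >= 4L) {
    can <- canonical_orientation(par[4], if (n_par >= 5L) par[5] else model_orient[2])
    out$theta_rad <- can[["theta"]]
    out$phi_rad <- if (n_par >= 5L) can[["phi"]] else model_orient[2]
  } else {
    out$theta_used <- model_orient[1]
    out$phi_used <- model_orient[2]
  }
  out
}

#' Fit a stack of simulated or recorded frames
#'
#' Batch driver around [mle_localize()]: shares one PSF lookup table across
#' frames with a common orientation context, derives per-frame seeds for the
#' random starting values, and binds results with the input's ground truth.
#'
#' @param sim Tibble with a `frame_px` list-column and columns `theta_rad`,
#'   `phi_rad` (from [simulate_frames()] or [read_frames()]).
#' @param cfg,coeffs,fit_cfg As in [mle_localize()].
#' @param background_mean Scalar or per-frame vector; `NULL` means 0.
#' @param n_eff `NULL` (estimate per frame) or scalar/vector.
#' @param seed Master seed for starting values.
#' @return Input tibble (minus `frame_px`) with fit columns appended; fitted
#'   columns are prefixed `fit_`.
#' @export
fit_frames <- function(sim, cfg = optical_config(),
                       coeffs = zernike_coefficients(),
                       fit_cfg = fit_config(),
                       background_mean = NULL, n_eff = NULL, seed = 1) {
  n <- nrow(sim)
  bg <- if (is.null(background_mean)) rep(0, n) else rep_len(background_mean, n)
  ne <- if (is.null(n_eff)) rep(list(NULL), n) else as.list(rep_len(n_eff, n))
  child <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  shared_table <- NULL
  use_table <- fit_cfg$fitted_parameters == "xyd" &&
    fit_cfg$orientation_input == "exact"
  if (use_table && n > 0 &&
      length(unique(sim$theta_rad)) == 1 && length(unique(sim$phi_rad)) == 1) {
    shared_table <- psf_table(sim$theta_rad[1], sim$phi_rad[1], cfg, coeffs,
                              roi_px = nrow(sim$frame_px[[1]]),
                              fit_oversampling = fit_cfg$oversampling)
  }
  fits <- purrr::map(seq_len(n), function(i) {
    mle_localize(sim$frame_px[[i]], c(sim$theta_rad[i], sim$phi_rad[i]),
                 cfg, coeffs, fit_cfg, n_eff = ne[[i]],
                 background_mean = bg[i], table = shared_table,
                 seed = child[i])
  })
  fits <- dplyr::bind_rows(fits)
  names(fits) <- paste0("fit_", names(fits))
  dplyr::bind_cols(dplyr::select(sim, -dplyr::any_of("frame_px")), fits)
}
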