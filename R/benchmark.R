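#' Define one ensemble benchmarking condition
#'
#' A condition fixes the dipole orientation, a defocus grid, the photon
#' budget, background and astigmatism, the fit configuration, and the number
#' of repetitions; [run_ensemble()] executes it reproducibly from the seed.
#'
#' @param theta,phi Orientation in radians, or `orientation = "random"` to
#'   redraw per repetition (hemisphere-uniform).
#' @param defocus Defocus grid in nm.
#' @param n_photons Photon budget (`N_eff`, or `N_max` when
#'   `excitation_coupling` is on).
#' @param background_sd Background standard deviation `b`.
#' @param astigmatism_nm Vertical-astigmatism coefficient w6 in nm RMS (0 for
#'   the astigmatism-free scenario); or pass full `coeffs`.
#' @param coeffs Optional explicit [zernike_coefficients] overriding
#'   `astigmatism_nm`.
#' @param fit A [fit_config].
#' @param n_rep Repetitions per defocus grid point (>= 2).
#' @param excitation_coupling Orientation-dependent photon yield.
#' @param roi_px ROI size in pixels.
#' @param seed Master seed of the condition.
#' @param orientation `"fixed"` (use theta/phi) or `"random"`.
#' @return Object of class `ensemble_condition`.
#' @export
ensemble_condition <- function(theta = pi / 2, phi = pi / 4,
                               defocus = seq(-500, 500, by = 100),
                               n_photons = 5e5, background_sd = 0,
                               astigmatism_nm = 0.11 * 680,
                               coeffs = NULL,
                               fit = fit_config(),
                               n_rep = 200,
                               excitation_coupling = FALSE,
                               roi_px = 17,
                               seed = 1,
                               orientation = c("fixed", "random")) {
  orientation <- match.arg(orientation)
  if (n_rep < 2) stop("`n_rep` must be >= 2")
  if (length(defocus) < 1) stop("`defocus` grid must be non-empty")
  if (is.null(coeffs)) {
    coeffs <- if (astigmatism_nm != 0) {
      zernike_coefficients(`6` = astigmatism_nm)
    } else zernike_coefficients()
  }
  structure(list(theta = theta, phi = phi, defocus = defocus,
                 n_photons = n_photons, background_sd = background_sd,
                 coeffs = coeffs, fit = fit, n_rep = as.integer(n_rep),
                 excitation_coupling = excitation_coupling,
                 roi_px = as.integer(roi_px), seed = seed,
                 orientation = orientation),
            class = "ensemble_condition")
}

#' @export
print.ensemble_condition <- function(x, ...) {
  cat(sprintf(paste0("<ensemble_condition> theta %.3f phi %.3f (%s) | %d defocus points x %d reps\n",
                     "  N %g, b %g, w6 %g nm, coupling %s, fit %s/%s, seed %d\n"),
              x$theta, x$phi, x$orientation, length(x$defocus), x$n_rep,
              x$n_photons, x$background_sd,
              if ("6" %in% names(x$coeffs)) x$coeffs[["6"]] else 0,
              if (x$excitation_coupling) "on" else "off",
              x$fit$fitted_parameters, x$fit$orientation_input, x$seed))
  invisible(x)
}

#' Run a seeded localization ensemble
#'
#' For every repetition at every defocus grid point: draw a ground-truth
#' position, render a frame with Poisson shot noise and background, estimate
#' the background from a signal-free companion frame and the photon number
#' from the corrected pixel sum, and run the least-squares-initialized MLE.
#' Child seeds are derived per (grid point, repetition) from the condition
#' seed, so any sub-ensemble is independently reproducible.
#'
#' @param cond An [ensemble_condition].
#' @param cfg An [optical_config].
#' @param compute_crb Also evaluate the Cramér-Rao bound per grid point.
#' @param progress Print a line per defocus grid point.
#' @return Object of class `dipole_ensemble`: list with `results` (one row
#'   per fit), `stats` (per defocus point x parameter: bias `mu`, precision
#'   `sigma`, standard errors, CRB, ratio), `condition`, `cfg`.
#' @export
run_ensemble <- function(cond, cfg = optical_config(), compute_crb = TRUE,
                         progress = FALSE) {
  stopifnot(inherits(cond, "ensemble_condition"))
  acq <- acquisition_params(n_max = cond$n_photons,
                            background_sd = cond$background_sd,
                            roi_px = cond$roi_px,
                            excitation_coupling = cond$excitation_coupling)
  fixed_orient <- cond$orientation == "fixed"
  use_table <- cond$fit$fitted_parameters == "xyd" && fixed_orient &&
    cond$fit$orientation_input != "noisy"
  renderer <- if (fixed_orient) {
    psf_renderer(cond$theta, cond$phi, cfg, cond$coeffs,
                 roi_px = cond$roi_px, oversampling = acq$oversampling)
  } else NULL
  d_span <- range(cond$defocus)
  table <- if (use_table) {
    psf_table(cond$theta, cond$phi, cfg, cond$coeffs, roi_px = cond$roi_px,
              fit_oversampling = cond$fit$oversampling,
              d_range_nm = c(min(-900, d_span[1] - 400),
                             max(900, d_span[2] + 400)))
  } else NULL

  seeds <- withr::with_seed(cond$seed,
    matrix(sample.int(.Machine$integer.max - 1L,
                      length(cond$defocus) * cond$n_rep),
           nrow = cond$n_rep))

  run_point <- function(gi) {
    d <- cond$defocus[gi]
    rows <- purrr::map(seq_len(cond$n_rep), function(ri) {
      withr::with_seed(seeds[ri, gi], {
        orient <- if (fixed_orient) c(cond$theta, cond$phi) else
          c(acos(stats::runif(1)), stats::runif(1, 0, 2 * pi))
        gt <- sample_ground_truth(1, d, orient, acq)
        rend <- if (fixed_orient) renderer else NULL
        frame <- render_frame(gt[1, ], cfg, cond$coeffs, acq, renderer = rend)
        dark <- matrix(stats::rpois(cond$roi_px^2, cond$background_sd^2),
                       cond$roi_px, cond$roi_px)
        bg_hat <- estimate_background(dark)
        fit <- mle_localize(frame, orient, cfg, cond$coeffs, cond$fit,
                            background_mean = bg_hat, table = table)
        dplyr::bind_cols(
          dplyr::rename(gt[1, ], theta_true = "theta_rad", phi_true = "phi_rad"),
          stats::setNames(fit, paste0("fit_", names(fit))),
          tibble::tibble(rep = ri, child_seed = seeds[ri, gi]))
      })
    })
    out <- dplyr::bind_rows(rows)
    out$d_nm <- d
    if (progress) {
      message(sprintf("  d = %+5.0f nm: %d/%d converged", d,
                      sum(out$fit_converged), cond$n_rep))
    }
    out
  }
  results <- dplyr::bind_rows(purrr::map(seq_along(cond$defocus), run_point))

  stats <- results |>
    dplyr::group_by(.data$d_nm) |>
    dplyr::group_modify(function(g, key) precision_bias(dplyr::bind_cols(g, key))) |>
    dplyr::ungroup()

  if (compute_crb && fixed_orient) {
    crb_tbl <- crb_grid(cond$theta, cond$phi, cond$defocus,
                        n_photons = cond$n_photons,
                        background_sd = cond$background_sd,
                        coeffs = cond$coeffs, cfg = cfg,
                        excitation_coupling = cond$excitation_coupling,
                        roi_px = cond$roi_px) |>
      tidyr_longer_crb()
    stats <- dplyr::left_join(stats, crb_tbl, by = c("d_nm", "parameter")) |>
      dplyr::mutate(ratio = .data$sigma / .data$sqrt_crb_nm)
  }
  structure(list(results = results, stats = stats, condition = cond, cfg = cfg),
            class = "dipole_ensemble")
}

# reshape a crb_grid() row set to long (d_nm, parameter, sqrt_crb_nm)
tidyr_longer_crb <- function(crb_tbl) {
  dplyr::bind_rows(
    tibble::tibble(d_nm = crb_tbl$d_nm, parameter = "x", sqrt_crb_nm = crb_tbl$sqrt_crb_x_nm),
    tibble::tibble(d_nm = crb_tbl$d_nm, parameter = "y", sqrt_crb_nm = crb_tbl$sqrt_crb_y_nm),
    tibble::tibble(d_nm = crb_tbl$d_nm, parameter = "d", sqrt_crb_nm = crb_tbl$sqrt_crb_d_nm))
}

#' Bias and precision of an ensemble of fits
#'
#' Bias is the mean estimation error `mu = mean(hat - true)`; precision is
#' the sample standard deviation of the error (n - 1 denominator). Standard
#' errors are `sigma/sqrt(n)` for `mu` and `sigma/sqrt(2(n-1))` for `sigma`.
#' Only converged fits enter the statistics; the convergence count is
#' reported.
#'
#' @param results Tibble with columns `x_nm`, `fit_x_nm`, ... as produced by
#'   [run_ensemble()].
#' @param parameters Which parameters to summarize.
#' @return Tibble with one row per parameter: `parameter`, `n`, `n_converged`,
#'   `mu`, `sigma`, `se_mu`, `se_sigma` (all nm).
#' @export
precision_bias <- function(results, parameters = c("x", "y", "d")) {
  conv <- results[results$fit_converged %in% TRUE, , drop = FALSE]
  if (nrow(conv) < 2) {
    stop("fewer than two converged fits in the ensemble; no statistics available")
  }
  rows <- purrr::map(parameters, function(p) {
    err <- conv[[paste0("fit_", p, "_nm")]] - conv[[paste0(p, "_nm")]]
    n <- length(err)
    sg <- stats::sd(err)
    tibble::tibble(parameter = p, n = nrow(results), n_converged = n,
                   mu = mean(err), sigma = sg,
                   se_mu = sg / sqrt(n), se_sigma = sg / sqrt(2 * (n - 1)))
  })
  dplyr::bind_rows(rows)
}

#' Compare ensemble precision with the Cramér-Rao bound
#'
#' Computes `sigma / sqrt(CRB)` per parameter and defocus point with a
#' pass/fail flag at `ceiling`, and flags ratios suspiciously below 1 (more
#' than 3 standard errors of the sample SD), which for an unbiased estimator
#' would indicate an inconsistency.
#'
#' @param ensemble A `dipole_ensemble` whose stats carry CRB columns, or a
#'   stats tibble with `sigma`, `sqrt_crb_nm`, `n_converged`.
#' @param ceiling Acceptance ceiling for the ratio (default 1.15).
#' @return Tibble with `d_nm`, `parameter`, `sigma`, `sqrt_crb_nm`, `ratio`,
#'   `pass`, `suspicious_low`.
#' @export
crb_comparison <- function(ensemble, ceiling = 1.15) {
  stats <- if (inherits(ensemble, "dipole_ensemble")) ensemble$stats else ensemble
  if (!("sqrt_crb_nm" %in% names(stats))) {
    stop("no CRB columns present; run the ensemble with `compute_crb = TRUE`")
  }
  dplyr::mutate(
    dplyr::select(stats, dplyr::all_of(c("d_nm", "parameter", "n_converged",
                                         "sigma", "sqrt_crb_nm"))),
    ratio = .data$sigma / .data$sqrt_crb_nm,
    pass = .data$ratio <= ceiling,
    suspicious_low = .data$ratio < 1 - 3 / sqrt(2 * .data$n_converged))
}

#' Precision versus ROI size
#'
#' Repeats an ensemble at several ROI edge lengths and reports the achieved
#' precision together with the bound, reproducing the ROI-robustness analysis
#' (deviations from the bound are expected mainly at very small ROIs).
#'
#' @param roi_sizes Odd ROI edge lengths in pixels.
#' @param cond Template [ensemble_condition] (its `roi_px` is overridden).
#' @param cfg An [optical_config].
#' @return Tibble: `roi_px` plus the per-parameter ensemble stats and CRB.
#' @export
roi_size_sweep <- function(roi_sizes, cond, cfg = optical_config()) {
  if (any(roi_sizes %% 2 != 1)) stop("ROI sizes must be odd")
  purrr::map(roi_sizes, function(rp) {
    ci <- cond
    ci$roi_px <- as.integer(rp)
    ens <- run_ensemble(ci, cfg)
    dplyr::mutate(ens$stats, roi_px = as.integer(rp))
  }) |> dplyr::bind_rows()
}
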