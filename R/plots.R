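#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-condition statistics of an ensemble
#'
#' @param x A `dipole_ensemble` from [run_ensemble()].
#' @param ... Unused.
#' @return Tibble: one row per (defocus, parameter) with bias `mu`, precision
#'   `sigma`, standard errors, and — when computed — the matching
#'   `sqrt_crb_nm` and `ratio`.
#' @export
tidy.dipole_ensemble <- function(x, ...) {
  x$stats
}

#' One-row summary of an ensemble
#'
#' @param x A `dipole_ensemble`.
#' @param ... Unused.
#' @return One-row tibble: condition descriptors, convergence fraction, the
#'   worst lateral CRB ratio and the largest |bias|/se over the grid.
#' @export
glance.dipole_ensemble <- function(x, ...) {
  st <- x$stats
  lat <- st[st$parameter %in% c("x", "y"), , drop = FALSE]
  tibble::tibble(
    theta = x$condition$theta, phi = x$condition$phi,
    n_photons = x$condition$n_photons,
    background_sd = x$condition$background_sd,
    n_rep = x$condition$n_rep,
    n_defocus = length(x$condition$defocus),
    convergence = mean(x$results$fit_converged),
    max_abs_bias_nm = max(abs(lat$mu)),
    max_bias_z = max(abs(lat$mu) / lat$se_mu),
    worst_lateral_ratio = if ("ratio" %in% names(st)) max(lat$ratio) else NA_real_)
}

#' Plot a PSF image
#'
#' @param object A `psf_image`.
#' @param ... Unused.
#' @return A ggplot raster of the normalized intensity with object-space axes.
#' @export
autoplot.psf_image <- function(object, ...) {
  px <- attr(object, "pixel_nm")
  n <- nrow(object)
  centers <- (seq_len(n) - (n + 1) / 2) * px
  df <- expand.grid(x = centers, y = centers)
  df$intensity <- as.vector(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = "intensity")
}

#' Plot ensemble bias and precision against the Cramér-Rao bound
#'
#' Precision (solid, points) and bias (dotted) per fitted parameter across
#' the defocus grid, with the CRB as a dashed line where available.
#'
#' @param object A `dipole_ensemble`.
#' @param parameters Parameters to show (default lateral + defocus).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dipole_ensemble <- function(object, parameters = c("x", "y", "d"), ...) {
  st <- object$stats[object$stats$parameter %in% parameters, , drop = FALSE]
  p <- ggplot2::ggplot(st, ggplot2::aes(x = .data$d_nm, colour = .data$parameter)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sigma)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$sigma)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mu), linetype = "dotted") +
    ggplot2::labs(x = "defocus d (nm)",
                  y = "precision σ (solid) / bias μ (dotted), nm",
                  colour = "parameter")
  if ("sqrt_crb_nm" %in% names(st)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$sqrt_crb_nm),
                                linetype = "dashed")
  }
  p
}
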