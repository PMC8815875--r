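#' Convert a Noll single index to radial order and azimuthal frequency
#'
#' Zernike polynomials are indexed here by Noll's single index `j` (piston is
#' `j = 1`, defocus `j = 4`, vertical astigmatism `j = 6`). The mapping follows
#' Noll's ordering: radial orders `n` in increasing order, within an order the
#' azimuthal frequencies `|m|` in increasing order, and for `m != 0` the even
#' index of the pair carries the cosine term, the odd index the sine term.
#'
#' @param j Integer vector of Noll indices (each >= 1).
#' @return A data frame with columns `j`, `n` (radial order), `m` (azimuthal
#'   frequency, >= 0) and `parity` (`"cos"`, `"sin"`, or `"none"` for m = 0).
#' @export
#' @examples
#' noll_index_to_nm(1:11)
noll_index_to_nm <- function(j) {
  if (!is.numeric(j) || any(!is.finite(j)) || any(j < 1) || any(j != round(j))) {
    stop("Noll indices must be integers >= 1, got: ", paste(j, collapse = ", "))
  }
  j <- as.integer(j)
  jmax <- max(j)
  # generate the Noll ordering up to jmax
  tab_j <- integer(0); tab_n <- integer(0); tab_m <- integer(0); tab_p <- character(0)
  jj <- 1L; n <- 0L
  while (jj <= jmax) {
    ms <- seq.int(if (n %% 2L == 0L) 0L else 1L, n, by = 2L)
    for (m in ms) {
      if (m == 0L) {
        tab_j <- c(tab_j, jj); tab_n <- c(tab_n, n); tab_m <- c(tab_m, 0L)
        tab_p <- c(tab_p, "none"); jj <- jj + 1L
      } else {
        # pair (cos, sin): even j -> cos, odd j -> sin
        pair <- c(jj, jj + 1L)
        for (p in pair) {
          tab_j <- c(tab_j, p); tab_n <- c(tab_n, n); tab_m <- c(tab_m, m)
          tab_p <- c(tab_p, if (p %% 2L == 0L) "cos" else "sin")
        }
        jj <- jj + 2L
      }
    }
    n <- n + 1L
  }
  idx <- match(j, tab_j)
  data.frame(j = j, n = tab_n[idx], m = tab_m[idx], parity = tab_p[idx],
             stringsAsFactors = FALSE)
}

# Zernike radial polynomial R_n^m(rho), explicit factorial sum
zernike_radial <- function(n, m, rho) {
  val <- numeric(length(rho))
  for (k in 0:((n - m) / 2)) {
    coef <- (-1)^k * exp(lgamma(n - k + 1) - lgamma(k + 1) -
                           lgamma((n + m) / 2 - k + 1) - lgamma((n - m) / 2 - k + 1))
    val <- val + coef * rho^(n - 2 * k)
  }
  val
}

#' Evaluate an orthonormal Zernike polynomial (Noll indexing)
#'
#' Evaluates the unit-RMS (orthonormal over the unit disk) Zernike polynomial
#' with Noll index `j` at normalized pupil coordinates `(u, v)`. Outside the
#' unit disk the value is 0. In this convention the RMS of `w * Z_j` over the
#' disk is `|w|`, so aberration coefficients carry length units (nanometers of
#' RMS wavefront error).
#'
#' @param j Single Noll index (integer >= 1).
#' @param u,v Numeric vectors (or matrices) of normalized pupil coordinates.
#' @return Numeric array of the same shape as `u`.
#' @export
#' @examples
#' zernike_polynomial(4, 0, 0)        # orthonormal defocus at center: -sqrt(3)
#' zernike_polynomial(6, 0.5, 0)      # vertical astigmatism: sqrt(6) * 0.25
zernike_polynomial <- function(j, u, v) {
  if (length(j) != 1L) stop("`j` must be a single Noll index")
  nm <- noll_index_to_nm(j)
  if (!identical(dim(u), dim(v)) || length(u) != length(v)) {
    stop("`u` and `v` must have identical shapes")
  }
  rho2 <- u^2 + v^2
  inside <- rho2 <= 1
  rho <- sqrt(pmin(rho2, 1))
  out <- numeric(length(u))
  n <- nm$n; m <- nm$m
  norm <- if (m == 0L) sqrt(n + 1) else sqrt(2 * (n + 1))
  rad <- zernike_radial(n, m, rho)
  ang <- if (m == 0L) 1 else {
    phi <- atan2(v, u)
    if (nm$parity == "cos") cos(m * phi) else sin(m * phi)
  }
  out[inside] <- (norm * rad * ang)[inside]
  dim(out) <- dim(u)
  out
}

#' Create a Zernike coefficient set
#'
#' Coefficients are given in nanometers of RMS wavefront error on the
#' orthonormal (Noll) basis; absent indices are zero. Convenience names are
#' accepted: `astigmatism_rms_nm` maps to Noll index 6.
#'
#' @param ... Either a single named numeric vector/list, or name-value pairs.
#'   Names are Noll indices (`"4"`, `"6"`, ...) or convenience names.
#' @return An object of class `zernike_coefficients`: a named numeric vector
#'   keyed by Noll index.
#' @export
#' @examples
#' zernike_coefficients(astigmatism_rms_nm = 0.11 * 680)
#' zernike_coefficients(`6` = 74.8, `11` = 20)
zernike_coefficients <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) ) args <- as.list(args[[1]])
  if (length(args) == 1L && !is.null(names(args)) && names(args) == "" ) args <- as.list(args[[1]])
  if (length(args) == 0L) {
    out <- numeric(0)
    names(out) <- character(0)
    class(out) <- "zernike_coefficients"
    return(out)
  }
  nm <- names(args)
  if (is.null(nm) || any(nm == "")) stop("all Zernike coefficients must be named")
  nm[nm == "astigmatism_rms_nm"] <- "6"
  idx <- suppressWarnings(as.integer(nm))
  if (any(is.na(idx))) {
    stop("unknown Zernike coefficient name(s): ",
         paste(names(args)[is.na(idx)], collapse = ", "),
         " (use Noll indices or 'astigmatism_rms_nm')")
  }
  vals <- vapply(args, function(x) as.numeric(x)[1], numeric(1))
  if (any(!is.finite(vals))) stop("Zernike coefficients must be finite")
  if (any(idx < 1)) stop("Noll indices must be >= 1")
  # merge duplicates by summation (e.g. '6' given twice)
  out <- tapply(vals, idx, sum)
  out <- out[order(as.integer(names(out)))]
  storage.mode(out) <- "double"
  out <- stats::setNames(as.numeric(out), names(out))
  class(out) <- "zernike_coefficients"
  out
}

#' @export
print.zernike_coefficients <- function(x, ...) {
  cat("<zernike_coefficients> (nm RMS, Noll indices)\n")
  if (length(x) == 0) cat("  (none: unaberrated)\n")
  else for (i in seq_along(x)) cat(sprintf("  Z%-3s % .3f\n", names(x)[i], x[i]))
  invisible(x)
}

#' Cell-centered square sampling grid over the pupil
#'
#' Builds an `n x n` cell-centered Cartesian grid on `[-1, 1]^2` with the
#' circular aperture mask `u^2 + v^2 <= 1`. Cell-centered sampling makes the
#' midpoint quadrature of pupil integrals second-order accurate and keeps the
#' grid exactly symmetric about the origin.
#'
#' @param n Samples per axis (>= 32; default 128).
#' @return Object of class `pupil_grid`: list with matrices `u`, `v` (first
#'   index varies `u`), logical `mask`, axis vector `axis`, and cell area `du2`.
#' @export
pupil_grid <- function(n = 128) {
  if (!is.numeric(n) || length(n) != 1 || n < 32 || n != round(n)) {
    stop("`n` must be a single integer >= 32")
  }
  n <- as.integer(n)
  ax <- (seq_len(n) - 0.5) / n * 2 - 1
  u <- matrix(ax, n, n)          # u varies along rows
  v <- matrix(ax, n, n, byrow = TRUE)
  rho <- sqrt(u^2 + v^2)
  cell <- 2 / n
  # anti-aliased aperture: cells cut by the rim get their area coverage
  # (8x8 subsampled), which restores smooth convergence of pupil sums in n
  weight <- matrix(as.numeric(rho <= 1), n, n)
  edge <- which(abs(rho - 1) < cell)
  if (length(edge)) {
    m <- 256L
    xs_off <- ((seq_len(m) - 0.5) / m - 0.5) * cell
    for (idx in edge) {
      # coverage by slicing the cell in u: height of the disk chord in each
      # slice, clamped to the cell, midpoint-integrated
      us <- u[idx] + xs_off
      chord <- sqrt(pmax(1 - us^2, 0))
      lo <- v[idx] - cell / 2
      hi <- v[idx] + cell / 2
      covered <- pmin(pmax(chord, lo), hi) - pmin(pmax(-chord, lo), hi)
      weight[idx] <- mean(covered) / cell
    }
  }
  structure(list(n = n, axis = ax, u = u, v = v,
                 mask = (u^2 + v^2) <= 1, weight = weight, du2 = cell^2),
            class = "pupil_grid")
}

#' @export
print.pupil_grid <- function(x, ...) {
  cat(sprintf("<pupil_grid> %d x %d cell-centered samples on [-1,1]^2, %d inside aperture\n",
              x$n, x$n, sum(x$mask)))
  invisible(x)
}

#' Assemble an aberration wavefront from Zernike coefficients
#'
#' Returns `W(u, v) = sum_j w_j Z_j(u, v)` in nanometers on the aperture and 0
#' outside. The wavefront enters the imaging model as the pupil phase
#' `exp(i 2 pi W / lambda)`.
#'
#' @param coeffs A [zernike_coefficients] object (or named vector accepted by it).
#' @param grid A [pupil_grid].
#' @return Numeric `n x n` matrix of wavefront error in nm.
#' @export
#' @examples
#' g <- pupil_grid(64)
#' W <- build_wavefront(zernike_coefficients(`6` = 74.8), g)
#' # RMS over the disk equals the coefficient:
#' sqrt(mean(W[g$mask]^2))
build_wavefront <- function(coeffs, grid) {
  if (!inherits(coeffs, "zernike_coefficients")) coeffs <- zernike_coefficients(coeffs)
  if (!inherits(grid, "pupil_grid")) stop("`grid` must be a pupil_grid")
  W <- matrix(0, grid$n, grid$n)
  for (i in seq_along(coeffs)) {
    j <- as.integer(names(coeffs)[i])
    W <- W + coeffs[[i]] * zernike_polynomial(j, grid$u, grid$v)
  }
  W[!grid$mask] <- 0
  W
}

# Wavefront for the imaging model: evaluated at radially projected coordinates
# so rim cells with partial aperture coverage (centers just outside the unit
# disk) carry the boundary phase instead of a spurious jump to zero.
wavefront_on_pupil <- function(coeffs, grid) {
  if (!inherits(coeffs, "zernike_coefficients")) coeffs <- zernike_coefficients(coeffs)
  rho <- pmin(sqrt(grid$u^2 + grid$v^2), 1)
  phi <- atan2(grid$v, grid$u)
  W <- matrix(0, grid$n, grid$n)
  for (i in seq_along(coeffs)) {
    j <- as.integer(names(coeffs)[i])
    nm <- noll_index_to_nm(j)
    norm <- if (nm$m == 0L) sqrt(nm$n + 1) else sqrt(2 * (nm$n + 1))
    ang <- if (nm$m == 0L) 1 else if (nm$parity == "cos") cos(nm$m * phi) else sin(nm$m * phi)
    W <- W + coeffs[[i]] * norm * zernike_radial(nm$n, nm$m, rho) * ang
  }
  W
}
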