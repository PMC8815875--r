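cfg <- optical_config()

test_that("every PSF image is normalized to unit ROI sum", {
  states <- list(
    dipole_state(theta = pi / 2, phi = 0),
    dipole_state(x = 51, y = -87, d = 350, theta = pi / 3, phi = pi / 4),
    dipole_state(d = -500, theta = 0),
    dipole_state(x = -100, theta = pi / 6, phi = 1.1))
  for (co in list(no_coeffs(), astig_coeffs())) {
    for (st in states) {
      expect_lt(abs(sum(psf_image(st, cfg, co)) - 1), 1e-12)
    }
  }
})

test_that("dipole sign symmetries of the intensity", {
  # rotating the dipole in-plane by 180 degrees rotates the image by 180
  # degrees (vertical astigmatism and defocus are both invariant under it)
  a <- unclass(psf_image(dipole_state(d = 200, theta = pi / 3, phi = 0.7), cfg, astig_coeffs()))
  b <- unclass(psf_image(dipole_state(d = 200, theta = pi / 3, phi = 0.7 + pi), cfg, astig_coeffs()))
  expect_lt(max(abs(b - a[nrow(a):1, ncol(a):1])), 1e-7)
  # for an in-plane dipole, (theta, phi + pi) IS the antipodal orientation:
  # identical intensity everywhere
  a2 <- psf_image(dipole_state(d = 200, theta = pi / 2, phi = 0.7), cfg, astig_coeffs())
  b2 <- psf_image(dipole_state(d = 200, theta = pi / 2, phi = 0.7 + pi), cfg, astig_coeffs())
  expect_lt(max(abs(a2 - b2)), 1e-13)
})

test_that("mirror symmetry about the dipole plane (phi = 0, y -> -y)", {
  for (d in c(0, 250)) for (th in c(pi / 2, pi / 3)) {
    p <- unclass(psf_image(dipole_state(d = d, theta = th, phi = 0), cfg, astig_coeffs()))
    expect_lt(max(abs(p - p[, ncol(p):1])), 1e-14)
  }
})

test_that("90-degree dipole rotation maps to image transpose/rotation", {
  # with vertical astigmatism at d = 0, the in-plane dipole rotated by 90
  # degrees gives the transposed image
  p0 <- unclass(psf_image(dipole_state(theta = pi / 2, phi = 0), cfg, astig_coeffs()))
  p90 <- unclass(psf_image(dipole_state(theta = pi / 2, phi = pi / 2), cfg, astig_coeffs()))
  expect_lt(max(abs(t(p0) - p90)), 1e-7)
  # without astigmatism, rotating phi by 90 degrees rotates the image
  q0 <- unclass(psf_image(dipole_state(theta = pi / 3, phi = 0), cfg))
  q90 <- unclass(psf_image(dipole_state(theta = pi / 3, phi = pi / 2), cfg))
  n <- nrow(q0)
  rot <- t(q0)[, n:1]  # coordinate rotation by +90 degrees
  # the anti-aliased rim weights are u/v-symmetric only to quadrature accuracy
  expect_lt(max(abs(q90 - rot)), 1e-7)
})

test_that("axial dipole: dark pupil center, ring-shaped symmetric image", {
  pf <- bfp_field(0, 0, cfg)
  n <- pf$grid$n
  # no sample sits exactly at the origin; the nearest cell center carries a
  # field of order rho_cell ~ 1/n of the rim field
  ctr <- abs(pf$x[n / 2, n / 2]) + abs(pf$y[n / 2, n / 2])
  expect_lt(ctr, 3 / n * max(abs(pf$x)))
  p <- unclass(psf_image(dipole_state(theta = 0), cfg))
  c0 <- (nrow(p) + 1) / 2
  expect_lt(p[c0, c0], max(p))          # ring, not a peak
  expect_lt(max(abs(p - t(p))), 1e-7)   # rotational symmetry on the grid
})

test_that("image_field obeys the Fourier shift theorem and piston invariance", {
  g64 <- pupil_grid(64)
  pf <- bfp_field(pi / 3, pi / 4, cfg, g64)
  xs <- seq(-200, 200, by = 50)
  # a linear pupil phase W = NA * delta * u displaces the image by delta:
  # field with the tilt at x equals the untilted field at x - delta
  delta <- 108.33
  W_tilt <- cfg$numerical_aperture * delta * g64$u
  f_tilt <- image_field(pf, W_tilt, xs, xs, defocus_nm = 150)
  f_shift <- image_field(pf, NULL, xs - delta, xs, defocus_nm = 150)
  expect_equal(f_tilt$x, f_shift$x, tolerance = 1e-10)
  expect_equal(f_tilt$y, f_shift$y, tolerance = 1e-10)
  # piston adds a global phase: normalized intensity unchanged
  g <- pupil_grid(128)
  st <- dipole_state(x = 20, d = 100, theta = pi / 3, phi = pi / 4)
  p1 <- psf_image(st, cfg, zernike_coefficients(`6` = 74.8), grid = g)
  p2 <- psf_image(st, cfg, zernike_coefficients(`1` = 321, `6` = 74.8), grid = g)
  expect_lt(max(abs(p1 - p2)), 1e-13)
  # wavefront grid mismatch and empty coordinates are rejected
  expect_error(image_field(pf, matrix(0, 3, 3), xs, xs), "does not match")
  expect_error(image_field(pf, NULL, numeric(0), xs), "empty")
})

test_that("image_field intensities agree with the psf_image pipeline", {
  st <- dipole_state(x = 30, y = -40, d = 200, theta = pi / 3, phi = pi / 4)
  g <- pupil_grid(128)
  pf <- bfp_field(st$theta, st$phi, cfg, g)
  s <- (seq_len(17 * 3) - (17 * 3 + 1) / 2) * cfg$object_pixel_nm / 3
  # unaberrated: the two routes share everything but the code path
  fl <- image_field(pf, NULL, s - st$x, s - st$y, defocus_nm = st$d)
  ii <- dipoleloc:::bin_subpixels(Mod(fl$x)^2 + Mod(fl$y)^2, 3)
  direct <- psf_image(st, cfg, no_coeffs(), oversampling = 3, grid = g)
  expect_equal(ii / sum(ii), unclass(direct), tolerance = 1e-10,
               ignore_attr = TRUE)
  # with astigmatism, supplying the model's rim-clamped wavefront makes the
  # two routes agree exactly; the public wavefront (zero outside the disk)
  # differs only in partially covered rim cells
  W_model <- dipoleloc:::wavefront_on_pupil(astig_coeffs(), g)
  fl2 <- image_field(pf, W_model, s - st$x, s - st$y, defocus_nm = st$d)
  ii2 <- dipoleloc:::bin_subpixels(Mod(fl2$x)^2 + Mod(fl2$y)^2, 3)
  direct2 <- psf_image(st, cfg, astig_coeffs(), oversampling = 3, grid = g)
  expect_equal(ii2 / sum(ii2), unclass(direct2), tolerance = 1e-10,
               ignore_attr = TRUE)
  fl3 <- image_field(pf, build_wavefront(astig_coeffs(), g),
                     s - st$x, s - st$y, defocus_nm = st$d)
  ii3 <- dipoleloc:::bin_subpixels(Mod(fl3$x)^2 + Mod(fl3$y)^2, 3)
  expect_equal(ii3 / sum(ii3), unclass(direct2), tolerance = 2e-2,
               ignore_attr = TRUE)
})

test_that("renderer closure reproduces psf_image to machine precision", {
  r <- psf_renderer(pi / 6, pi / 4, cfg, astig_coeffs())
  ref <- psf_image(dipole_state(x = 37, y = -61, d = 213, theta = pi / 6, phi = pi / 4),
                   cfg, astig_coeffs())
  expect_lt(max(abs(r(37, -61, 213) - ref)), 1e-15)
})

test_that("discretization converges with pupil sampling and oversampling", {
  st <- dipole_state(x = 40, y = -30, d = 300, theta = pi / 3, phi = pi / 4)
  ref <- unclass(psf_image(st, cfg, astig_coeffs(), grid = pupil_grid(512)))
  errs <- sapply(c(64, 128, 256), function(np) {
    max(abs(unclass(psf_image(st, cfg, astig_coeffs(), grid = pupil_grid(np))) - ref)) / max(ref)
  })
  expect_true(all(diff(errs) < 0))  # monotone refinement
  p128 <- unclass(psf_image(st, cfg, astig_coeffs(), grid = pupil_grid(128)))
  p256 <- unclass(psf_image(st, cfg, astig_coeffs(), grid = pupil_grid(256)))
  expect_lt(max(abs(p128 - p256)) / max(p256), 1e-4)
  # oversampling refinement at the default pupil sampling
  p9 <- unclass(psf_image(st, cfg, astig_coeffs(), oversampling = 9))
  p18 <- unclass(psf_image(st, cfg, astig_coeffs(), oversampling = 18))
  expect_lt(max(abs(p9 - p18)) / max(p18), 2e-4)
})

test_that("input validation: aperture bound, ROI parity, oversampling", {
  expect_error(optical_config(numerical_aperture = 1.2), "immersion")
  expect_error(optical_config(numerical_aperture = 1.0), "immersion")
  expect_error(psf_image(dipole_state(), cfg, roi_px = 16), "odd")
  expect_error(psf_image(dipole_state(), cfg, oversampling = 0), "oversampling")
  expect_error(dipole_state(theta = 2), "theta")
})

test_that("astigmatic line-focus separation calibrates the astigmatism", {
  sep <- astigmatic_foci_separation(cfg, astig_coeffs())
  expect_lt(abs(sep - 1400), 0.15 * 1400)
  # separation is linear in the astigmatism coefficient
  sep2 <- astigmatic_foci_separation(cfg, zernike_coefficients(`6` = 2 * 74.8),
                                     d_range = c(-2600, 2600), d_step = 20)
  expect_lt(abs(sep2 - 2 * sep) / (2 * sep), 0.05)
  expect_equal(astigmatic_foci_separation(cfg, zernike_coefficients()), 0)
  # a too-narrow scan range is diagnosed
  expect_error(astigmatic_foci_separation(cfg, astig_coeffs(),
                                          d_range = c(-300, 300)),
               "widen")
})
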