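cfg <- optical_config()

test_that("expected pixel counts: linearity, background offset, pixel shift", {
  st <- dipole_state(theta = pi / 2, phi = pi / 4)
  nu0 <- expected_pixels(st, cfg, astig_coeffs(), n_eff = 5e5, background_mean = 0)
  nu_b <- expected_pixels(st, cfg, astig_coeffs(), n_eff = 5e5, background_mean = 9e4)
  expect_equal(sum(nu0), 5e5, tolerance = 1e-12)
  expect_equal(nu_b - nu0, matrix(9e4, 17, 17), tolerance = 1e-12)
  # translating the emitter by exactly one pixel shifts the interior pattern
  px <- cfg$object_pixel_nm
  nu1 <- expected_pixels(dipole_state(x = px, theta = pi / 2, phi = pi / 4),
                         cfg, astig_coeffs(), n_eff = 5e5, background_mean = 0)
  # interior pixels shift by one index exactly, up to the overall window
  # renormalization (the PSF mass inside the shifted window differs by the
  # tails crossing the ROI edge)
  expect_equal(nu1[2:17, ] / sum(nu1[2:17, ]), nu0[1:16, ] / sum(nu0[1:16, ]),
               tolerance = 1e-9)
})

test_that("Fisher matrix is symmetric, positive definite, and scales with photons", {
  st <- dipole_state(d = 150, theta = pi / 3, phi = pi / 4)
  info <- fisher_matrix(st, cfg, astig_coeffs(), n_eff = 5e5)
  expect_equal(info, t(info))
  expect_true(all(eigen(info, symmetric = TRUE)$values > 0))
  info10 <- fisher_matrix(st, cfg, astig_coeffs(), n_eff = 5e6)
  expect_equal(unclass(info10), 10 * unclass(info), tolerance = 1e-10)
  # symmetric condition: x-y cross information vanishes
  info_sym <- fisher_matrix(dipole_state(theta = pi / 2, phi = 0), cfg, no_coeffs())
  expect_lt(abs(info_sym["x", "y"]),
            1e-3 * sqrt(info_sym["x", "x"] * info_sym["y", "y"]))
})

test_that("difference-quotient steps are inside the converged regime", {
  st <- dipole_state(d = 200, theta = pi / 3, phi = pi / 4)
  i1 <- fisher_matrix(st, cfg, astig_coeffs(), step_xy_nm = 1, step_d_nm = 2)
  i2 <- fisher_matrix(st, cfg, astig_coeffs(), step_xy_nm = 0.5, step_d_nm = 1)
  expect_lt(max(abs(i2 - i1) / abs(i1)), 0.005)
  expect_error(fisher_matrix(st, cfg, step_xy_nm = 0), "positive")
})

test_that("bounds: closed form, photon scaling, background penalty", {
  i_diag <- structure(diag(c(4, 4, 0.25)), class = c("fisher_matrix", "matrix"),
                      dimnames = list(c("x", "y", "d"), c("x", "y", "d")))
  expect_equal(unname(crb(i_diag)), c(0.5, 0.5, 2))
  g1 <- crb_grid(pi / 2, pi / 4, 0, n_photons = 5e5, coeffs = astig_coeffs())
  g10 <- crb_grid(pi / 2, pi / 4, 0, n_photons = 5e6, coeffs = astig_coeffs())
  expect_equal(g1$sqrt_crb_x_nm / g10$sqrt_crb_x_nm, sqrt(10), tolerance = 1e-6)
  gb <- crb_grid(pi / 2, pi / 4, c(-300, 0, 300), background_sd = 300,
                 coeffs = astig_coeffs())
  g0 <- crb_grid(pi / 2, pi / 4, c(-300, 0, 300), background_sd = 0,
                 coeffs = astig_coeffs())
  expect_true(all(gb$sqrt_crb_x_nm > g0$sqrt_crb_x_nm))
  expect_true(all(gb$sqrt_crb_y_nm > g0$sqrt_crb_y_nm))
  expect_true(all(gb$sqrt_crb_d_nm > g0$sqrt_crb_d_nm))
})

test_that("with astigmatism the lateral bounds mirror under defocus reversal", {
  g <- crb_grid(pi / 2, pi / 4, seq(-400, 400, 200), coeffs = astig_coeffs())
  expect_equal(g$sqrt_crb_x_nm, rev(g$sqrt_crb_y_nm), tolerance = 1e-6)
})

test_that("degenerate conditions fail with an explicit diagnosis", {
  # axial dipole without astigmatism at focus: defocus is unidentifiable
  info <- fisher_matrix(dipole_state(theta = 0), cfg, no_coeffs())
  expect_error(crb(info), "'d'")
  # no excited photons under coupling
  expect_error(crb_grid(0, 0, 0, excitation_coupling = TRUE,
                        coeffs = astig_coeffs()),
               "singular")
})

test_that("information grows (bounds shrink) with the fitted ROI", {
  vals <- sapply(c(9, 17, 25), function(roi) {
    crb_grid(pi / 6, pi / 4, 0, coeffs = astig_coeffs(), roi_px = roi)$sqrt_crb_x_nm
  })
  expect_true(all(diff(vals) < 1e-6))  # non-increasing with small slack
})
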