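test_that("polarized excitation yield follows the squared projections", {
  y <- excitation_yield(pi / 2, 0, 5e5)
  expect_equal(y$n_x, 5e5)
  expect_equal(y$n_y, 0)
  expect_equal(y$n_eff, 5e5)
  # axial dipole is never excited
  expect_equal(excitation_yield(0, 1.2, 5e5)$n_eff, 0)
  # equal split at theta = phi = pi/4
  y2 <- excitation_yield(pi / 4, pi / 4, 4e5)
  expect_equal(y2$n_x, 1e5)
  expect_equal(y2$n_y, 1e5)
  expect_equal(y2$n_eff, 2e5)
  # bookkeeping identity, vectorized
  yv <- excitation_yield(runif(20, 0, pi / 2), runif(20, 0, 2 * pi))
  expect_equal(yv$n_x + yv$n_y, yv$n_eff)
})

test_that("ground-truth sampling is seeded, centered and grid-faithful", {
  g1 <- sample_ground_truth(1000, defocus = seq(-500, 500, 100),
                            orientation = c(pi / 3, pi / 4), seed = 42)
  g2 <- sample_ground_truth(1000, defocus = seq(-500, 500, 100),
                            orientation = c(pi / 3, pi / 4), seed = 42)
  expect_identical(g1, g2)
  expect_setequal(unique(g1$d_nm), seq(-500, 500, 100))
  expect_true(all(abs(g1$x_nm) <= 108) && all(abs(g1$y_nm) <= 108))
  # uniform moments: mean 0 +/- 3 standard errors, se = (216/sqrt(12))/sqrt(n)
  se <- 216 / sqrt(12) / sqrt(1000)
  expect_lt(abs(mean(g1$x_nm)), 3 * se)
  expect_lt(abs(mean(g1$y_nm)), 3 * se)
  # hemisphere-uniform orientations: cos(theta) uniform on (0, 1)
  gr <- sample_ground_truth(4000, orientation = "random", seed = 7)
  expect_lt(abs(mean(cos(gr$theta_rad)) - 0.5), 3 * sqrt(1 / 12 / 4000))
  # excitation coupling propagates to n_eff
  gc <- sample_ground_truth(10, orientation = c(pi / 6, 0),
                            acq = acquisition_params(excitation_coupling = TRUE),
                            seed = 1)
  expect_equal(gc$n_eff, rep(5e5 * sin(pi / 6)^2, 10))
})

test_that("frame rendering follows the Poisson pixel model", {
  cfg <- default_cfg()
  acq <- acquisition_params(background_sd = 300)
  # pure background: mean b^2 = 9e4 per pixel
  gt0 <- tibble::tibble(x_nm = 0, y_nm = 0, d_nm = 0, theta_rad = pi / 2,
                        phi_rad = 0, n_eff = 0)
  withr::with_seed(3, {
    fr <- render_frame(gt0, cfg, no_coeffs(), acq)
    expect_lt(abs(mean(fr) - 9e4), 3 * 300 / 17)
  })
  # no photons at all -> empty frame
  acq0 <- acquisition_params(background_sd = 0)
  expect_true(all(render_frame(gt0, cfg, no_coeffs(), acq0) == 0))
  # expected counts: n_eff * (unit-mass PSF) + K * b^2
  gt <- tibble::tibble(x_nm = 30, y_nm = -50, d_nm = 200, theta_rad = pi / 3,
                       phi_rad = pi / 4, n_eff = 5e5)
  nu <- render_frame(gt, cfg, astig_coeffs(), acq, expected_only = TRUE)
  expect_equal(sum(nu), 5e5 + 17^2 * 9e4, tolerance = 1e-12)
  # empirical mean and variance/mean ratio over repeated small frames
  gt_small <- tibble::tibble(x_nm = 0, y_nm = 0, d_nm = 0, theta_rad = pi / 2,
                             phi_rad = pi / 4, n_eff = 2000)
  acq_s <- acquisition_params(n_max = 2000, background_sd = 5, roi_px = 9)
  rend <- psf_renderer(pi / 2, pi / 4, cfg, astig_coeffs(), roi_px = 9)
  nu_s <- render_frame(gt_small, cfg, astig_coeffs(), acq_s, rend, expected_only = TRUE)
  frames <- withr::with_seed(11, replicate(3000, {
    render_frame(gt_small, cfg, astig_coeffs(), acq_s, rend)
  }))
  m <- apply(frames, c(1, 2), mean)
  v <- apply(frames, c(1, 2), var)
  expect_true(all(abs(m - nu_s) < 3 * sqrt(nu_s / 3000) + 1e-9))
  ratio <- v / m
  se_ratio <- sqrt(2 / 3000)
  expect_true(all(abs(ratio - 1) < 4 * se_ratio))
})

test_that("simulated stacks are bit-reproducible from the seed", {
  cfg <- default_cfg()
  acq <- acquisition_params(background_sd = 100)
  s1 <- simulate_frames(4, 100, c(pi / 3, pi / 4), cfg, astig_coeffs(), acq, seed = 9)
  s2 <- simulate_frames(4, 100, c(pi / 3, pi / 4), cfg, astig_coeffs(), acq, seed = 9)
  expect_identical(s1, s2)
  s3 <- simulate_frames(4, 100, c(pi / 3, pi / 4), cfg, astig_coeffs(), acq, seed = 10)
  expect_false(identical(s1$frame_px[[1]], s3$frame_px[[1]]))
  expect_true(all(vapply(s1$frame_px, function(f) all(f >= 0 & f == round(f)), TRUE)))
})
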