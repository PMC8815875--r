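cfg <- optical_config()

test_that("background and photon-number estimators behave as linear estimators", {
  expect_equal(estimate_background(matrix(7.5, 17, 17)), 7.5)
  expect_equal(estimate_background(matrix(0, 17, 17)), 0)
  withr::with_seed(5, {
    dark <- matrix(rpois(289, 9e4), 17, 17)
    expect_lt(abs(estimate_background(dark) - 9e4), 3 * 300 / 17)
  })
  # telescoping identity on a noise-free frame
  st <- dipole_state(x = 20, y = 30, d = 100, theta = pi / 3, phi = pi / 4)
  frame <- expected_image(st, background = 250)
  expect_equal(estimate_neff(frame, 250), 5e5, tolerance = 1e-9)
  expect_equal(estimate_neff(expected_image(st)), 5e5, tolerance = 1e-9)
  expect_warning(est <- estimate_neff(matrix(0, 17, 17), 10), "clipped")
  expect_equal(est, 1)
  # unbiasedness across noisy frames
  nu <- expected_image(st, background = 1e4)
  withr::with_seed(8, {
    ests <- replicate(400, estimate_neff(matrix(rpois(289, nu), 17, 17), 1e4))
  })
  se <- sqrt(sum(nu)) / sqrt(400)
  expect_lt(abs(mean(ests) - 5e5), 3 * se)
})

test_that("likelihood is maximal at the truth for exact-model data", {
  st <- dipole_state(x = 10, y = -20, d = 150, theta = pi / 3, phi = pi / 4)
  frame <- expected_image(st, background = 1e4)
  args <- list(frame = frame, cfg = cfg, coeffs = astig_coeffs(),
               n_eff = 5e5, background_mean = 1e4)
  nll0 <- do.call(negative_log_likelihood,
                  c(args, list(x = st$x, y = st$y, d = st$d,
                               theta = st$theta, phi = st$phi)))
  for (delta in list(c(10, 0, 0), c(0, 10, 0), c(0, 0, 60), c(-7, 5, -40))) {
    nllp <- do.call(negative_log_likelihood,
                    c(args, list(x = st$x + delta[1], y = st$y + delta[2],
                                 d = st$d + delta[3],
                                 theta = st$theta, phi = st$phi)))
    expect_gt(nllp, nll0)
  }
  # stationarity: central-difference gradient at the truth is tiny compared
  # with the gradient 50 nm away
  gfun <- function(x0) {
    h <- 0.5
    sapply(1:2, function(i) {
      dd <- c(0, 0); dd[i] <- h
      (do.call(negative_log_likelihood,
               c(args, list(x = x0[1] + dd[1], y = x0[2] + dd[2], d = st$d,
                            theta = st$theta, phi = st$phi))) -
       do.call(negative_log_likelihood,
               c(args, list(x = x0[1] - dd[1], y = x0[2] - dd[2], d = st$d,
                            theta = st$theta, phi = st$phi)))) / (2 * h)
    })
  }
  g_truth <- gfun(c(st$x, st$y))
  g_far <- gfun(c(st$x + 50, st$y))
  expect_lt(sqrt(sum(g_truth^2)), 1e-3 * sqrt(sum(g_far^2)))
})

test_that("raw and normalized likelihoods have the same ordering and optimum", {
  st <- dipole_state(x = 10, y = -20, d = 150, theta = pi / 2, phi = pi / 4)
  frame <- withr::with_seed(2, matrix(rpois(289, expected_image(st, background = 1e4)), 17, 17))
  cand <- rbind(c(10, -20, 150), c(12, -20, 150), c(10, -15, 120), c(0, 0, 0))
  vals <- apply(cand, 1, function(p) {
    raw <- negative_log_likelihood(frame, p[1], p[2], p[3], st$theta, st$phi,
                                   cfg, astig_coeffs(), 5e5, 1e4)
    nrm <- negative_log_likelihood(frame, p[1], p[2], p[3], st$theta, st$phi,
                                   cfg, astig_coeffs(), 5e5, 1e4,
                                   likelihood = "normalized")
    c(raw, nrm)
  })
  expect_equal(order(vals[1, ]), order(vals[2, ]))
  expect_true(attr(negative_log_likelihood(frame, 0, 0, 0, st$theta, st$phi,
                                           cfg, astig_coeffs(), 5e5, 1e4),
                   "factorial_dropped"))
  # both fit modes land on the same estimate
  tb <- table_pi2()
  f_raw <- mle_localize(frame, c(st$theta, st$phi), cfg, astig_coeffs(),
                        fit_config(likelihood = "raw"), background_mean = 1e4,
                        table = tb, seed = 31)
  f_nrm <- mle_localize(frame, c(st$theta, st$phi), cfg, astig_coeffs(),
                        fit_config(likelihood = "normalized"),
                        background_mean = 1e4, table = tb, seed = 31)
  # the rescaled objective stops at a slightly different point of the same
  # basin (identical minimizer up to optimizer termination tolerance)
  expect_equal(f_raw$x_nm, f_nrm$x_nm, tolerance = 0.02)
  expect_equal(f_raw$d_nm, f_nrm$d_nm, tolerance = 0.02)
})

test_that("lookup-table model matches the direct Fourier model", {
  tb <- table_pi2()
  r3 <- psf_renderer(pi / 2, pi / 4, cfg, astig_coeffs(), oversampling = 3)
  for (p in list(c(0, 0, 0), c(37.3, -61.2, 213.4), c(-100, 95, -480))) {
    direct <- 5e5 * r3(p[1], p[2], p[3]) + 1e4
    tabm <- dipoleloc:::table_model_image(tb, p[1], p[2], p[3], 5e5, 1e4)
    expect_lt(max(abs(tabm - direct) / direct), 1e-4)
  }
  # analytic gradient of the tabulated objective matches finite differences
  frame <- withr::with_seed(3, matrix(rpois(289, 5e5 * r3(20, -30, 150) + 1e4), 17, 17))
  obj <- dipoleloc:::table_objective(tb, frame, 5e5, 1e4, "nll")
  p0 <- c(18, -28, 140)
  g <- obj$gr(p0)
  for (i in 1:3) {
    e <- c(0, 0, 0); e[i] <- 1e-3
    expect_equal(g[i], (obj$fn(p0 + e) - obj$fn(p0 - e)) / 2e-3,
                 tolerance = 1e-3)
  }
})

test_that("least-squares initialization lands near the truth and is seeded", {
  st <- dipole_state(x = 25, y = -40, d = 0, theta = pi / 2, phi = pi / 4)
  frame <- expected_image(st)
  tb <- table_pi2()
  init1 <- withr::with_seed(12, least_squares_init(frame, tb, 5e5, 0))
  init2 <- withr::with_seed(12, least_squares_init(frame, tb, 5e5, 0))
  expect_identical(init1, init2)
  expect_lt(abs(init1$par[1] - st$x), 5)
  expect_lt(abs(init1$par[2] - st$y), 5)
})

test_that("noise-free frames are recovered for all benchmark orientations and defocus", {
  # parameter recovery to discretization tolerance across the full
  # orientation x defocus grid of the benchmark protocol, astigmatism on
  ds <- seq(-500, 500, by = 100)
  for (th in c(pi / 2, pi / 3, pi / 6, 0)) {
    for (ph in c(0, pi / 4)) {
      tb <- psf_table(th, ph, cfg, astig_coeffs())
      rend <- psf_renderer(th, ph, cfg, astig_coeffs())
      for (d in ds) {
        truth <- withr::with_seed(1000 + round(100 * th + 10 * ph) + d,
                                  c(runif(2, -108, 108), d))
        frame <- 5e5 * rend(truth[1], truth[2], truth[3])
        fit <- mle_localize(frame, c(th, ph), cfg, astig_coeffs(),
                            table = tb, background_mean = 0,
                            seed = 77 + d)
        expect_true(fit$converged)
        expect_lt(abs(fit$x_nm - truth[1]), 0.5)
        expect_lt(abs(fit$y_nm - truth[2]), 0.5)
        expect_lt(abs(fit$d_nm - truth[3]), 5)
      }
    }
  }
})

test_that("fitting the orientation too recovers a noise-free tilted dipole", {
  st <- dipole_state(x = 30, y = -20, d = 150, theta = pi / 3, phi = pi / 4)
  frame <- expected_image(st)
  fit <- mle_localize(frame, c(st$theta, st$phi), cfg, astig_coeffs(),
                      fit_config("xydtp", oversampling = 3),
                      n_eff = 5e5, background_mean = 0, seed = 5)
  expect_true(fit$converged)
  expect_lt(abs(fit$x_nm - st$x), 2)
  expect_lt(abs(fit$y_nm - st$y), 2)
  expect_lt(abs(fit$theta_rad - st$theta), 0.05)
  expect_lt(abs(((fit$phi_rad - st$phi + pi) %% (2 * pi)) - pi), 0.05)
})

test_that("orientation wrapping respects the antipodal equivalence", {
  w <- dipoleloc:::canonical_orientation(pi / 3 + pi / 2, 0.3)  # theta > pi/2
  expect_true(w[["theta"]] >= 0 && w[["theta"]] <= pi / 2)
  expect_equal(w[["theta"]], pi / 2 - pi / 3, tolerance = 1e-12)
  expect_equal(w[["phi"]], (0.3 + pi) %% (2 * pi), tolerance = 1e-12)
  same <- dipoleloc:::canonical_orientation(0.4, 5.1)
  expect_equal(unname(same), c(0.4, 5.1), tolerance = 1e-12)
})

test_that("batch fitting is seed-deterministic and shares the table", {
  sim <- simulate_frames(3, 0, c(pi / 2, pi / 4), cfg, astig_coeffs(),
                         acquisition_params(background_sd = 100), seed = 21)
  f1 <- fit_frames(sim, cfg, astig_coeffs(), background_mean = 1e4, seed = 4)
  f2 <- fit_frames(sim, cfg, astig_coeffs(), background_mean = 1e4, seed = 4)
  drop_time <- function(x) x[, setdiff(names(x), "fit_runtime_s")]
  expect_identical(drop_time(f1), drop_time(f2))
  expect_true(all(f1$fit_converged))
  expect_false(any(c("frame_px") %in% names(f1)))
})
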