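test_that("slope weights reproduce the OLS slope and its identities", {
  expect_equal(slope_weights(1), c(-1, 1))
  expect_equal(slope_weights(2), c(-0.5, 0, 0.5))
  set.seed(51)
  for (n in c(1, 2, 5, 11)) {
    y <- rnorm(n + 1)
    ols <- unname(coef(lm(y ~ x, data.frame(x = 0:n, y = y)))[2])
    expect_equal(sum(slope_weights(n) * y), ols, tolerance = 1e-10)
  }
  for (n in 1:50) {
    L <- slope_weights(n)
    expect_equal(sum(L), 0, tolerance = 1e-12)
    expect_equal(sum((0:n) * L), 1, tolerance = 1e-12)
  }
  expect_error(slope_weights(0), "interval")
})

test_that("lag-0 latent autocorrelation has unit diagonal, all entries bounded", {
  p <- default_structure_params("ventricle-like")
  m <- assemble_model(p)
  r0 <- autocorrelation(m, 50, 0)
  expect_equal(unname(diag(r0)), c(1, 1), tolerance = 1e-12)
  for (age in c(20, 40, 60, 80)) for (lag in c(0, 1, 5, 15)) {
    r <- autocorrelation(m, age, lag)
    expect_true(all(abs(r) <= 1 + 1e-12))
  }
})

test_that("lag-0 autocovariance returns the propagated covariance exactly", {
  p <- default_structure_params("hippocampus-like")
  m <- assemble_model(p)
  k <- snap_age(m$grid, 57)
  b <- propagate_belief(initial_state_distribution(p, covariate_profile()),
                        m$system, 0, k)
  expect_equal(unname(autocovariance(m, 57, 0)), b$Sigma, tolerance = 1e-12)
  mm <- autocovariance(m, 57, 0, measured = TRUE, sigma_r = 50)
  expect_equal(mm$ss, b$Sigma[1, 1] + 50^2)
})

test_that("measurement noise attenuates autocorrelation", {
  p <- default_structure_params("hippocampus-like")
  m <- assemble_model(p)
  for (lag in c(2, 10, 30)) {
    lat <- autocorrelation(m, 45, lag)["s", "s"]
    meas <- autocorrelation(m, 45, lag, measured = TRUE)["s", "s"]
    expect_lt(abs(meas), abs(lat))
  }
  expect_lte(abs(volume_change_correlation(m, 70, measured = TRUE)),
             abs(volume_change_correlation(m, 70, measured = FALSE)))
})

test_that("explained variance is one at the reference age and tracks rho^2", {
  p <- default_structure_params("hippocampus-like")
  m <- assemble_model(p)
  expect_equal(explained_variance(m, 30), 1)
  for (a in c(45, 65, 85)) {
    expect_equal(explained_variance(m, a),
                 autocorrelation(m, 30, a - 30)["s", "s"]^2, tolerance = 1e-12)
    expect_equal(explained_variance(m, a, measured = TRUE),
                 autocorrelation(m, 30, a - 30, measured = TRUE)["s", "s"]^2,
                 tolerance = 1e-12)
  }
  expect_error(explained_variance(m, 25), "ref_age")
})

test_that("a deterministic model keeps explained variance at one", {
  p <- model_params(fs = 0, fv = 0.1, b_ctrl = c(0, -1, -2, -3, -4),
                    q_ctrl = rep(-Inf, 5),
                    init_mean_coeffs = c(7000, 0, 0, -1, 0, 0),
                    init_cov = diag(c(300^2, 0)),
                    site_biases = c(a = 0), site_noise_sds = c(a = 10))
  m <- assemble_model(p)
  for (a in c(40, 60, 90))
    expect_equal(explained_variance(m, a), 1, tolerance = 1e-9)
})

test_that("volume-change correlation vanishes without coupling or noise", {
  p <- model_params(fs = 0, fv = 0, b_ctrl = rep(0, 5), q_ctrl = rep(-Inf, 5),
                    init_mean_coeffs = c(100, 0, 0, 1, 0, 0),
                    init_cov = diag(c(25, 4)),
                    site_biases = c(a = 0), site_noise_sds = c(a = 1))
  m <- assemble_model(p)
  expect_equal(volume_change_correlation(m, 18, measured = FALSE), 0)
})

test_that("delta correlation equals the two-session slope correlation", {
  set.seed(52)
  models <- list(assemble_model(default_structure_params("hippocampus-like")),
                 assemble_model(default_structure_params("ventricle-like")))
  for (m in models) for (case in list(c(42, 4), c(60, 6), c(30, 12))) {
    d <- delta_estimate_correlation(m, case[1], case[2])
    s <- slope_estimate_correlation(m, case[1], case[2], sessions = 2)
    expect_equal(d, s, tolerance = 1e-12)
  }
  expect_error(delta_estimate_correlation(models[[1]], 50, 0), "interval")
  expect_error(slope_estimate_correlation(models[[1]], 50, 5, sessions = 3),
               "grid")
})

test_that("a noise-free constant change rate is measured perfectly", {
  p <- model_params(fs = 0, fv = 0, b_ctrl = rep(0, 5), q_ctrl = rep(-Inf, 5),
                    init_mean_coeffs = c(100, 0, 0, 1, 0, 0),
                    init_cov = diag(c(25, 4)),
                    site_biases = c(a = 0), site_noise_sds = c(a = 1))
  m <- assemble_model(p)
  expect_equal(delta_estimate_correlation(m, 30, 5, sigma_r = 0), 1,
               tolerance = 1e-9)
  expect_equal(slope_estimate_correlation(m, 30, 6, 4, sigma_r = 0), 1,
               tolerance = 1e-9)
})

test_that("norm curves report the propagated mean and 2-SD band", {
  p <- default_structure_params("hippocampus-like")
  m <- assemble_model(p)
  nc <- norm_curves(m, ages = c(18, 40, 70))
  at18 <- nc[nc$age == 18, ]
  b0 <- initial_state_distribution(p, covariate_profile())
  expect_equal(at18$mean, b0$mu)
  expect_equal(at18$hi - at18$mean, 2 * sqrt(diag(b0$Sigma)))
  k <- snap_age(m$grid, 70)
  b70 <- propagate_belief(b0, m$system, 0, k)
  at70 <- nc[nc$age == 70, ]
  expect_equal(at70$hi - at70$lo, 4 * sqrt(diag(b70$Sigma)), tolerance = 1e-10)
  # degenerate model: bands collapse on the mean curve
  pd <- model_params(fs = 0, fv = 0.1, b_ctrl = c(0, -1, -2, -3, -4),
                     q_ctrl = rep(-Inf, 5),
                     init_mean_coeffs = c(7000, 0, 0, -1, 0, 0),
                     init_cov = matrix(0, 2, 2),
                     site_biases = c(a = 0), site_noise_sds = c(a = 10))
  ncd <- norm_curves(assemble_model(pd), ages = c(30, 60, 90))
  expect_equal(ncd$lo, ncd$mean)
  expect_equal(ncd$hi, ncd$mean)
})

test_that("explained variance declines with target age on the fixtures", {
  for (tag in c("hippocampus-like", "ventricle-like")) {
    m <- assemble_model(default_structure_params(tag))
    ev <- explained_variance(m, 30:95)
    expect_true(all(diff(ev) <= 1e-12))
  }
})

test_that("slope-estimate SD follows the analytic design formulas", {
  expect_equal(design_slope_sd(study_design(4, 2, "equal", sigma_r = 3)),
               sqrt(2) * 3 / 4, tolerance = 1e-12)
  d1 <- design_slope_sd(study_design(2, 7, "equal", sigma_r = 1.3))
  d2 <- design_slope_sd(study_design(4, 7, "equal", sigma_r = 1.3))
  expect_equal(d1 / d2, 2, tolerance = 1e-12)
  # weight-sum identity: Var = sum(Lambda_i^2) sigma^2 / dt^2, dt = T/(N-1)
  for (N in 2:50) {
    L <- slope_weights(N - 1)
    T <- 6; sr <- 2.5
    expect_equal(design_slope_sd(study_design(T, N, "equal", sr)),
                 sqrt(sum(L^2) * sr^2) / (T / (N - 1)), tolerance = 1e-12)
  }
  expect_error(study_design(3, 5, "endpoint-clusters"), "even")
  expect_error(study_design(-1, 2), "positive")
})

test_that("signal-to-noise ratio scales with the change rate", {
  d <- study_design(4, 2, "equal", sigma_r = 3)
  expect_equal(design_snr(d, -10), 10 / design_slope_sd(d))
})

test_that("session matching recovers the trivial and capped cases", {
  ref <- study_design(2, 2, "equal", sigma_r = 1)
  expect_equal(sessions_to_match(ref, interval = 2, "equal"), 2L)
  tight <- study_design(10, 2, "equal", sigma_r = 1)
  expect_warning(n <- sessions_to_match(tight, interval = 1, "equal",
                                        n_max = 50L), "unreachable")
  expect_true(is.na(n))
})

test_that("posterior draws induce ordered credible bands on norm curves", {
  set.seed(53)
  p <- default_structure_params("hippocampus-like", n_sites = 2)
  th <- unname(params_to_theta(p))
  draws <- t(replicate(25, th + rnorm(length(th), 0, 0.02 * pmax(abs(th), 1))))
  colnames(draws) <- names(params_to_theta(p))
  fake_fit <- structure(list(draws = draws, site_ids = names(p$site_biases),
                             knots = p$b_spline$knots,
                             icv_center = 0, icv_scale = 1),
                        class = "posterior_fit")
  m <- assemble_model(p)
  nc <- norm_curves(m, ages = c(30, 60, 85), posterior = fake_fit,
                    n_draws = 25)
  expect_true(all(nc$mean_lo95 <= nc$mean_lo50 + 1e-12))
  expect_true(all(nc$mean_lo50 <= nc$mean_hi50 + 1e-12))
  expect_true(all(nc$mean_hi50 <= nc$mean_hi95 + 1e-12))
  # the band tracks the point curve computed from the central parameters
  expect_lt(max(abs(nc$mean - (nc$mean_lo95 + nc$mean_hi95) / 2) /
                  pmax(abs(nc$mean), 1)), 0.25)
})
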