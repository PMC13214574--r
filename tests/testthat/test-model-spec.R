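test_that("spline interpolation is exact for constants, lines and knots", {
  sp <- nc_spline(rep(3, 5))
  expect_equal(eval_spline(sp, c(18, 33.7, 61.2, 100)), rep(3, 4))
  k <- default_knots()
  sp2 <- nc_spline(0.1 * (k - 18))
  tt <- seq(18, 100, by = 0.7)
  expect_equal(eval_spline(sp2, tt), 0.1 * (tt - 18), tolerance = 1e-12)
  vals <- c(2, -1, 0.5, 4, -3)
  sp3 <- nc_spline(vals)
  expect_equal(eval_spline(sp3, k), vals, tolerance = 1e-12)
})

test_that("spline matches an independent tridiagonal natural-spline solve", {
  set.seed(11)
  k <- default_knots()
  for (rep in 1:5) {
    vals <- rnorm(5, 0, 3)
    sp <- nc_spline(vals)
    tt <- seq(18, 100, length.out = 1000)
    expect_equal(eval_spline(sp, tt), tri_natural_spline(k, vals, tt),
                 tolerance = 1e-10)
  }
})

test_that("spline is C2 at interior knots and clamps outside the range", {
  sp <- nc_spline(c(1, 4, -2, 0, 3))
  h <- 1e-4
  for (kn in default_knots()[2:4]) {
    d2 <- function(x) (eval_spline(sp, x + h) - 2 * eval_spline(sp, x) +
                         eval_spline(sp, x - h)) / h^2
    expect_equal(d2(kn - 5 * h), d2(kn + 5 * h), tolerance = 1e-2)
  }
  expect_equal(eval_spline(sp, 10), eval_spline(sp, 18))
  expect_equal(eval_spline(sp, 140), eval_spline(sp, 100))
  expect_error(eval_spline(sp, NaN), "finite")
})

test_that("spline basis reproduces evaluation as a linear map", {
  set.seed(4)
  vals <- rnorm(5)
  tt <- seq(18, 100, length.out = 57)
  W <- braintraj:::spline_basis(default_knots(), tt)
  expect_equal(as.numeric(W %*% vals), eval_spline(nc_spline(vals), tt),
               tolerance = 1e-12)
})

make_test_params <- function(...) {
  args <- utils::modifyList(list(
    fs = 0.01, fv = 0.2,
    b_ctrl = c(0, -1, -2, -3, -4), q_ctrl = rep(1, 5),
    init_mean_coeffs = c(7000, 200, 50, -1, 0.3, 0.1),
    init_cov = diag(c(100, 4)),
    site_biases = c(a = 5, b = -5),
    site_noise_sds = c(a = 2, b = 3)), list(...))
  do.call(model_params, args)
}

test_that("initial state distribution is the stated linear form", {
  p0 <- make_test_params(init_mean_coeffs = c(7000, 0, 0, -1, 0, 0))
  for (cv in list(covariate_profile(0, 0), covariate_profile(1, 2.5)))
    expect_equal(initial_state_distribution(p0, cv)$mu, c(7000, -1))
  p <- make_test_params(init_mean_coeffs = c(7000, 200, 50, -1, 0.3, 0.1))
  b <- initial_state_distribution(p, covariate_profile(sex = 1, icv = 2))
  expect_equal(b$mu[1], 7300)
  expect_equal(b$Sigma, diag(c(100, 4)))
  d <- initial_state_distribution(p, covariate_profile(1, 1.3))$mu -
    initial_state_distribution(p, covariate_profile(0, 1.3))$mu
  expect_equal(d, c(200, 0.3))
})

test_that("initial state mean is affine in sex and icv", {
  p <- make_test_params()
  mu <- function(s, i) initial_state_distribution(p, covariate_profile(s, i))$mu
  # second differences in icv vanish, sex effect is constant across icv
  expect_equal(mu(0, 2) - 2 * mu(0, 1) + mu(0, 0), c(0, 0), tolerance = 1e-10)
  expect_equal(mu(1, 3) - mu(0, 3), mu(1, -1) - mu(0, -1), tolerance = 1e-10)
})

test_that("continuous system matrices have the stated structure", {
  p <- make_test_params(fs = 0, fv = 0)
  cs <- continuous_system(p, 40)
  expect_equal(cs$F, matrix(c(0, 0, 1, 0), 2, 2))
  p2 <- make_test_params(fs = 0.01, fv = 0.2)
  cs2 <- continuous_system(p2, 40)
  expect_equal(cs2$F[2, ], c(-0.01, -0.2))
  expect_equal(cs2$B[1], 0)
  expect_equal(cs2$B[2], accel_bias_at(p2, 40))
  expect_true(all(cs2$Q[c(1, 2, 3)] == 0) && cs2$Q[2, 2] > 0)
})

test_that("feedback dynamics are non-expansive for sampled parameter sets", {
  set.seed(21)
  for (i in 1:50) {
    fs <- runif(1, 0, 1); fv <- runif(1, 0, 1)
    F <- matrix(c(0, -fs, 1, -fv), 2, 2)
    expect_lte(max(Re(eigen(F, only.values = TRUE)$values)), 1e-12)
  }
})

test_that("parameter invariants are enforced", {
  expect_error(make_test_params(fs = -0.1), "fs")
  expect_error(make_test_params(init_cov = matrix(c(1, 2, 2, 1), 2, 2)),
               "semidefinite")
  expect_error(make_test_params(site_biases = c(a = 5, b = 0)), "sum to zero")
  expect_error(make_test_params(site_noise_sds = c(a = 0, b = 3)), "positive")
  expect_error(covariate_profile(sex = 2), "sex")
})

test_that("parameter count follows the site count", {
  expect_equal(n_parameters(1), 22)
  expect_equal(n_parameters(39, count_constrained = TRUE), 99)
  expect_equal(n_parameters(13) - n_parameters(12), 2)
})

test_that("softplus link is a stable inverse pair", {
  x <- c(1e-6, 0.3, 5, 50, 500)
  expect_equal(softplus(softplus_inv(x)), x, tolerance = 1e-9)
})
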