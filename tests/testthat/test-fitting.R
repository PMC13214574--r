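make_small_cohort <- function(n = 60, seed = 5, n_sites = 2) {
  p <- default_structure_params("hippocampus-like", n_sites = n_sites)
  simulate_cohort(p, cohort_design(n_subjects = n, n_sites = n_sites),
                  seed = seed)
}

test_that("theta transform round-trips model parameters", {
  set.seed(61)
  for (i in 1:5) {
    p <- random_small_params(n_sites = 3)
    th <- params_to_theta(p)
    p2 <- theta_to_params(th, names(p$site_biases))
    expect_equal(p2$fs, p$fs, tolerance = 1e-10)
    expect_equal(p2$init_cov, p$init_cov, tolerance = 1e-8)
    expect_equal(p2$site_biases, p$site_biases, tolerance = 1e-10)
    expect_equal(p2$site_noise_sds, p$site_noise_sds, tolerance = 1e-8)
    expect_equal(p2$b_spline$values, p$b_spline$values)
  }
})

test_that("log posterior decomposes additively over disjoint subject sets", {
  coh <- make_small_cohort(40)
  obs <- coh$observations
  pri <- prior_spec(obs, sigma_r_center = 80)
  p <- default_structure_params("hippocampus-like", n_sites = 2)
  ids <- unique(obs$subject_id)
  g1 <- obs[obs$subject_id %in% ids[1:20], ]
  g2 <- obs[!obs$subject_id %in% ids[1:20], ]
  # subtract the shared prior term to isolate the likelihood contributions
  pri_only <- function(d) {
    pk <- braintraj:::build_fit_pack(d, pri, age_grid(),
                                     icv_center = 0, icv_scale = 1)
    th <- unname(params_to_theta(p))
    sum(dnorm(th, pk$pack$prior_mean, pk$pack$prior_sd, log = TRUE))
  }
  lp_lik <- function(d) {
    p2 <- p; p2$icv_center <- 0; p2$icv_scale <- 1
    log_posterior(p2, d, pri) - pri_only(d)
  }
  expect_equal(lp_lik(obs), lp_lik(g1) + lp_lik(g2), tolerance = 1e-8)
})

test_that("likelihood term of the posterior matches per-subject filters", {
  coh <- make_small_cohort(15)
  obs <- coh$observations
  pri <- prior_spec(obs)
  p <- default_structure_params("hippocampus-like", n_sites = 2)
  p$icv_center <- 0; p$icv_scale <- 1
  th <- unname(params_to_theta(p))
  pk <- braintraj:::build_fit_pack(obs, pri, age_grid(),
                                   icv_center = 0, icv_scale = 1)
  lp <- log_posterior(p, obs, pri)
  prior_term <- sum(dnorm(th, pk$pack$prior_mean, pk$pack$prior_sd, log = TRUE))
  m <- assemble_model(p)
  ll <- 0
  for (id in unique(obs$subject_id)) {
    d <- obs[obs$subject_id == id, ]
    s <- subject_observations(d$age, d$volume, d$site,
                              covariate_profile(d$sex[1], d$icv[1]))
    ll <- ll + marginal_loglik(m, s)
  }
  expect_equal(lp - prior_term, ll, tolerance = 1e-8)
})

test_that("structured gradient matches a plain finite-difference oracle", {
  set.seed(62)
  coh <- make_small_cohort(25)
  pri <- prior_spec(coh$observations, sigma_r_center = 80)
  pk <- braintraj:::build_fit_pack(coh$observations, pri, age_grid())
  f <- function(t) braintraj:::.cpp_log_post(t, pk$pack)
  th0 <- braintraj:::initial_theta(pk, pri)
  for (rep in 1:3) {
    th <- th0 + rnorm(length(th0), 0, 0.05) * pk$pack$prior_sd * 0.1
    g <- braintraj:::.cpp_log_post_grad(th, pk$pack, 1e-6)
    g_plain <- vapply(seq_along(th), function(i) {
      h <- 1e-5 * max(1, abs(th[i]))
      tp <- th; tp[i] <- th[i] + h
      tm <- th; tm[i] <- th[i] - h
      (f(tp) - f(tm)) / (2 * h)
    }, numeric(1))
    expect_equal(g, g_plain, tolerance = 1e-4)
  }
})

test_that("MAP fitting is deterministic and improves on the start", {
  coh <- make_small_cohort(40)
  pri <- prior_spec(coh$observations, sigma_r_center = 80)
  cfg <- fit_config(restarts = 2, maxit = 150)
  m1 <- fit_map(coh$observations, pri, cfg, seed = 9)
  m2 <- fit_map(coh$observations, pri, cfg, seed = 9)
  expect_identical(attr(m1, "theta"), attr(m2, "theta"))
  expect_gt(attr(m1, "logpost"),
            log_posterior(theta_to_params(
              braintraj:::initial_theta(
                braintraj:::build_fit_pack(coh$observations, pri, cfg$grid),
                pri),
              sort(unique(coh$observations$site)),
              icv_center = m1$icv_center, icv_scale = m1$icv_scale),
              coh$observations, pri))
})

test_that("a single site is pinned to zero bias by the constraint", {
  coh <- make_small_cohort(30, n_sites = 1)
  pri <- prior_spec(coh$observations, sigma_r_center = 80)
  map <- fit_map(coh$observations, pri, fit_config(restarts = 1, maxit = 100),
                 seed = 3)
  expect_equal(unname(map$site_biases), 0)
})

test_that("posterior sampling is reproducible and carries diagnostics", {
  coh <- make_small_cohort(25)
  pri <- prior_spec(coh$observations, sigma_r_center = 80)
  cfg <- fit_config(restarts = 1, maxit = 150, warmup = 60, n_draws = 60,
                    max_treedepth = 6)
  map <- fit_map(coh$observations, pri, cfg, seed = 4)
  f1 <- sample_posterior(coh$observations, pri, map, cfg, seed = 11)
  f2 <- sample_posterior(coh$observations, pri, map, cfg, seed = 11)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(c("rhat", "ess") %in% names(f1$diagnostics$table)))
  # positive-parameter draws map to strictly positive SDs
  for (i in seq(1, nrow(f1$draws), by = 10)) {
    pd <- params_from_draw(f1, i)
    expect_true(all(pd$site_noise_sds > 0))
    expect_true(all(sigma_q_at(pd, seq(18, 100, by = 5)) >= 0))
    expect_gte(pd$fs, 0)
  }
})

test_that("posterior-predictive calibration covers held-out data", {
  p <- default_structure_params("hippocampus-like", n_sites = 2)
  coh <- simulate_cohort(p, cohort_design(n_subjects = 80, n_sites = 2),
                         seed = 13)
  pri <- prior_spec(coh$observations, sigma_r_center = 80, sigma_q_center = 10)
  cfg <- fit_config(restarts = 1, maxit = 200, warmup = 150, n_draws = 250,
                    max_treedepth = 7)
  map <- fit_map(coh$observations, pri, cfg, seed = 6)
  fit <- sample_posterior(coh$observations, pri, map, cfg, seed = 7)
  # held-out data generated from the fitted parameters themselves: coverage
  # of the posterior-predictive intervals should then sit at nominal (small
  # cushion for the extra width of the draw mixture relative to the MAP)
  held <- simulate_cohort(map, cohort_design(n_subjects = 150, n_sites = 2),
                          seed = 14)$observations
  cal <- calibration_check(fit, held, n_draws = 40)
  for (r in seq_len(nrow(cal))) {
    se <- sqrt(cal$level[r] * (1 - cal$level[r]) / cal$n[r])
    expect_lt(abs(cal$coverage[r] - cal$level[r]), 3 * se + 0.02)
  }
  expect_equal(calibration_check(fit, held, levels = 0)$coverage, 0)
  expect_equal(calibration_check(fit, held, levels = 1)$coverage, 1)
  expect_error(calibration_check(fit, held[0, ]), "held-out")
})

test_that("the sampler reproduces a known correlated Gaussian", {
  set.seed(42)
  n <- 6
  A <- matrix(rnorm(n * n), n)
  S <- A %*% t(A) + diag(n)
  mu <- rnorm(n, 0, 2)
  P <- solve(S)
  lp <- function(t) -0.5 * as.numeric(t(t - mu) %*% P %*% (t - mu))
  gr <- function(t) as.numeric(-P %*% (t - mu))
  ch <- braintraj:::nuts_chain(lp, gr, rep(0, n),
                               braintraj:::new_metric(diag(1, n)),
                               warmup = 300, n_draws = 2000,
                               max_treedepth = 8)
  expect_equal(ch$n_divergent, 0L)
  expect_lt(max(abs(colMeans(ch$draws) - mu) / sqrt(diag(S))), 0.15)
  expect_lt(max(abs(apply(ch$draws, 2, sd) / sqrt(diag(S)) - 1)), 0.12)
})

test_that("constraint-violating parameters yield -Inf with a reason", {
  coh <- make_small_cohort(10)
  pri <- prior_spec(coh$observations)
  p <- default_structure_params("hippocampus-like", n_sites = 2)
  p$fs <- -0.5
  lp <- log_posterior(p, coh$observations, pri)
  expect_identical(as.numeric(lp), -Inf)
  expect_match(attr(lp, "reason"), "fs")
  expect_error(log_posterior(p, coh$observations[0, ], pri), "empty")
})
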