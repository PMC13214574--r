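test_that("cohort simulation is deterministic given the seed", {
  p <- default_structure_params("hippocampus-like")
  d <- cohort_design(n_subjects = 40)
  c1 <- simulate_cohort(p, d, seed = 99)
  c2 <- simulate_cohort(p, d, seed = 99)
  c3 <- simulate_cohort(p, d, seed = 100)
  expect_identical(c1$observations, c2$observations)
  expect_identical(c1$truth, c2$truth)
  expect_false(identical(c1$observations$volume, c3$observations$volume))
})

test_that("a noise-free degenerate model lands on the population mean", {
  p <- model_params(fs = 0.001, fv = 0.1, b_ctrl = c(0, -1, -2, -3, -4),
                    q_ctrl = rep(-Inf, 5),
                    init_mean_coeffs = c(7000, 0, 0, -1, 0, 0),
                    init_cov = matrix(0, 2, 2),
                    site_biases = c(site1 = 0), site_noise_sds = c(site1 = 1e-9))
  coh <- simulate_cohort(p, cohort_design(n_subjects = 30, n_sites = 1),
                         seed = 3)
  m <- assemble_model(p)
  mu <- vapply(seq_len(nrow(coh$observations)), function(i) {
    k <- snap_age(m$grid, coh$observations$age[i])
    braintraj:::prior_belief_at(m, k)$mu[1]
  }, numeric(1))
  expect_equal(coh$observations$volume, mu, tolerance = 1e-6)
})

test_that("simulated moments match the analytic propagation", {
  set.seed(71)
  p <- default_structure_params("ventricle-like")
  m <- assemble_model(p)
  n <- 20000
  sims <- simulate_latent_trajectories(m, n, steps_keep = c(0, 22, 52))
  for (k in c(0, 22, 52)) {
    b <- braintraj:::prior_belief_at(m, k)
    Z <- sims[[as.character(k)]]
    for (j in 1:2) {
      expect_lt(abs(mean(Z[, j]) - b$mu[j]), 3 * sd(Z[, j]) / sqrt(n))
      expect_lt(abs(var(Z[, j]) - b$Sigma[j, j]),
                3 * sd((Z[, j] - mean(Z[, j]))^2) / sqrt(n))
    }
  }
})

test_that("re-centering one site's bias shifts its volumes exactly", {
  p <- default_structure_params("hippocampus-like", n_sites = 2)
  shift <- 120
  p2 <- p
  p2$site_biases <- p$site_biases + c(shift / 2, -shift / 2)
  d <- cohort_design(n_subjects = 50, n_sites = 2)
  c1 <- simulate_cohort(p, d, seed = 17)
  c2 <- simulate_cohort(p2, d, seed = 17)
  delta <- c2$observations$volume - c1$observations$volume
  expected <- ifelse(c1$observations$site == "site1", shift / 2, -shift / 2)
  expect_equal(delta, expected, tolerance = 1e-9)
  expect_identical(c1$truth, c2$truth)   # latent states unaffected by bias
})

test_that("session counts follow the design distribution", {
  p <- default_structure_params("hippocampus-like")
  probs <- c(0.5, 0.3, 0.2)
  d <- cohort_design(n_subjects = 600, session_count_probs = probs,
                     baseline_age_range = c(18, 80))
  coh <- simulate_cohort(p, d, seed = 23)
  counts <- table(table(coh$observations$subject_id))
  # truncation at the grid end can only reduce counts; baseline <= 80 with
  # max 2 follow-ups keeps all sessions on the grid here
  obs_p <- as.numeric(counts[c("1", "2", "3")]) / 600
  for (i in 1:3) {
    se <- sqrt(probs[i] * (1 - probs[i]) / 600)
    expect_lt(abs(obs_p[i] - probs[i]), 3 * se)
  }
})

test_that("observation tables round-trip through CSV and validate", {
  p <- default_structure_params("hippocampus-like")
  coh <- simulate_cohort(p, cohort_design(n_subjects = 20), seed = 5)
  path <- tempfile(fileext = ".csv")
  write_observation_table(coh$observations, path)
  back <- read_observation_table(path)
  expect_equal(back$volume, coh$observations$volume, tolerance = 1e-12)
  expect_equal(back$subject_id, coh$observations$subject_id)
  bad <- coh$observations
  bad$age[3] <- 150
  expect_error(validate_observation_table(bad), "row")
  expect_error(validate_observation_table(coh$observations[, -2]),
               "missing required column")
  expect_error(
    validate_observation_table(coh$observations, sites = "siteZ"),
    "unknown site")
})

test_that("parameter fixtures are valid and show their tagged dynamics", {
  expect_error(default_structure_params("cortex"), "hippocampus-like")
  for (tag in c("hippocampus-like", "ventricle-like")) {
    p <- default_structure_params(tag)
    expect_silent(validate_params(p))
  }
  mh <- assemble_model(default_structure_params("hippocampus-like"))
  ev <- explained_variance(mh, c(40, 50, 60, 75, 90))
  expect_true(all(ev[1:3] > 0.8))
  expect_lt(ev[5], ev[3])
  mv <- assemble_model(default_structure_params("ventricle-like"))
  expect_gt(volume_change_correlation(mv, 40), 0)
})
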