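# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the spline oracle solves the tridiagonal
# natural-spline system directly, the discretization oracle integrates the
# defining initial-value problems with an adaptive ODE solver, and the state-inference oracle assembles the dense joint
# Gaussian over latent states and observations from the lag-propagation
# identities.

# ---- natural cubic spline via the textbook tridiagonal solve -------------
tri_natural_spline <- function(knots, values, t) {
  n <- length(knots)
  h <- diff(knots)
  # second derivatives M: natural boundary M1 = Mn = 0
  A <- matrix(0, n - 2, n - 2)
  rhs <- numeric(n - 2)
  for (i in 2:(n - 1)) {
    j <- i - 1
    A[j, j] <- (h[i - 1] + h[i]) / 3
    if (j > 1) A[j, j - 1] <- h[i - 1] / 6
    if (j < n - 2) A[j, j + 1] <- h[i] / 6
    rhs[j] <- (values[i + 1] - values[i]) / h[i] -
      (values[i] - values[i - 1]) / h[i - 1]
  }
  M <- c(0, solve(A, rhs), 0)
  vapply(t, function(x) {
    i <- findInterval(x, knots, rightmost.closed = TRUE)
    i <- min(max(i, 1), n - 1)
    a <- knots[i]; b <- knots[i + 1]; hh <- h[i]
    ((b - x)^3 / 6 * M[i] + (x - a)^3 / 6 * M[i + 1]) / hh +
      (values[i] / hh - hh * M[i] / 6) * (b - x) +
      (values[i + 1] / hh - hh * M[i + 1] / 6) * (x - a)
  }, numeric(1))
}

# ---- discretization oracle: adaptive ODE integration of the defining
# initial-value problems (transition, input and covariance integrals), at
# tolerances far below the comparison threshold; independent of any
# matrix-exponential code path
quad_discretize <- function(F, b, q, delta) {
  Qc <- diag(c(0, q))
  rhs <- function(s, y, parms) {
    Phi <- matrix(y[1:4], 2, 2)
    E <- Phi %*% c(0, b)
    Qd <- Phi %*% Qc %*% t(Phi)
    list(c(as.numeric(F %*% Phi), as.numeric(E),
           Qd[1, 1], Qd[1, 2], Qd[2, 2]))
  }
  y0 <- c(as.numeric(diag(2)), 0, 0, 0, 0, 0)
  out <- deSolve::ode(y0, c(0, delta), rhs, NULL,
                      method = "lsoda", rtol = 1e-12, atol = 1e-13)
  y <- out[2, -1]
  list(F_star = matrix(y[1:4], 2, 2),
       B_star = unname(y[5:6]),
       Q_star = matrix(c(y[7], y[8], y[8], y[9]), 2, 2))
}

# ---- dense joint-Gaussian oracle for likelihood and smoothing ------------

# mean and covariance of the stacked latent states z_0..z_K for a subject,
# built from the one-step recursions and the lag identity
# Cov(z_a, z_b) = Sigma_a (F*^(b-a))'
dense_latent_moments <- function(model, covariates) {
  K <- model$grid$K
  Fs <- model$system$F_star
  b0 <- initial_state_distribution(model$params, covariates)
  mus <- vector("list", K + 1)
  Sig <- vector("list", K + 1)
  mus[[1]] <- b0$mu; Sig[[1]] <- b0$Sigma
  for (k in 1:K) {
    mus[[k + 1]] <- as.numeric(Fs %*% mus[[k]] + model$system$B_star[k, ])
    Qk <- matrix(c(model$system$Q_star[k, 1], model$system$Q_star[k, 2],
                   model$system$Q_star[k, 2], model$system$Q_star[k, 3]), 2, 2)
    Sig[[k + 1]] <- Fs %*% Sig[[k]] %*% t(Fs) + Qk
  }
  G <- matrix(0, 2 * (K + 1), 2 * (K + 1))
  for (a in 0:K) {
    Fn <- diag(2)
    for (b in a:K) {
      blk <- Sig[[a + 1]] %*% t(Fn)    # Cov(z_a, z_b)
      G[2 * a + 1:2, 2 * b + 1:2] <- blk
      G[2 * b + 1:2, 2 * a + 1:2] <- t(blk)
      Fn <- Fs %*% Fn
    }
  }
  list(mu = unlist(mus), G = G)
}

mvn_logpdf <- function(y, mu, S) {
  L <- chol(S)
  z <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# exact joint-Gaussian log-likelihood and per-step conditional moments of
# the latent states given a subject's observations
dense_subject_oracle <- function(model, subject) {
  lm_ <- dense_latent_moments(model, subject$covariates)
  m <- length(subject$steps)
  idx_s <- 2 * subject$steps + 1           # s-component rows of stacked z
  site_i <- match(subject$sites, names(model$params$site_biases))
  bias <- unname(model$params$site_biases[site_i])
  rvar <- unname(model$params$site_noise_sds[site_i]^2)
  A <- matrix(0, m, length(lm_$mu))
  for (i in seq_len(m)) A[i, idx_s[i]] <- 1
  mu_y <- as.numeric(A %*% lm_$mu) + bias
  S_y <- A %*% lm_$G %*% t(A) + diag(rvar, m)
  ll <- mvn_logpdf(subject$volumes, mu_y, S_y)
  CzA <- lm_$G %*% t(A)
  W <- CzA %*% solve(S_y)
  mu_c <- lm_$mu + as.numeric(W %*% (subject$volumes - mu_y))
  G_c <- lm_$G - W %*% t(CzA)
  K <- model$grid$K
  list(loglik = ll,
       mean = t(vapply(0:K, function(k) mu_c[2 * k + 1:2], numeric(2))),
       cov = t(vapply(0:K, function(k) {
         S <- G_c[2 * k + 1:2, 2 * k + 1:2]
         c(S[1, 1], S[1, 2], S[2, 2])
       }, numeric(3))))
}

# ---- random model generator for the randomized oracle suites -------------
random_small_params <- function(n_sites = 2) {
  sites <- paste0("s", seq_len(n_sites))
  biases <- stats::rnorm(n_sites, 0, 3)
  biases <- biases - mean(biases)
  A <- matrix(stats::rnorm(4, 0, c(8, 1, 1, 0.8)), 2, 2)
  model_params(
    fs = stats::runif(1, 0, 0.05), fv = stats::runif(1, 0, 0.4),
    b_ctrl = stats::rnorm(5, 0, 1),
    q_ctrl = stats::rnorm(5, 0.5, 1),
    init_mean_coeffs = c(stats::rnorm(1, 100, 10), stats::rnorm(2, 0, 5),
                         stats::rnorm(3, 0, 1)),
    init_cov = A %*% t(A) + diag(1e-6, 2),
    site_biases = stats::setNames(biases, sites),
    site_noise_sds = stats::setNames(stats::runif(n_sites, 0.5, 5), sites))
}

random_subject <- function(grid, sites, max_obs = 8, min_obs = 1) {
  m <- sample(min_obs:max_obs, 1)
  steps <- sort(sample(0:grid$K, m))
  subject_observations(
    ages = grid$ages[steps + 1],
    volumes = stats::rnorm(m, 100, 15),
    sites = sample(sites, m, replace = TRUE),
    covariates = covariate_profile(sample(0:1, 1), stats::rnorm(1)),
    grid = grid)
}
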