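#' Age grid for exact discretization
#'
#' Ages are discretized to a shared grid `t0 + k * delta`, `k = 0..K`.
#' Beliefs live on grid ages; transitions `k -> k+1` carry the zero-order
#' hold inputs evaluated at the left endpoint of each interval.
#'
#' @param t0 initial age in years (default 18).
#' @param delta sampling period in years (default 1.0).
#' @param t_max last age covered by the grid (default 100).
#' @return an `age_grid` object with fields `t0`, `delta`, `K` (number of
#'   transition steps) and `ages` (length `K + 1`).
#' @export
age_grid <- function(t0 = 18, delta = 1.0, t_max = 100) {
  stopifnot(delta > 0, t_max > t0)
  K <- as.integer(round((t_max - t0) / delta))
  structure(list(t0 = t0, delta = delta, K = K,
                 ages = t0 + delta * (0:K)),
            class = "age_grid")
}

#' Map an age to the nearest grid step
#'
#' Ties (ages exactly between two grid steps) round toward the younger age.
#'
#' @param grid an [age_grid()].
#' @param age ages in years.
#' @return integer step indices (0-based).
#' @export
snap_age <- function(grid, age) {
  k <- as.integer(floor((age - grid$t0) / grid$delta + 0.5))
  # half-way points round down (toward younger age)
  frac <- (age - grid$t0) / grid$delta
  k <- ifelse(abs(frac - floor(frac) - 0.5) < 1e-12, as.integer(floor(frac)), k)
  if (any(k < 0 | k > grid$K)) stop("age outside the model grid")
  k
}

#' Gaussian belief over the latent state
#'
#' @param mu length-2 mean (volume mm^3, change rate mm^3/year).
#' @param Sigma 2x2 symmetric covariance, numerically PSD
#'   (eigenvalues `>= -1e-10` relative).
#' @return a `gaussian_belief` object.
#' @export
gaussian_belief <- function(mu, Sigma) {
  mu <- as.numeric(mu)
  Sigma <- as.matrix(Sigma)
  stopifnot(length(mu) == 2, all(dim(Sigma) == 2))
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(1, max(abs(ev)))))
    stop("belief covariance is not positive semidefinite")
  structure(list(mu = mu, Sigma = Sigma), class = "gaussian_belief")
}

#' Exact zero-order-hold discretization of one interval
#'
#' Computes the transition matrix, input and process covariance of the
#' discrete system over a step of length `delta`, holding the bias `b` and
#' process-noise variance `q` constant over the interval:
#' `F_star = expm(F delta)`,
#' `B_star = int_0^delta expm(F s) (0, b)' ds`,
#' `Q_star = int_0^delta expm(F s) diag(0, q) expm(F' s) ds`,
#' evaluated with the Van Loan augmented-matrix-exponential construction.
#'
#' @param F 2x2 continuous drift matrix.
#' @param b acceleration bias held over the interval (mm^3/year^2).
#' @param q process-noise variance held over the interval.
#' @param delta interval length in years, `> 0`.
#' @return list with `F_star` (2x2), `B_star` (length 2), `Q_star` (2x2).
#' @export
discretize_interval <- function(F, b, q, delta) {
  if (!all(is.finite(F)) || !is.finite(b) || !is.finite(q) ||
      !is.finite(delta) || delta <= 0)
    stop("discretize_interval requires finite inputs and delta > 0")
  parts <- .cpp_vanloan_parts(F, delta)
  Qs <- q * parts$M2
  list(F_star = parts$F_star,
       B_star = as.numeric(b * parts$m1),
       Q_star = (Qs + t(Qs)) / 2)
}

#' Assemble the discrete-time system on an age grid
#'
#' Precomputes the shared transition matrix and the per-step inputs and
#' process covariances implied by the model's splines under the left-endpoint
#' zero-order hold.
#'
#' @param p model parameters.
#' @param grid an [age_grid()]; defaults to the 1-year grid over 18--100.
#' @return a `discrete_system` with `F_star` (2x2), `B_star` (`K` x 2),
#'   `Q_star` (`K` x 3 packed as `q11, q12, q22`), `H = (1, 0)`, the site
#'   registry, and the grid.
#' @export
discretize_system <- function(p, grid = age_grid()) {
  validate_params(p)
  parts <- .cpp_vanloan_parts(matrix(c(0, -p$fs, 1, -p$fv), 2, 2), grid$delta)
  t_left <- grid$ages[seq_len(grid$K)]
  b <- accel_bias_at(p, t_left)
  qv <- sigma_q_at(p, t_left)^2
  structure(list(
    F_star = parts$F_star,
    B_star = cbind(b * parts$m1[1], b * parts$m1[2]),
    Q_star = cbind(qv * parts$M2[1, 1], qv * parts$M2[1, 2],
                   qv * parts$M2[2, 2]),
    H = c(1, 0),
    sites = names(p$site_biases),
    grid = grid
  ), class = "discrete_system")
}

#' Propagate a Gaussian belief through the discrete system
#'
#' Applies the exact mean and covariance recursions
#' `mu_{k+1} = F* mu_k + B*_k`, `Sigma_{k+1} = F* Sigma_k F*' + Q*_k`
#' for `n` steps starting from step `k`, symmetrizing the covariance after
#' each step.
#'
#' @param belief a [gaussian_belief()] at grid step `k`.
#' @param system a [discretize_system()] result.
#' @param k 0-based start step.
#' @param n number of steps, `>= 0`.
#' @return the propagated [gaussian_belief()] at step `k + n`.
#' @export
propagate_belief <- function(belief, system, k, n) {
  stopifnot(inherits(belief, "gaussian_belief"), n >= 0, k >= 0)
  if (k + n > system$grid$K) stop("propagation beyond the age grid")
  if (n == 0) return(belief)
  Fs <- system$F_star
  mu <- belief$mu
  S <- belief$Sigma
  for (j in k + seq_len(n)) {
    mu <- as.numeric(Fs %*% mu + system$B_star[j, ])
    Qk <- matrix(c(system$Q_star[j, 1], system$Q_star[j, 2],
                   system$Q_star[j, 2], system$Q_star[j, 3]), 2, 2)
    S <- Fs %*% S %*% t(Fs) + Qk
    S <- (S + t(S)) / 2
  }
  gaussian_belief(mu, S)
}

#' Assemble a model: parameters bound to a grid with cached discretization
#'
#' Most analysis functions need the parameters, the age grid and the
#' discrete system together; this bundles them once.
#'
#' @param p model parameters.
#' @param grid an [age_grid()].
#' @return a `braintraj_model` list with `params`, `grid`, `system`.
#' @export
assemble_model <- function(p, grid = age_grid()) {
  structure(list(params = p, grid = grid, system = discretize_system(p, grid)),
            class = "braintraj_model")
}

# belief at grid step k for a covariate profile (population prior)
prior_belief_at <- function(model, k, cov = covariate_profile()) {
  b0 <- initial_state_distribution(model$params, cov)
  propagate_belief(b0, model$system, 0L, k)
}
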