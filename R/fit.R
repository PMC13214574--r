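#' @title Bayesian fitting: MAP optimization and posterior sampling
#' @description
#' Parameters are estimated on an unconstrained scale (softplus links for
#' positive quantities, log-Cholesky for the initial covariance, J-1 free
#' site biases with the last defined by the sum-to-zero constraint).
#' Maximum a posteriori estimates are found with L-BFGS; a No-U-Turn
#' sampler initialized at the MAP then draws from the posterior.
#' @name fitting
NULL

# ---- unconstrained parameterization --------------------------------------

theta_names <- function(site_ids) {
  J <- length(site_ids)
  c("u_fs", "u_fv", paste0("b", 1:5), paste0("q", 1:5),
    "beta_s0", "beta_s0_sex", "beta_s0_icv",
    "beta_v0", "beta_v0_sex", "beta_v0_icv",
    "l11", "l21", "l22",
    if (J > 1) paste0("bias_", site_ids[seq_len(J - 1)]),
    paste0("u_sr_", site_ids))
}

#' Map model parameters to the unconstrained vector
#' @param p a [model_params()] object (feedbacks and noise SDs must be
#'   strictly positive and `init_cov` positive definite).
#' @return named numeric vector.
#' @export
params_to_theta <- function(p) {
  validate_params(p)
  L <- t(chol(p$init_cov))
  th <- c(softplus_inv(p$fs), softplus_inv(p$fv),
          p$b_spline$values, p$q_spline$values,
          unname(p$init_mean_coeffs),
          log(L[1, 1]), L[2, 1], log(L[2, 2]),
          unname(p$site_biases[-length(p$site_biases)]),
          softplus_inv(unname(p$site_noise_sds)))
  stats::setNames(th, theta_names(names(p$site_biases)))
}

#' Map an unconstrained vector back to model parameters
#' @param theta unconstrained vector in the layout of [params_to_theta()].
#' @param site_ids character vector of site ids.
#' @param knots spline knots.
#' @param icv_center,icv_scale ICV standardization constants to record.
#' @return a [model_params()] object.
#' @export
theta_to_params <- function(theta, site_ids, knots = default_knots(),
                            icv_center = 0, icv_scale = 1) {
  J <- length(site_ids)
  stopifnot(length(theta) == 20 + 2 * J)
  L <- matrix(c(exp(theta[19]), theta[20], 0, exp(theta[21])), 2, 2)
  free <- if (J > 1) theta[22:(20 + J)] else numeric(0)
  biases <- stats::setNames(c(free, -sum(free)), site_ids)
  model_params(
    fs = softplus(theta[1]), fv = softplus(theta[2]),
    b_ctrl = theta[3:7], q_ctrl = theta[8:12],
    init_mean_coeffs = theta[13:18],
    init_cov = L %*% t(L),
    site_biases = biases,
    site_noise_sds = stats::setNames(softplus(theta[(21 + J):(20 + 2 * J)]),
                                     site_ids),
    knots = knots, icv_center = icv_center, icv_scale = icv_scale)
}

# ---- data packing --------------------------------------------------------

# Compile an observation table into the flat structure consumed by the C++
# objective: snapped grid steps, per-subject offsets, site indices, spline
# basis over the left interval endpoints, ICV standardization, priors.
build_fit_pack <- function(data, priors, grid = age_grid(),
                           knots = default_knots(),
                           icv_center = NULL, icv_scale = NULL) {
  validate_observation_table(data)
  site_ids <- sort(unique(as.character(data$site)))
  J <- length(site_ids)
  if (is.null(icv_center)) icv_center <- mean(data$icv)
  if (is.null(icv_scale)) {
    icv_scale <- stats::sd(data$icv)
    if (!is.finite(icv_scale) || icv_scale == 0) icv_scale <- 1
  }
  ord <- order(data$subject_id, data$age)
  d <- data[ord, ]
  subj <- unique(d$subject_id)
  first <- match(d$subject_id, subj)
  steps <- snap_age(grid, d$age)
  # drop grid-step collisions within subject (keep the earlier scan)
  keep <- !duplicated(cbind(first, steps))
  if (any(!keep))
    warning(sprintf("%d scan(s) collided on grid steps; keeping the earlier scan",
                    sum(!keep)))
  d <- d[keep, ]; steps <- steps[keep]; first <- first[keep]
  counts <- tabulate(first, nbins = length(subj))
  pv <- prior_vectors(priors, J)
  list(pack = list(
         W = spline_basis(knots, grid$ages[seq_len(grid$K)]),
         K = grid$K, delta = grid$delta,
         subj_ptr = as.integer(c(0, cumsum(counts))),
         obs_step = as.integer(steps),
         obs_y = as.numeric(d$volume),
         obs_site = as.integer(match(as.character(d$site), site_ids) - 1L),
         sex = as.numeric(d$sex[!duplicated(first)]),
         icv = (as.numeric(d$icv[!duplicated(first)]) - icv_center) / icv_scale,
         n_sites = J,
         prior_mean = pv$mean, prior_sd = pv$sd),
       site_ids = site_ids, subjects = subj, grid = grid, knots = knots,
       icv_center = icv_center, icv_scale = icv_scale)
}

#' Log posterior of model parameters given an observation table
#'
#' The sum over subjects of the exact marginal log-likelihood (latent
#' trajectories integrated out by the Kalman filter) plus the Gaussian
#' log-prior evaluated on the unconstrained scale.
#'
#' @param params a [model_params()] object; its sites must cover the data.
#' @param data observation table.
#' @param priors a [prior_spec()].
#' @param grid the [age_grid()].
#' @return scalar log posterior density (unconstrained scale). Parameters
#'   violating the model constraints yield `-Inf` with the violated
#'   invariant in attribute `"reason"`.
#' @export
log_posterior <- function(params, data, priors = prior_spec(data),
                          grid = age_grid()) {
  if (nrow(data) == 0) stop("empty observation table")
  unknown <- setdiff(unique(as.character(data$site)), names(params$site_biases))
  if (length(unknown))
    stop(sprintf("unknown site id(s): %s", paste(unknown, collapse = ", ")))
  pk <- build_fit_pack(data, priors, grid, knots = params$b_spline$knots,
                       icv_center = params$icv_center,
                       icv_scale = params$icv_scale)
  # align theta to the pack's site ordering
  p2 <- params
  p2$site_biases <- params$site_biases[pk$site_ids]
  p2$site_noise_sds <- params$site_noise_sds[pk$site_ids]
  th <- tryCatch(params_to_theta(p2), error = function(e) e)
  if (inherits(th, "error"))
    return(structure(-Inf, reason = conditionMessage(th)))
  .cpp_log_post(unname(th), pk$pack)
}

#' Gradient of the log posterior on the unconstrained scale
#'
#' Structured central finite differences computed in compiled code: the
#' matrix-exponential discretization is recomputed only for the two
#' feedback coordinates it depends on.
#'
#' @inheritParams log_posterior
#' @param eps relative finite-difference step.
#' @return named gradient vector.
#' @export
log_posterior_grad <- function(params, data, priors = prior_spec(data),
                               grid = age_grid(), eps = 1e-6) {
  pk <- build_fit_pack(data, priors, grid, knots = params$b_spline$knots,
                       icv_center = params$icv_center,
                       icv_scale = params$icv_scale)
  p2 <- params
  p2$site_biases <- params$site_biases[pk$site_ids]
  p2$site_noise_sds <- params$site_noise_sds[pk$site_ids]
  th <- params_to_theta(p2)
  stats::setNames(.cpp_log_post_grad(unname(th), pk$pack, eps), names(th))
}

#' Fit configuration
#'
#' @param grid the [age_grid()] to fit on (default 1-year steps, 18--100).
#' @param restarts number of jittered L-BFGS restarts (best kept).
#' @param maxit maximum L-BFGS iterations per restart.
#' @param jitter_sd SD of the Gaussian jitter applied to the starting
#'   point of restarts after the first.
#' @param warmup,n_draws NUTS warm-up and retained draws.
#' @param max_treedepth NUTS maximum tree depth.
#' @param target_accept dual-averaging target acceptance probability.
#' @param n_chains number of chains (one by default; more enable between-
#'   chain diagnostics).
#' @return a `fit_config` list.
#' @export
fit_config <- function(grid = age_grid(), restarts = 3, maxit = 400,
                       jitter_sd = 0.3, warmup = 300, n_draws = 1000,
                       max_treedepth = 9, target_accept = 0.92,
                       n_chains = 1) {
  structure(list(grid = grid, restarts = restarts, maxit = maxit,
                 jitter_sd = jitter_sd, warmup = warmup, n_draws = n_draws,
                 max_treedepth = max_treedepth, target_accept = target_accept,
                 n_chains = n_chains),
            class = "fit_config")
}

# data-informed starting point on the unconstrained scale
initial_theta <- function(pk, priors) {
  pv <- prior_vectors(priors, pk$pack$n_sites)
  th <- pv$mean
  th[13] <- mean(pk$pack$obs_y)                       # beta_s0 at sample mean
  th[19] <- log(max(stats::sd(pk$pack$obs_y), 1))     # l11 near sample SD
  th
}

#' Maximum a posteriori fit by L-BFGS
#'
#' Maximizes the log posterior on the unconstrained scale with L-BFGS-B,
#' using the structured finite-difference gradient, from a data-informed
#' start plus jittered restarts; the best converged optimum is kept. The
#' result is bitwise reproducible given the same data, priors, config and
#' seed.
#'
#' @param data observation table (at least two sites unless the single
#'   site's bias is to be pinned at zero by the constraint).
#' @param priors a [prior_spec()].
#' @param config a [fit_config()].
#' @param seed integer seed controlling the restart jitter.
#' @param icv_center,icv_scale override the ICV standardization (defaults:
#'   sample mean and SD of the data).
#' @return a [model_params()] object with attributes `theta`, `logpost`,
#'   `optim_trace` and the fitted site registry.
#' @export
fit_map <- function(data, priors = prior_spec(data), config = fit_config(),
                    seed = 1, icv_center = NULL, icv_scale = NULL) {
  pk <- build_fit_pack(data, priors, config$grid,
                       icv_center = icv_center, icv_scale = icv_scale)
  th0 <- initial_theta(pk, priors)
  ps <- pk$pack$prior_sd   # prior scales precondition the optimizer
  set.seed(as.integer(seed))
  best <- NULL
  trace <- list()
  for (r in seq_len(config$restarts)) {
    start <- if (r == 1) th0 else
      th0 + stats::rnorm(length(th0), 0, config$jitter_sd) * ps
    fit <- stats::optim(start,
                        fn = function(t) {
                          v <- -.cpp_log_post(t, pk$pack)
                          if (is.finite(v)) v else 1e12  # L-BFGS-B needs finite values
                        },
                        gr = function(t) -.cpp_log_post_grad(t, pk$pack, 1e-6),
                        method = "L-BFGS-B",
                        control = list(maxit = config$maxit, factr = 1e7,
                                       parscale = ps))
    trace[[r]] <- list(value = -fit$value, convergence = fit$convergence,
                       message = fit$message)
    if (fit$convergence %in% c(0L, 1L) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    e <- simpleError("MAP optimization did not converge in any restart")
    e$trace <- trace
    stop(e)
  }
  out <- theta_to_params(best$par, pk$site_ids, pk$knots,
                         pk$icv_center, pk$icv_scale)
  attr(out, "theta") <- stats::setNames(best$par, theta_names(pk$site_ids))
  attr(out, "logpost") <- -best$value
  attr(out, "optim_trace") <- trace
  out
}

#' Draw from the posterior with the No-U-Turn sampler
#'
#' Initializes at the MAP estimate, preconditions with a diagonal metric
#' taken from the curvature of the log posterior at the MAP, adapts the
#' step size by dual averaging over the warm-up, and retains `n_draws`
#' draws (defaults 300 warm-up, 1,000 retained). Diagnostics include
#' rank-normalized split R-hat, bulk effective sample size and the
#' divergent-transition count (a high divergence fraction warns but does
#' not fail).
#'
#' @param data observation table.
#' @param priors a [prior_spec()].
#' @param init a [model_params()] object to start from, typically the
#'   [fit_map()] result.
#' @param config a [fit_config()].
#' @param seed integer seed; the same seed reproduces the draw matrix.
#' @param icv_center,icv_scale override the ICV standardization (defaults:
#'   sample mean and SD of the data; use the values the `init` fit used).
#' @return a `posterior_fit` with `draws` (draws x parameters, unconstrained
#'   scale), `map_params`, `diagnostics`, `site_ids`, `grid`, `seed`,
#'   `config`.
#' @export
sample_posterior <- function(data, priors = prior_spec(data), init,
                             config = fit_config(), seed = 1,
                             icv_center = NULL, icv_scale = NULL) {
  pk <- build_fit_pack(data, priors, config$grid,
                       icv_center = icv_center, icv_scale = icv_scale)
  p2 <- init
  p2$site_biases <- init$site_biases[pk$site_ids]
  p2$site_noise_sds <- init$site_noise_sds[pk$site_ids]
  th0 <- unname(params_to_theta(p2))
  lp <- function(t) .cpp_log_post(t, pk$pack)
  gr <- function(t) .cpp_log_post_grad(t, pk$pack, 1e-6)
  metric <- map_curvature_metric(gr, th0,
                                 prior_vectors(priors, pk$pack$n_sites)$sd)
  set.seed(as.integer(seed))
  chains <- vector("list", config$n_chains)
  for (c in seq_len(config$n_chains)) {
    chains[[c]] <- nuts_chain(lp, gr, th0, metric,
                              warmup = config$warmup, n_draws = config$n_draws,
                              max_treedepth = config$max_treedepth,
                              target_accept = config$target_accept)
  }
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(draws) <- theta_names(pk$site_ids)
  divergent <- sum(vapply(chains, function(ch) ch$n_divergent, numeric(1)))
  diag_tab <- data.frame(
    parameter = colnames(draws),
    rhat = apply(draws, 2, function(x) split_rhat(x, config$n_chains)),
    ess = apply(draws, 2, function(x) bulk_ess(x, config$n_chains)))
  frac_div <- divergent / (config$n_chains * config$n_draws)
  if (frac_div > 0.05)
    warning(sprintf("%.1f%% divergent transitions; treat results with caution",
                    100 * frac_div))
  structure(list(draws = draws, map_params = init,
                 diagnostics = list(table = diag_tab,
                                    n_divergent = divergent,
                                    divergent_fraction = frac_div,
                                    step_size = vapply(chains, `[[`,
                                                       numeric(1), "step_size")),
                 site_ids = pk$site_ids, grid = config$grid,
                 knots = pk$knots,
                 icv_center = pk$icv_center, icv_scale = pk$icv_scale,
                 seed = as.integer(seed), config = config),
            class = "posterior_fit")
}

#' Model parameters implied by one posterior draw
#' @param fit a `posterior_fit`.
#' @param i draw index.
#' @return a [model_params()] object.
#' @export
params_from_draw <- function(fit, i) {
  theta_to_params(fit$draws[i, ], fit$site_ids, fit$knots,
                  fit$icv_center, fit$icv_scale)
}

# dense metric from the negative Hessian of the log posterior at the MAP
# (finite differences of the gradient, symmetrized, eigenvalues floored);
# decorrelates the posterior so NUTS trajectories stay short
map_curvature_metric <- function(gr, th, prior_sd, h = 1e-3, dense = FALSE) {
  n <- length(th)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    hi <- h * max(1, abs(th[i]))
    tp <- th; tp[i] <- th[i] + hi
    tm <- th; tm[i] <- th[i] - hi
    H[i, ] <- -(gr(tp) - gr(tm)) / (2 * hi)
  }
  H <- (H + t(H)) / 2
  if (!dense) H <- diag(pmax(diag(H), 1 / prior_sd^2))
  if (!all(is.finite(H))) H <- diag(1 / prior_sd^2)
  new_metric(H)
}

#' Posterior-predictive calibration on held-out data
#'
#' For each held-out measurement the model's marginal predictive
#' distribution (population prior at the subject's covariates, plus site
#' bias and site noise) is evaluated over posterior draws; the probability
#' integral transform of the observation under that mixture gives, per
#' nominal central-interval level, the fraction of measurements covered.
#'
#' @param fit a `posterior_fit`.
#' @param heldout observation table of subjects not used in fitting.
#' @param levels nominal central-interval levels.
#' @param n_draws number of posterior draws used (thinned evenly).
#' @return data frame with columns `level`, `coverage`, `n`.
#' @export
calibration_check <- function(fit, heldout,
                              levels = c(0.5, 0.8, 0.9, 0.95),
                              n_draws = 100) {
  if (is.null(heldout) || nrow(heldout) == 0) stop("empty held-out table")
  validate_observation_table(heldout, sites = fit$site_ids)
  idx <- unique(round(seq(1, nrow(fit$draws), length.out =
                            min(n_draws, nrow(fit$draws)))))
  ks <- snap_age(fit$grid, heldout$age)
  icv_std <- (heldout$icv - fit$icv_center) / fit$icv_scale
  site <- as.character(heldout$site)
  pit_by_draw <- vapply(idx, function(d) {
    p <- params_from_draw(fit, d)
    model <- assemble_model(p, fit$grid)
    # the predictive mean is linear in (sex, icv): propagate the reference
    # profile and the two covariate effects once along the grid
    base <- prof_s <- prof_i <- svar <- numeric(fit$grid$K + 1)
    b00 <- initial_state_distribution(p, covariate_profile(0, 0))
    b10 <- initial_state_distribution(p, covariate_profile(1, 0))
    b01 <- initial_state_distribution(p, covariate_profile(0, 1))
    for (k in 0:fit$grid$K) {
      if (k > 0) {
        b00 <- propagate_belief(b00, model$system, k - 1L, 1L)
        b10 <- propagate_belief(b10, model$system, k - 1L, 1L)
        b01 <- propagate_belief(b01, model$system, k - 1L, 1L)
      }
      base[k + 1] <- b00$mu[1]
      prof_s[k + 1] <- b10$mu[1] - b00$mu[1]
      prof_i[k + 1] <- b01$mu[1] - b00$mu[1]
      svar[k + 1] <- b00$Sigma[1, 1]
    }
    m <- base[ks + 1] + heldout$sex * prof_s[ks + 1] + icv_std * prof_i[ks + 1] +
      unname(p$site_biases[site])
    s <- sqrt(svar[ks + 1] + unname(p$site_noise_sds[site])^2)
    stats::pnorm(heldout$volume, m, s)
  }, numeric(nrow(heldout)))
  u <- rowMeans(pit_by_draw)
  data.frame(level = levels,
             coverage = vapply(levels, function(L)
               mean(abs(u - 0.5) <= L / 2), numeric(1)),
             n = nrow(heldout))
}
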