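#' Prior specification on the unconstrained parameter scale
#'
#' All priors are Gaussian on the unconstrained scale. Positive parameters
#' (feedback coefficients, the process-noise level, site noise SDs) reach
#' their natural scale through a softplus link, so their variance-type
#' priors are squared-softplus transformed Gaussians; unconstrained
#' parameters (spline control values of the acceleration bias, covariate
#' coefficients, site biases) carry wide Gaussians directly.
#'
#' The site noise prior follows the construction of centering on a
#' measurement-SD guess for the structure with prior SD equal to that
#' center. When an observation table is supplied, the initial-mean priors
#' are centered on the sample mean volume with generous scales.
#'
#' @param data optional observation table used to center the level priors.
#' @param sigma_r_center center of the per-site measurement-noise SD prior
#'   (mm^3); its prior SD equals the center.
#' @param sigma_q_center center of the process-noise SD prior.
#' @param b_scale prior SD of the acceleration-bias control values.
#' @param bias_scale prior SD of the free site biases (mm^3).
#' @param level_center,level_scale center/SD of the initial mean volume
#'   prior (overridden by `data`).
#' @param rate_scale prior SD of the initial mean change rate and its
#'   covariate coefficients.
#' @param sigma_s0_center,sigma_v0_center centers of the initial-SD priors.
#' @param feedback_loc,feedback_scale prior location/scale of the
#'   unconstrained feedback coordinates.
#' @param sigma_r_scale,sigma_q_scale prior scales of the noise-SD
#'   coordinates on the unconstrained scale; the defaults equal the centers
#'   (a weakly informative choice whose transformed SD roughly matches the
#'   center).
#' @param chol_scale prior scale of the log-diagonal initial-covariance
#'   coordinates.
#' @return a `prior_spec` object.
#' @export
prior_spec <- function(data = NULL,
                       sigma_r_center = 80,
                       sigma_q_center = 5,
                       b_scale = 50,
                       bias_scale = 200,
                       level_center = 8000, level_scale = 4000,
                       rate_scale = 30,
                       sigma_s0_center = 1000,
                       sigma_v0_center = 5,
                       feedback_loc = -4, feedback_scale = 2,
                       sigma_r_scale = NULL, sigma_q_scale = NULL,
                       chol_scale = 1.5) {
  if (is.null(sigma_r_scale)) sigma_r_scale <- max(sigma_r_center, 1)
  if (is.null(sigma_q_scale)) sigma_q_scale <- max(sigma_q_center, 1)
  if (!is.null(data)) {
    level_center <- mean(data$volume)
    level_scale <- max(3 * stats::sd(data$volume), 1)
  }
  structure(list(
    sigma_r_center = sigma_r_center, sigma_q_center = sigma_q_center,
    b_scale = b_scale, bias_scale = bias_scale,
    level_center = level_center, level_scale = level_scale,
    rate_scale = rate_scale,
    sigma_s0_center = sigma_s0_center, sigma_v0_center = sigma_v0_center,
    feedback_loc = feedback_loc, feedback_scale = feedback_scale,
    sigma_r_scale = sigma_r_scale, sigma_q_scale = sigma_q_scale,
    chol_scale = chol_scale
  ), class = "prior_spec")
}

# expand a prior_spec into per-coordinate Gaussian (mean, sd) vectors
# aligned with the unconstrained theta layout for J sites
prior_vectors <- function(priors, n_sites) {
  stopifnot(inherits(priors, "prior_spec"), n_sites >= 1)
  J <- n_sites
  uq <- softplus_inv(priors$sigma_q_center)
  ur <- softplus_inv(priors$sigma_r_center)
  m <- c(priors$feedback_loc, priors$feedback_loc,       # u_fs, u_fv
         rep(0, 5),                                      # b spline
         rep(uq, 5),                                     # q spline (unconstrained)
         priors$level_center, 0, 0,                      # beta_s0, sex, icv
         0, 0, 0,                                        # beta_v0, sex, icv
         log(priors$sigma_s0_center), 0, log(priors$sigma_v0_center),
         rep(0, J - 1),                                  # free site biases
         rep(ur, J))                                     # u_sr
  s <- c(priors$feedback_scale, priors$feedback_scale,
         rep(priors$b_scale, 5),
         rep(priors$sigma_q_scale, 5),
         priors$level_scale, priors$level_scale, priors$level_scale,
         priors$rate_scale, priors$rate_scale, priors$rate_scale,
         priors$chol_scale, priors$sigma_v0_center, priors$chol_scale,
         rep(priors$bias_scale, J - 1),
         rep(priors$sigma_r_scale, J))
  if (any(s <= 0)) stop("all prior scales must be positive")
  list(mean = m, sd = s)
}
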