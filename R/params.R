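#' Continuous-time model parameters
#'
#' Bundles every fitted quantity of the stochastic dynamical model of adult
#' brain-structure volumes. The latent state `z(t) = (s(t), v(t))` couples
#' the true volume `s` (mm^3) with its change rate `v` (mm^3/year) through
#' \deqn{\dot s = v, \qquad \dot v = -f_s s - f_v v + b(t) + w_q(t),}
#' where `b(t)` is an age-dependent acceleration bias and `w_q` is white
#' noise with age-dependent variance `sigma_q^2(t)`. Measurements add a
#' site bias (constrained to sum to zero over sites) and site-specific
#' Gaussian noise; the initial state at age 18 is Gaussian with a mean
#' linear in sex and standardized ICV.
#'
#' @param fs volume-feedback coefficient (1/year^2), `>= 0`.
#' @param fv rate-feedback coefficient (1/year), `>= 0`.
#' @param b_ctrl five control values of the acceleration-bias spline `b(t)`
#'   (mm^3/year^2).
#' @param q_ctrl five control values, on the unconstrained scale, of the
#'   process-noise spline; `sigma_q(t) = softplus(spline(t))`.
#' @param init_mean_coeffs named or plain numeric length-6 vector
#'   `(beta_s0, beta_s0_sex, beta_s0_icv, beta_v0, beta_v0_sex, beta_v0_icv)`.
#' @param init_cov 2x2 symmetric positive semidefinite covariance of the
#'   initial latent state.
#' @param site_biases named numeric vector of additive site biases (mm^3);
#'   must sum to zero (within `1e-6` of the magnitude scale).
#' @param site_noise_sds named numeric vector of per-site measurement-noise
#'   SDs (mm^3), positive, same names as `site_biases`.
#' @param knots spline knot ages shared by `b(t)` and the noise spline.
#' @param icv_center,icv_scale the ICV standardization constants (raw ICV is
#'   mapped to `(icv - icv_center) / icv_scale` before entering the model);
#'   defaults treat ICV as already standardized.
#' @param sex_coding documentation string for the binary sex code.
#' @return an object of class `braintraj_params`.
#' @examples
#' p <- model_params(
#'   fs = 1e-4, fv = 0.1,
#'   b_ctrl = c(0, -0.5, -1, -3, -6),
#'   q_ctrl = softplus_inv(c(1, 1, 2, 6, 10)),
#'   init_mean_coeffs = c(8000, 300, 400, -2, 0.5, 0),
#'   init_cov = diag(c(700^2, 2^2)),
#'   site_biases = c(a = 40, b = -40),
#'   site_noise_sds = c(a = 60, b = 90)
#' )
#' @export
model_params <- function(fs, fv, b_ctrl, q_ctrl, init_mean_coeffs, init_cov,
                         site_biases, site_noise_sds,
                         knots = default_knots(),
                         icv_center = 0, icv_scale = 1,
                         sex_coding = "female=0, male=1") {
  p <- structure(list(
    fs = as.numeric(fs), fv = as.numeric(fv),
    b_spline = nc_spline(b_ctrl, knots),
    q_spline = nc_spline(q_ctrl, knots),
    init_mean_coeffs = stats::setNames(as.numeric(init_mean_coeffs),
      c("beta_s0", "beta_s0_sex", "beta_s0_icv",
        "beta_v0", "beta_v0_sex", "beta_v0_icv")),
    init_cov = as.matrix(init_cov),
    site_biases = site_biases,
    site_noise_sds = site_noise_sds,
    icv_center = as.numeric(icv_center), icv_scale = as.numeric(icv_scale),
    sex_coding = sex_coding
  ), class = "braintraj_params")
  validate_params(p)
  p
}

#' Validate model parameters
#'
#' Checks the structural invariants: non-negative feedback (so the feedback
#' term is never expansive), positive semidefinite initial covariance,
#' sum-to-zero site biases, and strictly positive site noise SDs.
#'
#' @param p a `braintraj_params` object.
#' @return `p`, invisibly; errors describe the violated invariant.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "braintraj_params"))
  if (!is.finite(p$fs) || p$fs < 0) stop("fs must be finite and >= 0")
  if (!is.finite(p$fv) || p$fv < 0) stop("fv must be finite and >= 0")
  if (length(p$init_mean_coeffs) != 6 || !all(is.finite(p$init_mean_coeffs)))
    stop("init_mean_coeffs must be 6 finite values")
  S <- p$init_cov
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
    stop("init_cov must be symmetric")
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(1, max(abs(ev)))))
    stop("init_cov must be positive semidefinite")
  if (length(p$site_biases) != length(p$site_noise_sds) ||
      !identical(names(p$site_biases), names(p$site_noise_sds)))
    stop("site_biases and site_noise_sds must share site names")
  if (is.null(names(p$site_biases)) && length(p$site_biases) > 0)
    stop("site parameters must be named by site id")
  tol <- 1e-6 * max(1, max(abs(p$site_biases)))
  if (length(p$site_biases) && abs(sum(p$site_biases)) > tol)
    stop("site biases must sum to zero across sites")
  if (any(p$site_noise_sds <= 0)) stop("all site noise SDs must be positive")
  invisible(p)
}

#' @export
print.braintraj_params <- function(x, ...) {
  cat("<braintraj_params>\n")
  cat(sprintf("  feedback: fs = %.4g /yr^2, fv = %.4g /yr\n", x$fs, x$fv))
  cat(sprintf("  b(t) control values (mm^3/yr^2): %s\n",
              paste(signif(x$b_spline$values, 3), collapse = ", ")))
  cat(sprintf("  sigma_q(t) at knots (mm^3/yr^2 per sqrt(yr)): %s\n",
              paste(signif(softplus(x$q_spline$values), 3), collapse = ", ")))
  cat(sprintf("  initial mean coeffs: %s\n",
              paste(sprintf("%s=%.4g", names(x$init_mean_coeffs),
                            x$init_mean_coeffs), collapse = ", ")))
  cat(sprintf("  initial SDs: s %.4g mm^3, v %.4g mm^3/yr (corr %.3f)\n",
              sqrt(x$init_cov[1, 1]), sqrt(x$init_cov[2, 2]),
              stats::cov2cor(x$init_cov + diag(1e-300, 2))[1, 2]))
  cat(sprintf("  sites: %d (bias range %.4g..%.4g, noise SD range %.4g..%.4g)\n",
              length(x$site_biases),
              min(x$site_biases), max(x$site_biases),
              min(x$site_noise_sds), max(x$site_noise_sds)))
  invisible(x)
}

#' Covariate profile of an individual
#'
#' @param sex binary sex code (0 or 1; the convention is recorded in the
#'   parameter object, default female=0, male=1).
#' @param icv intracranial volume, on the standardized scale the model was
#'   fitted on.
#' @return a `covariate_profile` list.
#' @export
covariate_profile <- function(sex = 0, icv = 0) {
  if (!sex %in% c(0, 1)) stop("sex must be coded 0 or 1")
  if (!is.finite(icv)) stop("icv must be finite")
  structure(list(sex = sex, icv = icv), class = "covariate_profile")
}

#' Age-dependent process-noise SD sigma_q(t)
#' @param p model parameters.
#' @param t ages in years.
#' @return numeric vector of noise SDs (mm^3/year^2 per sqrt(year)).
#' @export
sigma_q_at <- function(p, t) softplus(eval_spline(p$q_spline, t))

#' Acceleration bias b(t)
#' @param p model parameters.
#' @param t ages in years.
#' @return numeric vector (mm^3/year^2).
#' @export
accel_bias_at <- function(p, t) eval_spline(p$b_spline, t)

#' Initial latent-state distribution at age 18
#'
#' The mean is linear in sex and standardized ICV; the covariance is shared
#' across individuals.
#'
#' @param p model parameters.
#' @param cov a [covariate_profile()].
#' @return a [gaussian_belief()] at the initial age.
#' @export
initial_state_distribution <- function(p, cov = covariate_profile()) {
  validate_params(p)
  b <- p$init_mean_coeffs
  mu <- c(b[1] + b[2] * cov$sex + b[3] * cov$icv,
          b[4] + b[5] * cov$sex + b[6] * cov$icv)
  gaussian_belief(unname(mu), p$init_cov)
}

#' Continuous-time system matrices at an age
#'
#' Returns the drift matrix, bias input and process-noise intensity of the
#' matrix form of the dynamics:
#' `F = [[0, 1], [-fs, -fv]]`, `B(t) = (0, b(t))`,
#' `Q(t) = diag(0, sigma_q^2(t))`.
#'
#' @param p model parameters.
#' @param t age in years.
#' @return list with elements `F` (2x2), `B` (length 2), `Q` (2x2).
#' @export
continuous_system <- function(p, t) {
  list(F = matrix(c(0, -p$fs, 1, -p$fv), 2, 2),
       B = c(0, accel_bias_at(p, t)),
       Q = diag(c(0, sigma_q_at(p, t)^2)))
}

#' Number of model parameters as a function of site count
#'
#' The parameter count is 2 feedback coefficients, 2 x 5 spline control
#' values, 6 initial-mean coefficients, 3 free entries of the initial
#' covariance, one bias and one noise SD per site. With the sum-to-zero
#' constraint only `n_sites - 1` biases are free.
#'
#' @param n_sites number of imaging sites.
#' @param count_constrained if `TRUE`, count one bias per site (including
#'   the constrained one); if `FALSE` (default) count only free parameters.
#' @return integer parameter count.
#' @export
n_parameters <- function(n_sites, count_constrained = FALSE) {
  stopifnot(n_sites >= 1)
  21L + 2L * as.integer(n_sites) - (if (count_constrained) 0L else 1L)
}
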