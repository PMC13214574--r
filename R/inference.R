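#' Observations of one subject, snapped to the model grid
#'
#' Scan ages are rounded to the nearest grid step (ties toward the younger
#' age). If two scans land on the same step, the earlier scan is kept and a
#' warning is emitted.
#'
#' @param ages scan ages in years.
#' @param volumes measured volumes (mm^3).
#' @param sites site ids (character), one per scan.
#' @param covariates a [covariate_profile()].
#' @param grid the [age_grid()] the model uses.
#' @param id optional subject id.
#' @return a `subject_observations` object with 0-based grid steps.
#' @export
subject_observations <- function(ages, volumes, sites,
                                 covariates = covariate_profile(),
                                 grid = age_grid(), id = "subject") {
  stopifnot(length(ages) == length(volumes), length(ages) == length(sites))
  o <- order(ages)
  ages <- ages[o]; volumes <- volumes[o]; sites <- as.character(sites[o])
  steps <- snap_age(grid, ages)
  if (anyDuplicated(steps)) {
    warning(sprintf("subject %s: multiple scans snapped to one grid step; keeping the earlier scan", id))
    keep <- !duplicated(steps)
    steps <- steps[keep]; volumes <- volumes[keep]; sites <- sites[keep]
  }
  structure(list(id = id, covariates = covariates, steps = steps,
                 volumes = volumes, sites = sites, grid = grid),
            class = "subject_observations")
}

# resolve site ids against the model registry; error names the unknown site
site_index <- function(model, sites) {
  idx <- match(sites, names(model$params$site_biases))
  if (anyNA(idx)) {
    bad <- unique(sites[is.na(idx)])
    stop(sprintf("unknown site id(s): %s", paste(bad, collapse = ", ")))
  }
  idx
}

#' Marginal log-likelihood of a subject's observation sequence
#'
#' The exact likelihood `p(y_1, ..., y_m)` of all of a subject's scans under
#' the model, with the latent trajectory marginalized out analytically via
#' the prediction-error decomposition of the Kalman filter. A single scan
#' and a dense longitudinal series are handled identically.
#'
#' @param model an [assemble_model()] result.
#' @param subject a [subject_observations()].
#' @return scalar log-probability.
#' @export
marginal_loglik <- function(model, subject) {
  stopifnot(inherits(model, "braintraj_model"),
            inherits(subject, "subject_observations"))
  if (length(subject$steps) == 0) return(0)
  idx <- site_index(model, subject$sites)
  prior <- initial_state_distribution(model$params, subject$covariates)
  res <- .cpp_filter_subject(
    prior$mu, c(prior$Sigma[1, 1], prior$Sigma[1, 2], prior$Sigma[2, 2]),
    as.numeric(t(model$system$F_star)), model$system$B_star, model$system$Q_star,
    as.integer(subject$steps), subject$volumes,
    unname(model$params$site_biases[idx]),
    unname(model$params$site_noise_sds[idx]^2),
    FALSE)
  res$loglik
}

#' Posterior latent trajectory of a subject (RTS smoother)
#'
#' Runs the Kalman filter forward over the full grid and the
#' Rauch-Tung-Striebel recursion backward, yielding the posterior mean and
#' covariance of the latent state at every grid age given all of the
#' subject's observations. With no observations the posterior equals the
#' prior propagation.
#'
#' @param model an [assemble_model()] result.
#' @param subject a [subject_observations()].
#' @return a `latent_posterior` with fields `ages`, `mean` (`(K+1)` x 2),
#'   `cov` (`(K+1)` x 3 packed `s_ss, s_sv, s_vv`), matching `filtered_*`
#'   fields, and `loglik`.
#' @export
smooth_posterior <- function(model, subject) {
  stopifnot(inherits(model, "braintraj_model"),
            inherits(subject, "subject_observations"))
  prior <- initial_state_distribution(model$params, subject$covariates)
  m <- length(subject$steps)
  if (m > 0) {
    idx <- site_index(model, subject$sites)
    bias <- unname(model$params$site_biases[idx])
    rvar <- unname(model$params$site_noise_sds[idx]^2)
  } else {
    bias <- numeric(0); rvar <- numeric(0)
  }
  res <- .cpp_filter_subject(
    prior$mu, c(prior$Sigma[1, 1], prior$Sigma[1, 2], prior$Sigma[2, 2]),
    as.numeric(t(model$system$F_star)), model$system$B_star, model$system$Q_star,
    as.integer(subject$steps), subject$volumes, bias, rvar, TRUE)
  sm <- .cpp_rts_smooth(res$pred, res$filt, as.numeric(t(model$system$F_star)))
  structure(list(
    ages = model$grid$ages,
    mean = sm[, 1:2, drop = FALSE],
    cov = sm[, 3:5, drop = FALSE],
    filtered_mean = res$filt[, 1:2, drop = FALSE],
    filtered_cov = res$filt[, 3:5, drop = FALSE],
    predicted_cov = res$pred[, 3:5, drop = FALSE],
    loglik = res$loglik
  ), class = "latent_posterior")
}
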