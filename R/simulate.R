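#' Design of a synthetic multi-site longitudinal cohort
#'
#' Describes the sampling structure of a synthetic cohort: how many
#' subjects, how baseline ages are spread, how many sessions each subject
#' contributes, the spacing of follow-ups, the number of imaging sites and
#' the sex/ICV distributions. The defaults mirror the shape of large pooled
#' aging cohorts: dense age coverage between 50 and 70 years, roughly 45%
#' single-session participants with a decaying tail up to 12 sessions, and
#' subjects nested within sites. They emulate the statistical structure of
#' such samples without replicating any real cohort.
#'
#' @param n_subjects number of subjects.
#' @param baseline_age_weights function of age returning an (unnormalized)
#'   sampling weight for integer baseline ages.
#' @param baseline_age_range range of baseline ages (years).
#' @param session_count_probs named or plain probability vector over the
#'   number of sessions per subject (index = session count).
#' @param interval_probs probability vector over integer inter-scan
#'   intervals in grid steps (index = interval).
#' @param n_sites number of imaging sites; each subject is scanned at one
#'   site.
#' @param sex_ratio probability of code 1 (male).
#' @param icv_sd SD of the standardized ICV values.
#' @return a `cohort_design` object.
#' @export
cohort_design <- function(n_subjects = 500,
                          baseline_age_weights = function(a)
                            0.35 + 1.3 * exp(-((a - 60) / 13)^2),
                          baseline_age_range = c(18, 90),
                          session_count_probs = default_session_probs(),
                          interval_probs = c(0.4, 0.35, 0.15, 0.1),
                          n_sites = 3,
                          sex_ratio = 0.5,
                          icv_sd = 1) {
  stopifnot(n_subjects >= 1, n_sites >= 1,
            all(session_count_probs >= 0), all(interval_probs >= 0))
  session_count_probs <- session_count_probs / sum(session_count_probs)
  interval_probs <- interval_probs / sum(interval_probs)
  structure(list(n_subjects = as.integer(n_subjects),
                 baseline_age_weights = baseline_age_weights,
                 baseline_age_range = baseline_age_range,
                 session_count_probs = session_count_probs,
                 interval_probs = interval_probs,
                 n_sites = as.integer(n_sites),
                 sex_ratio = sex_ratio, icv_sd = icv_sd),
            class = "cohort_design")
}

#' Default distribution of sessions per subject
#'
#' Mass 0.45 at a single session and a geometric tail over 2--12 sessions,
#' emulating pooled samples that mix cross-sectional and longitudinal arms.
#' @return probability vector indexed by session count.
#' @export
default_session_probs <- function() {
  p <- c(0.45, 0.55 * 0.62^(0:10) * (1 - 0.62) / (1 - 0.62^11))
  p / sum(p)
}

# eigenvalue square root of a 2x2 PSD matrix (robust to rank deficiency)
psd_sqrt2 <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2) %*% t(e$vectors)
}

#' Simulate latent trajectories on the grid
#'
#' Forward-simulates `n` independent latent trajectories of the discrete
#' system from the initial distribution at a fixed covariate profile,
#' returning the latent state at the requested grid steps. Used for
#' Monte-Carlo verification of the closed-form moments and by the cohort
#' generator.
#'
#' @param model an [assemble_model()] result.
#' @param n number of trajectories.
#' @param steps_keep 0-based grid steps at which to return the state.
#' @param covariates a [covariate_profile()].
#' @return list of `n` x 2 matrices (columns: volume, change rate), one per
#'   kept step, named by step.
#' @export
simulate_latent_trajectories <- function(model, n, steps_keep,
                                         covariates = covariate_profile()) {
  steps_keep <- sort(unique(as.integer(steps_keep)))
  kmax <- max(steps_keep)
  if (kmax > model$grid$K) stop("requested step beyond the grid")
  b0 <- initial_state_distribution(model$params, covariates)
  L0 <- psd_sqrt2(b0$Sigma)
  Z <- matrix(stats::rnorm(2 * n), n, 2) %*% t(L0)
  Z[, 1] <- Z[, 1] + b0$mu[1]; Z[, 2] <- Z[, 2] + b0$mu[2]
  out <- vector("list", length(steps_keep))
  names(out) <- as.character(steps_keep)
  Fs <- model$system$F_star
  if (0 %in% steps_keep) out[["0"]] <- Z
  if (kmax > 0) for (k in 1:kmax) {
    Qk <- matrix(c(model$system$Q_star[k, 1], model$system$Q_star[k, 2],
                   model$system$Q_star[k, 2], model$system$Q_star[k, 3]), 2, 2)
    Lk <- psd_sqrt2(Qk)
    W <- matrix(stats::rnorm(2 * n), n, 2) %*% t(Lk)
    Z <- Z %*% t(Fs) + W
    Z[, 1] <- Z[, 1] + model$system$B_star[k, 1]
    Z[, 2] <- Z[, 2] + model$system$B_star[k, 2]
    if (k %in% steps_keep) out[[as.character(k)]] <- Z
  }
  out
}

#' Simulate a synthetic multi-site longitudinal cohort
#'
#' Draws covariates, a site, a baseline age and a session schedule for each
#' subject, forward-simulates the subject's latent trajectory from age 18
#' under the discrete dynamics, and emits measured volumes with site bias
#' and site noise at the scheduled ages. Sessions that would fall past the
#' end of the grid are truncated. The true latent volume and change rate at
#' each scan are recorded in a sidecar truth table.
#'
#' @param params model parameters used as the generative truth.
#' @param design a [cohort_design()].
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @param grid the [age_grid()] to simulate on.
#' @return a `braintraj_cohort` list: `observations` (data frame with
#'   columns `subject_id, age, sex, icv, site, volume`) and `truth`
#'   (columns `subject_id, age, latent_volume, latent_rate`).
#' @export
simulate_cohort <- function(params, design, seed, grid = age_grid()) {
  validate_params(params)
  stopifnot(inherits(design, "cohort_design"))
  if (length(params$site_biases) < design$n_sites)
    stop("params define fewer sites than the design requests")
  set.seed(as.integer(seed))
  n <- design$n_subjects
  sex <- stats::rbinom(n, 1, design$sex_ratio)
  icv <- stats::rnorm(n, 0, design$icv_sd)
  site_ids <- names(params$site_biases)[seq_len(design$n_sites)]
  site <- sample(site_ids, n, replace = TRUE)
  ages_grid <- seq(design$baseline_age_range[1], design$baseline_age_range[2])
  w <- design$baseline_age_weights(ages_grid)
  base_age <- sample(ages_grid, n, replace = TRUE, prob = w / sum(w))
  n_sess <- sample(seq_along(design$session_count_probs), n, replace = TRUE,
                   prob = design$session_count_probs)
  # schedule: baseline step plus cumulative integer intervals, truncated at K
  sched <- lapply(seq_len(n), function(i) {
    k0 <- snap_age(grid, base_age[i])
    if (n_sess[i] == 1) return(k0)
    gaps <- sample(seq_along(design$interval_probs), n_sess[i] - 1,
                   replace = TRUE, prob = design$interval_probs)
    ks <- k0 + cumsum(c(0, gaps))
    ks[ks <= grid$K]
  })
  model <- assemble_model(params, grid)
  Fs <- model$system$F_star
  Qchol <- lapply(seq_len(grid$K), function(k)
    psd_sqrt2(matrix(c(model$system$Q_star[k, 1], model$system$Q_star[k, 2],
                       model$system$Q_star[k, 2], model$system$Q_star[k, 3]),
                     2, 2)))
  icv_std <- (icv - params$icv_center) / params$icv_scale
  b0 <- lapply(seq_len(n), function(i)
    initial_state_distribution(params, covariate_profile(sex[i], icv_std[i])))
  L0 <- psd_sqrt2(params$init_cov)
  Z <- matrix(stats::rnorm(2 * n), n, 2) %*% t(L0)
  mu0 <- t(vapply(b0, function(b) b$mu, numeric(2)))
  Z <- Z + mu0
  kmax <- max(unlist(sched))
  obs <- vector("list", n)
  tru <- vector("list", n)
  sbias <- params$site_biases[site]
  ssd <- params$site_noise_sds[site]
  for (k in 0:kmax) {
    at_k <- which(vapply(sched, function(s) k %in% s, logical(1)))
    for (i in at_k) {
      y <- Z[i, 1] + sbias[i] + stats::rnorm(1, 0, ssd[i])
      obs[[i]] <- rbind(obs[[i]],
        data.frame(subject_id = sprintf("S%04d", i), age = grid$ages[k + 1],
                   sex = sex[i], icv = icv[i], site = site[i], volume = y))
      tru[[i]] <- rbind(tru[[i]],
        data.frame(subject_id = sprintf("S%04d", i), age = grid$ages[k + 1],
                   latent_volume = Z[i, 1], latent_rate = Z[i, 2]))
    }
    if (k < kmax) {
      W <- matrix(stats::rnorm(2 * n), n, 2) %*% t(Qchol[[k + 1]])
      Z <- Z %*% t(Fs) + W
      Z[, 1] <- Z[, 1] + model$system$B_star[k + 1, 1]
      Z[, 2] <- Z[, 2] + model$system$B_star[k + 1, 2]
    }
  }
  observations <- do.call(rbind, obs)
  rownames(observations) <- NULL
  truth <- do.call(rbind, tru)
  rownames(truth) <- NULL
  structure(list(observations = observations, truth = truth,
                 seed = as.integer(seed)),
            class = "braintraj_cohort")
}

#' Read and validate an observation table
#'
#' @param path CSV file with header
#'   `subject_id,age,sex,icv,site,volume`.
#' @param sites optional site registry; unknown sites trigger a validation
#'   error.
#' @return validated data frame.
#' @export
read_observation_table <- function(path, sites = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_observation_table(tab, sites)
}

#' @rdname read_observation_table
#' @param table an observation data frame.
#' @export
write_observation_table <- function(table, path) {
  validate_observation_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate an observation table
#'
#' Checks required columns, age range, finite volumes, strictly increasing
#' ages within subject, and (optionally) a site registry.
#'
#' @param tab observation data frame.
#' @param sites optional character vector of known site ids.
#' @return the table, invisibly on success.
#' @export
validate_observation_table <- function(tab, sites = NULL) {
  required <- c("subject_id", "age", "sex", "icv", "site", "volume")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  bad <- which(!is.finite(tab$age) | tab$age < 18 | tab$age > 100)
  if (length(bad))
    stop(sprintf("age out of range [18, 100] at row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  bad <- which(!is.finite(tab$volume))
  if (length(bad))
    stop(sprintf("non-finite volume at row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  if (!all(tab$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  for (id in unique(tab$subject_id)) {
    a <- tab$age[tab$subject_id == id]
    if (is.unsorted(a, strictly = TRUE))
      stop(sprintf("ages of subject %s are not strictly increasing", id))
  }
  if (!is.null(sites)) {
    unknown <- setdiff(unique(tab$site), sites)
    if (length(unknown))
      stop(sprintf("unknown site id(s): %s", paste(unknown, collapse = ", ")))
  }
  invisible(tab)
}

#' Synthetic parameter fixtures with documented qualitative behavior
#'
#' Ready-made parameter sets whose qualitative dynamics mirror two
#' archetypes of adult brain structures. These are synthetic fixtures
#' designed for testing and demonstration; they are not fitted estimates.
#'
#' * `"hippocampus-like"`: a structure with a large stable young-adult
#'   level, slow early decline, and change-rate variability that rises
#'   sharply after about age 60, so explained variance from age 30 stays
#'   high until 60 and then falls.
#' * `"ventricle-like"`: a structure with a modest young-adult level
#'   spread, accelerating growth, and change-rate variability present from
#'   early adulthood, so a single volume correlates positively with the
#'   change rate already by age 40.
#'
#' @param structure_tag one of `"hippocampus-like"`, `"ventricle-like"`.
#' @param n_sites number of sites in the fixture registry (default 3).
#' @return a [model_params()] object.
#' @export
default_structure_params <- function(structure_tag, n_sites = 3) {
  tags <- c("hippocampus-like", "ventricle-like")
  if (!structure_tag %in% tags)
    stop(sprintf("unknown tag '%s'; available: %s", structure_tag,
                 paste(tags, collapse = ", ")))
  site_ids <- paste0("site", seq_len(n_sites))
  biases <- seq(-40, 40, length.out = n_sites)
  biases <- biases - mean(biases)
  if (structure_tag == "hippocampus-like") {
    model_params(
      fs = 1e-5, fv = 0.05,
      b_ctrl = c(-0.1, -0.2, -1.2, -3.0, -3.6),
      q_ctrl = softplus_inv(c(0.3, 0.6, 3, 28, 80)),
      init_mean_coeffs = c(8300, 400, 450, -2, -0.2, 0),
      init_cov = matrix(c(700^2, 0.2 * 700 * 1.5,
                          0.2 * 700 * 1.5, 1.5^2), 2, 2),
      site_biases = stats::setNames(biases, site_ids),
      site_noise_sds = stats::setNames(seq(60, 100, length.out = n_sites),
                                       site_ids)
    )
  } else {
    model_params(
      fs = 1e-5, fv = 0.04,
      b_ctrl = c(2, 3, 12, 28, 30),
      q_ctrl = softplus_inv(c(25, 30, 60, 110, 180)),
      init_mean_coeffs = c(15000, 1500, 1200, 60, 10, 0),
      init_cov = matrix(c(2500^2, 0.3 * 2500 * 50,
                          0.3 * 2500 * 50, 50^2), 2, 2),
      site_biases = stats::setNames(biases * 3, site_ids),
      site_noise_sds = stats::setNames(seq(250, 400, length.out = n_sites),
                                       site_ids)
    )
  }
}
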