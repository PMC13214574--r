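#' @title Closed-form correlation and study-design analytics
#' @description
#' The linear-Gaussian structure of the model gives every population-level
#' quantity in closed form: lagged autocovariance/autocorrelation of the
#' latent volume and change rate, explained-variance curves relative to a
#' young-adult reference age, the correlation of single-volume, delta and
#' least-squares slope estimators with the latent change rate, norm curves,
#' and analytic study-design power for slope estimation.
#' @name dynamics_analysis
NULL

mat_pow2 <- function(A, n) {
  P <- diag(2)
  for (i in seq_len(n)) P <- A %*% P
  P
}

latent_cov_at <- function(model, k) {
  prior_belief_at(model, k)$Sigma
}

# default per-scan noise SD: the mean of the site noise SDs, the convention
# used when displaying population-level results
default_sigma_r <- function(model) {
  sds <- model$params$site_noise_sds
  if (length(sds) == 0) 0 else mean(sds)
}

steps_from <- function(model, age, lag) {
  k <- snap_age(model$grid, age)
  n <- as.integer(round(lag / model$grid$delta))
  if (abs(n * model$grid$delta - lag) > 1e-9) stop("lag must be a grid multiple")
  if (n < 0) stop("lag must be >= 0 (the autocovariance is symmetric in lag)")
  if (k + n > model$grid$K) stop("age + lag beyond the model grid")
  list(k = k, n = n)
}

#' Lagged autocovariance of the latent state
#'
#' For the latent state the closed form is `K(z_k, z_{k+n}) = F*^(n) Sigma_k`;
#' entry `[i, j]` is `Cov(z_{k+n}[i], z_k[j])` with component order
#' (volume, change rate). With `measured = TRUE` the same covariances hold
#' for the measured volume (noise is independent of the latent state), but
#' the lag-0 measured-volume variance gains the measurement-noise variance.
#'
#' @param model an [assemble_model()] result.
#' @param age base age in years (grid age).
#' @param lag lag in years, `>= 0`, a multiple of the grid step.
#' @param measured if `TRUE`, also return measured-volume blocks.
#' @param sigma_r per-scan noise SD used for measured quantities; defaults
#'   to the mean site noise SD.
#' @return latent 2x2 covariance matrix; if `measured`, a list with
#'   `latent`, the measured-volume autocovariance `ss`, and the cross
#'   covariances `s_hat_then_z` / `z_then_s_hat` (identical to the latent
#'   cross covariances).
#' @export
autocovariance <- function(model, age, lag, measured = FALSE,
                           sigma_r = default_sigma_r(model)) {
  st <- steps_from(model, age, lag)
  Sk <- latent_cov_at(model, st$k)
  M <- mat_pow2(model$system$F_star, st$n) %*% Sk
  dimnames(M) <- list(later = c("s", "v"), base = c("s", "v"))
  if (!measured) return(M)
  ss <- if (st$n == 0) Sk[1, 1] + sigma_r^2 else M[1, 1]
  list(latent = M, ss = ss,
       s_hat_then_z = M[, 1], z_then_s_hat = M[1, ])
}

#' Lagged autocorrelation matrix
#'
#' Elementwise normalization of the lagged autocovariance by the component
#' standard deviations at the two ages; at lag 0 this is the ordinary
#' correlation matrix. With `measured = TRUE` the volume component at both
#' ages is the measured volume (its variance inflated by the noise
#' variance), while the change rate stays latent; entry `["v", "s"]` is then
#' the correlation between a measured volume and the latent change rate.
#'
#' @inheritParams autocovariance
#' @return 2x2 matrix of correlations, rows = components at `age + lag`,
#'   columns = components at `age`, component order (s, v).
#' @export
autocorrelation <- function(model, age, lag, measured = FALSE,
                            sigma_r = default_sigma_r(model)) {
  st <- steps_from(model, age, lag)
  Sk <- latent_cov_at(model, st$k)
  Skn <- latent_cov_at(model, st$k + st$n)
  M <- mat_pow2(model$system$F_star, st$n) %*% Sk
  vk <- diag(Sk); vkn <- diag(Skn)
  if (measured) {
    vk[1] <- vk[1] + sigma_r^2
    vkn[1] <- vkn[1] + sigma_r^2
    if (st$n == 0) M[1, 1] <- M[1, 1] + sigma_r^2 # two scans of one session share noise
  }
  comp <- c("s", "v")
  for (i in 1:2) {
    if (vk[i] <= 0) stop(sprintf("zero variance in component '%s' at the base age", comp[i]))
    if (vkn[i] <= 0) stop(sprintf("zero variance in component '%s' at the target age", comp[i]))
  }
  R <- M / (sqrt(vkn) %o% sqrt(vk))
  dimnames(R) <- list(later = comp, base = comp)
  R
}

#' Explained variance of later-life volume from a young-adult reference
#'
#' The squared correlation between the (latent or measured) volume at a
#' reference age and at a later target age, holding sex and ICV fixed (the
#' covariates enter the mean only, so conditioning on them contributes no
#' variance). This decomposes later-life volume variation into the share
#' carried by the stable reference-age level versus accumulated change.
#' With noise and `target_age == ref_age` the two measurements are treated
#' as independent noise draws of the same session age, giving
#' `(Sigma_ss / (Sigma_ss + sigma_r^2))^2`.
#'
#' @param model an [assemble_model()] result.
#' @param target_age later age, `>= ref_age`.
#' @param ref_age reference age (default 30 years).
#' @param measured include measurement noise in both volumes.
#' @param sigma_r per-scan noise SD for the measured variant.
#' @return R-squared in `[0, 1]`.
#' @export
explained_variance <- function(model, target_age, ref_age = 30,
                               measured = FALSE,
                               sigma_r = default_sigma_r(model)) {
  if (any(target_age < ref_age)) stop("target_age must be >= ref_age")
  vapply(target_age, function(a) {
    if (measured && a == ref_age) {
      k <- snap_age(model$grid, ref_age)
      s2 <- latent_cov_at(model, k)[1, 1]
      return((s2 / (s2 + sigma_r^2))^2)
    }
    st <- steps_from(model, ref_age, a - ref_age)
    Sk <- latent_cov_at(model, st$k)
    Skn <- latent_cov_at(model, st$k + st$n)
    num <- (mat_pow2(model$system$F_star, st$n) %*% Sk)[1, 1]
    r2 <- if (measured) sigma_r^2 else 0
    vk <- Sk[1, 1] + r2
    vkn <- Skn[1, 1] + r2
    if (vk <= 0 || vkn <= 0) stop("zero volume variance at an endpoint age")
    num^2 / (vk * vkn)
  }, numeric(1))
}

#' Correlation between volume and the latent change rate at one age
#'
#' How well a single (measured or latent) volume, compared against the
#' age norm, proxies the individual's current latent change rate: the
#' `["v", "s"]` entry of the lag-0 autocorrelation, with measurement noise
#' inflating only the volume variance.
#'
#' @param model an [assemble_model()] result.
#' @param age grid age in years.
#' @param measured use the measured volume (default) or the latent one.
#' @param sigma_r per-scan noise SD.
#' @return correlation in `[-1, 1]`.
#' @export
volume_change_correlation <- function(model, age, measured = TRUE,
                                      sigma_r = default_sigma_r(model)) {
  vapply(age, function(a)
    autocorrelation(model, a, 0, measured = measured,
                    sigma_r = sigma_r)["v", "s"], numeric(1))
}

#' Correlation of the two-point delta estimate with the latent change rate
#'
#' The delta estimate is the time-normalized difference of two measured
#' volumes, `(s_hat_{k+n} - s_hat_k) / (n delta)`; its correlation with the
#' latent change rate at the later session follows from the closed-form
#' auto- and cross-covariances (the normalization cancels).
#'
#' @param model an [assemble_model()] result.
#' @param base_age age of the first scan (years).
#' @param lag years between the scans, `>= 1` grid step.
#' @param sigma_r per-scan noise SD (independent across the two scans).
#' @return correlation between the delta estimate and the latent change
#'   rate at `base_age + lag`.
#' @export
delta_estimate_correlation <- function(model, base_age, lag,
                                       sigma_r = default_sigma_r(model)) {
  st <- steps_from(model, base_age, lag)
  if (st$n == 0) stop("delta estimate needs a nonzero interval between scans")
  Sk <- latent_cov_at(model, st$k)
  Skn <- latent_cov_at(model, st$k + st$n)
  M <- mat_pow2(model$system$F_star, st$n) %*% Sk
  num <- Skn[2, 1] - M[2, 1]
  dvar <- Skn[1, 1] + Sk[1, 1] + 2 * sigma_r^2 - 2 * M[1, 1]
  num / sqrt(dvar * Skn[2, 2])
}

#' Least-squares slope weights over equally spaced measurements
#'
#' The ordinary least-squares slope over `n + 1` equally spaced measurements
#' is the linear functional with weights
#' `Lambda_i = 12 / (n (n+1) (n+2)) * (i - n/2)`, `i = 0..n`, in per-step
#' units (divide by the step length for a per-year slope). The weights have
#' zero response to a constant level and unit response to a unit-per-step
#' linear trend.
#'
#' @param n_intervals number of inter-measurement intervals `n >= 1`.
#' @return numeric weight vector of length `n_intervals + 1`.
#' @export
slope_weights <- function(n_intervals) {
  n <- n_intervals
  if (n < 1) stop("need at least one interval between measurements")
  i <- 0:n
  12 / (n * (n + 1) * (n + 2)) * (i - n / 2)
}

#' Correlation of the multi-session slope estimate with the latent change rate
#'
#' Sessions are spread equally over the interval and must land on grid
#' steps. The OLS slope over the measured volumes is a linear functional of
#' the measurement vector, so its correlation with the latent change rate at
#' the last session follows from the measurement auto-covariance matrix and
#' the cross covariance with the change rate.
#'
#' @param model an [assemble_model()] result.
#' @param base_age age of the first session (years).
#' @param lag years between first and last session.
#' @param sessions number of sessions `>= 2`.
#' @param sigma_r per-scan noise SD (iid across sessions).
#' @return correlation between the slope estimate and the latent change
#'   rate at `base_age + lag`.
#' @export
slope_estimate_correlation <- function(model, base_age, lag, sessions,
                                       sigma_r = default_sigma_r(model)) {
  st <- steps_from(model, base_age, lag)
  if (sessions < 2) stop("need at least two sessions")
  if (st$n < 1) stop("slope estimate needs a nonzero interval")
  sp <- st$n / (sessions - 1)
  if (abs(sp - round(sp)) > 1e-9)
    stop("sessions cannot be placed equally on the grid over this interval")
  sp <- as.integer(round(sp))
  a <- st$k + sp * (0:(sessions - 1))     # session grid steps
  tt <- model$grid$ages[a + 1]
  w <- (tt - mean(tt)) / sum((tt - mean(tt))^2)  # OLS slope weights (per year)
  N <- sessions
  C <- matrix(0, N, N)
  covs <- lapply(a, function(k) latent_cov_at(model, k))
  for (i in seq_len(N)) for (j in i:N) {
    M <- mat_pow2(model$system$F_star, a[j] - a[i]) %*% covs[[i]]
    C[i, j] <- C[j, i] <- M[1, 1]
  }
  diag(C) <- diag(C) + sigma_r^2
  last <- st$k + st$n
  cv <- vapply(seq_len(N), function(i)
    (mat_pow2(model$system$F_star, last - a[i]) %*% covs[[i]])[2, 1],
    numeric(1))
  Svv <- latent_cov_at(model, last)[2, 2]
  sum(w * cv) / sqrt(drop(t(w) %*% C %*% w) * Svv)
}

#' Population norm curves: mean and 2-SD band of volume and change rate
#'
#' Propagates the initial distribution for a fixed covariate profile along
#' the grid and reports, per age, the population mean and the mean plus or
#' minus two latent SDs for both the volume and the change rate. If a
#' posterior fit is supplied, central 50% and 95% credible bands for each
#' curve are added by evaluating it over the posterior draws.
#'
#' @param model an [assemble_model()] result.
#' @param ages grid ages to report (default: every grid age up to 90).
#' @param covariates a [covariate_profile()].
#' @param posterior optional `posterior_fit` from [sample_posterior()].
#' @param n_draws number of posterior draws used for the bands.
#' @return a data frame with columns `age`, `variable` ("volume" or
#'   "rate"), `mean`, `sd`, `lo`, `hi` (the 2-SD band) and, with a
#'   posterior, `mean_lo50/mean_hi50/mean_lo95/mean_hi95`.
#' @export
norm_curves <- function(model, ages = NULL, covariates = covariate_profile(),
                        posterior = NULL, n_draws = 200) {
  if (is.null(ages))
    ages <- model$grid$ages[model$grid$ages <= min(90, max(model$grid$ages))]
  ks <- snap_age(model$grid, ages)
  rows <- lapply(seq_along(ages), function(i) {
    b <- prior_belief_at(model, ks[i], covariates)
    sd <- sqrt(pmax(diag(b$Sigma), 0))
    data.frame(age = ages[i], variable = c("volume", "rate"),
               mean = b$mu, sd = sd,
               lo = b$mu - 2 * sd, hi = b$mu + 2 * sd)
  })
  out <- do.call(rbind, rows)
  if (!is.null(posterior)) {
    idx <- round(seq(1, nrow(posterior$draws), length.out =
                       min(n_draws, nrow(posterior$draws))))
    draw_means <- vapply(idx, function(d) {
      pd <- params_from_draw(posterior, d)
      md <- assemble_model(pd, model$grid)
      unlist(lapply(seq_along(ages), function(i)
        prior_belief_at(md, ks[i], covariates)$mu))
    }, numeric(2 * length(ages)))
    qs <- t(apply(draw_means, 1, stats::quantile,
                  probs = c(0.025, 0.25, 0.75, 0.975)))
    out$mean_lo95 <- qs[, 1]; out$mean_lo50 <- qs[, 2]
    out$mean_hi50 <- qs[, 3]; out$mean_hi95 <- qs[, 4]
  }
  out
}

#' Longitudinal study design for slope estimation
#'
#' @param interval total years between the first and last session (`T > 0`).
#' @param sessions number of sessions `N >= 2` (even for endpoint clusters).
#' @param scheme `"equal"` for equal spacing across the interval, or
#'   `"endpoint-clusters"` for `N/2` scans at each endpoint.
#' @param sigma_r per-scan measurement-noise SD.
#' @return a `study_design` object.
#' @export
study_design <- function(interval, sessions, scheme = c("equal", "endpoint-clusters"),
                         sigma_r = 1) {
  scheme <- match.arg(scheme)
  if (interval <= 0) stop("interval must be positive")
  if (sessions < 2) stop("need at least two sessions")
  if (scheme == "endpoint-clusters" && sessions %% 2 != 0)
    stop("endpoint clusters need an even number of sessions")
  structure(list(interval = interval, sessions = as.integer(sessions),
                 scheme = scheme, sigma_r = sigma_r),
            class = "study_design")
}

#' Standard deviation of the slope estimate under a study design
#'
#' Assumes iid per-scan noise and a constant latent change rate over the
#' interval. Equal spacing of `N` sessions over interval `T` gives slope
#' variance `12 sigma_r^2 (N - 1) / (T^2 N (N + 1))`; clustering `N/2`
#' independent scans at each endpoint gives `4 sigma_r^2 / (N T^2)`.
#'
#' @param design a [study_design()].
#' @return SD of the slope estimate (volume units per year).
#' @export
design_slope_sd <- function(design) {
  stopifnot(inherits(design, "study_design"))
  N <- design$sessions; T <- design$interval; s2 <- design$sigma_r^2
  v <- switch(design$scheme,
    "equal" = 12 * s2 * (N - 1) / (T^2 * N * (N + 1)),
    "endpoint-clusters" = 4 * s2 / (N * T^2))
  sqrt(v)
}

#' Signal-to-noise ratio of the slope estimate
#'
#' The magnitude of the mean change rate over the interval divided by the
#' SD of the slope estimate.
#'
#' @param design a [study_design()].
#' @param change_rate mean latent change rate over the interval
#'   (volume units per year).
#' @return dimensionless SNR.
#' @export
design_snr <- function(design, change_rate) {
  abs(change_rate) / design_slope_sd(design)
}

#' Sessions needed to match the reliability of a reference design
#'
#' The smallest session count whose slope-estimate SD under the candidate
#' scheme and interval is less than or equal to the reference design's.
#' Matching the gain of doubling the scan interval with two sessions
#' requires 22 equally spaced sessions over the original interval, or 8
#' sessions clustered at its endpoints.
#'
#' @param reference a [study_design()] giving the target reliability.
#' @param interval interval of the candidate design (years).
#' @param scheme candidate spacing scheme.
#' @param n_max largest session count considered before declaring the
#'   target unreachable.
#' @return minimal integer session count, or `NA` (with a warning) if no
#'   count up to `n_max` reaches the target.
#' @export
sessions_to_match <- function(reference, interval,
                              scheme = c("equal", "endpoint-clusters"),
                              n_max = 10000L) {
  scheme <- match.arg(scheme)
  target <- design_slope_sd(reference)
  step <- if (scheme == "endpoint-clusters") 2L else 1L
  for (N in seq(2L, n_max, by = step)) {
    d <- study_design(interval, N, scheme, reference$sigma_r)
    if (design_slope_sd(d) <= target) return(N)
  }
  warning("target reliability unreachable within n_max sessions")
  NA_integer_
}
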