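# No-U-Turn sampler with slice termination and dual-averaging step-size
# adaptation (Hoffman & Gelman, 2014, Algorithms 3 and 6), preconditioned
# with a fixed dense metric (the log-posterior curvature at the MAP), so
# that near-Gaussian posteriors need only short trajectories. The
# posterior is supplied as log density and gradient on the unconstrained
# scale.

# metric: list(L = chol factor of the mass matrix M (lower), Minv)
new_metric <- function(M) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  lam <- pmax(e$values, max(e$values) * 1e-8)
  M <- e$vectors %*% (lam * t(e$vectors))
  list(L = t(chol(M)), Minv = e$vectors %*% ((1 / lam) * t(e$vectors)))
}

draw_momentum <- function(metric) {
  as.numeric(metric$L %*% stats::rnorm(nrow(metric$L)))
}

leapfrog <- function(theta, r, eps, gr, metric) {
  r <- r + 0.5 * eps * gr(theta)
  theta <- theta + eps * as.numeric(metric$Minv %*% r)
  r <- r + 0.5 * eps * gr(theta)
  list(theta = theta, r = r)
}

joint_logp <- function(lp_val, r, metric)
  lp_val - 0.5 * sum(r * as.numeric(metric$Minv %*% r))

# one tree-doubling trajectory; returns the selected point and bookkeeping
build_tree <- function(theta, r, log_u, dir, depth, eps, lp, gr, metric,
                       joint0) {
  if (depth == 0) {
    st <- leapfrog(theta, r, dir * eps, gr, metric)
    lp_val <- lp(st$theta)
    joint <- joint_logp(lp_val, st$r, metric)
    if (is.na(joint)) joint <- -Inf
    divergent <- !is.finite(joint) || (log_u - joint) > 1000
    n_valid <- as.integer(is.finite(joint) && log_u <= joint)
    alpha <- if (is.finite(joint)) min(1, exp(min(0, joint - joint0))) else 0
    return(list(minus_theta = st$theta, minus_r = st$r,
                plus_theta = st$theta, plus_r = st$r,
                proposal = st$theta, proposal_lp = lp_val,
                n_valid = n_valid, stop = divergent, divergent = divergent,
                alpha = alpha, n_alpha = 1L))
  }
  t1 <- build_tree(theta, r, log_u, dir, depth - 1, eps, lp, gr, metric,
                   joint0)
  if (t1$stop) return(t1)
  if (dir == -1) {
    t2 <- build_tree(t1$minus_theta, t1$minus_r, log_u, dir, depth - 1, eps,
                     lp, gr, metric, joint0)
    t1$minus_theta <- t2$minus_theta; t1$minus_r <- t2$minus_r
  } else {
    t2 <- build_tree(t1$plus_theta, t1$plus_r, log_u, dir, depth - 1, eps,
                     lp, gr, metric, joint0)
    t1$plus_theta <- t2$plus_theta; t1$plus_r <- t2$plus_r
  }
  n_tot <- t1$n_valid + t2$n_valid
  if (n_tot > 0 && stats::runif(1) < t2$n_valid / n_tot) {
    t1$proposal <- t2$proposal; t1$proposal_lp <- t2$proposal_lp
  }
  dtheta <- t1$plus_theta - t1$minus_theta
  uturn <- sum(dtheta * as.numeric(metric$Minv %*% t1$minus_r)) < 0 ||
    sum(dtheta * as.numeric(metric$Minv %*% t1$plus_r)) < 0
  t1$n_valid <- n_tot
  t1$stop <- t2$stop || uturn
  t1$divergent <- t1$divergent || t2$divergent
  t1$alpha <- t1$alpha + t2$alpha
  t1$n_alpha <- t1$n_alpha + t2$n_alpha
  t1
}

find_initial_step <- function(lp, gr, theta, metric) {
  eps <- 1
  r <- draw_momentum(metric)
  j0 <- joint_logp(lp(theta), r, metric)
  st <- leapfrog(theta, r, eps, gr, metric)
  j1 <- joint_logp(lp(st$theta), st$r, metric)
  if (!is.finite(j1)) { # fall back to a conservative small step
    while (!is.finite(j1) && eps > 1e-10) {
      eps <- eps / 10
      st <- leapfrog(theta, r, eps, gr, metric)
      j1 <- joint_logp(lp(st$theta), st$r, metric)
    }
    return(eps)
  }
  a <- if (j1 - j0 > log(0.5)) 1 else -1
  while (a * (j1 - j0) > -a * log(2)) {
    eps <- eps * 2^a
    if (eps < 1e-10 || eps > 1e7) break
    st <- leapfrog(theta, r, eps, gr, metric)
    j1 <- joint_logp(lp(st$theta), st$r, metric)
    if (!is.finite(j1)) { eps <- eps / 2; break }
  }
  eps
}

nuts_chain <- function(lp, gr, theta0, metric, warmup, n_draws,
                       max_treedepth = 9, target_accept = 0.8) {
  n <- length(theta0)
  theta <- theta0
  eps <- find_initial_step(lp, gr, theta, metric)
  mu <- log(10 * eps)
  log_eps_bar <- 0; h_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  da_it <- 0   # dual-averaging iteration counter (reset on metric update)
  # windowed metric adaptation: re-estimate the dense metric from draws
  # collected in the middle of the warm-up, then re-adapt the step size
  win_lo <- floor(warmup * 0.25); win_hi <- floor(warmup * 0.75)
  collect <- warmup >= 150 && n < win_hi - win_lo
  win_draws <- if (collect) matrix(NA_real_, win_hi - win_lo, n) else NULL
  draws <- matrix(NA_real_, n_draws, n)
  n_divergent <- 0L
  total <- warmup + n_draws
  for (it in seq_len(total)) {
    r0 <- draw_momentum(metric)
    lp0 <- lp(theta)
    joint0 <- joint_logp(lp0, r0, metric)
    log_u <- joint0 - stats::rexp(1)   # slice variable
    minus_theta <- plus_theta <- theta
    minus_r <- plus_r <- r0
    proposal <- theta
    n_valid <- 1L
    depth <- 0
    stop_flag <- FALSE
    alpha_sum <- 0; n_alpha <- 0L
    while (!stop_flag && depth < max_treedepth) {
      dir <- if (stats::runif(1) < 0.5) -1 else 1
      if (dir == -1) {
        tr <- build_tree(minus_theta, minus_r, log_u, dir, depth, eps,
                         lp, gr, metric, joint0)
        minus_theta <- tr$minus_theta; minus_r <- tr$minus_r
      } else {
        tr <- build_tree(plus_theta, plus_r, log_u, dir, depth, eps,
                         lp, gr, metric, joint0)
        plus_theta <- tr$plus_theta; plus_r <- tr$plus_r
      }
      if (!tr$stop && tr$n_valid > 0 &&
          stats::runif(1) < tr$n_valid / n_valid) {
        proposal <- tr$proposal
      }
      n_valid <- n_valid + tr$n_valid
      dtheta <- plus_theta - minus_theta
      stop_flag <- tr$stop ||
        sum(dtheta * as.numeric(metric$Minv %*% minus_r)) < 0 ||
        sum(dtheta * as.numeric(metric$Minv %*% plus_r)) < 0
      if (tr$divergent && it > warmup) n_divergent <- n_divergent + 1L
      alpha_sum <- alpha_sum + tr$alpha; n_alpha <- n_alpha + tr$n_alpha
      depth <- depth + 1
    }
    theta <- proposal
    if (it <= warmup) {
      da_it <- da_it + 1
      frac <- 1 / (da_it + t0)
      h_bar <- (1 - frac) * h_bar +
        frac * (target_accept - alpha_sum / max(n_alpha, 1L))
      log_eps <- min(mu - sqrt(da_it) / gamma * h_bar, log(1e6))
      w <- da_it^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (collect && it > win_lo && it <= win_hi)
        win_draws[it - win_lo, ] <- theta
      if (collect && it == win_hi) {
        # shrink the window covariance toward its diagonal, as the window
        # is short relative to the dimension
        S <- stats::cov(win_draws)
        w_n <- nrow(win_draws) / (nrow(win_draws) + 5)
        S <- w_n * S + (1 - w_n) * diag(diag(S) + 1e-8, n)
        if (all(is.finite(S)) && all(diag(S) > 0)) {
          metric <- new_metric(solve(S + 1e-10 * mean(diag(S)) * diag(n)))
          eps <- find_initial_step(lp, gr, theta, metric)
          mu <- log(10 * eps)
          log_eps_bar <- 0; h_bar <- 0; da_it <- 0
        }
      }
      if (it == warmup) eps <- exp(log_eps_bar)
    } else {
      draws[it - warmup, ] <- theta
    }
  }
  list(draws = draws, step_size = eps, n_divergent = n_divergent)
}

# ---- convergence diagnostics ---------------------------------------------

# rank-normalized split R-hat of a single parameter's concatenated chains
split_rhat <- function(x, n_chains = 1) {
  z <- stats::qnorm((rank(x) - 3 / 8) / (length(x) + 1 / 4))
  m <- matrix(z[seq_len(2 * n_chains * (length(z) %/% (2 * n_chains)))],
              ncol = 2 * n_chains)
  nn <- nrow(m)
  if (nn < 2) return(NA_real_)
  W <- mean(apply(m, 2, stats::var))
  B <- nn * stats::var(colMeans(m))
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# bulk effective sample size via Geyer's initial monotone sequence on the
# rank-normalized draws
bulk_ess <- function(x, n_chains = 1) {
  z <- stats::qnorm((rank(x) - 3 / 8) / (length(x) + 1 / 4))
  n <- length(z)
  if (stats::var(z) == 0) return(NA_real_)
  ac <- stats::acf(z, lag.max = min(n - 2, 500), plot = FALSE)$acf[, 1, 1]
  # Geyer pairs P_k = rho_{2k} + rho_{2k+1}: keep while positive, enforce
  # monotone decrease, tau = -1 + 2 * sum(P)
  P <- numeric(0)
  k <- 1
  while (k + 1 <= length(ac)) {
    p <- ac[k] + ac[k + 1]
    if (p < 0) break
    P <- c(P, p)
    k <- k + 2
  }
  if (length(P) == 0) return(n)
  P <- cummin(P)
  tau <- max(-1 + 2 * sum(P), 1e-8)
  n / tau
}
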