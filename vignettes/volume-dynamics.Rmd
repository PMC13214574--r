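---
title: "Modelling adult brain-volume trajectories as a stochastic dynamical system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adult brain-volume trajectories as a stochastic dynamical system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braintraj)
```

## The question the model answers

Adult brains differ enormously in the size of their structures, yet the
annual change of those structures is small — typically well under one
percent even in old age. A volume measured at, say, age 70 therefore mixes
two very different sources of variation: a stable individual level that was
already present in young adulthood, and the accumulation of systematic
differences in how fast each person's structure has been changing. The two
have opposite implications for cross-sectional studies of brain aging: only
the second reflects ongoing change. `braintraj` models the two sources
jointly and separates them analytically.

## The model

Each subject carries a latent state
$z(t) = (s(t), v(t))$: the true volume $s$ of a structure (mm³) free of
measurement noise and scanner bias, and its change rate $v$ (mm³/year),
with $t$ the age in years starting at $t_0 = 18$. The continuous-time
dynamics are linear with age-dependent inputs:

$$\dot s(t) = v(t), \qquad
  \dot v(t) = -f_s\, s(t) - f_v\, v(t) + b(t) + w_q(t),$$

where $f_s \ge 0$ and $f_v \ge 0$ are feedback coefficients (restricted to
non-positive feedback so the dynamics cannot grow exponentially), $b(t)$ is
an age-dependent acceleration bias, and $w_q$ is white noise with
age-dependent variance $\sigma_q^2(t)$. The functions $b(t)$ and the
noise level are natural cubic interpolating splines with five knots spaced
equally over ages 18–100; $\sigma_q(t)$ is kept positive by a softplus
link applied to an unconstrained spline. It is the *acceleration* that is
random: an individual's change rate at any age is the integral of all the
random and systematic pushes received so far, which is what lets the model
express both stable trajectories and late-life divergence.

A scan at site $j$ measures

$$\hat s(t) = s(t) + \beta_j + w_r(t), \qquad w_r \sim N(0, \sigma_{r,j}^2),$$

with additive site biases constrained to $\sum_j \beta_j = 0$ and one noise
SD per site. The initial state is Gaussian,
$z(t_0) \sim N(\mu_{z0}(\text{sex}, \text{ICV}), \Sigma_{z0})$, with a mean
linear in sex (coded female = 0, male = 1) and in intracranial volume
standardized to zero mean and unit SD (the standardization constants are
stored with the parameters so predictions use the same scale).

`n_parameters(J)` gives the parameter count for $J$ sites:
2 feedbacks + 2 × 5 spline values + 6 initial-mean coefficients + 3 free
covariance entries + $(J-1)$ free biases + $J$ noise SDs. The count is
exposed as a function rather than a constant because it is the site
registry of a particular data set that fixes it. The two splines share
knot placement.

## Exact discretization

Ages are discretized to a shared grid $t_0 + k\Delta$ with $\Delta = 1$
year by default (grid ages 18–100). Over one step the time-varying inputs
are held at their value at the *left* endpoint of the interval (a
zero-order hold, the plainest reading of holding parameters constant
within a step), and the discrete system

$$z_{k+1} = F^* z_k + B_k^* + w^*_{Q,k}$$

is exact for that held system: $F^* = e^{F\Delta}$,
$B^*_k = \int_0^\Delta e^{Fs}\,(0, b_k)^\top ds$, and
$Q^*_k = \int_0^\Delta e^{Fs}\, \mathrm{diag}(0, q_k)\, e^{F^\top s} ds$,
all evaluated with the Van Loan augmented-matrix-exponential construction
(a single block exponential; robust as $f_s, f_v \to 0$, where closed-form
2×2 algebra degenerates). Because $F$ is time-invariant, one exponential
serves the whole grid: $B^*_k$ and $Q^*_k$ are the per-step spline values
times fixed matrices. Covariances are symmetrized after every propagation
step to suppress floating-point drift. The tests verify the triple against
adaptive ODE integration of the defining integrals to 10⁻⁸ and check that
moments computed at $\Delta \in \{1, 0.5, 0.25\}$ converge at first order;
at the one-year grid the moment differences are below a few percent, and
scan ages are snapped to the nearest grid step (ties toward the younger
age; a second scan landing on an occupied step is dropped with a warning).

## Exact per-subject inference

Conditional on parameters the model is linear-Gaussian, so each subject's
marginal likelihood $p(y_0 \dots y_n)$ is computed exactly by the
prediction-error decomposition of a covariance Kalman filter (Joseph-form
updates for numerical symmetry; a square-root filter buys nothing at state
dimension 2), and the posterior of the latent trajectory given all of a
subject's scans by the Rauch–Tung–Striebel smoother. A single
cross-sectional scan and a dense longitudinal series are the same
computation. The suite checks both against a dense joint-Gaussian oracle —
the stacked covariance of all latent states and observations assembled
directly from the lag identities — to 10⁻⁸ on randomized models.

## Priors and fitting

All parameters are estimated on an unconstrained scale: softplus links for
$f_s$, $f_v$, $\sigma_q(t)$ and the site noise SDs (so the variance-type
priors are squared-softplus transformed Gaussians), a log-Cholesky
factorization for $\Sigma_{z0}$, and $J-1$ free site biases with the last
defined by the sum-to-zero constraint (exact by construction). Priors are
Gaussian on that scale. The site-noise prior follows the construction of
centering on a per-structure measurement-SD guess with prior SD equal to
the center (default center 80 mm³, appropriate for hippocampus-scale
structures); every location and scale is overridable through
`prior_spec()`, including the unconstrained-scale spreads
(`sigma_r_scale`, `sigma_q_scale`, `chol_scale`) for settings — such as
simulation-based calibration — where draws from the prior must themselves
be plausible generating models.

`fit_map()` maximizes the log posterior with L-BFGS-B, preconditioned by
the prior scales (`parscale`); without that preconditioning the mixed
scales of mm³-level and log-variance coordinates stall the line search far
from the optimum. Three jittered restarts guard against local optima; the
result is bitwise reproducible given data, configuration and seed. The
gradient is a structured central finite difference evaluated in compiled
code: the matrix exponential depends only on the two feedback
coordinates, so it is recomputed only for those, making a full gradient
cost roughly $2p$ fast Kalman passes for $p$ parameters.

`sample_posterior()` implements the No-U-Turn sampler (tree doubling with
slice termination, dual-averaging step-size adaptation, default target
acceptance 0.92) initialized at the MAP. No NUTS library is declared as a
dependency; the sampler is part of the package and is validated against a
known correlated Gaussian target in the tests. Geometry matters here: the
posterior couples $f_v$, the acceleration spline and the level parameters
along a curved ridge. The sampler therefore starts from a diagonal metric
built from the log-posterior curvature at the MAP, collects draws over the
middle half of the warm-up, and switches to a dense metric from the
(shrunk) empirical covariance of that window, re-adapting the step size
afterwards — the windowed strategy of mainstream HMC implementations. The
default schedule is 300 warm-up iterations and 1,000 retained draws from
one chain; multiple chains are available for between-chain diagnostics.
Rank-normalized split R-hat and a Geyer-pairs effective sample size are
attached to every fit, and the divergent-transition fraction warns (rather
than fails) above 5%.

`calibration_check()` evaluates, for held-out subjects, the probability
integral transform of each measurement under the posterior-predictive
mixture (population prior at the subject's covariates plus site bias and
noise, averaged over posterior draws) and reports empirical coverage of
central intervals at nominal levels 0.5, 0.8, 0.9 and 0.95.

## Closed-form analytics

Because the system is linear-Gaussian, every population-level quantity is
available in closed form from the per-step transition matrix and the
propagated covariance $\Sigma_k$:

* lagged autocovariance $K(z_k, z_{k+n}) = F^{*(n)} \Sigma_k$ and its
  elementwise-normalized autocorrelation; for measured volumes the noise
  variance enters each endpoint's denominator and the lag-0 variance;
* explained variance $R^2$ of later-life volume given the volume at a
  reference age (30 years by default): the squared volume–volume
  autocorrelation, with or without measurement noise. Covariates enter the
  mean only, so holding a profile fixed *is* the adjustment for sex and
  ICV. At target = reference with noise, the convention is two independent
  noise draws of the same session, giving
  $(\Sigma_{ss}/(\Sigma_{ss}+\sigma_r^2))^2$;
* the correlation between a single measured volume and the latent change
  rate at the same age (how well one scan proxies ongoing change);
* the correlation of the two-point *delta* estimate
  $(\hat s_{k+n} - \hat s_k)/(n\Delta)$ with the latent rate at the later
  scan, and of the least-squares *slope* estimate over equally spaced
  sessions (the OLS weights over $n+1$ points are
  $\Lambda_i = \tfrac{12}{n(n+1)(n+2)}(i - n/2)$ in per-step units; with
  two sessions the slope reduces exactly to the delta, and with three the
  middle session carries zero weight);
* population norm curves (mean ± 2 latent SD of volume and rate), with
  credible bands by evaluating over posterior draws when a fit is
  supplied.

Displayed measured-volume quantities use the mean of the per-site noise
SDs unless a specific `sigma_r` is passed.

Every one of these curves is verified against forward simulation of
200,000 latent trajectories from the same discrete system (within three
Monte-Carlo standard errors) in the acceptance suite; the simulator and
the analytic propagation share only the model definition, not the
covariance algebra.

## Study-design analytics

Under iid per-scan noise $\sigma_r$ and a constant latent change rate, the
SD of the OLS slope over $N$ equally spaced sessions spanning $T$ years is
$\sigma_r\sqrt{12(N-1)/(T^2 N(N+1))}$; clustering $N/2$ scans at each
endpoint gives $2\sigma_r/(\sqrt{N}\,T)$. `sessions_to_match()` inverts
these: matching the reliability gained by simply doubling the interval of
a two-session design requires 22 equally spaced sessions, or 8 sessions
clustered at the endpoints. The cluster result idealizes the cluster
scans as independent, which real back-to-back scans are not; it is a lower
bound on the sessions needed. The SNR helper divides the magnitude of the
mean change rate by the slope SD. Both printed counts are recomputed from
the formulas at run time by `scripts/acceptance.R`.

## The synthetic cohort generator

`simulate_cohort()` draws covariates, a site, a baseline age and a session
schedule per subject, forward-simulates the latent trajectory from age 18
with the exact discrete system, and emits measurements with site bias and
noise. The default design mirrors the shape of large pooled aging
samples: dense age coverage between 50 and 70, roughly 45% single-session
subjects with a decaying tail up to 12 sessions, one site per subject.
Sessions that would pass the end of the grid are truncated. A sidecar
table records the true latent volume and rate at every scan for recovery
tests; it is not part of the public data format.

Two documented fixtures, `default_structure_params()`, provide synthetic
parameter sets (not fitted estimates) whose qualitative dynamics mirror
two archetypes: a hippocampus-like structure (large stable young-adult
level, change-rate variability rising sharply after ~60, explained
variance from age 30 above 0.8 until 60 and falling steeply by 90) and a
ventricle-like structure (modest level spread, growth accelerating from
mid-life, rate variability present from young adulthood, volume–rate
correlation positive already at 40).

What the generator does *not* emulate — and therefore what passing tests
cannot certify about real data: skewed or heavy-tailed measurement error
and change-rate distributions, age- or size-dependent noise,
non-independent repeat scans within a session cluster, multiplicative
site effects, cohort and period effects, and informative dropout. The
generator is the generative model itself, so model-misspecification
robustness is out of its reach by construction.

## Problem sizes used by the test suite

The suite was sized to run comfortably on a single CPU: the dense-oracle
comparisons use a 20-year grid and 100 randomized subjects; the
Monte-Carlo verification uses 200,000 trajectories; parameter recovery
uses 500 subjects with three visits each; and simulation-based
calibration uses 20 replicate cohorts of 30 subjects on an 18–70 grid
with 250 warm-up / 400 retained draws, with truths drawn from a
deliberately tighter prior so that every replicate is a plausible cohort.
Coverage of 90% intervals is asserted within the replicate-clustered
Monte-Carlo error; at this reduced scale the short chains make the
estimate mildly conservative (slightly below nominal), which the error
band accommodates.

## Known limitations

* Gaussian everywhere: no robust observation model, no skewness. Real
  ventricular volumes in particular are right-skewed.
* Additive site effects only; no multiplicative scanner scaling.
* The one-year grid snaps scan ages by up to six months; sub-annual
  designs need a finer `age_grid()`.
* Finite-difference gradients are exact enough for L-BFGS and NUTS at
  this dimension (checked to 10⁻⁴ against independent differencing), but
  the approach would not scale to models with hundreds of parameters.
* Single-chain defaults favor speed; rank-normalized split R-hat on one
  chain can miss multimodality. Use `n_chains > 1` for publication-grade
  diagnostics.
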