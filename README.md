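# braintraj

Stochastic dynamical modelling of adult brain-structure volume
trajectories from multi-site longitudinal MRI.

## The problem

Volumetric differences between adult brains are large (tens of percent),
while longitudinal change is slow (well under 1% per year for most
structures). A volume measured at any single age therefore mixes a
**stable individual level**, set by young adulthood, with the
**accumulated effect of individual differences in change rate**. Telling
the two apart matters for anyone interpreting cross-sectional volumes as
evidence of ongoing brain aging, and for anyone designing a longitudinal
study that must detect individual change against measurement noise.
`braintraj` is for researchers in imaging neuroscience and biostatistics
who want to make that decomposition explicit, fit it to pooled multi-site
cohort data, and derive its consequences analytically.

## The model

Each subject carries a latent state `z(t) = (s(t), v(t))` — the true
volume of a structure (mm³) and its change rate (mm³/year) — evolving in
continuous time from age 18 as

```
ds/dt = v
dv/dt = -fs s - fv v + b(t) + w_q(t),   Var[w_q](t) = sigma_q^2(t)
```

with non-negative feedback coefficients `fs`, `fv`, an age-dependent
acceleration bias `b(t)` and an age-dependent process-noise level
`sigma_q(t)`, both natural cubic splines with five knots over ages
18–100. A scan at site `j` measures `s(t) + beta_j + noise`, with
sum-to-zero site biases and per-site noise SDs. The initial state is
Gaussian with a mean linear in sex and standardized intracranial volume.

Because the model is linear-Gaussian, everything downstream is exact:
zero-order-hold discretization by the Van Loan matrix exponential,
per-subject marginal likelihoods by Kalman filtering, latent-trajectory
posteriors by RTS smoothing, and closed-form autocorrelation,
explained-variance and estimator-correlation curves. Fitting is Bayesian:
MAP by L-BFGS, then a No-U-Turn sampler initialized at the MAP.
`vignette("volume-dynamics")` derives all of it.

## Worked example

```r
library(braintraj)

# a synthetic 300-subject multi-site cohort from a documented
# hippocampus-like parameter fixture (not fitted values)
params <- default_structure_params("hippocampus-like")
cohort <- simulate_cohort(params, cohort_design(n_subjects = 300), seed = 7)
head(cohort$observations, 3)
#>   subject_id age sex        icv  site   volume
#> 1      S0001  41   1 -0.3556944 site3 8762.711
#> 2      S0002  59   0  1.0973004 site2 7791.956
#> 3      S0002  60   0  1.0973004 site2 7835.021

# Bayesian fit: MAP estimate under weakly informative priors
priors <- prior_spec(cohort$observations, sigma_r_center = 80,
                     sigma_q_center = 10)
map <- fit_map(cohort$observations, priors, fit_config(restarts = 2), seed = 1)
map
#> <braintraj_params>
#>   feedback: fs = 0.0001114 /yr^2, fv = 0.00695 /yr
#>   sigma_q(t) at knots (mm^3/yr^2 per sqrt(yr)): 0.399, 0.743, 1.57, 18.4, 25.2
#>   initial mean coeffs: beta_s0=8280, beta_s0_sex=478.6, beta_s0_icv=401.1, ...
#>   initial SDs: s 691 mm^3, v 4.768 mm^3/yr (corr 0.600)
#>   sites: 3 (bias range -48.75..68.18, noise SD range 62.49..96.48)

model <- assemble_model(map)

# how much later-life volume variance the age-30 level explains:
# nearly all of it until 60, then less as change-rate differences build up
explained_variance(model, c(40, 60, 80))
#> [1] 0.997 0.973 0.786

# a single volume is a weak proxy for the current change rate
volume_change_correlation(model, c(50, 80))
#> [1] 0.147 0.281

# a 2-year follow-up at age 78-80: the two-point delta estimate, and the
# 3-session slope (identical - the middle session carries zero OLS weight)
delta_estimate_correlation(model, base_age = 78, lag = 2)
#> [1] 0.581
slope_estimate_correlation(model, base_age = 78, lag = 2, sessions = 3)
#> [1] 0.581

# study design: SD of a slope estimate from 2 scans 4 years apart with
# 60 mm^3 per-scan noise, and the sessions needed to match that
# reliability in half the time
design_slope_sd(study_design(interval = 4, sessions = 2, sigma_r = 60))
#> [1] 21.2132
sessions_to_match(study_design(4, 2, sigma_r = 60), interval = 2,
                  scheme = "equal")
#> [1] 22
```

`sample_posterior()` continues from the MAP to full posterior draws with
convergence diagnostics; `norm_curves()`, `autocorrelation()` and
`calibration_check()` cover the remaining analyses. Thin command-line
wrappers for simulation, fitting, curve export and design calculations
live in `inst/cli/`.

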