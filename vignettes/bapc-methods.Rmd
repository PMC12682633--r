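---
title: "Methods: Bayesian age-period-cohort modelling of disease burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian age-period-cohort modelling of disease burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bapcburden)
```

This vignette is the package's own account of its statistical machinery:
the model, its priors and identifiability scheme, the approximate-inference
algorithm and its accuracy contract, the forecasting and validation layers,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices that were genuinely open.

## The descriptive layer

Age-standardized rates are weighted means of age-specific rates,
$\mathrm{ASR} = \frac{\sum_i a_i w_i}{\sum_i w_i} \times 10^5$, reported
per 100,000 person-years. Internally all rates are per person-year; the
GBD-dialect `rate` metric (already per 100,000) is divided by $10^5$ at
ingestion so that no quantity is ever scaled twice. The standard population
is deliberately pluggable: the shipped default is the WHO World Standard
aggregated to eighteen 5-year groups, but comparative claims should state
the standard explicitly, because different agencies use different internal
standards and the ASR is only comparable under a shared one.

The EAPC is the log-linear trend summary
$100(e^{\beta}-1)$ from an ordinary least-squares fit of
$\ln \mathrm{ASR}_t$ on calendar year, with the CI transformed the same
way. No formula for an "estimated annual percentage change" is universal;
this log-linear definition is the one consistent with reporting a single
percentage with a symmetric-in-$\beta$ CI, and it is exact on geometric
series (a 2%/year series returns exactly 2.0000 with zero residual
variance — one of the package's acceptance checks). It requires strictly
positive ASRs and at least three years, and is equivariant under shifting
the year labels.

Risk attribution multiplies totals by pre-computed population attributable
fractions at the finest common stratum and aggregates afterwards; PAFs are
not additive across nested risk categories (behavioural ⊃ smoking, dietary
⊃ its components), so the package reports each risk row independently and
never sums across a hierarchy. SDI quintile assignment is rank-based with
equal-mass cutpoints by default and deterministic tie-breaking by location
label; explicit value cutpoints are accepted for agency-defined bands.

## The age-period-cohort model

Counts on an $A \times T$ Lexis grid (age groups of width $M$ periods,
annual periods) are modelled as
$$y_{at} \sim \mathrm{Poisson}\!\left(n_{at}\, e^{\eta_{at}}\right),
\qquad
\eta_{at} = \mu + \alpha_a + \beta_t + \gamma_{c(a,t)}
          + \textstyle\sum_k \delta_k x_k(t),$$
with cohort index $c(a,t) = M(A-a) + t$ running over the grid diagonals
(oldest age at the first period is cohort 1; when $M > 1$, the single-year
birth cohorts sharing a diagonal share one effect value). The Poisson
likelihood with a person-years offset is the standard choice for
registry-scale event counts; an optional negative-binomial switch (default
off) adds an estimated dispersion hyperparameter for data with
extra-Poisson variation.

Each of $\alpha$, $\beta$, $\gamma$ gets a random-walk smoothing prior,
$$\log p(u \mid \tau) = \frac{m-k}{2}\log\tau
  - \frac{\tau}{2}\sum_j (\Delta^k u)_j^2 + \text{const},$$
of order $k = 2$ by default. The second-order walk is flat on linear
trends, which is exactly the degeneracy that makes APC drift
unidentifiable; it is also what lets the forecast continue a trend rather
than revert to a level. The order is configurable per effect because the
literature is split between first- and second-order smooths for period and
cohort effects; the package's default uses second order for all three and
places the penalized-complexity prior on each walk's innovation standard
deviation regardless of order, which honours both the "smooth fields" and
the "PC prior with a simple base model" conventions where they are
compatible.

The PC prior on a standard deviation is exponential with rate
$\lambda = -\ln(\alpha_0)/U$, i.e. $P(\sigma > U) = \alpha_0$. The default
$U = 1$, $\alpha_0 = 0.01$ says: on the log-rate scale, a smoothing
standard deviation above 1 (a factor of $e$ per step) has prior
probability 1%. This is weakly informative at registry scale — the
posterior modes in the synthetic experiments sit two orders of magnitude
below $U$ — and both hyperparameters are exposed in `apc_spec()` for
sensitivity analysis. The intercept and covariate coefficients carry weak
normal priors (sd 100 and 10).

Covariate series are centred to mean zero over the observed years before
entering $\eta$, so they perturb the period structure without shifting the
intercept; their coefficients $\delta_k$ are estimated jointly under the
weak prior, with the option of fixing them by supplying a degenerate
series. Whether such exposure elasticities should be estimated or imposed
from external meta-regressions is a genuinely open design question; the
package estimates them because it must stand alone without access to any
external meta-regression machinery, and estimated-with-weak-prior nests
the imposed case.

### Identifiability

Only $\eta$ (and its functionals: fitted rates, ASRs, forecasts) is
identifiable; the individual effects are not, because level shifts and one
linear trend can be moved between components without changing $\eta$. The
package makes this explicit rather than implicit: effects are represented
in orthonormal bases that enforce a declared constraint set exactly —
sum-to-zero on $\alpha$, $\beta$, $\gamma$ plus a zero linear trend on the
cohort effect (default, drift carried by the period effect), or the mirror
set with drift on the cohort effect. Hard reparameterisation was chosen
over soft constraints or post-hoc projection because it keeps every
curvature matrix positive definite and makes the constraint exact in every
posterior draw. An acceptance check verifies that the two constraint sets
give $\eta$ posteriors agreeing within Monte-Carlo tolerance (0.02 on the
log-rate scale at 1,000 draws); reported effect curves should always be
read jointly with their constraint set.

### Inference

The model is a latent Gaussian model with a three-dimensional (four with
overdispersion) hyperparameter: the smoothing log-precisions
$\theta = (\log\tau_\alpha, \log\tau_\beta, \log\tau_\gamma)$. Inference
proceeds in the classic nested fashion:

1. For fixed $\theta$, the conditional posterior of the latent field is
   approximated by a Gaussian at its mode (Newton optimization with
   step-halving; the mode and Cholesky factor of the curvature are exact
   up to the convergence tolerance, $10^{-9}$ on the Newton decrement).
2. The marginal posterior of $\theta$ is approximated by the Laplace
   formula and maximized by Nelder-Mead; its curvature at the mode comes
   from central finite differences (step 0.1).
3. Hyperparameter uncertainty is propagated by drawing a small number of
   $\theta$ values (default 20) from the Gaussian approximation at the
   mode and drawing equal shares of the requested latent samples (default
   1,000, matching the package's Monte-Carlo uncertainty convention) from
   each conditional Gaussian.

The accuracy contract — posterior mean of $\eta$ within 0.05 log-rate of a
long-run MCMC sampler on small instances — is enforced in the test suite
against an independent JAGS implementation of the same hierarchy; the
measured gap on a $4\times 8$ grid is about 0.01. Interval calibration is
checked by simulation: over 50 synthetic replicates of the full
age-period-cohort scenario at the desk scale ($18 \times 32$), the
fraction of grid cells whose true $\eta$ lies inside the 95% interval must
fall in $[0.90, 0.98]$.

Numerical choices that matter:

* The Poisson log-likelihood is accumulated in saturated-anchored form,
  $y\log(m/y) - (m - y)$ per cell, keeping each term $O(1)$ near the fit.
  The naive $y\log m - m$ form loses ~10 significant digits at
  registry-scale counts, which is enough to derail the hyperparameter
  search when an effect sits exactly in the walk's null space (e.g. a
  purely linear period effect) and its precision is weakly identified.
* Smoothing log-precisions are restricted to $[-12, 18]$ (σ roughly
  between $10^{-4}$ and 400 on the log-rate scale) by a smooth penalty;
  outside that range the marginal is numerically flat and scientifically
  meaningless.
* Quantiles everywhere are linear-interpolation sample quantiles.
* Degenerate inputs error early and specifically: missing Lexis cells are
  listed by (age group, year); grids need at least 3 age groups, 4
  periods and 4 cohorts; non-finite states, non-positive precisions and
  invalid PC hyperparameters are rejected at the boundary.

### Forecasting

Per posterior sample, the period and cohort effects are continued beyond
the observed window by their own random walks — order equal to the
smoothing order, innovation standard deviation taken from that sample's
precision draw — while age effects are held fixed and covariates follow a
scenario rule (`hold_last` by default, linear continuation or an explicit
future series optionally; hold-last is the conservative choice when no
exposure forecast is trusted). Future rates $e^{\tilde\eta}$ are
standardized to an ASR per future year and summarized by 2.5/50/97.5
percentiles. Because RW2 extrapolation continues the local trend, a true
log-linear drift is recovered unbiasedly (checked over 50 seeds), and
interval width grows monotonically with horizon (checked over a 30-year
projection). A zero horizon returns the last fitted year's summaries
unchanged.

### Back-testing and model criticism

`backtest()` splits the grid at a given year (at least four training
periods and one test period), refits on the training window only, and
scores the held-out window. Two choices deserve justification:

* **Scale.** Scores default to the log-rate scale, where the model is
  linear and errors are comparable across age groups with rates spanning
  orders of magnitude; the per-100,000 rate scale is available. Cells
  with zero observed counts cannot be scored on the log scale and are
  dropped with their number reported (at desk-scale synthetic counts there
  are none).
* **Predictive scoring.** Intervals, medians and CRPS are computed from
  the posterior *predictive* distribution — for each posterior draw of the
  future rate, one count is drawn from the likelihood with the test-year
  person-years — not from the latent-rate posterior. Observed rates carry
  sampling noise; latent-rate intervals are systematically anticonservative
  against observations (measured ≈0.87 coverage at nominal 95% in the
  package's own experiments), whereas predictive intervals are calibrated
  (≈0.97 over 50 replicates). Zero predictive count draws are
  continuity-corrected to 0.5 before the log transform.

DIC uses the posterior-mean linear predictor as its plug-in; WAIC's
effective-parameter term is the sum of per-cell log-likelihood variances
(nonnegative by construction); CPO uses the harmonic-mean estimator with
an instability flag when any cell's weights have coefficient of variation
above 10 — the estimator is simple and testable, and the flag marks where
an importance-sampling refinement would be needed.

## The synthetic-data generator

The generator emulates the statistical structure the model assumes: a
deterministic population pyramid with geometric growth
($n_{at} = \text{base} \times \text{shape}(a) \times (1+g)^{t-1}$),
additive log-rate effects, and Poisson sampling. Scenarios build up in
steps — `age_only` (a quadratic log-rate age curve rising steeply with
age, as for colorectal cancer), `drift` (adds a linear period trend,
default 0.02/year), `full_apc` (adds a smooth cohort wave, amplitude 0.15,
with the model's cohort constraints imposed on the truth so that recovery
is well-posed), `covariate` (adds a known log-linear exposure effect,
$\delta^* = 0.3$ on a smoothly declining series). Default desk scale is
$A = 18$ five-year groups (0–4 … 85 plus) over $T = 32$ years
(1990–2021), with the rate scale calibrated so expected total events are
of order $10^5$–$10^6$ — the scale of a major cancer site — and a small
$4 \times 8$ instance is used where an MCMC oracle must run long. The
heavy simulation studies (interval calibration, drift recovery) use 50
replicates at 400 posterior draws; back-test calibration uses
$10 \times 32$ grids, sizes chosen to make the studies routine to rerun.

What the generator does **not** emulate — and hence what passing tests do
not show about real extractions: estimation-pipeline artifacts (smoothed,
correlated estimates rather than raw counts; uncertainty already attached
to inputs), under-registration and its model-based correction, reporting
shocks such as pandemic-era ascertainment gaps, age-heaping, migration,
and any spatial or between-location correlation. Calibration statements
here are statements about the model class under its own assumptions.

## Known limitations

* The Gaussian hyperparameter integration is cruder than a full
  exploration of the marginal posterior; for very small grids or nearly
  unidentified precisions the $\eta$ posterior remains accurate (the MCMC
  cross-check), but hyperparameter marginals themselves should not be
  over-interpreted.
* Effects are reported under hard constraints; comparing effect curves
  across publications requires matching constraint conventions.
* Strata are fitted independently — no borrowing across sexes or
  locations — mirroring per-stratum reporting practice; a pooled both-sex
  stratum is fitted on pooled counts, which is not the average of the
  sex-specific forecasts.
* The harmonic-mean CPO estimator can be unstable for influential cells;
  the flag reports this but no importance-sampling refinement is
  implemented.
* Forecast uncertainty reflects the model's random-walk continuation
  only; structural breaks (new screening programmes, therapeutic shifts)
  are outside the model class, so long-horizon intervals are best read as
  trend-continuation uncertainty.
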