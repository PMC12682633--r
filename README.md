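# bapcburden

Descriptive and projective analysis of disease burden on age-by-period
(Lexis) grids, built for GBD-results-style extractions such as national or
global colorectal-cancer burden series. The package is aimed at
epidemiologists and biostatisticians who need to (i) summarize burden
levels and trends — age-standardized rates, annual percentage change,
risk-factor attribution — and (ii) project burden decades ahead with a
Bayesian age-period-cohort (BAPC) model whose calibration can be checked by
back-testing, all without depending on any proprietary estimation pipeline.
A synthetic-data generator with known ground truth makes every stage
testable end to end.

## The models

**Age-standardized rate.** For age-specific rates `a_i` and standard
population weights `w_i` over `A` age groups,

    ASR = ( Σ_{i=1..A} a_i w_i / Σ_{i=1..A} w_i ) × 100000.

The default weight table is the WHO World Standard aggregated to eighteen
5-year groups; any two-column `age_group, weight` file can be plugged in,
and the ASR is invariant to rescaling the weights.

**EAPC.** The estimated annual percentage change fits
`ln(ASR_t) = α + β t + ε_t` by ordinary least squares and reports
`100 (e^β − 1)` with the 95% CI `100 (e^{β ± 1.96 SE(β)} − 1)`.

**Attributable burden.** Pre-computed population attributable fractions are
applied multiplicatively, `attributable = PAF × total`, joined at the
finest common stratum.

**The BAPC model.** Counts on the Lexis grid follow
`y_{at} ~ Poisson(n_{at} e^{η_{at}})` with person-years `n_{at}` as
exposure and linear predictor

    η_at = μ + α_a + β_t + γ_c(a,t) + Σ_k δ_k x_k(t),      c(a,t) = M(A−a) + t,

where `α`, `β`, `γ` are age, period and cohort effects smoothed by
second-order random walks (order configurable per effect), `x_k(t)` are
optional centered exposure covariates with log-linear coefficients `δ_k`,
and each random-walk standard deviation σ carries a penalized-complexity
prior — exponential with rate `λ = −ln(α₀)/U` so that `P(σ > U) = α₀`
(default `U = 1`, `α₀ = 0.01`). Inference is a Laplace approximation for
latent Gaussian models: a Gaussian approximation to the latent field at its
conditional mode, with the smoothing hyperparameters integrated over a
Gaussian approximation to their Laplace-approximate marginal posterior.
Only `η` and its functionals are identifiable; effects are reported under
an explicit constraint set (sum-to-zero on all three effects plus a zero
linear cohort trend, so drift sits in the period effect), and the `η`
posterior is invariant to the choice of valid constraint set. Forecasts
continue the period and cohort walks with posterior-sampled innovation
standard deviations; uncertainty intervals are 2.5/50/97.5 percentiles over
1,000 posterior draws by default.

**Validation.** `backtest()` refits on a training window, forecasts the
held-out years and scores the posterior predictive distribution of the
observed rates: MAE, RMSE, mean ensemble CRPS
(`mean|X−y| − ½ mean|X−X′|`), and 95% interval coverage, plus DIC, WAIC and
conditional predictive ordinates of the training fit.

## Worked example

```r
library(bapcburden)

# 1. simulate a synthetic burden dataset with known truth (18 age groups,
#    1990-2021, colorectal-cancer-like rates)
pop   <- generate_population(A = 18, T = 32, base_size = 3e6)
truth <- generate_apc_truth(A = 18, T = 32, scenario = "full_apc", d = 0.02)
data  <- generate_dataset(truth, pop, seed = 42)
data$grid
#> <lexis_grid> 18 age groups x 32 years (1990-2021), M = 5, 117 cohorts
#>   total events 743964 over 2.02e+09 person-years

# 2. descriptive layer: age-standardized rates and EAPC
w      <- read_standard_population()          # WHO World Standard
series <- lexis_asr_series(data$grid, w)
tail(series, 3)
#>    year      asr
#> 30 2019 20.47539
#> 31 2020 21.03320
#> 32 2021 21.29959
compute_eapc(series)
#> EAPC 1.79% per year (95% CI: 1.75 to 1.83)

# 3. fit the Bayesian APC model and project 30 years
fit <- fit_apc(data$grid, apc_spec(sample_count = 1000, seed = 1))
fc  <- apc_forecast(fit, horizon = 30, weights = w)
tail(fc$summary, 3)
#>    year      asr    lower    upper
#> 28 2049 42.19965 36.45908 50.53905
#> 29 2050 43.02183 36.96187 51.79761
#> 30 2051 43.82865 37.43012 53.30046

# 4. back-test on the 1990-2010 / 2011-2021 split
backtest(data$grid, apc_spec(sample_count = 1000, seed = 1), split_year = 2010)
#> <validation_report> trained 1990-2010, tested 2011-2021 (log scale)
#>   MAE 0.0829  RMSE 0.1546  CRPS 0.0591  95% coverage 0.970 (198 cells)
#>   DIC 3194.9  WAIC 3195.5  sum log CPO -1598.1
```

The ASR series rises at about 1.8%/year because the simulated truth
carries a 2%/year period drift partly offset by the cohort wave; the
projection continues that drift with widening uncertainty, and the
back-test shows near-nominal 95% coverage on the held-out decade — the
model class matches the generator, so this is the calibration one should
see when the method is working.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
package's full workflow on the synthetic world, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R     # synthetic GBD-style extraction
Rscript analysis/02_descriptive.R  # ASR, EAPC, attribution, SDI quintiles
Rscript analysis/03_project.R      # 30-year BAPC projection
Rscript analysis/04_backtest.R     # 1990-2010 / 2011-2021 back-test
```

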