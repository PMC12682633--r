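test_that("cohort index maps Lexis diagonals deterministically", {
  expect_equal(as.numeric(build_cohort_index(1, 5, 3)), 1:5)
  co <- build_cohort_index(3, 3, 1)
  expect_equal(co[2, 2], 3)
  expect_equal(sort(unique(as.integer(co))), 1:5)  # exactly 5 cohorts
  expect_equal(co[3, 1], 1)                        # oldest age, first period
  expect_equal(co[1, 3], 5)                        # youngest age, last period
  co5 <- build_cohort_index(18, 32, 5)
  expect_equal(max(co5), 5 * 17 + 32)
  expect_error(build_cohort_index(0, 3, 1), ">= 1")
})

test_that("random-walk prior penalizes differences and spares its null space", {
  expect_equal(rw_log_prior(c(1, 2, 3, 4), 2, 3), (4 - 2) / 2 * log(3))
  expect_equal(rw_log_prior(rep(2.5, 6), 1, 7), (6 - 1) / 2 * log(7))
  u <- c(0, 1, 3)
  expect_equal(rw_log_prior(u, 2, 2),
               (3 - 2) / 2 * log(2) - 2 / 2 * oracle_rw_quadform(u, 2))
  expect_equal(oracle_rw_quadform(u, 2), 1)  # (Delta^2 u) = (1)
  set.seed(3)
  for (i in 1:20) {
    m <- sample(4:12, 1); k <- sample(1:2, 1); tau <- runif(1, 0.1, 5)
    v <- rnorm(m)
    expect_equal(rw_log_prior(v, k, tau),
                 (m - k) / 2 * log(tau) - tau / 2 * oracle_rw_quadform(v, k),
                 tolerance = 1e-12)
  }
  expect_error(rw_log_prior(1:4, 2, 0), "positive")
  expect_error(rw_log_prior(1:2, 2, 1), "at least")
})

test_that("PC prior is exponential in sigma with the defining tail property", {
  U <- 1; a <- 0.01
  lambda <- -log(a) / U
  expect_equal(pc_prior_logdensity(0, U, a), log(lambda))
  expect_equal(exp(pc_prior_logdensity(0, U, a)), 4.60517, tolerance = 1e-5)
  total <- stats::integrate(function(s) exp(pc_prior_logdensity(s, U, a)),
                            0, Inf, rel.tol = 1e-12)$value
  expect_equal(total, 1, tolerance = 1e-8)
  tail <- stats::integrate(function(s) exp(pc_prior_logdensity(s, U, a)),
                           U, Inf, rel.tol = 1e-12)$value
  expect_equal(tail, a, tolerance = 1e-8)
  expect_error(pc_prior_logdensity(1, -1, 0.5), "positive")
  expect_error(pc_prior_logdensity(1, 1, 1.5), "\\(0, 1\\)")
})

test_that("log_posterior matches a term-by-term summation oracle", {
  inst <- small_apc_instance(A = 3, Tn = 4, n_cell = 1e3, seed = 21)
  grid <- inst$grid
  spec <- apc_spec(seed = 1)
  state <- list(mu = -5.8, alpha = c(-0.3, 0.1, 0.2),
                beta = c(-0.02, 0, 0.01, 0.01),
                gamma = c(0.05, -0.02, 0, -0.03, 0.01, -0.01),
                sigma = c(age = 0.5, period = 0.2, cohort = 0.3))
  got <- log_posterior(state, grid, spec)
  # independent re-summation, term by term
  co <- build_cohort_index(3, 4, 1)
  ll <- 0
  for (a in 1:3) for (t in 1:4) {
    eta <- state$mu + state$alpha[a] + state$beta[t] + state$gamma[co[a, t]]
    ll <- ll + grid$y[a, t] * log(grid$n[a, t] * exp(eta)) -
      grid$n[a, t] * exp(eta)
  }
  pri <- 0
  for (comp in list(list(state$alpha, "age"), list(state$beta, "period"),
                    list(state$gamma, "cohort"))) {
    tau <- state$sigma[[comp[[2]]]]^-2
    d <- diff(comp[[1]], differences = 2)
    pri <- pri + (length(comp[[1]]) - 2) / 2 * log(tau) - tau / 2 * sum(d^2)
    lam <- -log(spec$pc_alpha) / spec$pc_u
    pri <- pri + log(lam) - lam * state$sigma[[comp[[2]]]]
  }
  pri <- pri + stats::dnorm(state$mu, 0, 100, log = TRUE)
  expect_equal(got, ll + pri, tolerance = 1e-12)
})

test_that("likelihood term is invariant to intercept/effect translation", {
  inst <- small_apc_instance(A = 4, Tn = 5, n_cell = 1e3, seed = 8)
  spec <- apc_spec(seed = 1, mu_sd = 1e8)  # near-flat intercept prior
  base <- list(mu = -6, alpha = c(-0.2, 0, 0.1, 0.1),
               beta = rep(0, 5), gamma = rep(0, 8),
               sigma = c(age = 1, period = 1, cohort = 1))
  shifted <- base
  k <- 0.37
  shifted$mu <- base$mu - k
  shifted$alpha <- base$alpha + k
  l1 <- log_posterior(base, inst$grid, spec)
  l2 <- log_posterior(shifted, inst$grid, spec)
  # priors on alpha (differences) and the near-flat mu prior are unchanged
  expect_equal(l1, l2, tolerance = 1e-7)
})

test_that("the RW2 cohort null space is absorbed by period and intercept", {
  # adding a linear-in-index function to the cohort effect and compensating
  # in the period effect and intercept leaves every eta unchanged
  A <- 5; Tn <- 6; M <- 1
  co <- build_cohort_index(A, Tn, M)
  set.seed(9)
  alpha <- rnorm(A); beta <- rnorm(Tn); gamma <- rnorm(max(co)); mu <- -3
  k <- 0.8
  eta1 <- outer(alpha, beta, "+") + mu + matrix(gamma[co], A, Tn)
  alpha2 <- alpha + k * seq_len(A)
  beta2 <- beta - (k / M) * seq_len(Tn)
  gamma2 <- gamma + (k / M) * seq_len(max(co))
  mu2 <- mu - k * A
  eta2 <- outer(alpha2, beta2, "+") + mu2 + matrix(gamma2[co], A, Tn)
  expect_equal(eta1, eta2, tolerance = 1e-12)
})

test_that("fit_apc is deterministic given the spec seed", {
  inst <- small_apc_instance()
  spec <- apc_spec(sample_count = 50, seed = 5, n_theta = 5)
  f1 <- fit_apc(inst$grid, spec)
  f2 <- fit_apc(inst$grid, spec)
  expect_identical(f1$eta, f2$eta)
  expect_identical(f1$samples$log_tau, f2$samples$log_tau)
  f3 <- fit_apc(inst$grid, apc_spec(sample_count = 50, seed = 6, n_theta = 5))
  expect_false(identical(f1$eta, f3$eta))
})

test_that("age effects are recovered when period and cohort are truly zero", {
  tr <- generate_apc_truth(A = 8, T = 10, scenario = "age_only", age_width = 5)
  # raise the intercept so every age cell is informative at n = 1e6:
  # alpha is untouched, only mu changes
  eta <- tr$eta - tr$mu - 7
  n <- matrix(1e6, 8, 10)
  y <- bapcburden:::with_seed(31,
    matrix(stats::rpois(80, n * exp(eta)), 8, 10))
  grid <- lexis_grid(y, n, default_age_groups(8), 1990:1999, age_width = 5)
  fit <- fit_apc(grid, apc_spec(sample_count = 300, seed = 14, n_theta = 10))
  alpha_hat <- colMeans(fit$samples$alpha)
  expect_lt(max(abs(alpha_hat - tr$alpha)), 0.05)
  beta_hat <- colMeans(fit$samples$beta)
  expect_lt(max(abs(beta_hat)), 0.05)
})

test_that("fitted totals track observed totals within posterior spread", {
  inst <- small_apc_instance(n_cell = 2e4, seed = 13)
  fit <- fit_apc(inst$grid, apc_spec(sample_count = 400, seed = 3))
  nv <- as.numeric(inst$grid$n)
  totals <- apply(fit$eta, 1, function(e) sum(nv * exp(as.numeric(e))))
  expect_lt(abs(mean(totals) - sum(inst$grid$y)), 3 * stats::sd(totals))
})

test_that("posterior contracts as exposure grows", {
  tr <- generate_apc_truth(A = 6, T = 12, scenario = "full_apc", age_width = 5)
  rmse <- sapply(c(1, 10, 100), function(scale) {
    n <- matrix(2e4 * scale, 6, 12)
    y <- bapcburden:::with_seed(77,
      matrix(stats::rpois(72, n * exp(tr$eta)), 6, 12))
    grid <- lexis_grid(y, n, default_age_groups(6), 1990:2001, age_width = 5)
    fit <- fit_apc(grid, apc_spec(sample_count = 200, seed = 4, n_theta = 8))
    sqrt(mean((eta_posterior_mean(fit) - tr$eta)^2))
  })
  expect_true(all(diff(rmse) < 0))
})

test_that("known covariate effects are recovered at the nominal rate", {
  tr <- generate_apc_truth(A = 6, T = 16, scenario = "covariate",
                           age_width = 5)
  pop <- generate_population(A = 6, T = 16, base_size = 2e6)
  cov_spec <- list(list(name = "exposure", x = tr$covariates[[1]]$x,
                        rule = "hold_last"))
  hits <- 0; R <- 15
  for (r in seq_len(R)) {
    ds <- generate_dataset(tr, pop, seed = 900 + r)
    fit <- fit_apc(ds$grid,
                   apc_spec(sample_count = 300, seed = 950 + r, n_theta = 10,
                            covariates = cov_spec))
    ci <- stats::quantile(fit$samples$delta[, 1], c(0.025, 0.975))
    if (ci[1] <= tr$covariates[[1]]$delta &&
        tr$covariates[[1]]$delta <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 11)  # binomial(15, 0.95) lower band
})

test_that("degenerate grids and specs are rejected", {
  inst <- small_apc_instance()
  expect_error(apc_spec(sample_count = 0), "sample_count")
  expect_error(apc_spec(pc_alpha = 2), "\\(0, 1\\)")
  expect_error(apc_spec(rw_order = c(age = 3, period = 2, cohort = 2)),
               "1 or 2")
  g <- inst$grid
  short <- lexis_grid(g$y[, 1:3], g$n[, 1:3], g$age_groups, g$years[1:3],
                      age_width = 1)
  expect_error(fit_apc(short, apc_spec(seed = 1)), "at least 4 periods")
})
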