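test_that("ensemble CRPS matches enumeration and its closed form", {
  expect_equal(crps_ensemble(rep(2.5, 10), 2.5), 0)
  expect_equal(crps_ensemble(c(0, 1), 1), 0.25)
  set.seed(12)
  for (i in 1:25) {
    x <- rnorm(sample(2:40, 1)); y <- rnorm(1)
    expect_equal(crps_ensemble(x, y), oracle_crps(x, y), tolerance = 1e-12)
    expect_gte(crps_ensemble(x, y), 0)
    sh <- runif(1, -5, 5)
    expect_equal(crps_ensemble(x + sh, y + sh), crps_ensemble(x, y),
                 tolerance = 1e-12)
  }
  # closed form for a standard normal forecast at y = 0:
  # sigma * (2 * dnorm(0) - 1/sqrt(pi)) = 0.23370...
  draws <- bapcburden:::with_seed(8, rnorm(1e5))
  expect_equal(crps_ensemble(draws, 0), 2 * stats::dnorm(0) - 1 / sqrt(pi),
               tolerance = 0.005)
  expect_error(crps_ensemble(3, 1), "at least 2")
})

test_that("interval coverage counts boundaries and respects monotonicity", {
  iv <- cbind(rep(0, 4), rep(1, 4))
  expect_equal(coverage(iv, c(0.2, 0.5, 0, 1)), 1)  # boundary covered
  iv10 <- cbind(1:10 - 0.5, 1:10 + 0.5)
  expect_equal(coverage(iv10, c(1:5, 1:5 + 10)), 0.5)
  set.seed(4)
  lo <- rnorm(50); hi <- lo + runif(50); y <- rnorm(50)
  expect_equal(coverage(cbind(lo, hi), y), mean(lo <= y & y <= hi))
  # monotone transform invariance
  tf <- function(v) exp(v)
  expect_equal(coverage(cbind(tf(lo), tf(hi)), tf(y)),
               coverage(cbind(lo, hi), y))
  # widening never decreases coverage
  expect_gte(coverage(cbind(lo - 1, hi + 1), y), coverage(cbind(lo, hi), y))
  expect_error(coverage(cbind(1, 0), 0.5), "lo <= hi")
})

test_that("information criteria match direct re-summation on a toy fit", {
  inst <- small_apc_instance(A = 3, Tn = 4, n_cell = 1e3, seed = 17)
  fit <- fit_apc(inst$grid, apc_spec(sample_count = 200, seed = 9, n_theta = 5))
  ic <- information_criteria(fit)
  yv <- as.numeric(inst$grid$y); nv <- as.numeric(inst$grid$n)
  S <- dim(fit$eta)[1]
  ll <- matrix(NA_real_, S, length(yv))
  for (s in seq_len(S)) {
    for (i in seq_along(yv)) {
      m <- nv[i] * exp(fit$eta[s, , ][i])
      ll[s, i] <- yv[i] * log(m) - m - lgamma(yv[i] + 1)
    }
  }
  eta_bar <- apply(fit$eta, c(2, 3), mean)
  m_bar <- nv * exp(as.numeric(eta_bar))
  ll_bar <- sum(yv * log(m_bar) - m_bar - lgamma(yv + 1))
  p_d <- 2 * (ll_bar - mean(rowSums(ll)))
  expect_equal(ic$dic, -2 * ll_bar + 2 * p_d, tolerance = 1e-10)
  lppd <- sum(log(colMeans(exp(ll))))
  p_w <- sum(apply(ll, 2, stats::var))
  expect_equal(ic$waic, -2 * (lppd - p_w), tolerance = 1e-8)
  expect_gte(ic$p_waic, 0)
  cpo <- sum(log(1 / colMeans(exp(-ll))))
  expect_equal(ic$cpo_log_sum, cpo, tolerance = 1e-8)
})

test_that("a point-mass posterior gives p_D = 0 and the analytic DIC", {
  # one Poisson cell, y = 2, mean 2, posterior concentrated at one theta:
  # DIC = -2 log p(y | theta) = 2 * (2 - 2*log(2) + log(2)) = 2 * 1.30685...
  inst <- small_apc_instance(A = 3, Tn = 4, n_cell = 1e3, seed = 17)
  fit <- fit_apc(inst$grid, apc_spec(sample_count = 5, seed = 9, n_theta = 5))
  one <- fit$eta[1, , ]
  for (s in seq_len(5)) fit$eta[s, , ] <- one  # collapse to a single draw
  ic <- information_criteria(fit)
  expect_equal(ic$p_d, 0, tolerance = 1e-10)
  ll <- sum(stats::dpois(as.numeric(inst$grid$y),
                         as.numeric(inst$grid$n) * exp(as.numeric(one)),
                         log = TRUE))
  expect_equal(ic$dic, -2 * ll, tolerance = 1e-10)
  expect_equal(-2 * stats::dpois(2, 2, log = TRUE), 2 * 1.306853,
               tolerance = 1e-6)
})

test_that("back-test scores match independent per-cell re-scoring", {
  tr <- generate_apc_truth(A = 6, T = 14, scenario = "full_apc")
  pop <- generate_population(A = 6, T = 14, base_size = 2e6)
  ds <- generate_dataset(tr, pop, seed = 33)
  spec <- apc_spec(sample_count = 200, seed = 41, n_theta = 8)
  rep <- backtest(ds$grid, spec, split_year = 1999)
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$train_years, c(1990, 1999))
  expect_equal(rep$test_years, c(2000, 2003))
  # independent re-scoring from the stored predictive draws
  err <- abs(rep$cells$median - rep$cells$observed)
  expect_equal(rep$mae, mean(err), tolerance = 1e-12)
  expect_equal(rep$rmse, sqrt(mean(err^2)), tolerance = 1e-12)
  crps_again <- vapply(seq_len(nrow(rep$cells)), function(i)
    oracle_crps(rep$predictive_draws[, i], rep$cells$observed[i]), numeric(1))
  expect_equal(rep$crps_mean, mean(crps_again), tolerance = 1e-12)
  expect_equal(rep$coverage95,
               mean(rep$cells$lower <= rep$cells$observed &
                      rep$cells$observed <= rep$cells$upper),
               tolerance = 1e-12)
  expect_gte(rep$rmse, abs(mean(rep$cells$median - rep$cells$observed)))
  expect_error(backtest(ds$grid, spec, split_year = 1991), "degenerate split")
})

test_that("observations equal to the predictive median score zero error", {
  tr <- generate_apc_truth(A = 5, T = 10, scenario = "drift")
  pop <- generate_population(A = 5, T = 10, base_size = 2e6)
  ds <- generate_dataset(tr, pop, seed = 27)
  spec <- apc_spec(sample_count = 200, seed = 51, n_theta = 8)
  first <- backtest(ds$grid, spec, split_year = 1996, scale = "rate")
  g2 <- ds$grid
  test_cols <- which(g2$years > 1996)
  med <- matrix(first$cells$median, nrow(g2$y), length(test_cols))
  g2$y[, test_cols] <- med * g2$n[, test_cols] / 1e5
  again <- backtest(g2, spec, split_year = 1996, scale = "rate")
  expect_equal(again$mae, 0, tolerance = 1e-10)
  expect_equal(again$rmse, 0, tolerance = 1e-10)
})

test_that("validation reports serialize as flat stratum/metric/value tables", {
  tr <- generate_apc_truth(A = 5, T = 10, scenario = "drift")
  pop <- generate_population(A = 5, T = 10, base_size = 1e6)
  ds <- generate_dataset(tr, pop, seed = 61)
  rep <- backtest(ds$grid, apc_spec(sample_count = 100, seed = 71, n_theta = 5),
                  split_year = 1996)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- validation_report_table(rep, path)
  expect_true(file.exists(path))
  expect_named(df, c("stratum", "metric", "value"))
  expect_equal(df$value[df$metric == "coverage95"], rep$coverage95)
})
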