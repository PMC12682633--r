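test_that("compute_asr matches the weighted-mean definition and its bounds", {
  expect_equal(compute_asr(rep(0, 5), rep(1, 5)), 0)
  expect_equal(compute_asr(rep(0.001, 7), c(5, 1, 9, 2, 2, 0.5, 3)), 100)
  expect_equal(compute_asr(c(1e-4, 1e-3, 1e-2), c(50, 30, 20)), 235.0)
  set.seed(42)
  for (i in 1:200) {
    A <- sample(3:21, 1)
    rates <- runif(A, 0, 0.05)
    weights <- runif(A, 0.01, 10)
    asr <- compute_asr(rates, weights)
    expect_equal(asr, oracle_asr(rates, weights), tolerance = 1e-12)
    expect_gte(asr, min(rates) * 1e5 - 1e-9)
    expect_lte(asr, max(rates) * 1e5 + 1e-9)
    expect_equal(asr, compute_asr(rates, weights * runif(1, 0.1, 50)))
  }
  expect_error(compute_asr(c(-1e-4, 1e-3), c(1, 1)), "negative")
  expect_error(compute_asr(c(1e-4, 1e-3), c(0, 0)), "positive sum")
  expect_error(
    compute_asr(stats::setNames(1:2 / 1e4, c("a", "b")),
                stats::setNames(1:2, c("a", "c"))),
    "different age groups")
})

test_that("EAPC is exact on geometric growth and matches the OLS oracle", {
  flat <- asr_series(2001:2010, rep(50, 10))
  e0 <- compute_eapc(flat)
  expect_equal(e0$eapc, 0)
  expect_equal(e0$beta, 0)

  geom <- asr_series(1990:2021, 100 * 1.02^(0:31))
  e <- compute_eapc(geom)
  expect_equal(e$eapc, 2, tolerance = 1e-10)
  expect_equal(e$se, 0, tolerance = 1e-10)  # zero residual variance

  noisy <- asr_series(1990:2021,
                      bapcburden:::with_seed(7, 80 * exp(0.01 * (0:31) +
                                                           rnorm(32, 0, 0.05))))
  en <- compute_eapc(noisy)
  or <- oracle_loglinear_slope(noisy$year, noisy$asr)
  expect_equal(en$beta, or$beta, tolerance = 1e-10)
  expect_equal(en$se, or$se, tolerance = 1e-10)
  expect_equal(en$ci_lower, 100 * (exp(or$beta - 1.96 * or$se) - 1),
               tolerance = 1e-10)

  shifted <- asr_series(0:31, noisy$asr)
  expect_equal(compute_eapc(shifted)$eapc, en$eapc, tolerance = 1e-10)

  expect_error(compute_eapc(asr_series(1:2, c(1, 2))), "at least 3")
  zero <- data.frame(year = 1:5, asr = c(1, 2, 0, 4, 5))
  expect_error(compute_eapc(zero), "positive")
})

test_that("attributable burden is paf * total, joined by name, monotone", {
  expect_equal(attributable_burden(1000, 0), 0)
  expect_equal(attributable_burden(1000, 1), 1000)
  expect_equal(attributable_burden(200, 0.25), 50)
  tot <- stats::setNames(c(10, 20), c("x", "y"))
  paf <- stats::setNames(c(0.5, 0.1, 0.9), c("y", "x", "z"))
  expect_equal(unname(attributable_burden(tot, paf)), c(1, 10))
  expect_error(attributable_burden(10, 1.2), "\\[0, 1\\]")
  expect_error(attributable_burden(-5, 0.5), "nonnegative")
  set.seed(1)
  p <- sort(runif(10)); v <- attributable_burden(rep(7, 10), p)
  expect_true(all(diff(v) >= 0))
})

test_that("SDI quintiles follow the rank-based sort-and-slice rule", {
  five <- stats::setNames(c(0.1, 0.3, 0.5, 0.7, 0.9), letters[1:5])
  q <- stratify_by_sdi(five)
  expect_equal(as.character(q),
               c("low", "medium-low", "medium", "medium-high", "high"))
  ten <- bapcburden:::with_seed(5, stats::setNames(runif(10), LETTERS[1:10]))
  expect_equal(as.character(stratify_by_sdi(ten)),
               unname(oracle_quintiles(ten)))
  # deterministic tie-break by label
  tied <- stats::setNames(rep(0.5, 5), c("e", "d", "c", "b", "a"))
  q2 <- stratify_by_sdi(tied)
  expect_equal(as.character(q2[order(names(tied))]),
               c("low", "medium-low", "medium", "medium-high", "high"))
  expect_error(stratify_by_sdi(stats::setNames(1.2, "x")), "\\[0, 1\\]")
})

test_that("crude rate agrees with population-weighted ASR", {
  expect_equal(crude_rate(0, 1e6), 0)
  expect_equal(crude_rate(50, 1e6), 5)
  expect_error(crude_rate(10, 0), "positive")
  # ASR with weights proportional to the population equals the crude rate
  pop <- generate_population(A = 6, T = 4, base_size = 1e5)
  tr <- generate_apc_truth(A = 6, T = 4, scenario = "age_only")
  ds <- generate_dataset(tr, pop, seed = 2)
  t1 <- 1
  rates <- ds$grid$y[, t1] / ds$grid$n[, t1]
  expect_equal(compute_asr(rates, ds$grid$n[, t1]),
               crude_rate(sum(ds$grid$y[, t1]), sum(ds$grid$n[, t1])),
               tolerance = 1e-10)
})
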