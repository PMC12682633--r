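#' Ensemble continuous ranked probability score
#'
#' The standard ensemble estimator of the CRPS for a forecast represented
#' by draws \eqn{X_1, \ldots, X_S} against an observation \eqn{y}:
#' \deqn{CRPS = \frac{1}{S}\sum_i |X_i - y| -
#'   \frac{1}{2S^2}\sum_i\sum_j |X_i - X_j|.}
#' Nonnegative, zero for a perfect deterministic forecast, and invariant
#' under joint translation of the draws and the observation.
#'
#' @param samples Numeric vector of at least 2 forecast draws.
#' @param y Observed value (scalar).
#' @return The CRPS (a single nonnegative number).
#' @export
crps_ensemble <- function(samples, y) {
  x <- as.numeric(samples)
  check_that(length(x) >= 2, "need at least 2 forecast draws, got %d", length(x))
  check_that(is.numeric(y) && length(y) == 1 && is.finite(y),
             "y must be a single finite number")
  S <- length(x)
  term1 <- mean(abs(x - y))
  # E|X - X'| via the sorted-sample identity (O(S log S), exact)
  xs <- sort(x)
  i <- seq_len(S)
  term2 <- 2 * sum((2 * i - S - 1) * xs) / S^2
  term1 - term2 / 2
}

#' Empirical interval coverage
#'
#' Fraction of cells whose observation lies inside its interval; boundary
#' values count as covered. Invariant under any strictly monotone transform
#' applied jointly to intervals and observations, and monotone in interval
#' width.
#'
#' @param intervals Two-column matrix (or data.frame) of `(lo, hi)` per
#'   cell, `lo <= hi`.
#' @param y Observed values, one per cell.
#' @return The covered fraction in `[0, 1]`.
#' @export
coverage <- function(intervals, y) {
  m <- as.matrix(intervals)
  check_that(ncol(m) == 2, "intervals must have two columns (lo, hi)")
  check_that(nrow(m) == length(y), "need one interval per observation")
  check_that(all(m[, 1] <= m[, 2]), "need lo <= hi for every interval")
  mean(m[, 1] <= y & y <= m[, 2])
}

#' DIC, WAIC and conditional predictive ordinates of an APC fit
#'
#' Model-criticism criteria computed from per-sample, per-cell Poisson (or
#' negative-binomial) log-likelihoods:
#' * DIC: \eqn{-2 \ln p(y \mid \bar\theta) + 2 p_D} with
#'   \eqn{p_D = 2[\ln p(y \mid \bar\theta) - E\{\ln p(y \mid \theta)\}]},
#'   where \eqn{\bar\theta} is the posterior mean linear predictor.
#' * WAIC: \eqn{-2[\sum_i \ln E\{p(y_i \mid \theta)\} -
#'   \sum_i Var\{\ln p(y_i \mid \theta)\}]}; the effective-parameter term
#'   is a sum of variances, hence nonnegative.
#' * CPO: per-cell leave-one-out predictive ordinate estimated by the
#'   harmonic mean of per-sample likelihoods, reported as
#'   \eqn{\sum_i \ln CPO_i}; `cpo_unstable` flags cells whose
#'   harmonic-mean weights have coefficient of variation above 10.
#'
#' @param fit An [fit_apc()] result.
#' @param grid The [lexis_grid()] the fit was computed on (defaults to
#'   `fit$grid`).
#' @return A list with `dic`, `p_d`, `waic`, `p_waic`, `cpo_log_sum`,
#'   `cpo_unstable` (logical flag) and `n_unstable`.
#' @export
information_criteria <- function(fit, grid = fit$grid) {
  stopifnot(inherits(fit, "apc_fit"))
  check_that(!is.null(fit$eta), "fit carries no per-sample linear predictor")
  S <- dim(fit$eta)[1]
  yv <- as.numeric(grid$y); nv <- as.numeric(grid$n)
  ncell <- length(yv)
  eta_mat <- matrix(fit$eta, S, ncell)      # samples x cells
  ll <- matrix(NA_real_, S, ncell)
  nb <- fit$spec$overdispersion
  for (s in seq_len(S)) {
    m <- nv * exp(eta_mat[s, ])
    ll[s, ] <- if (nb) {
      r <- exp(fit$samples$log_tau[s, "log_size"])
      stats::dnbinom(yv, size = r, mu = m, log = TRUE)
    } else {
      stats::dpois(yv, m, log = TRUE)
    }
  }
  eta_bar <- colMeans(eta_mat)
  ll_bar <- if (nb) {
    r_bar <- exp(mean(fit$samples$log_tau[, "log_size"]))
    sum(stats::dnbinom(yv, size = r_bar, mu = nv * exp(eta_bar), log = TRUE))
  } else {
    sum(stats::dpois(yv, nv * exp(eta_bar), log = TRUE))
  }
  mean_ll <- mean(rowSums(ll))
  p_d <- 2 * (ll_bar - mean_ll)
  dic <- -2 * ll_bar + 2 * p_d
  # WAIC with a stable log-mean-exp
  lme <- function(col) {
    mx <- max(col)
    mx + log(mean(exp(col - mx)))
  }
  lppd_i <- apply(ll, 2, lme)
  p_waic_i <- apply(ll, 2, stats::var)
  waic <- -2 * (sum(lppd_i) - sum(p_waic_i))
  # CPO_i = harmonic mean of likelihoods = 1 / mean(exp(-ll))
  log_cpo_i <- -apply(-ll, 2, lme)
  wts_cv <- apply(ll, 2, function(col) {
    w <- exp(-(col - max(col)) - log(sum(exp(-(col - max(col))))))
    stats::sd(w) / mean(w)
  })
  unstable <- wts_cv > 10
  list(dic = dic, p_d = p_d, waic = waic, p_waic = sum(p_waic_i),
       cpo_log_sum = sum(log_cpo_i),
       cpo_unstable = any(unstable), n_unstable = sum(unstable))
}

#' Back-test the APC model on a held-out window
#'
#' Fits the model on the training years (up to and including `split_year`),
#' forecasts the remaining years, and scores the predicted age-specific
#' rates against the held-out observed rates: MAE and RMSE of the posterior
#' median, mean ensemble CRPS, and 95% interval coverage. Because observed
#' rates carry sampling noise, forecasts are scored through their posterior
#' predictive distribution: for each posterior draw of the future rate a
#' count is drawn from the likelihood with the test-year person-years, so
#' intervals are calibrated against what is actually observed. Scoring is
#' on the log-rate scale by default (the scale on which the model is
#' linear); cells with zero observed counts cannot be scored on that scale
#' and are dropped with their number recorded (zero predictive draws are
#' continuity-corrected to 0.5 counts). Deterministic given the spec seed.
#'
#' @param grid A [lexis_grid()] covering train and test years.
#' @param spec An [apc_spec()].
#' @param split_year Last training year; must leave at least 4 training
#'   periods and 1 test period.
#' @param scale `"log"` (default) or `"rate"` (per 100,000).
#' @return An object of class `validation_report`: per-cell scores
#'   aggregated into `mae`, `rmse`, `crps_mean`, `coverage95`, model
#'   criticism (`dic`, `waic`, `cpo_log_sum`) from the training fit, the
#'   split definition, `n_scored` and `n_dropped`.
#' @export
backtest <- function(grid, spec, split_year, scale = c("log", "rate")) {
  stopifnot(inherits(grid, "lexis_grid"))
  scale <- match.arg(scale)
  years <- grid$years
  train <- which(years <= split_year)
  test <- which(years > split_year)
  check_that(length(train) >= 4 && length(test) >= 1,
             "degenerate split: %d training and %d test periods (need >= 4 and >= 1)",
             length(train), length(test))
  tg <- lexis_grid(grid$y[, train, drop = FALSE], grid$n[, train, drop = FALSE],
                   grid$age_groups, years[train], grid$age_width)
  fit <- fit_apc(tg, spec)
  A <- nrow(grid$y)
  H <- length(test)
  fc <- apc_forecast(fit, H, seed = spec$seed + 1L,
                     weights = stats::setNames(rep(1, A), grid$age_groups))
  ic <- information_criteria(fit)
  n_test <- grid$n[, test, drop = FALSE]
  obs_rate <- grid$y[, test, drop = FALSE] / n_test
  S <- dim(fc$rate_samples)[1]
  pred_mat <- matrix(fc$rate_samples, S, A * H)   # latent rates per draw
  nv_test <- as.numeric(n_test)
  # posterior predictive rates: one count draw per posterior rate draw
  ystar <- with_seed(spec$seed + 2L, {
    matrix(stats::rpois(S * A * H,
                        pred_mat * matrix(nv_test, S, A * H, byrow = TRUE)),
           S, A * H)
  })
  pred_rate <- ystar / matrix(nv_test, S, A * H, byrow = TRUE)
  if (scale == "log") {
    keep <- which(obs_rate > 0)
    obs <- log(obs_rate)[keep]
    cc <- 0.5 / matrix(nv_test, S, A * H, byrow = TRUE)
    trans <- function(v, cell) log(pmax(v, cc[, cell]))
  } else {
    keep <- seq_along(obs_rate)
    obs <- 1e5 * as.numeric(obs_rate)[keep]
    trans <- function(v, cell) 1e5 * v
  }
  n_cells <- length(keep)
  check_that(n_cells > 0, "no scorable cells on the %s scale", scale)
  med <- lo <- hi <- crps_i <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    cell <- keep[i]
    draws <- trans(pred_rate[, cell], cell)
    qs <- stats::quantile(draws, c(0.025, 0.5, 0.975), names = FALSE)
    lo[i] <- qs[1]; med[i] <- qs[2]; hi[i] <- qs[3]
    crps_i[i] <- crps_ensemble(draws, obs[i])
  }
  err <- med - obs
  rep <- list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
              crps_mean = mean(crps_i),
              coverage95 = coverage(cbind(lo, hi), obs),
              dic = ic$dic, waic = ic$waic, cpo_log_sum = ic$cpo_log_sum,
              train_years = range(years[train]), test_years = range(years[test]),
              scale = scale, n_scored = n_cells,
              n_dropped = length(obs_rate) - n_cells,
              cells = data.frame(cell = keep, observed = obs, median = med,
                                 lower = lo, upper = hi, crps = crps_i),
              predictive_draws = vapply(seq_len(n_cells), function(i)
                trans(pred_rate[, keep[i]], keep[i]), numeric(S)),
              fit = fit, forecast = fc)
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> trained %d-%d, tested %d-%d (%s scale)\n",
              x$train_years[1], x$train_years[2], x$test_years[1],
              x$test_years[2], x$scale))
  cat(sprintf("  MAE %.4f  RMSE %.4f  CRPS %.4f  95%% coverage %.3f (%d cells)\n",
              x$mae, x$rmse, x$crps_mean, x$coverage95, x$n_scored))
  cat(sprintf("  DIC %.1f  WAIC %.1f  sum log CPO %.1f\n",
              x$dic, x$waic, x$cpo_log_sum))
  invisible(x)
}

#' Serialize a validation report as a flat table
#'
#' @param report A [backtest()] result.
#' @param path Optional CSV path; when given the table is written there.
#' @return A data.frame with columns `stratum`, `metric`, `value`.
#' @export
validation_report_table <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  metrics <- c("mae", "rmse", "crps_mean", "coverage95", "dic", "waic",
               "cpo_log_sum", "n_scored", "n_dropped")
  df <- data.frame(
    stratum = sprintf("train_%d_%d_test_%d_%d", report$train_years[1],
                      report$train_years[2], report$test_years[1],
                      report$test_years[2]),
    metric = metrics,
    value = vapply(metrics, function(m) as.numeric(report[[m]]), numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
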