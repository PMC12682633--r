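#' Extend a covariate series over a forecast horizon
#'
#' Covariate series enter the linear predictor centered to mean zero over
#' the observed years; future values are generated by a scenario rule and
#' centered with the same observed-year mean (so a constant series
#' contributes nothing, observed or projected).
#'
#' @param x Numeric covariate series covering all observed years.
#' @param rule `"hold_last"` (default: every future value equals the last
#'   observed value) or `"linear"` (continue the least-squares linear trend
#'   of the observed series), or a numeric vector of explicit future values
#'   of length at least `H`.
#' @param H Forecast horizon (number of future years, >= 0).
#' @return A list with `observed` (centered observed series), `future`
#'   (centered future series of length `H`) and `center` (the observed
#'   mean that was subtracted).
#' @export
covariate_design <- function(x, rule = "hold_last", H) {
  x <- as.numeric(x)
  check_that(length(x) >= 2, "covariate series needs at least 2 observations")
  check_that(is.numeric(H) && length(H) == 1 && H >= 0, "H must be >= 0")
  ctr <- mean(x)
  if (is.numeric(rule)) {
    check_that(length(rule) >= H,
               "explicit scenario series has length %d, need at least %d",
               length(rule), H)
    fut <- rule[seq_len(H)]
  } else if (identical(rule, "hold_last")) {
    fut <- rep(x[length(x)], H)
  } else if (identical(rule, "linear")) {
    t_obs <- seq_along(x)
    fit <- stats::lm.fit(cbind(1, t_obs), x)
    co <- fit$coefficients
    fut <- co[1] + co[2] * (length(x) + seq_len(H))
  } else {
    stop(sprintf("unknown covariate scenario rule: '%s'", as.character(rule)),
         call. = FALSE)
  }
  list(observed = x - ctr, future = fut - ctr, center = ctr)
}

# Continue one random-walk path H steps with per-sample innovation sd.
.rw_extend <- function(path, order, H, sd) {
  m <- length(path)
  out <- c(path, numeric(H))
  for (h in seq_len(H)) {
    i <- m + h
    drift <- if (order == 2) 2 * out[i - 1] - out[i - 2] else out[i - 1]
    out[i] <- drift + stats::rnorm(1, 0, sd)
  }
  out[m + seq_len(H)]
}

#' Project the fitted APC model over a future horizon
#'
#' For each posterior sample, the period and cohort effects are continued
#' beyond the observed window by their own random walks (same order as the
#' smoothing prior, innovation standard deviation taken from that sample's
#' precision), age effects are held fixed, and covariates follow the
#' scenario rule. Future age-specific rates are `exp(eta)` and are
#' standardized to an ASR per year with [compute_asr()]. Summaries are the
#' 2.5th, 50th and 97.5th percentiles over samples (linear-interpolation
#' quantiles), matching 1,000-draw Monte Carlo uncertainty intervals at the
#' default sample count.
#'
#' @param fit An [fit_apc()] result.
#' @param horizon Number of future years `H >= 0`. `H = 0` returns the last
#'   fitted year's summaries unchanged.
#' @param weights Standard-population weights for the ASR (defaults to the
#'   builtin WHO World Standard; see [read_standard_population()]).
#' @param scenario Covariate scenario: `NULL` (use each covariate's own
#'   rule), a single rule name applied to all covariates, or a named list
#'   of rules / explicit future series per covariate.
#' @param seed Seed for the extrapolation innovations (default
#'   `fit$spec$seed + 1`).
#' @return An object of class `apc_forecast`: `years`, `summary` (a
#'   data.frame with `year`, `asr`, `lower`, `upper`), the per-sample ASR
#'   matrix `asr_samples` (samples x years) and the per-sample age-specific
#'   rate array `rate_samples` (samples x age x years).
#' @export
apc_forecast <- function(fit, horizon, weights = read_standard_population(),
                         scenario = NULL, seed = NULL) {
  stopifnot(inherits(fit, "apc_fit"))
  check_that(is.numeric(horizon) && length(horizon) == 1 && horizon >= 0,
             "horizon must be >= 0")
  H <- as.integer(horizon)
  grid <- fit$grid
  A <- nrow(grid$y); Tn <- ncol(grid$y); S <- dim(fit$eta)[1]
  M <- grid$age_width
  w <- as.numeric(weights)
  if (!is.null(names(weights))) {
    check_that(setequal(names(weights), grid$age_groups),
               "weights and grid cover different age groups")
    w <- as.numeric(weights)[match(grid$age_groups, names(weights))]
  }
  if (H == 0) {
    rates_last <- exp(fit$eta[, , Tn])
    asr_last <- apply(rates_last, 1, compute_asr, weights = w)
    qs <- stats::quantile(asr_last, c(0.025, 0.5, 0.975), names = FALSE)
    out <- list(years = max(grid$years),
                summary = data.frame(year = max(grid$years), asr = qs[2],
                                     lower = qs[1], upper = qs[3]),
                asr_samples = matrix(asr_last, S, 1),
                rate_samples = array(rates_last, dim = c(S, A, 1)))
    class(out) <- "apc_forecast"
    return(out)
  }
  spec <- fit$spec
  K <- length(spec$covariates)
  Xf <- matrix(0, H, max(K, 1))
  if (K > 0) {
    for (k in seq_len(K)) {
      cv <- spec$covariates[[k]]
      rule <- cv$rule %||% "hold_last"
      if (!is.null(scenario)) {
        if (is.list(scenario)) {
          rule <- scenario[[cv$name]] %||% rule
        } else {
          rule <- scenario
        }
      }
      Xf[, k] <- covariate_design(cv$x, rule, H)$future
    }
  }
  ob <- spec$rw_order["period"]; oc <- spec$rw_order["cohort"]
  sd_b <- exp(-fit$samples$log_tau[, "period"] / 2)
  sd_c <- exp(-fit$samples$log_tau[, "cohort"] / 2)
  future_years <- max(grid$years) + seq_len(H)
  # cohort index of future cell (a, T+h): M*(A-a) + T + h, up to M*(A-1)+T+H
  rate_samples <- array(NA_real_, dim = c(S, A, H))
  asr_samples <- matrix(NA_real_, S, H)
  a_seq <- seq_len(A)
  with_seed(seed %||% (fit$spec$seed + 1L), {
    for (s in seq_len(S)) {
      beta_f <- .rw_extend(fit$samples$beta[s, ], ob, H, sd_b[s])
      gamma_f <- .rw_extend(fit$samples$gamma[s, ], oc, H, sd_c[s])
      gamma_all <- c(fit$samples$gamma[s, ], gamma_f)
      for (h in seq_len(H)) {
        co <- M * (A - a_seq) + Tn + h
        eta_h <- fit$samples$mu[s] + fit$samples$alpha[s, ] + beta_f[h] +
          gamma_all[co]
        if (K > 0) eta_h <- eta_h +
            as.numeric(fit$samples$delta[s, , drop = FALSE] %*% Xf[h, seq_len(K)])
        rate_samples[s, , h] <- exp(eta_h)
        asr_samples[s, h] <- sum(rate_samples[s, , h] * w) / sum(w) * 1e5
      }
    }
  })
  qs <- apply(asr_samples, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  out <- list(years = future_years,
              summary = data.frame(year = future_years, asr = qs[2, ],
                                   lower = qs[1, ], upper = qs[3, ]),
              asr_samples = asr_samples,
              rate_samples = rate_samples)
  class(out) <- "apc_forecast"
  out
}

#' @export
print.apc_forecast <- function(x, ...) {
  n <- length(x$years)
  cat(sprintf("<apc_forecast> %d year(s), %d samples\n", n, nrow(x$asr_samples)))
  print(utils::head(x$summary, 5), row.names = FALSE)
  if (n > 5) cat(sprintf("  ... %d more year(s); final-year ASR %.2f (%.2f-%.2f)\n",
                         n - 5, x$summary$asr[n], x$summary$lower[n],
                         x$summary$upper[n]))
  invisible(x)
}
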