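#' Default age-group labels
#'
#' @param A Number of 5-year groups (default 18: `0 to 4` ... `85 plus`).
#' @param width Group width in years (default 5).
#' @return Character vector of labels.
#' @export
default_age_groups <- function(A = 18, width = 5) {
  lo <- (seq_len(A) - 1) * width
  c(sprintf("%d to %d", lo[-A], lo[-A] + width - 1),
    sprintf("%d plus", lo[A]))
}

#' Generate a deterministic population (person-years) grid
#'
#' Person-years follow `n[a, t] = base_size * shape(a) * (1 + growth_rate)^(t-1)`
#' with `t = 1` the first year: a fixed age pyramid scaled by geometric
#' growth. Deterministic (the seed argument is accepted for interface
#' uniformity but no randomness is used).
#'
#' @param A,T Numbers of age groups and years.
#' @param base_size Person-years scale per age group in the first year
#'   (> 0). The default, combined with the default rate scale of
#'   [generate_apc_truth()], gives expected total counts of order
#'   1e5-1e6 over an 18 x 32 grid.
#' @param growth_rate Annual growth rate (default 0.01).
#' @param pyramid_shape `"pyramid"` (default: geometrically thinning with
#'   age, mean 1), `"uniform"`, or a numeric vector of `A` positive
#'   relative sizes.
#' @param years First calendar year (default 1990) or full year vector.
#' @param seed Unused; present for interface uniformity.
#' @return A [population_grid()].
#' @export
generate_population <- function(A = 18, T = 32, base_size = 6e6,
                                growth_rate = 0.01,
                                pyramid_shape = "pyramid",
                                years = 1990, seed = NULL) {
  check_that(base_size > 0, "base_size must be positive")
  if (is.numeric(pyramid_shape)) {
    check_that(length(pyramid_shape) == A && all(pyramid_shape > 0),
               "numeric pyramid_shape needs %d positive values", A)
    shape <- pyramid_shape
  } else if (identical(pyramid_shape, "uniform")) {
    shape <- rep(1, A)
  } else if (identical(pyramid_shape, "pyramid")) {
    shape <- 0.97^((seq_len(A) - 1) * 5 / 5 * 1.5)
    shape <- shape / mean(shape)
  } else {
    stop(sprintf("unknown pyramid_shape: '%s'", pyramid_shape), call. = FALSE)
  }
  yrs <- if (length(years) == 1) years + seq_len(T) - 1 else years
  check_that(length(yrs) == T, "years must give %d calendar years", T)
  n <- outer(shape, (1 + growth_rate)^(seq_len(T) - 1)) * base_size
  population_grid(n, default_age_groups(A), yrs)
}

#' Generate ground-truth APC effect curves
#'
#' Builds a known truth for the synthetic Lexis grid: a quadratic log-rate
#' age curve (rising steeply with age, as for colorectal-cancer incidence),
#' optionally a linear period drift, a smooth cohort wave, and a log-linear
#' covariate effect. The curves satisfy the same identifiability
#' constraints the model imposes (sum-to-zero age/period/cohort, zero
#' linear trend on the cohort curve; drift carried by the period curve).
#'
#' @param A,T Grid dimensions.
#' @param scenario One of `"age_only"` (zero period and cohort effects),
#'   `"drift"` (adds a linear period trend of `d` per year), `"full_apc"`
#'   (adds a smooth cohort wave), `"covariate"` (full_apc plus a known
#'   covariate effect `delta_star * x(t)` with a declining exposure
#'   series).
#' @param d Period drift per year on the log scale (default 0.02).
#' @param cohort_amplitude Amplitude of the cohort wave (default 0.15).
#' @param delta_star True covariate coefficient (default 0.3, covariate
#'   scenario only).
#' @param age_width Age width `M` in period units (default 5).
#' @param seed Seed (the default curves are deterministic; the seed is
#'   recorded so the truth object fully describes a generated dataset).
#' @return An object of class `synthetic_truth` with elements `mu`,
#'   `alpha` (length `A`), `beta` (length `T`), `gamma` (cohort curve),
#'   `drift`, `covariates` (list with `x`, `delta`), `eta` (the `A x T`
#'   true log-rate matrix), `scenario`, `age_width` and `seed`.
#' @export
generate_apc_truth <- function(A = 18, T = 32,
                               scenario = c("age_only", "drift", "full_apc",
                                            "covariate"),
                               d = 0.02, cohort_amplitude = 0.15,
                               delta_star = 0.3, age_width = 5, seed = 1L) {
  scenario <- match.arg(scenario)
  a <- seq_len(A)
  raw_age <- -14.2 + 0.62 * a * (18 / A) - 0.009 * (a * (18 / A))^2
  mu <- mean(raw_age)
  alpha <- raw_age - mu
  t_idx <- seq_len(T)
  beta <- rep(0, T)
  if (scenario != "age_only") beta <- d * (t_idx - mean(t_idx))
  C <- age_width * (A - 1) + T
  gamma <- rep(0, C)
  if (scenario %in% c("full_apc", "covariate")) {
    cc <- seq_len(C)
    wave <- cohort_amplitude * sin(2 * pi * cc / (C / 2))
    # impose the model's cohort constraints: sum-to-zero, zero linear trend
    X <- cbind(1, cc - mean(cc))
    wave <- wave - X %*% qr.solve(X, wave)
    gamma <- as.numeric(wave)
  }
  covariates <- list()
  if (scenario == "covariate") {
    x <- 1 - 0.012 * (t_idx - 1)      # smoothly declining exposure level
    covariates <- list(list(name = "exposure", x = x, rule = "hold_last",
                            delta = delta_star))
  }
  cohort <- build_cohort_index(A, T, age_width)
  eta <- outer(alpha, beta, "+") + mu + matrix(gamma[cohort], A, T)
  for (cv in covariates) {
    eta <- eta + cv$delta * matrix(cv$x - mean(cv$x), A, T, byrow = TRUE)
  }
  structure(list(mu = mu, alpha = alpha, beta = beta, gamma = gamma,
                 drift = if (scenario == "age_only") 0 else d,
                 covariates = covariates, eta = eta,
                 scenario = scenario, age_width = as.integer(age_width),
                 A = A, T = T, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Draw a synthetic Lexis dataset from a ground truth
#'
#' Samples counts `y[a, t] ~ Poisson(n[a, t] * exp(eta[a, t]))` with the
#' stated seed and returns both the in-memory [lexis_grid()] and (when
#' `path` is given) a GBD-dialect file containing mutually consistent
#' `metric = "number"` and `metric = "rate"` rows
#' (`rate = 1e5 * number / n` exactly), plus a JSON truth sidecar.
#' Byte-identical outputs for identical (truth, population, seed).
#'
#' @param truth A [generate_apc_truth()] object.
#' @param population A [population_grid()] with matching dimensions.
#' @param seed Integer seed for the Poisson draws (default `truth$seed`).
#' @param path Optional CSV output path; the truth sidecar is written next
#'   to it as `<path>.truth.json`.
#' @param measure,location,sex,cause Labels for the emitted records.
#' @return A list with `grid` (the [lexis_grid()]), `table` (the
#'   [burden_table()]) and `path` (or `NULL`).
#' @export
generate_dataset <- function(truth, population, seed = truth$seed,
                             path = NULL, measure = "incidence",
                             location = "Synthetica", sex = "both",
                             cause = "Colorectal cancer") {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(population, "population_grid"))
  n <- population$n
  check_that(all(dim(n) == dim(truth$eta)),
             "population (%d x %d) and truth (%d x %d) dimensions disagree",
             nrow(n), ncol(n), nrow(truth$eta), ncol(truth$eta))
  mean_counts <- n * exp(truth$eta)
  check_that(all(mean_counts <= 1e12),
             "overflow-scale expected counts (max %.3g > 1e12)", max(mean_counts))
  y <- with_seed(seed, matrix(stats::rpois(length(mean_counts), mean_counts),
                              nrow(n), ncol(n)))
  grid <- lexis_grid(y, n, population$age_groups, population$years,
                     truth$age_width)
  A <- nrow(y); Tn <- ncol(y)
  base <- data.frame(
    measure = measure, location = location, sex = sex,
    age = rep(population$age_groups, times = Tn),
    cause = cause, rei = NA_character_,
    year = rep(population$years, each = A),
    stringsAsFactors = FALSE)
  num <- base; num$metric <- "number"; num$val <- as.numeric(y)
  rat <- base; rat$metric <- "rate"; rat$val <- 1e5 * as.numeric(y) / as.numeric(n)
  tab <- rbind(num, rat)
  tab$lower <- tab$val; tab$upper <- tab$val
  tab <- tab[, gbd_columns]
  tab <- burden_table(tab)
  if (!is.null(path)) {
    write_burden_table(tab, path)
    sidecar <- paste0(path, ".truth.json")
    jsonlite::write_json(
      list(mu = truth$mu, alpha = truth$alpha, beta = truth$beta,
           gamma = truth$gamma, drift = truth$drift,
           scenario = truth$scenario, age_width = truth$age_width,
           seed = seed,
           covariates = lapply(truth$covariates, function(cv)
             list(name = cv$name, x = cv$x, delta = cv$delta))),
      sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(grid = grid, table = tab, path = path)
}
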