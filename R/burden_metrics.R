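#' Age-standardized rate (ASR)
#'
#' Computes the age-standardized rate per 100,000 person-years,
#' \deqn{ASR = \frac{\sum_{i=1}^{A} a_i w_i}{\sum_{i=1}^{A} w_i} \times 100000,}
#' where \eqn{a_i} is the age-specific rate (per person-year) of the
#' \eqn{i}th age group and \eqn{w_i} the standard-population weight. The
#' result is invariant to positive rescaling of the weights and bounded by
#' the smallest and largest age-specific rate (times 100,000).
#'
#' @param rates Numeric vector of age-specific rates per person-year. If
#'   named and `weights` is named, the two are aligned by age-group label
#'   and must cover identical groups.
#' @param weights A [read_standard_population()] vector, or any nonnegative
#'   numeric vector with `sum(weights) > 0`.
#' @return The ASR per 100,000 (a single number).
#' @export
compute_asr <- function(rates, weights) {
  w <- as.numeric(weights)
  a <- as.numeric(rates)
  if (!is.null(names(rates)) && !is.null(names(weights))) {
    check_that(setequal(names(rates), names(weights)),
               "rates and weights cover different age groups")
    w <- as.numeric(weights)[match(names(rates), names(weights))]
  }
  check_that(length(a) == length(w),
             "rates (%d) and weights (%d) differ in length", length(a), length(w))
  check_that(all(is.finite(a)) && all(a >= 0), "negative or non-finite rate")
  check_that(all(is.finite(w)) && all(w >= 0) && sum(w) > 0,
             "weights must be nonnegative with positive sum")
  sum(a * w) / sum(w) * 1e5
}

#' ASR time series container
#'
#' @param years Integer vector of calendar years.
#' @param asr Numeric vector of ASRs per 100,000 (nonnegative).
#' @param lower,upper Optional uncertainty bounds with
#'   `lower <= asr <= upper`.
#' @return A data.frame with class `asr_series`.
#' @export
asr_series <- function(years, asr, lower = NULL, upper = NULL) {
  check_that(length(years) == length(asr), "years and asr differ in length")
  check_that(all(is.finite(asr)) && all(asr >= 0), "asr must be nonnegative")
  df <- data.frame(year = as.integer(years), asr = as.numeric(asr))
  if (!is.null(lower) || !is.null(upper)) {
    check_that(!is.null(lower) && !is.null(upper), "supply both lower and upper")
    check_that(all(lower <= asr + 1e-12) && all(asr <= upper + 1e-12),
               "need lower <= asr <= upper")
    df$lower <- as.numeric(lower); df$upper <- as.numeric(upper)
  }
  class(df) <- c("asr_series", "data.frame")
  df
}

#' Estimated annual percentage change (EAPC)
#'
#' Fits the standard log-linear trend model
#' \eqn{\ln(ASR_t) = \alpha + \beta t + \epsilon_t} by ordinary least
#' squares and reports \eqn{EAPC = 100(e^{\beta} - 1)} with the 95% CI
#' \eqn{100(e^{\beta \pm 1.96\,SE(\beta)} - 1)}. Time-shift equivariant:
#' relabelling the years changes nothing.
#'
#' @param series An [asr_series()] (or data.frame with `year`, `asr`) of at
#'   least 3 years with strictly positive ASRs.
#' @return A list of class `eapc_result`: `eapc`, `ci_lower`, `ci_upper`
#'   (percent per year), `beta` (log-scale slope), `se` (its standard
#'   error).
#' @export
compute_eapc <- function(series) {
  df <- as.data.frame(series)
  check_that(all(c("year", "asr") %in% names(df)), "series needs year and asr")
  check_that(nrow(df) >= 3, "need at least 3 years, got %d", nrow(df))
  check_that(all(df$asr > 0), "all ASR values must be strictly positive")
  fit <- stats::lm(log(asr) ~ year, data = df)
  beta <- unname(stats::coef(fit)["year"])
  # exact series (zero residual) are legitimate inputs; silence the
  # "essentially perfect fit" advisory
  se <- unname(sqrt(suppressWarnings(stats::vcov(fit))["year", "year"]))
  res <- list(eapc = 100 * (exp(beta) - 1),
              ci_lower = 100 * (exp(beta - 1.96 * se) - 1),
              ci_upper = 100 * (exp(beta + 1.96 * se) - 1),
              beta = beta, se = se)
  class(res) <- "eapc_result"
  res
}

#' @export
print.eapc_result <- function(x, ...) {
  cat(sprintf("EAPC %.2f%% per year (95%% CI: %.2f to %.2f)\n",
              x$eapc, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Risk-attributable burden from a population attributable fraction
#'
#' Applies pre-computed PAFs to total burden: `attributable = paf * total`.
#' Vectorized; when both arguments are named they are joined by name.
#' Monotone nondecreasing in both arguments.
#'
#' @param total Nonnegative burden value(s) (counts, rates, or DALYs).
#' @param paf Population attributable fraction(s) in `[0, 1]`.
#' @return `paf * total`, with names from `total`.
#' @export
attributable_burden <- function(total, paf) {
  check_that(all(is.finite(paf)) && all(paf >= 0) && all(paf <= 1),
             "paf must lie in [0, 1]")
  check_that(all(is.finite(total)) && all(total >= 0), "total must be nonnegative")
  if (!is.null(names(total)) && !is.null(names(paf))) {
    check_that(all(names(total) %in% names(paf)),
               "paf missing for stratum: %s",
               paste(setdiff(names(total), names(paf)), collapse = ", "))
    paf <- paf[names(total)]
  }
  total * paf
}

#' Stratify locations into socio-demographic index (SDI) quintiles
#'
#' Assigns each location to one of five quintiles (low, medium-low, medium,
#' medium-high, high). By default the assignment is by rank with equal-mass
#' cutpoints; ties are broken by location label order so the result is
#' deterministic. Alternatively, explicit SDI cutpoints can be supplied.
#'
#' @param sdi Named numeric vector: location -> SDI value in `[0, 1]`.
#' @param cutpoints Optional increasing numeric vector of 4 interior SDI
#'   cutpoints; when given, assignment is by value rather than rank.
#' @return Named factor of quintile labels, one per location, in the input
#'   order.
#' @export
stratify_by_sdi <- function(sdi, cutpoints = NULL) {
  check_that(!is.null(names(sdi)) && all(nzchar(names(sdi))),
             "sdi must be a named vector (location -> value)")
  check_that(all(is.finite(sdi)) && all(sdi >= 0) && all(sdi <= 1),
             "sdi values must lie in [0, 1]")
  labels <- c("low", "medium-low", "medium", "medium-high", "high")
  if (is.null(cutpoints)) {
    n <- length(sdi)
    ord <- order(sdi, names(sdi))          # ties broken by label order
    rank <- integer(n); rank[ord] <- seq_len(n)
    q <- floor((rank - 1) * 5 / n) + 1
  } else {
    check_that(length(cutpoints) == 4 && all(diff(cutpoints) > 0),
               "cutpoints must be 4 increasing values")
    q <- findInterval(sdi, cutpoints) + 1
  }
  out <- factor(labels[q], levels = labels)
  names(out) <- names(sdi)
  out
}

#' Crude rate per 100,000 person-years
#'
#' @param counts Total event count (nonnegative).
#' @param person_years Total person-years (strictly positive).
#' @return `100000 * counts / person_years`.
#' @export
crude_rate <- function(counts, person_years) {
  check_that(all(is.finite(person_years)) && all(person_years > 0),
             "person_years must be positive")
  check_that(all(is.finite(counts)) && all(counts >= 0),
             "counts must be nonnegative")
  1e5 * counts / person_years
}

#' Age-specific rates of a Lexis grid
#'
#' @param grid A [lexis_grid()].
#' @return Matrix of rates per person-year, `y / n`, named like the grid.
#' @export
age_specific_rates <- function(grid) {
  stopifnot(inherits(grid, "lexis_grid"))
  grid$y / grid$n
}

#' ASR series of a Lexis grid
#'
#' Applies [compute_asr()] to each year's column of age-specific rates.
#'
#' @param grid A [lexis_grid()].
#' @param weights Standard-population weights aligned with the grid's age
#'   groups (see [read_standard_population()]).
#' @return An [asr_series()] over the grid's years.
#' @export
lexis_asr_series <- function(grid, weights) {
  r <- age_specific_rates(grid)
  w <- as.numeric(weights)
  if (!is.null(names(weights))) {
    check_that(setequal(names(weights), grid$age_groups),
               "weights and grid cover different age groups")
    w <- as.numeric(weights)[match(grid$age_groups, names(weights))]
  }
  asr <- apply(r, 2, compute_asr, weights = w)
  asr_series(grid$years, asr)
}
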