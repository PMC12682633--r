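#' Cohort index of an age-by-period grid
#'
#' On a Lexis grid with `A` age groups (1 = youngest), `T` periods and age
#' width `M` (in period units), diagonals are birth cohorts indexed
#' `c(a, t) = M (A - a) + t`: the oldest age group at the first period is
#' cohort 1, the youngest at the last period is cohort `M (A - 1) + T`.
#' When `M > 1` several single-year birth cohorts share one index (cohort
#' coarsening); they share one effect value in the model.
#'
#' @param A,T Number of age groups and periods (>= 1).
#' @param M Age-group width in period units (>= 1).
#' @return Integer `A x T` matrix of cohort indices.
#' @export
build_cohort_index <- function(A, T, M) {
  check_that(A >= 1 && T >= 1 && M >= 1, "A, T, M must all be >= 1")
  outer(seq_len(A), seq_len(T), function(a, t) M * (A - a) + t)
}

#' Random-walk log-prior density (up to a constant)
#'
#' Improper Gaussian smoothness prior of order 1 or 2 on an effect vector:
#' \deqn{\log p(u \mid \tau) = \frac{m - k}{2}\log\tau -
#'   \frac{\tau}{2}\sum_j (\Delta^k u)_j^2 + const,}
#' with \eqn{\Delta} the forward difference, \eqn{m} the vector length and
#' \eqn{k} the order. RW1 is flat on constants; RW2 is flat on all linear
#' trends (the null space that makes age-period-cohort drift unidentifiable).
#'
#' @param u Numeric effect vector of length `> order`.
#' @param order Walk order, 1 or 2.
#' @param tau Precision of the innovations (> 0).
#' @return Log-density up to an additive constant.
#' @export
rw_log_prior <- function(u, order, tau) {
  u <- as.numeric(u); order <- unname(order); tau <- unname(tau)
  check_that(order %in% c(1, 2), "order must be 1 or 2")
  check_that(is.numeric(tau) && length(tau) == 1 && is.finite(tau) && tau > 0,
             "tau must be a positive number")
  check_that(length(u) >= order + 1, "length(u) must be at least order + 1")
  d <- diff(u, differences = order)
  (length(u) - order) / 2 * log(tau) - tau / 2 * sum(d^2)
}

#' Penalized-complexity prior on a random-walk standard deviation
#'
#' The PC prior for a random-effect standard deviation, built from a base
#' model of a degenerate (zero-variance) random walk, is exponential on
#' \eqn{\sigma} with rate \eqn{\lambda = -\ln(\alpha)/U}, so that
#' \eqn{P(\sigma > U) = \alpha}: the smoothing standard deviation is
#' unlikely to exceed `U`.
#'
#' @param sigma Standard deviation (>= 0); vectorized.
#' @param U Reference upper value (> 0).
#' @param alpha Tail probability in (0, 1).
#' @return Log-density `log(lambda) - lambda * sigma`.
#' @export
pc_prior_logdensity <- function(sigma, U, alpha) {
  check_that(is.numeric(U) && length(U) == 1 && is.finite(U) && U > 0,
             "U must be positive")
  check_that(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1,
             "alpha must lie in (0, 1)")
  check_that(all(is.finite(sigma)) && all(sigma >= 0), "sigma must be >= 0")
  lambda <- -log(alpha) / U
  log(lambda) - lambda * sigma
}

#' Age-period-cohort model specification
#'
#' Configuration of the Bayesian APC model: the log-rate of cell `(a, t)` is
#' \deqn{\eta_{at} = \mu + \alpha_a + \beta_t + \gamma_{c(a,t)} +
#'   \sum_k \delta_k x_k(t),}
#' with counts `y ~ Poisson(n e^eta)` (person-years offset), random-walk
#' smoothing priors on the age, period and cohort effects, PC priors on
#' each effect's innovation standard deviation, and weak normal priors on
#' the intercept and the covariate coefficients. Only `eta` (and functionals
#' of it such as forecasts) are identifiable; individual effects are
#' reported under the declared constraint set.
#'
#' @param rw_order Named integer vector with elements `age`, `period`,
#'   `cohort`, each 1 or 2 (default all 2: second-order smooths).
#' @param pc_u,pc_alpha PC-prior parameters: `P(sigma > pc_u) = pc_alpha`
#'   on the log-rate scale. Defaults `U = 1`, `alpha = 0.01`.
#' @param covariates Optional list of covariates, each a list with `name`,
#'   `x` (numeric series over the observed years), and `rule` (future
#'   extension rule, `"hold_last"` or `"linear"`). Series are centered to
#'   mean zero over the observed years before entering `eta`.
#' @param sample_count Number of posterior draws (default 1000).
#' @param overdispersion `FALSE` (Poisson, default) or `TRUE`
#'   (negative-binomial with an estimated dispersion hyperparameter).
#' @param constraints `"drift_period"` (default: sum-to-zero on all three
#'   effects plus zero linear trend on the cohort effect, so drift is
#'   carried by the period effect) or `"drift_cohort"` (the mirror set).
#' @param seed Integer seed controlling every stochastic step of the fit.
#' @param n_theta Number of hyperparameter draws used for integration
#'   (default `min(20, sample_count)`).
#' @param mu_sd,delta_sd Standard deviations of the weak normal priors on
#'   the intercept and covariate coefficients (defaults 100 and 10).
#' @return An object of class `apc_spec`.
#' @export
apc_spec <- function(rw_order = c(age = 2, period = 2, cohort = 2),
                     pc_u = 1, pc_alpha = 0.01,
                     covariates = list(),
                     sample_count = 1000,
                     overdispersion = FALSE,
                     constraints = c("drift_period", "drift_cohort"),
                     seed = 1L,
                     n_theta = NULL,
                     mu_sd = 100, delta_sd = 10) {
  constraints <- match.arg(constraints)
  check_that(all(c("age", "period", "cohort") %in% names(rw_order)),
             "rw_order needs named elements age, period, cohort")
  check_that(all(rw_order %in% c(1, 2)), "rw orders must be 1 or 2")
  check_that(sample_count >= 1, "sample_count must be >= 1")
  check_that(pc_u > 0, "pc_u must be positive")
  check_that(pc_alpha > 0 && pc_alpha < 1, "pc_alpha must lie in (0, 1)")
  for (cv in covariates) {
    check_that(is.list(cv) && !is.null(cv$name) && !is.null(cv$x),
               "each covariate needs name and x")
  }
  structure(list(rw_order = rw_order[c("age", "period", "cohort")],
                 pc_u = pc_u, pc_alpha = pc_alpha,
                 covariates = covariates,
                 sample_count = as.integer(sample_count),
                 overdispersion = isTRUE(overdispersion),
                 constraints = constraints,
                 seed = as.integer(seed),
                 n_theta = n_theta,
                 mu_sd = mu_sd, delta_sd = delta_sd),
            class = "apc_spec")
}

# ---- internal model assembly -------------------------------------------

# Orthonormal basis of the subspace orthogonal to the columns of M.
.null_basis <- function(m, constraint_cols) {
  MASS::Null(constraint_cols)
}

# Structure (penalty) matrix of an RW of given order on m points.
.rw_penalty <- function(m, order) {
  D <- diff(diag(m), differences = order)
  crossprod(D)
}

# Build design, penalty and index structures for a grid + spec.
.apc_bases <- function(grid, spec) {
  A <- nrow(grid$y); Tn <- ncol(grid$y); C <- grid$n_cohorts
  check_that(A >= 3, "need at least 3 age groups, got %d", A)
  check_that(Tn >= 4, "need at least 4 periods, got %d", Tn)
  check_that(C >= 4, "need at least 4 cohorts, got %d", C)
  lin <- function(m) {
    v <- seq_len(m) - (m + 1) / 2
    cbind(rep(1, m), v)
  }
  S_A <- .null_basis(A, matrix(1, A, 1))
  if (spec$constraints == "drift_period") {
    S_B <- .null_basis(Tn, matrix(1, Tn, 1))
    S_C <- .null_basis(C, lin(C))
  } else {
    S_B <- .null_basis(Tn, lin(Tn))
    S_C <- .null_basis(C, matrix(1, C, 1))
  }
  ia <- rep(seq_len(A), times = Tn)
  it <- rep(seq_len(Tn), each = A)
  ic <- grid$cohort[cbind(ia, it)]
  K <- length(spec$covariates)
  X <- NULL
  xc <- list()
  if (K > 0) {
    X <- matrix(0, A * Tn, K)
    for (k in seq_len(K)) {
      x <- as.numeric(spec$covariates[[k]]$x)
      check_that(length(x) == Tn,
                 "covariate '%s' has length %d, need %d (one per observed year)",
                 spec$covariates[[k]]$name, length(x), Tn)
      xc[[k]] <- x - mean(x)
      X[, k] <- xc[[k]][it]
    }
  }
  Z <- cbind(1, S_A[ia, , drop = FALSE], S_B[it, , drop = FALSE],
             S_C[ic, , drop = FALSE])
  if (K > 0) Z <- cbind(Z, X)
  pa <- ncol(S_A); pb <- ncol(S_B); pc_ <- ncol(S_C)
  idx <- list(mu = 1L,
              age = 1L + seq_len(pa),
              period = 1L + pa + seq_len(pb),
              cohort = 1L + pa + pb + seq_len(pc_),
              delta = if (K > 0) 1L + pa + pb + pc_ + seq_len(K) else integer(0))
  P <- list(age    = crossprod(S_A, .rw_penalty(A, spec$rw_order["age"]) %*% S_A),
            period = crossprod(S_B, .rw_penalty(Tn, spec$rw_order["period"]) %*% S_B),
            cohort = crossprod(S_C, .rw_penalty(C, spec$rw_order["cohort"]) %*% S_C))
  rank <- vapply(P, function(Pm) {
    ev <- eigen(Pm, symmetric = TRUE, only.values = TRUE)$values
    sum(ev > max(ev) * 1e-9)
  }, numeric(1))
  list(A = A, Tn = Tn, C = C, K = K, Z = Z, S_A = S_A, S_B = S_B, S_C = S_C,
       idx = idx, P = P, rank = rank, ia = ia, it = it, ic = ic,
       xc = xc, p = ncol(Z))
}

# Prior precision matrix of the reduced latent field for log-precisions lt.
.apc_Q <- function(bases, spec, lt) {
  p <- bases$p
  Q <- matrix(0, p, p)
  Q[1, 1] <- 1 / spec$mu_sd^2
  for (comp in c("age", "period", "cohort")) {
    id <- bases$idx[[comp]]
    Q[id, id] <- exp(lt[comp]) * bases$P[[comp]]
  }
  if (bases$K > 0) {
    id <- bases$idx$delta
    Q[cbind(id, id)] <- 1 / spec$delta_sd^2
  }
  Q
}

# Log-likelihood pieces for Poisson or negative-binomial counts.
# Returns ll (sum, anchored at the saturated model so that individual terms
# stay O(1) near the fit -- large-count cancellation would otherwise swamp
# the hyperparameter marginal), gradient and curvature wrt eta.
.count_loglik <- function(y, n, eta, family = "poisson", size = NULL) {
  m <- n * exp(pmin(eta, 30))
  if (family == "poisson") {
    d <- m - y
    ll_i <- -d
    pos <- y > 0
    ll_i[pos] <- y[pos] * log1p(d[pos] / y[pos]) - d[pos]
    list(ll = sum(ll_i),
         g = y - m,
         w = m)
  } else {
    # stable C implementation; counts must be (near-)integer for the
    # negative-binomial switch
    r <- size
    list(ll = sum(stats::dnbinom(round(y), size = r, mu = m, log = TRUE)),
         g = y - (y + r) * m / (r + m),
         w = (y + r) * r * m / (r + m)^2)
  }
}

# Bounds on the smoothing log-precisions: sigma between ~1e-4 and ~400.
.lt_bounds <- c(-12, 18)

.lt_penalty <- function(theta) {
  100 * sum(pmax(0, theta - .lt_bounds[2])^2 +
              pmax(0, .lt_bounds[1] - theta)^2)
}

# Newton optimization of the conditional latent mode given hyperparameters.
.apc_newton <- function(bases, yv, nv, Q, family, size, x0 = NULL,
                        max_iter = 100, tol = 1e-9) {
  Z <- bases$Z
  x <- x0 %||% numeric(bases$p)
  fval <- function(x, eta) {
    lk <- .count_loglik(yv, nv, eta, family, size)
    lk$ll - 0.5 * sum(x * (Q %*% x))
  }
  eta <- as.numeric(Z %*% x)
  f <- fval(x, eta)
  for (iter in seq_len(max_iter)) {
    lk <- .count_loglik(yv, nv, eta, family, size)
    grad <- as.numeric(crossprod(Z, lk$g)) - as.numeric(Q %*% x)
    H <- crossprod(Z * sqrt(lk$w)) + Q
    R <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(R)) {
      H <- H + diag(1e-8, nrow(H))
      R <- chol(H)
    }
    step <- backsolve(R, backsolve(R, grad, transpose = TRUE))
    dec <- sum(grad * step)
    if (!is.finite(dec)) stop("non-finite Newton step in latent optimization",
                              call. = FALSE)
    if (dec < tol * (1 + abs(f))) {
      return(list(x = x, chol = R, f = f, eta = eta, iter = iter,
                  converged = TRUE))
    }
    s <- 1
    repeat {
      x_new <- x + s * step
      eta_new <- as.numeric(Z %*% x_new)
      f_new <- fval(x_new, eta_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      s <- s / 2
      if (s < 1e-10) stop("Newton line search failed (non-convergence)",
                          call. = FALSE)
    }
    x <- x_new; eta <- eta_new; f <- f_new
  }
  stop(sprintf("latent optimization did not converge in %d iterations", max_iter),
       call. = FALSE)
}

# PC prior on log tau (change of variables from sigma = exp(-lt/2)).
.pc_log_prior_lt <- function(lt, U, alpha) {
  lambda <- -log(alpha) / U
  log(lambda) - lambda * exp(-lt / 2) - lt / 2 - log(2)
}

# Laplace-approximate log marginal posterior of the hyperparameters.
.apc_log_marginal <- function(theta, bases, spec, yv, nv, warm) {
  lt <- c(age = theta[1], period = theta[2], cohort = theta[3])
  family <- if (spec$overdispersion) "nbinom" else "poisson"
  size <- if (spec$overdispersion) exp(theta[4]) else NULL
  Q <- .apc_Q(bases, spec, lt)
  opt <- tryCatch(.apc_newton(bases, yv, nv, Q, family, size, x0 = warm$x),
                  error = function(e) NULL)
  if (is.null(opt)) return(list(value = -Inf, opt = NULL))
  warm$x <- opt$x
  lp_theta <- sum(.pc_log_prior_lt(lt, spec$pc_u, spec$pc_alpha))
  if (spec$overdispersion) {
    lp_theta <- lp_theta + stats::dnorm(theta[4], mean = 4, sd = 2, log = TRUE)
  }
  ldet_prior <- 0.5 * sum(bases$rank * lt)
  ldet_H <- 2 * sum(log(diag(opt$chol)))
  list(value = opt$f + lp_theta + ldet_prior - 0.5 * ldet_H, opt = opt)
}

#' Joint log-posterior density of an APC model state
#'
#' Evaluates, up to an additive constant, the unnormalized log-posterior of
#' a full state (latent effects plus hyperparameters) given a Lexis grid:
#' the Poisson likelihood term
#' \eqn{\sum_{a,t} [y \ln(n e^{\eta}) - n e^{\eta}]}, the random-walk
#' smoothing priors ([rw_log_prior()]) for the age, period and cohort
#' effects with \eqn{\tau = \sigma^{-2}}, the PC priors
#' ([pc_prior_logdensity()]) on the three standard deviations, and weak
#' normal priors on the intercept and covariate coefficients. Used by the
#' test harness (e.g. MCMC oracles) and exposed for model criticism; the
#' translation invariances of the unconstrained parameterization (e.g.
#' shifting mass between intercept and age effects) hold exactly for the
#' likelihood term.
#'
#' @param state List with elements `mu` (scalar), `alpha` (length `A`),
#'   `beta` (length `T`), `gamma` (length `n_cohorts`), optional `delta`
#'   (one per covariate) and `sigma` (named: `age`, `period`, `cohort`).
#' @param grid A [lexis_grid()].
#' @param spec An [apc_spec()].
#' @return The log-posterior density up to a constant.
#' @export
log_posterior <- function(state, grid, spec) {
  A <- nrow(grid$y); Tn <- ncol(grid$y); C <- grid$n_cohorts
  check_that(length(state$alpha) == A, "alpha must have length %d", A)
  check_that(length(state$beta) == Tn, "beta must have length %d", Tn)
  check_that(length(state$gamma) == C, "gamma must have length %d", C)
  delta <- state$delta %||% numeric(0)
  check_that(length(delta) == length(spec$covariates),
             "delta must have one element per covariate")
  vals <- c(state$mu, state$alpha, state$beta, state$gamma, delta,
            state$sigma)
  check_that(all(is.finite(vals)), "non-finite state")
  sig <- state$sigma
  check_that(all(c("age", "period", "cohort") %in% names(sig)),
             "state$sigma needs named elements age, period, cohort")
  check_that(all(sig > 0), "sigma values must be positive")
  eta <- outer(state$alpha, state$beta, "+") + state$mu +
    matrix(state$gamma[grid$cohort], A, Tn)
  if (length(delta) > 0) {
    for (k in seq_along(delta)) {
      x <- as.numeric(spec$covariates[[k]]$x)
      xc <- x - mean(x)
      eta <- eta + delta[k] * matrix(xc, A, Tn, byrow = TRUE)
    }
  }
  ll <- sum(grid$y * log(grid$n * exp(eta)) - grid$n * exp(eta))
  lp <- rw_log_prior(state$alpha, spec$rw_order["age"], sig[["age"]]^-2) +
    rw_log_prior(state$beta, spec$rw_order["period"], sig[["period"]]^-2) +
    rw_log_prior(state$gamma, spec$rw_order["cohort"], sig[["cohort"]]^-2) +
    sum(pc_prior_logdensity(unname(sig[c("age", "period", "cohort")]),
                            spec$pc_u, spec$pc_alpha)) +
    stats::dnorm(state$mu, 0, spec$mu_sd, log = TRUE)
  if (length(delta) > 0) {
    lp <- lp + sum(stats::dnorm(delta, 0, spec$delta_sd, log = TRUE))
  }
  ll + lp
}

#' Fit the Bayesian age-period-cohort model
#'
#' Approximate Bayesian inference for the latent-Gaussian APC model: the
#' conditional posterior of the latent field given the smoothing
#' log-precisions is replaced by a Gaussian approximation at its mode
#' (Laplace approximation); the hyperparameter posterior is explored by a
#' Laplace-approximate marginal, maximized numerically, with integration by
#' drawing hyperparameter values from a Gaussian approximation at that mode.
#' Joint posterior samples of all latent quantities are returned; the fit
#' is deterministic given `spec$seed`.
#'
#' Identifiability: effects are represented in an orthonormal basis that
#' enforces the spec's constraint set exactly (sum-to-zero on age, period
#' and cohort effects, plus a zero linear trend on the cohort — or period —
#' effect). Only the linear predictor `eta` and its functionals are
#' identifiable; two valid constraint sets give the same `eta` posterior up
#' to Monte Carlo error.
#'
#' @param grid A complete [lexis_grid()] with at least 3 age groups and 4
#'   periods.
#' @param spec An [apc_spec()].
#' @return An object of class `apc_fit`: posterior sample matrices
#'   (`mu`, `alpha`, `beta`, `gamma`, `delta`, `log_tau`), the linear
#'   predictor array `eta` (samples x age x period), hyperparameter mode
#'   and covariance, and fit diagnostics.
#' @export
fit_apc <- function(grid, spec) {
  stopifnot(inherits(grid, "lexis_grid"), inherits(spec, "apc_spec"))
  check_that(!anyNA(grid$y) && !anyNA(grid$n), "grid contains empty cells")
  bases <- .apc_bases(grid, spec)
  yv <- as.numeric(grid$y); nv <- as.numeric(grid$n)
  warm <- new.env(parent = emptyenv()); warm$x <- NULL
  nll <- function(theta) {
    v <- .apc_log_marginal(theta, bases, spec, yv, nv, warm)$value
    if (!is.finite(v)) 1e10 else -v + .lt_penalty(theta)
  }
  d_theta <- if (spec$overdispersion) 4L else 3L
  theta0 <- c(4, 4, 4, if (spec$overdispersion) 4)
  opt <- stats::optim(theta0, nll, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-8))
  if (opt$value >= 1e10) {
    stop("hyperparameter optimization failed to find a finite marginal posterior",
         call. = FALSE)
  }
  theta_mode <- opt$par
  # central-difference Hessian of the log marginal at the mode
  h <- 0.1
  Hm <- matrix(0, d_theta, d_theta)
  f0 <- -opt$value
  fs <- function(th) -nll(th)
  for (i in seq_len(d_theta)) {
    ei <- replace(numeric(d_theta), i, h)
    Hm[i, i] <- (fs(theta_mode + ei) - 2 * f0 + fs(theta_mode - ei)) / h^2
    if (i < d_theta) for (j in seq((i + 1), d_theta)) {
      ej <- replace(numeric(d_theta), j, h)
      Hm[i, j] <- Hm[j, i] <-
        (fs(theta_mode + ei + ej) - fs(theta_mode + ei - ej) -
           fs(theta_mode - ei + ej) + fs(theta_mode - ei - ej)) / (4 * h^2)
    }
  }
  Sigma_theta <- tryCatch({
    S <- solve(-Hm)
    if (!all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > 0)) {
      stop("not pd")
    }
    S
  }, error = function(e) diag(0.09, d_theta))
  S <- spec$sample_count
  nt <- min(spec$n_theta %||% 20L, S)
  family <- if (spec$overdispersion) "nbinom" else "poisson"
  p <- bases$p
  draws <- matrix(NA_real_, S, p)
  lt_draws <- matrix(NA_real_, S, d_theta)
  with_seed(spec$seed, {
    thetas <- MASS::mvrnorm(nt, mu = theta_mode, Sigma = Sigma_theta)
    if (nt == 1) thetas <- matrix(thetas, 1)
    thetas <- pmin(pmax(thetas, .lt_bounds[1]), .lt_bounds[2])
    alloc <- rep(seq_len(nt), length.out = S)
    for (j in seq_len(nt)) {
      th <- thetas[j, ]
      lm_j <- .apc_log_marginal(th, bases, spec, yv, nv, warm)
      if (is.null(lm_j$opt)) {  # fall back to the mode if a draw is degenerate
        th <- theta_mode
        warm$x <- NULL
        lm_j <- .apc_log_marginal(th, bases, spec, yv, nv, warm)
        if (is.null(lm_j$opt)) {
          stop("latent Gaussian approximation failed at the hyperparameter mode",
               call. = FALSE)
        }
      }
      rows <- which(alloc == j)
      zmat <- matrix(stats::rnorm(length(rows) * p), p, length(rows))
      draws[rows, ] <- t(lm_j$opt$x + backsolve(lm_j$opt$chol, zmat))
      lt_draws[rows, ] <- matrix(th, length(rows), d_theta, byrow = TRUE)
    }
  })
  idx <- bases$idx
  alpha_s <- draws[, idx$age, drop = FALSE] %*% t(bases$S_A)
  beta_s  <- draws[, idx$period, drop = FALSE] %*% t(bases$S_B)
  gamma_s <- draws[, idx$cohort, drop = FALSE] %*% t(bases$S_C)
  mu_s <- draws[, idx$mu]
  delta_s <- if (bases$K > 0) draws[, idx$delta, drop = FALSE] else
    matrix(0, S, 0)
  eta_s <- draws %*% t(bases$Z)          # S x (A*T)
  eta <- array(eta_s, dim = c(S, bases$A, bases$Tn))
  colnames(lt_draws) <- c("age", "period", "cohort",
                          if (spec$overdispersion) "log_size")[seq_len(d_theta)]
  structure(list(
    samples = list(mu = mu_s, alpha = alpha_s, beta = beta_s,
                   gamma = gamma_s, delta = delta_s, log_tau = lt_draws),
    eta = eta,
    grid = grid, spec = spec, bases = bases,
    theta_mode = theta_mode, theta_vcov = Sigma_theta,
    log_marginal = -opt$value,
    diagnostics = list(optim_convergence = opt$convergence,
                       optim_evals = opt$counts[["function"]],
                       family = family)),
    class = "apc_fit")
}

#' @export
print.apc_fit <- function(x, ...) {
  d <- dim(x$eta)
  cat(sprintf("<apc_fit> %d posterior samples on a %d x %d grid (%s likelihood)\n",
              d[1], d[2], d[3], x$diagnostics$family))
  sig <- exp(-x$theta_mode[1:3] / 2)
  cat(sprintf("  smoothing sd (mode): age %.3g, period %.3g, cohort %.3g\n",
              sig[1], sig[2], sig[3]))
  invisible(x)
}

#' Posterior mean of the linear predictor
#'
#' @param fit An [fit_apc()] result.
#' @return `A x T` matrix of posterior mean log-rates.
#' @export
eta_posterior_mean <- function(fit) {
  m <- apply(fit$eta, c(2, 3), mean)
  dimnames(m) <- dimnames(fit$grid$y)
  m
}

#' Per-cell posterior quantiles of the linear predictor
#'
#' @param fit An [fit_apc()] result.
#' @param probs Quantile probabilities (default 2.5% and 97.5%).
#' @return A list of `A x T` matrices, one per probability.
#' @export
eta_posterior_interval <- function(fit, probs = c(0.025, 0.975)) {
  out <- lapply(probs, function(p) {
    m <- apply(fit$eta, c(2, 3), stats::quantile, probs = p, names = FALSE)
    dimnames(m) <- dimnames(fit$grid$y)
    m
  })
  names(out) <- paste0("q", format(100 * probs, trim = TRUE))
  out
}
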