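# Independent oracles and small fixtures used across the test files.
# Every oracle here is coded directly from the defining formula, without
# calling the implementation under test.

# brute-force weighted mean: the defining ASR formula, summed term by term
oracle_asr <- function(rates, weights) {
  num <- 0; den <- 0
  for (i in seq_along(rates)) {
    num <- num + rates[i] * weights[i]
    den <- den + weights[i]
  }
  num / den * 1e5
}

# ordinary least squares of log(asr) on year via explicit normal equations
oracle_loglinear_slope <- function(year, asr) {
  x <- year; z <- log(asr); n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxz <- sum(x * z) - sum(x) * sum(z) / n
  beta <- sxz / sxx
  resid <- z - (mean(z) - beta * mean(x)) - beta * x
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  list(beta = beta, se = se)
}

# dense structure-matrix quadratic form for the RW prior
oracle_rw_quadform <- function(u, order) {
  m <- length(u)
  D <- diff(diag(m), differences = order)
  R <- t(D) %*% D
  as.numeric(t(u) %*% R %*% u)
}

# double-loop ensemble CRPS
oracle_crps <- function(x, y) {
  S <- length(x)
  t1 <- sum(abs(x - y)) / S
  t2 <- 0
  for (i in seq_len(S)) for (j in seq_len(S)) t2 <- t2 + abs(x[i] - x[j])
  t1 - t2 / (2 * S^2)
}

# sort-and-slice quintile assignment
oracle_quintiles <- function(sdi) {
  labels <- c("low", "medium-low", "medium", "medium-high", "high")
  n <- length(sdi)
  ord <- order(sdi, names(sdi))
  out <- character(n)
  for (pos in seq_len(n)) {
    out[ord[pos]] <- labels[floor((pos - 1) * 5 / n) + 1]
  }
  stats::setNames(out, names(sdi))
}

# a small, moderately informative APC instance with known truth (M = 1)
small_apc_instance <- function(A = 4, Tn = 8, n_cell = 5e4, seed = 11,
                               mu = -6) {
  alpha <- seq(-0.6, 0.5, length.out = A); alpha <- alpha - mean(alpha)
  beta <- 0.03 * (seq_len(Tn) - mean(seq_len(Tn)))
  C <- A - 1 + Tn
  cc <- seq_len(C)
  gamma <- 0.1 * sin(2 * pi * cc / 6)
  X <- cbind(1, cc - mean(cc))
  gamma <- as.numeric(gamma - X %*% qr.solve(X, gamma))
  co <- build_cohort_index(A, Tn, 1)
  eta <- outer(alpha, beta, "+") + mu + matrix(gamma[co], A, Tn)
  n <- matrix(n_cell, A, Tn)
  y <- bapcburden:::with_seed(seed,
    matrix(stats::rpois(A * Tn, n * exp(eta)), A, Tn))
  grid <- lexis_grid(y, n, sprintf("%d to %d", seq_len(A) - 1, seq_len(A) - 1),
                     2000 + seq_len(Tn), age_width = 1)
  list(grid = grid, mu = mu, alpha = alpha, beta = beta, gamma = gamma,
       eta = eta)
}

# long-run MCMC oracle for the APC posterior via JAGS: an independent
# sampler for the same hierarchical model (random-walk increment form,
# vague proper priors standing in for the improper null-space directions)
jags_eta_oracle <- function(grid, pc_u = 1, pc_alpha = 0.01, mu_sd = 100,
                            n_burn = 10000, n_iter = 60000, thin = 6) {
  if (!requireNamespace("rjags", quietly = TRUE)) {
    stop("rjags is required for the MCMC oracle")
  }
  A <- nrow(grid$y); Tn <- ncol(grid$y); C <- grid$n_cohorts
  model_str <- "
  model {
    for (a in 1:A) { for (t in 1:T) {
      y[a,t] ~ dpois(m[a,t])
      log(m[a,t]) <- log(n[a,t]) + eta[a,t]
      eta[a,t] <- mu + alpha[a] + beta[t] + gamma[co[a,t]]
    }}
    mu ~ dnorm(0, prec_mu)
    alpha[1] ~ dnorm(0, 1e-6); alpha[2] ~ dnorm(0, 1e-6)
    for (i in 3:A) { alpha[i] ~ dnorm(2*alpha[i-1]-alpha[i-2], tau_a) }
    beta[1] ~ dnorm(0, 1e-6); beta[2] ~ dnorm(0, 1e-6)
    for (i in 3:T) { beta[i] ~ dnorm(2*beta[i-1]-beta[i-2], tau_b) }
    gamma[1] ~ dnorm(0, 1e-6); gamma[2] ~ dnorm(0, 1e-6)
    for (i in 3:C) { gamma[i] ~ dnorm(2*gamma[i-1]-gamma[i-2], tau_c) }
    sig_a ~ dexp(lambda); sig_b ~ dexp(lambda); sig_c ~ dexp(lambda)
    tau_a <- pow(sig_a, -2); tau_b <- pow(sig_b, -2); tau_c <- pow(sig_c, -2)
  }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = grid$y, n = grid$n, A = A, T = Tn, C = C,
                co = grid$cohort, lambda = -log(pc_alpha) / pc_u,
                prec_mu = 1 / mu_sd^2),
    n.chains = 1, quiet = TRUE,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1))
  update(jm, n_burn, progress.bar = "none")
  sm <- rjags::coda.samples(jm, "eta", n.iter = n_iter, thin = thin,
                            progress.bar = "none")
  matrix(colMeans(as.matrix(sm)), A, Tn)  # coda orders eta[a,t] column-major
}
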