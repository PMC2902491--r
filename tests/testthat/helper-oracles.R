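# Independent numerical oracles used across the test files. These
# deliberately avoid the package's computational paths: integration via
# stats::integrate, Gauss-Hermite nodes via Golub-Welsch on the Jacobi
# matrix, Monte-Carlo integration via plain BVN sampling.

# adaptive numerical integration of f over the real line
num_int <- function(f, rel.tol = 1e-10) {
  integrate(f, -Inf, Inf, rel.tol = rel.tol, abs.tol = 1e-12,
            subdivisions = 500L)$value
}

# moments of a density by numerical integration
num_moments <- function(dens) {
  m <- num_int(function(y) y * dens(y))
  v <- num_int(function(y) (y - m)^2 * dens(y))
  m3 <- num_int(function(y) (y - m)^3 * dens(y))
  list(mean = m, var = v, skewness = m3 / v^1.5)
}

# probabilists' Gauss-Hermite rule by Golub-Welsch (eigen of the Jacobi
# matrix of the Hermite recurrence), independent of the package's rule
gh_oracle <- function(n) {
  J <- matrix(0, n, n)
  for (k in seq_len(n - 1)) J[k, k + 1] <- J[k + 1, k] <- sqrt(k)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}

# conditional log-density of one subject's observations given (tau0, tau1),
# written from the model definition with base R only
cond_loglik_oracle <- function(y, X1, X2, beta1, beta2, sigma, delta,
                               tau0, tau1, link = "probit") {
  eta <- drop(X1 %*% beta1) + tau0
  p <- if (link == "probit") pnorm(eta) else plogis(eta)
  ll <- ifelse(y == 0, log(1 - p), log(p))
  pos <- y > 0
  if (any(pos)) {
    v <- log(y[pos]); mu <- drop(X2 %*% beta2)[pos] + tau1
    om <- sqrt(sigma^2 + delta^2)
    z <- (v - mu) / om
    ll[pos] <- ll[pos] + log(2) - log(om) + dnorm(z, log = TRUE) +
      pnorm(delta / sigma * z, log.p = TRUE)
  }
  sum(ll)
}

# Monte-Carlo marginal log-likelihood of one subject: average the
# conditional likelihood over draws from BVN(0, S) (vectorized over draws)
mc_subject_loglik <- function(y, X1, X2, beta1, beta2, sigma, delta, S,
                              n_draws = 1e6, link = "probit") {
  L <- t(chol(S))
  # antithetic pairs reduce the Monte-Carlo variance at fixed draw count
  zh <- matrix(rnorm(n_draws), 2, n_draws / 2)
  z <- cbind(zh, -zh)
  tau0 <- L[1, 1] * z[1, ]
  tau1 <- L[2, 1] * z[1, ] + L[2, 2] * z[2, ]
  eta0 <- drop(X1 %*% beta1)
  mu0 <- drop(X2 %*% beta2)
  om <- sqrt(sigma^2 + delta^2)
  lls <- 0
  for (j in seq_along(y)) {
    eta <- eta0[j] + tau0
    if (y[j] == 0) {
      lls <- lls + if (link == "probit") pnorm(-eta, log.p = TRUE) else
        plogis(-eta, log.p = TRUE)
    } else {
      zd <- (log(y[j]) - (mu0[j] + tau1)) / om
      lls <- lls +
        (if (link == "probit") pnorm(eta, log.p = TRUE) else
           plogis(eta, log.p = TRUE)) +
        log(2) - log(om) + dnorm(zd, log = TRUE) +
        pnorm(delta / sigma * zd, log.p = TRUE)
    }
  }
  mx <- max(lls)
  mx + log(mean(exp(lls - mx)))
}

# direct probit/log-normal two-part marginal likelihood fit by plain-R
# non-adaptive Gauss-Hermite quadrature: the independent oracle for the
# delta = 0 submodel
fit_lognormal_oracle <- function(d, points = 31, start) {
  X1 <- cbind(1, d$x); X2 <- cbind(1, d$x)
  gh <- gh_oracle(points)
  grid <- expand.grid(a = seq_len(points), b = seq_len(points))
  uw <- log(gh$weights[grid$a]) + log(gh$weights[grid$b])
  ids <- unique(d$subject)
  nll <- function(par) {
    beta1 <- par[1:2]; beta2 <- par[3:4]
    sigma <- exp(par[5])
    s11 <- exp(par[6]); s22 <- exp(par[7]); rho <- tanh(par[8])
    L <- t(chol(matrix(c(s11, rho * sqrt(s11 * s22),
                         rho * sqrt(s11 * s22), s22), 2, 2)))
    t0 <- L[1, 1] * gh$nodes[grid$a]
    t1 <- L[2, 1] * gh$nodes[grid$a] + L[2, 2] * gh$nodes[grid$b]
    tot <- 0
    for (id in ids) {
      rows <- d$subject == id
      y <- d$y[rows]
      eta0 <- drop(X1[rows, , drop = FALSE] %*% beta1)
      mu0 <- drop(X2[rows, , drop = FALSE] %*% beta2)
      eta <- outer(eta0, t0, "+")                 # m x K
      mu <- outer(mu0, t1, "+")
      zero <- y == 0
      ll <- matrix(0, length(y), length(t0))
      ll[zero, ] <- pnorm(-eta[zero, , drop = FALSE], log.p = TRUE)
      ll[!zero, ] <- pnorm(eta[!zero, , drop = FALSE], log.p = TRUE) +
        dnorm(log(y[!zero]), mu[!zero, , drop = FALSE], sigma, log = TRUE)
      a <- colSums(ll) + uw
      mx <- max(a)
      tot <- tot + mx + log(sum(exp(a - mx)))
    }
    -tot
  }
  o <- nlminb(start, nll, control = list(iter.max = 1000, eval.max = 2000,
                                         rel.tol = 1e-14))
  list(neg2ll = 2 * o$objective, par = o$par, convergence = o$convergence)
}

# skeleton "snhurdle" object for testing inference arithmetic in isolation
fake_fit <- function(estimates, se = NULL, neg2ll = 0, fixed_delta = NULL,
                     fingerprint = c(n_obs = 1, n_subjects = 1, sum_y = 0,
                                     sum_pos = 0)) {
  structure(list(estimates = estimates,
                 se = se %||% rep(NA_real_, length(estimates)),
                 neg2ll = neg2ll, fixed_delta = fixed_delta,
                 data_fingerprint = fingerprint),
            class = "snhurdle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small simulated dataset shared by several estimation tests
small_sn_data <- function(seed, n_subjects = 50, n_occasions = 10,
                          p_x = 0.25, delta = -0.8) {
  simulate_snhurdle_data(n_subjects = n_subjects, n_occasions = n_occasions,
                         beta1 = c(-0.5, 1.5), beta2 = c(-0.3, 0.7),
                         sigma = 0.6, delta = delta,
                         s11 = 0.8, s22 = 0.25, s12 = 0.15,
                         p_x = p_x, seed = seed)
}

fast_control <- function(points = 5, se = FALSE)
  snhurdle_control(points = points, adaptive = TRUE, se = se)
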