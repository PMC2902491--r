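#' Gauss-Hermite quadrature rule for the random-effects integral
#'
#' Builds the quadrature rule used to integrate each subject's conditional
#' likelihood over the bivariate-normal random intercepts. One-dimensional
#' Gauss-Hermite abscissae (from [pracma::gaussHermite()]) are rescaled to
#' the probabilists' convention, so that the weights sum to one and the
#' one-dimensional rule integrates polynomials of degree up to
#' `2 * points - 1` exactly against the standard normal kernel; the
#' two-dimensional rule is the tensor product.
#'
#' With `adaptive = FALSE` the product rule is centred at zero and scaled
#' by the Cholesky factor of the current random-effects covariance. With
#' `adaptive = TRUE` the rule is recentred per subject at the posterior
#' mode of the random effects and scaled by the local curvature, which
#' keeps a small rule accurate even when a subject's many repeated
#' measurements concentrate the integrand far inside the prior scale.
#'
#' @param points number of quadrature points per dimension.
#' @param adaptive logical; recentre per subject at the posterior mode?
#' @return An object of class `"gh_rule"` with elements `points`,
#'   `adaptive`, `nodes`/`weights` (the 1-D standard-normal rule) and the
#'   expanded 2-D grid `U` (K x 2) with log-weight adjustments `lwadj`.
#' @export
gh_rule <- function(points = 21, adaptive = FALSE) {
  if (length(points) != 1L || !is.finite(points) || points < 1)
    stop("'points' must be a positive integer")
  points <- as.integer(points)
  gh <- pracma::gaussHermite(points)
  nodes <- gh$x * sqrt(2)
  weights <- gh$w / sqrt(pi)
  g <- expand.grid(k1 = seq_len(points), k2 = seq_len(points))
  U <- cbind(nodes[g$k1], nodes[g$k2])
  lw <- log(weights[g$k1]) + log(weights[g$k2])
  # fold the inverse standard-normal kernel into the weight so that
  # sum_k exp(lwadj_k) f(C u_k + c) |C| approximates the integral of f
  lwadj <- lw + 0.5 * rowSums(U^2) + log(2 * pi)
  structure(list(points = points, adaptive = isTRUE(adaptive),
                 nodes = nodes, weights = weights, U = U, lwadj = lwadj),
            class = "gh_rule")
}

# lower Cholesky of a 2x2 SPD matrix, entries (c11, c21, c22)
chol2_lower <- function(S) {
  c11 <- sqrt(S[1, 1])
  c21 <- S[2, 1] / c11
  d <- S[2, 2] - c21^2
  if (!is.finite(d) || d <= 0) stop("random-effects covariance is not positive definite")
  c(c11, c21, sqrt(d))
}

.zeta <- function(x) exp(dnorm(x, log = TRUE) - pnorm(x, log.p = TRUE))

# first and second derivatives in eta of the binary-part log-likelihood
bin_derivs <- function(eta, positive, link) {
  if (link == "probit") {
    if (positive) {
      z <- .zeta(eta)
      list(d1 = z, d2 = -z * (eta + z))
    } else {
      z <- .zeta(-eta)
      list(d1 = -z, d2 = -z * (-eta + z))
    }
  } else {
    p <- plogis(eta)
    list(d1 = if (positive) 1 - p else -p, d2 = -p * (1 - p))
  }
}

# derivatives in mu of the skew-normal log-density of v = log y
sn_mu_derivs <- function(v, mu, sigma, delta) {
  om2 <- sigma^2 + delta^2
  omega <- sqrt(om2)
  alpha <- delta / sigma
  r <- (v - mu) / omega
  z <- .zeta(alpha * r)
  list(d1 = r / omega - (alpha / omega) * z,
       d2 = -1 / om2 - (alpha / omega)^2 * z * (alpha * r + z))
}

# posterior mode and curvature of the random effects for one subject;
# the two observation parts depend on tau0 and tau1 separately, so the
# conditional Hessian couples them only through the prior
posterior_mode <- function(y, logy, etab, mub, Sinv, sigma, delta, link,
                           start = c(0, 0), tol = 1e-9, maxit = 50) {
  pos <- y > 0
  tau <- start
  obj <- function(tau) {
    eta <- etab + tau[1]
    lp <- if (link == "probit") {
      ifelse(pos, pnorm(eta, log.p = TRUE), pnorm(-eta, log.p = TRUE))
    } else {
      ifelse(pos, plogis(eta, log.p = TRUE), plogis(-eta, log.p = TRUE))
    }
    sn <- if (any(pos))
      sum(dskewnorm(logy[pos], mub[pos] + tau[2], sigma, delta, log = TRUE)) else 0
    sum(lp) + sn - 0.5 * drop(tau %*% Sinv %*% tau)
  }
  f <- obj(tau)
  for (it in seq_len(maxit)) {
    eta <- etab + tau[1]
    d1e <- d2e <- numeric(length(y))
    if (any(pos)) {
      bp <- bin_derivs(eta[pos], TRUE, link)
      d1e[pos] <- bp$d1; d2e[pos] <- bp$d2
      sp <- sn_mu_derivs(logy[pos], mub[pos] + tau[2], sigma, delta)
      g2 <- sum(sp$d1); h22 <- sum(sp$d2)
    } else { g2 <- 0; h22 <- 0 }
    if (any(!pos)) {
      bz <- bin_derivs(eta[!pos], FALSE, link)
      d1e[!pos] <- bz$d1; d2e[!pos] <- bz$d2
    }
    g <- c(sum(d1e), g2) - drop(Sinv %*% tau)
    H <- matrix(c(sum(d2e), 0, 0, h22), 2, 2) - Sinv
    if (max(abs(g)) < tol) break
    step <- tryCatch(solve(-H, g), error = function(e) g)
    # step halving to guarantee ascent
    for (h in 0:20) {
      cand <- tau + step / 2^h
      fc <- obj(cand)
      if (is.finite(fc) && fc >= f - 1e-12) { tau <- cand; f <- fc; break }
    }
  }
  Sigma <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(Sigma) || any(!is.finite(Sigma)) || Sigma[1, 1] <= 0 ||
      Sigma[2, 2] <= 0 || det(Sigma) <= 0)
    return(NULL)
  list(tau = tau, Sigma = Sigma)
}

# node placement for all subjects: centres (n x 2) and Cholesky factors
# (n x 3) of the scaling matrices
place_nodes <- function(md, pars, rule, link) {
  n <- length(md$subjects)
  S <- pars$S
  if (!rule$adaptive) {
    cc <- chol2_lower(S)
    return(list(centers = matrix(0, n, 2),
                cholC = matrix(cc, n, 3, byrow = TRUE)))
  }
  Sinv <- solve(S)
  centers <- matrix(0, n, 2)
  cholC <- matrix(0, n, 3)
  prior_cc <- chol2_lower(S)
  for (i in seq_len(n)) {
    idx <- (md$sub_start[i] + 1L):(md$sub_start[i] + md$sub_len[i])
    etab <- drop(md$X1[idx, , drop = FALSE] %*% pars$beta1)
    mub <- drop(md$X2[idx, , drop = FALSE] %*% pars$beta2)
    pm <- posterior_mode(md$y[idx], md$logy[idx], etab, mub, Sinv,
                         pars$sigma, pars$delta, link)
    if (is.null(pm)) { # fall back to the prior placement for this subject
      cholC[i, ] <- prior_cc
    } else {
      centers[i, ] <- pm$tau
      cholC[i, ] <- chol2_lower(pm$Sigma)
    }
  }
  list(centers = centers, cholC = cholC)
}

#' Marginal log-likelihood of the two-part model
#'
#' Computes the marginal log-likelihood of a parameter set on a
#' long-format dataset: per subject, the conditional likelihood of all of
#' that subject's observations is integrated over the bivariate-normal
#' random intercepts with the product quadrature rule `rule`
#' (log-sum-exp accumulation, so subjects with many observations do not
#' underflow), and subject contributions are summed.
#'
#' @param pars an [snhurdle_pars()] object.
#' @param data long-format data frame containing the response and
#'   covariates.
#' @param formula two-part formula `y ~ binary part | severity part`.
#' @param subject name of the subject identifier column.
#' @param rule a [gh_rule()].
#' @param link `"probit"` or `"logit"`.
#' @param by_subject logical; return the per-subject vector instead of the
#'   total?
#' @param engine `"cpp"` (compiled) or `"R"` (plain-R reference
#'   implementation, used for cross-checking).
#' @return total log-likelihood, or a named per-subject vector.
#' @export
two_part_loglik <- function(pars, data, formula, subject,
                            rule = gh_rule(21), link = c("probit", "logit"),
                            by_subject = FALSE, engine = c("cpp", "R")) {
  link <- match.arg(link)
  engine <- match.arg(engine)
  stopifnot(inherits(pars, "snhurdle_pars"), inherits(rule, "gh_rule"))
  md <- build_model_data(formula, data, subject)
  if (nrow(md$X1) == 0L) stop("empty dataset")
  if (ncol(md$X1) != length(pars$beta1) || ncol(md$X2) != length(pars$beta2))
    stop("coefficient length does not match the design implied by 'formula'")
  pl <- place_nodes(md, pars, rule, link)
  ll <- eval_loglik(md, pars_to_theta(pars), ncol(md$X1), ncol(md$X2),
                    pl, rule, link, want_grad = FALSE, engine = engine)
  if (by_subject) setNames(ll$by_subject, md$subjects) else ll$loglik
}

pars_to_theta <- function(pars) {
  rho <- pars$s12 / sqrt(pars$s11 * pars$s22)
  c(pars$beta1, pars$beta2, log(pars$sigma), pars$delta,
    log(pars$s11), log(pars$s22), atanh(rho))
}

theta_to_pars <- function(theta, p1, p2, nm1 = NULL, nm2 = NULL) {
  s11 <- exp(theta[p1 + p2 + 3]); s22 <- exp(theta[p1 + p2 + 4])
  rho <- tanh(theta[p1 + p2 + 5])
  snhurdle_pars(beta1 = setNames(theta[seq_len(p1)], nm1),
                beta2 = setNames(theta[p1 + seq_len(p2)], nm2),
                sigma = exp(theta[p1 + p2 + 1]), delta = theta[p1 + p2 + 2],
                s11 = s11, s22 = s22, s12 = rho * sqrt(s11 * s22))
}

# shared dispatcher over the compiled and plain-R likelihood engines
eval_loglik <- function(md, theta, p1, p2, pl, rule, link,
                        want_grad = FALSE, engine = "cpp") {
  if (engine == "cpp") {
    cpp_tp_loglik(theta, p1, p2, md$y, md$logy, md$X1, md$X2,
                  md$sub_start, md$sub_len, pl$centers, pl$cholC,
                  rule$U, rule$lwadj, if (link == "probit") 0L else 1L,
                  want_grad)
  } else {
    r_tp_loglik(theta, p1, p2, md, pl, rule, link)
  }
}

# plain-R reference implementation of the same fixed-node quadrature sum
r_tp_loglik <- function(theta, p1, p2, md, pl, rule, link) {
  pars <- theta_to_pars(theta, p1, p2)
  n <- length(md$subjects)
  Sinv <- solve(pars$S)
  logdetS <- determinant(pars$S, logarithm = TRUE)$modulus
  by_subject <- numeric(n)
  for (i in seq_len(n)) {
    idx <- (md$sub_start[i] + 1L):(md$sub_start[i] + md$sub_len[i])
    cc <- pl$cholC[i, ]
    gk <- vapply(seq_len(nrow(rule$U)), function(k) {
      t0 <- pl$centers[i, 1] + cc[1] * rule$U[k, 1]
      t1 <- pl$centers[i, 2] + cc[2] * rule$U[k, 1] + cc[3] * rule$U[k, 2]
      tt <- c(t0, t1)
      lprior <- -log(2 * pi) - 0.5 * logdetS - 0.5 * drop(tt %*% Sinv %*% tt)
      sum(obs_logdensity(md$y[idx], md$X1[idx, , drop = FALSE],
                         md$X2[idx, , drop = FALSE], pars, t0, t1, link)) +
        lprior
    }, numeric(1))
    a <- gk + rule$lwadj + log(cc[1]) + log(cc[3])
    mx <- max(a)
    by_subject[i] <- mx + log(sum(exp(a - mx)))
  }
  list(loglik = sum(by_subject), by_subject = by_subject)
}
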