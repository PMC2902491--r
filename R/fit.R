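#' Control parameters for snhurdle fitting
#'
#' @param points quadrature points per dimension (see [gh_rule()]).
#' @param adaptive logical; recentre the rule per subject at the posterior
#'   mode of the random effects. The default (7-point adaptive) tracks the
#'   integrand where many repeated measurements concentrate it; a
#'   non-adaptive rule centred on the prior typically needs 20+ points per
#'   dimension for comparable accuracy on datasets with ~50 occasions per
#'   subject.
#' @param outer_max maximum number of node-replacement (recentring)
#'   cycles; within each cycle the quadrature nodes are held fixed so the
#'   analytic gradient is exact for the objective being optimized.
#' @param outer_tol relative change in -2 log-likelihood between cycles
#'   below which the placement is considered stable.
#' @param grad_tol gradient-norm tolerance (relative, scaled by
#'   `1 + |loglik|`) required to report convergence.
#' @param iter_max maximum iterations of the inner quasi-Newton optimizer.
#' @param se logical; compute the finite-difference Hessian and standard
#'   errors at the optimum.
#' @param warmup logical; precede the full-rule optimization by a cheap
#'   pass with a 3-point adaptive rule to move the start close to the
#'   optimum (the final cycles always use the full rule, so the reported
#'   optimum is unaffected).
#' @return a list of class `"snhurdle_control"`.
#' @export
snhurdle_control <- function(points = 7, adaptive = TRUE, outer_max = 8,
                             outer_tol = 1e-8, grad_tol = 1e-6,
                             iter_max = 500, se = TRUE, warmup = TRUE) {
  structure(list(points = points, adaptive = adaptive, outer_max = outer_max,
                 outer_tol = outer_tol, grad_tol = grad_tol,
                 iter_max = iter_max, se = se, warmup = warmup),
            class = "snhurdle_control")
}

#' Fit a two-part skew-normal hurdle model with correlated random intercepts
#'
#' Maximum marginal likelihood estimation of the random-effects two-part
#' model for a semicontinuous repeated-measures outcome: a probit (or
#' logit) regression for \eqn{P(Y_{ij} > 0)} and a skew-normal regression
#' (Sahu-Dey-Branco parameterization) for \eqn{\log Y_{ij}} given
#' \eqn{Y_{ij} > 0}, with subject-level random intercepts
#' \eqn{(\tau_{0i}, \tau_{1i}) \sim BVN(0, S)} in the two linear
#' predictors. The per-subject random-effects integral is approximated by
#' a Gauss-Hermite product rule (see [gh_rule()] and
#' [snhurdle_control()]); optimization is quasi-Newton
#' ([stats::nlminb()]) on an unconstrained parameterization
#' \eqn{(\beta_1, \beta_2, \log\sigma, \delta, \log s_{11}, \log s_{22},
#' \mathrm{atanh}\,\rho)} so every iterate has a positive scale and a
#' positive-definite covariance; results are reported on the natural
#' scale with delta-method standard errors.
#'
#' Starting values follow a two-stage scheme: stage one fits the
#' no-random-effects probit/log-skew-normal model (binary part by
#' [stats::glm.fit()], severity part by direct likelihood maximization);
#' stage two starts the random-effects parameters at
#' `s11 = 0.5, s22 = 0.5, s12 = 0`.
#'
#' @param formula two-part formula `y ~ binary covariates | severity
#'   covariates`; a single right-hand side is shared by both parts.
#' @param data long-format data frame; one row per subject-occasion, no
#'   missing values (aggregate and filter upstream, e.g. with
#'   [aggregate_diary()]).
#' @param subject name of the subject identifier column.
#' @param link link for the binary part, `"probit"` (default) or
#'   `"logit"`.
#' @param delta optional fixed value for the skewness parameter; `delta =
#'   0` fits the nested probit/log-normal submodel used by
#'   [lrt_delta_zero()].
#' @param control a [snhurdle_control()] list.
#' @param start optional [snhurdle_pars()] with starting values.
#' @return An object of class `"snhurdle"`; see [summary.snhurdle()],
#'   [predict.snhurdle()], [wald_tests()].
#' @examples
#' \donttest{
#' d <- synthesize_diary(n_subjects = 30, seed = 1)
#' w <- aggregate_diary(d)
#' fit <- snhurdle(y ~ viral + asthma | viral + asthma, data = w,
#'                 subject = "subject")
#' summary(fit)
#' }
#' @export
snhurdle <- function(formula, data, subject, link = c("probit", "logit"),
                     delta = NULL, control = snhurdle_control(),
                     start = NULL) {
  link <- match.arg(link)
  cl <- match.call()
  md <- build_model_data(formula, data, subject)
  if (nrow(md$X1) == 0L) stop("empty dataset")
  p1 <- ncol(md$X1); p2 <- ncol(md$X2)
  rule <- gh_rule(control$points, control$adaptive)
  fixed_delta <- !is.null(delta)
  if (fixed_delta) stopifnot(is.numeric(delta), length(delta) == 1L)

  # --- starting values ----------------------------------------------------
  theta <- if (!is.null(start)) {
    stopifnot(inherits(start, "snhurdle_pars"))
    pars_to_theta(start)
  } else {
    stage1_start(md, link, if (fixed_delta) delta else NULL)
  }
  if (fixed_delta) theta[p1 + p2 + 2] <- delta
  free <- rep(TRUE, p1 + p2 + 5)
  if (fixed_delta) free[p1 + p2 + 2] <- FALSE

  # --- outer recentring / inner optimization loop -------------------------
  embed <- function(th_free) { th <- theta; th[free] <- th_free; th }
  rules <- rep(list(rule), control$outer_max)
  is_warm <- rep(FALSE, control$outer_max)
  if (control$warmup && control$adaptive && control$points > 5 &&
      is.null(start)) {
    rules <- c(list(gh_rule(5, adaptive = TRUE)), rules)
    is_warm <- c(TRUE, is_warm)
  }
  neg2ll_prev <- Inf
  n_iter <- 0L
  inner_ok <- FALSE
  pl <- NULL
  for (cycle in seq_along(rules)) {
    rl <- rules[[cycle]]
    pl <- place_nodes(md, theta_to_pars(theta, p1, p2), rl, link)
    fn <- function(th_free)
      -eval_loglik(md, embed(th_free), p1, p2, pl, rl, link)$loglik
    gr <- function(th_free)
      -eval_loglik(md, embed(th_free), p1, p2, pl, rl, link,
                   want_grad = TRUE)$grad[free]
    opt <- nlminb(theta[free], fn, gr,
                  control = list(iter.max = control$iter_max,
                                 eval.max = 2L * control$iter_max,
                                 rel.tol = 1e-10))
    theta <- embed(opt$par)
    n_iter <- n_iter + opt$iterations
    if (is_warm[cycle]) next
    inner_ok <- opt$convergence == 0 || grepl("relative convergence|both X.*and relative|singular convergence", opt$message %||% "")
    neg2ll <- 2 * opt$objective
    if (abs(neg2ll - neg2ll_prev) < control$outer_tol * (1 + abs(neg2ll))) {
      neg2ll_prev <- neg2ll
      break
    }
    neg2ll_prev <- neg2ll
  }
  neg2ll <- neg2ll_prev

  llg <- eval_loglik(md, theta, p1, p2, pl, rule, link, want_grad = TRUE)
  gnorm <- max(abs(llg$grad[free])) / (1 + abs(llg$loglik))
  # Newton polish: quasi-Newton solvers can stall with a small but
  # above-tolerance gradient on flat surfaces; a few Newton steps with the
  # finite-difference Hessian of the analytic gradient clean this up
  if (inner_ok && gnorm > control$grad_tol) {
    for (np_it in 1:3) {
      H <- fd_hessian(function(th_free)
        -eval_loglik(md, embed(th_free), p1, p2, pl, rule, link,
                     want_grad = TRUE)$grad[free], theta[free])
      step <- tryCatch(solve((H + t(H)) / 2, llg$grad[free]),
                       error = function(e) NULL)
      if (is.null(step)) break
      cand <- theta; cand[free] <- theta[free] + step
      llc <- tryCatch(eval_loglik(md, cand, p1, p2, pl, rule, link,
                                  want_grad = TRUE),
                      error = function(e) NULL)
      if (is.null(llc) || !is.finite(llc$loglik) ||
          llc$loglik < llg$loglik - 1e-8) break
      theta <- cand; llg <- llc
      neg2ll <- -2 * llg$loglik
      gnorm <- max(abs(llg$grad[free])) / (1 + abs(llg$loglik))
      if (gnorm < control$grad_tol) break
    }
  }
  converged <- inner_ok && gnorm < control$grad_tol

  # --- standard errors (delta method to the natural scale) ----------------
  pars <- theta_to_pars(theta, p1, p2, colnames(md$X1), colnames(md$X2))
  nat_names <- c(paste0("b1_", colnames(md$X1)), paste0("b2_", colnames(md$X2)),
                 "sigma", "delta", "s11", "s22", "s12")
  est_nat <- c(pars$beta1, pars$beta2, pars$sigma, pars$delta,
               pars$s11, pars$s22, pars$s12)
  names(est_nat) <- nat_names
  se_nat <- rep(NA_real_, length(est_nat))
  vcov_nat <- matrix(NA_real_, length(est_nat), length(est_nat),
                     dimnames = list(nat_names, nat_names))
  if (control$se) {
    H <- fd_hessian(function(th_free)
      -eval_loglik(md, embed(th_free), p1, p2, pl, rule, link,
                   want_grad = TRUE)$grad[free], theta[free])
    Vf <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
    if (is.null(Vf) || any(!is.finite(Vf)) || any(diag(Vf) < 0)) {
      warning("singular or indefinite Hessian: standard errors reported as missing")
    } else {
      V <- matrix(0, p1 + p2 + 5, p1 + p2 + 5)
      V[free, free] <- Vf
      J <- nat_jacobian(theta, p1, p2)
      vcov_nat <- J %*% V %*% t(J)
      dimnames(vcov_nat) <- list(nat_names, nat_names)
      se_nat <- sqrt(pmax(diag(vcov_nat), 0))
      if (fixed_delta) se_nat[p1 + p2 + 2] <- NA_real_
      names(se_nat) <- nat_names
    }
  }

  structure(list(call = cl, formula = formula, f1 = md$f1, f2 = md$f2,
                 subject_col = subject, link = link,
                 pars = pars, theta = theta, free = free,
                 fixed_delta = if (fixed_delta) delta else NULL,
                 estimates = est_nat, se = se_nat, vcov = vcov_nat,
                 neg2ll = neg2ll,
                 n_params = sum(free), n_subjects = length(md$subjects),
                 n_obs = length(md$y),
                 aic = neg2ll + 2 * sum(free),
                 bic = neg2ll + sum(free) * log(length(md$subjects)),
                 converged = converged, n_iter = n_iter, grad_norm = gnorm,
                 control = control, rule = rule, placement = pl,
                 data_fingerprint = data_fingerprint(md),
                 md = md),
            class = "snhurdle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

data_fingerprint <- function(md) {
  c(n_obs = length(md$y), n_subjects = length(md$subjects),
    sum_y = sum(md$y), sum_pos = sum(md$y > 0))
}

# stage 1: no-random-effects probit/log-SN fit for starting values
stage1_start <- function(md, link, fixed_delta = NULL) {
  g <- glm.fit(md$X1, as.numeric(md$y > 0),
               family = binomial(link = link))
  b1 <- coef(g)
  b1[!is.finite(b1)] <- 0
  pos <- md$y > 0
  v <- md$logy[pos]
  X2p <- md$X2[pos, , drop = FALSE]
  lf <- lm.fit(X2p, v)
  b2 <- lf$coefficients
  b2[!is.finite(b2)] <- 0
  res <- lf$residuals
  s <- sd(res)
  skew <- mean(res^3) / s^3
  d0 <- if (!is.null(fixed_delta)) fixed_delta else sign(skew) * 0.5 * s
  if (d0 == 0 && is.null(fixed_delta)) d0 <- 1e-3
  sn_nll <- function(par) {
    b <- par[seq_len(ncol(X2p))]
    -sum(dskewnorm(v, drop(X2p %*% b), exp(par[ncol(X2p) + 1]),
                   if (is.null(fixed_delta)) par[ncol(X2p) + 2] else fixed_delta,
                   log = TRUE))
  }
  p0 <- c(b2, log(0.8 * s), if (is.null(fixed_delta)) d0)
  o <- tryCatch(optim(p0, sn_nll, method = "BFGS",
                      control = list(maxit = 200)),
                error = function(e) list(par = p0))
  b2 <- o$par[seq_len(ncol(X2p))]
  lsig <- o$par[ncol(X2p) + 1]
  dlt <- if (is.null(fixed_delta)) o$par[ncol(X2p) + 2] else fixed_delta
  # stage 2 random-effects starts
  c(b1, b2, lsig, dlt, log(0.5), log(0.5), 0)
}

# central-difference Jacobian of a gradient function = Hessian
fd_hessian <- function(grad_fn, x, eps = NULL) {
  p <- length(x)
  if (is.null(eps)) eps <- pmax(abs(x), 1) * .Machine$double.eps^(1 / 3)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    xp <- x; xp[j] <- xp[j] + eps[j]
    xm <- x; xm[j] <- xm[j] - eps[j]
    H[, j] <- (grad_fn(xp) - grad_fn(xm)) / (2 * eps[j])
  }
  H
}

# Jacobian of the natural-scale parameter vector w.r.t. theta
nat_jacobian <- function(theta, p1, p2) {
  np <- p1 + p2 + 5
  J <- diag(np)
  sigma <- exp(theta[p1 + p2 + 1])
  s11 <- exp(theta[p1 + p2 + 3]); s22 <- exp(theta[p1 + p2 + 4])
  rho <- tanh(theta[p1 + p2 + 5])
  J[p1 + p2 + 1, p1 + p2 + 1] <- sigma
  J[p1 + p2 + 3, p1 + p2 + 3] <- s11
  J[p1 + p2 + 4, p1 + p2 + 4] <- s22
  s12 <- rho * sqrt(s11 * s22)
  J[p1 + p2 + 5, p1 + p2 + 3] <- s12 / 2
  J[p1 + p2 + 5, p1 + p2 + 4] <- s12 / 2
  J[p1 + p2 + 5, p1 + p2 + 5] <- (1 - rho^2) * sqrt(s11 * s22)
  J
}
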