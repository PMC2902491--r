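#' @export
print.snhurdle <- function(x, ...) {
  cat("Two-part", x$link, "/ log-skew-normal hurdle model",
      if (!is.null(x$fixed_delta)) sprintf("(delta fixed at %g)", x$fixed_delta),
      "\n")
  cat("  subjects:", x$n_subjects, "  observations:", x$n_obs,
      "  zero fraction:",
      sprintf("%.3f", 1 - x$data_fingerprint["sum_pos"] / x$n_obs), "\n")
  cat("  -2 log-likelihood:", format(x$neg2ll, digits = 7),
      "  AIC:", format(x$aic, digits = 7),
      "  BIC:", format(x$bic, digits = 7), "\n")
  cat("  converged:", x$converged, " (", x$n_iter, "iterations, grad norm",
      format(x$grad_norm, digits = 3), ")\n\n")
  print(x$estimates)
  invisible(x)
}

star_code <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "***",
                              ifelse(p < 0.05, "**", ifelse(p < 0.10, "*", ""))))
}

#' Summarize a fitted snhurdle model
#'
#' Produces the per-parameter table of estimates, standard errors, Wald z
#' statistics and two-sided normal p-values, with significance stars at
#' the 0.10 / 0.05 / 0.01 levels, together with the fit statistics. The
#' Wald test for `delta` relies on the Sahu-Dey-Branco parameterization
#' being regular at `delta = 0`.
#'
#' @param object a fitted [snhurdle()] model.
#' @param ... unused.
#' @return a list of class `"summary.snhurdle"`.
#' @export
summary.snhurdle <- function(object, ...) {
  wt <- wald_tests(object)
  structure(list(fit = object, table = wt), class = "summary.snhurdle")
}

#' @export
print.summary.snhurdle <- function(x, ...) {
  f <- x$fit
  cat("Two-part", f$link, "/ log-skew-normal hurdle model\n")
  cat("Formula:", deparse(f$formula), "  subjects:", f$n_subjects, "\n\n")
  tab <- x$table
  out <- data.frame(
    estimate = sprintf("%.4g", tab$estimate),
    se = ifelse(is.na(tab$se), "-", sprintf("(%.4g)", tab$se)),
    z = ifelse(is.na(tab$z), "-", sprintf("%.3f", tab$z)),
    p = ifelse(is.na(tab$p), "-", format.pval(tab$p, digits = 3)),
    " " = star_code(tab$p), check.names = FALSE)
  rownames(out) <- tab$parameter
  print(out)
  cat("---  * p < 0.10  ** p < 0.05  *** p < 0.01\n")
  cat(sprintf("\n-2 Log Likelihood %.1f   AIC %.1f   BIC %.1f   (k = %d, n = %d)\n",
              f$neg2ll, f$aic, f$bic, f$n_params, f$n_subjects))
  if (!f$converged) cat("WARNING: optimizer did not satisfy the convergence criteria\n")
  invisible(x)
}

#' @export
coef.snhurdle <- function(object, ...) object$estimates

#' @export
vcov.snhurdle <- function(object, ...) object$vcov

#' @export
logLik.snhurdle <- function(object, ...) {
  structure(-object$neg2ll / 2, df = object$n_params,
            nobs = object$n_obs, class = "logLik")
}

#' Predictions from a fitted two-part skew-normal hurdle model
#'
#' For each row of `newdata` returns the probability of a positive
#' response, its complement (the probability of being symptom free) and
#' the expected log-severity given a positive response,
#' \eqn{E[\log Y \mid Y > 0] = x_2'\beta_2 + \delta\sqrt{2/\pi}}.
#' `mode = "conditional"` evaluates at random effects equal to zero;
#' `mode = "marginal"` integrates the positivity probability over the
#' estimated random-intercept distribution by Gauss-Hermite quadrature
#' (the expected log-severity is linear in \eqn{\tau_1}, so its marginal
#' and conditional values coincide). Marginal probabilities are pulled
#' towards 1/2 relative to conditional ones.
#'
#' @param object a fitted [snhurdle()] model.
#' @param newdata data frame with the model covariates; defaults to the
#'   fitting data.
#' @param mode `"conditional"` (random effects at zero) or `"marginal"`.
#' @param ... unused.
#' @return data frame with columns `p_positive`, `p_symptom_free`,
#'   `mean_log_severity`.
#' @export
predict.snhurdle <- function(object, newdata = NULL,
                             mode = c("conditional", "marginal"), ...) {
  mode <- match.arg(mode)
  md <- object$md
  if (is.null(newdata)) {
    X1 <- md$X1; X2 <- md$X2
  } else {
    t1 <- delete.response(terms(object$f1))
    t2 <- delete.response(terms(object$f2))
    X1 <- model.matrix(t1, model.frame(t1, newdata, na.action = na.fail))
    X2 <- model.matrix(t2, model.frame(t2, newdata, na.action = na.fail))
    if (!all(colnames(X1) == colnames(md$X1)) ||
        !all(colnames(X2) == colnames(md$X2)))
      stop("newdata does not provide the model covariates")
  }
  pars <- object$pars
  eta <- drop(X1 %*% pars$beta1)
  if (mode == "conditional") {
    p <- if (object$link == "probit") pnorm(eta) else plogis(eta)
  } else {
    r <- gh_rule(31)
    tau <- r$nodes * sqrt(pars$s11)
    pm <- vapply(tau, function(t0)
      if (object$link == "probit") pnorm(eta + t0) else plogis(eta + t0),
      numeric(length(eta)))
    p <- drop(matrix(pm, ncol = length(tau)) %*% r$weights)
  }
  mls <- drop(X2 %*% pars$beta2) + pars$delta * sqrt(2 / pi)
  data.frame(p_positive = p, p_symptom_free = 1 - p, mean_log_severity = mls)
}

#' Simulate responses from a fitted snhurdle model
#'
#' Draws complete response vectors from the fitted two-part model at the
#' fitting covariates: per subject a bivariate-normal random-intercept
#' pair, per occasion a Bernoulli positivity indicator through the fitted
#' link and, when positive, `exp` of a skew-normal draw.
#'
#' @param object a fitted [snhurdle()] model.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data frame with one column per simulation, rows aligned to the
#'   (subject-sorted) fitting data.
#' @export
simulate.snhurdle <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  md <- object$md
  pars <- object$pars
  n <- length(md$subjects)
  L <- chol2_lower(pars$S)
  out <- matrix(0, nrow = length(md$y), ncol = nsim)
  eta0 <- drop(md$X1 %*% pars$beta1)
  mu0 <- drop(md$X2 %*% pars$beta2)
  for (s in seq_len(nsim)) {
    z <- matrix(rnorm(2 * n), n, 2)
    tau0 <- L[1] * z[, 1]
    tau1 <- L[2] * z[, 1] + L[3] * z[, 2]
    i <- rep(seq_len(n), md$sub_len)
    eta <- eta0 + tau0[i]
    p <- if (object$link == "probit") pnorm(eta) else plogis(eta)
    pos <- rbinom(length(p), 1, p) == 1
    y <- numeric(length(p))
    if (any(pos))
      y[pos] <- exp(rskewnorm(sum(pos), mu0[pos] + tau1[i][pos],
                              pars$sigma, pars$delta))
    out[, s] <- y
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Residuals of a fitted snhurdle model
#'
#' Two-part models admit no single natural residual; two diagnostics are
#' offered. `type = "binary"` returns the Pearson residual of the
#' positivity indicator against the conditional (tau = 0) probability;
#' `type = "severity"` returns, for positive responses only, the
#' standardized log-scale residual
#' \eqn{(\log y - \hat{E}[\log Y \mid Y>0]) / \widehat{sd}}.
#'
#' @param object a fitted [snhurdle()] model.
#' @param type `"binary"` or `"severity"`.
#' @param ... unused.
#' @export
residuals.snhurdle <- function(object, type = c("binary", "severity"), ...) {
  type <- match.arg(type)
  md <- object$md
  pr <- predict(object, mode = "conditional")
  if (type == "binary") {
    (as.numeric(md$y > 0) - pr$p_positive) /
      sqrt(pr$p_positive * (1 - pr$p_positive))
  } else {
    pos <- md$y > 0
    mom <- skewnorm_moments(0, object$pars$sigma, object$pars$delta)
    (md$logy[pos] - pr$mean_log_severity[pos]) / sqrt(mom$var + object$pars$s22)
  }
}

#' Diagnostic plot for a fitted snhurdle model
#'
#' Left panel: histogram of log positive responses with the fitted
#' marginal skew-normal severity density (integrated over the
#' random-intercept distribution) overlaid at the average severity linear
#' predictor. Right panel: observed zero fraction against fitted
#' conditional positivity probability, binned into deciles.
#'
#' @param x a fitted [snhurdle()] model.
#' @param ... passed to [graphics::hist()].
#' @export
plot.snhurdle <- function(x, ...) {
  md <- x$md
  pos <- md$y > 0
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  v <- md$logy[pos]
  h <- hist(v, freq = FALSE, main = "log positive responses",
            xlab = "log y", ...)
  mu_bar <- mean(drop(md$X2[pos, , drop = FALSE] %*% x$pars$beta2))
  grid <- seq(min(v), max(v), length.out = 200)
  # marginal over tau1: SN convolved with N(0, s22) == SN with inflated sigma
  dens <- dskewnorm(grid, mu_bar, sqrt(x$pars$sigma^2 + x$pars$s22), x$pars$delta)
  lines(grid, dens, lwd = 2)
  pr <- predict(x, mode = "marginal")
  br <- unique(quantile(pr$p_positive, 0:10 / 10))
  bin <- cut(pr$p_positive, br, include.lowest = TRUE)
  obs <- tapply(as.numeric(md$y > 0), bin, mean)
  fitm <- tapply(pr$p_positive, bin, mean)
  plot(fitm, obs, xlab = "fitted P(Y > 0)", ylab = "observed fraction positive",
       main = "calibration (deciles)")
  abline(0, 1, lty = 2)
  invisible(x)
}

#' @importFrom stats quantile
#' @importFrom graphics lines plot
NULL
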