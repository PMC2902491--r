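#' Parameter set of the two-part skew-normal hurdle model
#'
#' Bundles and validates the full parameter vector of the model: the
#' binary-part coefficients `beta1`, the severity-part coefficients
#' `beta2`, the skew-normal scale `sigma` and skewness `delta`, and the
#' random-intercept covariance entries `s11` (binary part variance),
#' `s22` (severity part variance) and `s12` (their covariance). The
#' covariance matrix `[[s11, s12], [s12, s22]]` must be symmetric
#' positive definite.
#'
#' @param beta1 named or unnamed numeric vector, binary-part coefficients.
#' @param beta2 numeric vector, severity-part coefficients.
#' @param sigma positive scalar, skew-normal scale.
#' @param delta real scalar, skew-normal skewness.
#' @param s11,s22,s12 random-effects covariance entries.
#' @return An object of class `"snhurdle_pars"`.
#' @export
snhurdle_pars <- function(beta1, beta2, sigma, delta, s11, s22, s12 = 0) {
  check_sn_params(0, sigma, delta)
  S <- matrix(c(s11, s12, s12, s22), 2, 2)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(S)) || min(ev) <= 0)
    stop("random-effects covariance [[s11, s12], [s12, s22]] must be positive definite")
  structure(list(beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
                 sigma = sigma, delta = delta,
                 s11 = s11, s22 = s22, s12 = s12, S = S),
            names_beta1 = names(beta1), names_beta2 = names(beta2),
            class = "snhurdle_pars")
}

#' Probability of a positive response given the random intercept
#'
#' The binary part of the hurdle model:
#' \eqn{P(Y_{ij} > 0 \mid \tau_{0i}) = g^{-1}(x_{1ij}'\beta_1 + \tau_{0i})}
#' with \eqn{g^{-1} = \Phi} for the probit link or the logistic CDF for the
#' logit link. The linear predictor drives the probability of *having*
#' symptoms; the probability of being symptom free is its complement.
#'
#' @param x1 covariate vector (or matrix with one row per observation) of
#'   the binary part.
#' @param beta1 coefficient vector, same length as `ncol(x1)`.
#' @param tau0 subject random intercept (scalar or one per row).
#' @param link `"probit"` or `"logit"`.
#' @return probabilities in (0, 1).
#' @examples
#' prob_positive(c(1, 1), c(-1, 2.5))  # Phi(1.5) = 0.9332
#' @export
prob_positive <- function(x1, beta1, tau0 = 0, link = c("probit", "logit")) {
  link <- match.arg(link)
  if (!is.matrix(x1)) x1 <- matrix(x1, nrow = 1)
  if (ncol(x1) != length(beta1))
    stop("dimension mismatch: ncol(x1) = ", ncol(x1), ", length(beta1) = ", length(beta1))
  eta <- drop(x1 %*% beta1) + tau0
  if (link == "probit") pnorm(eta) else plogis(eta)
}

#' Log-density of one observation given the random effects
#'
#' The two-branch mixture density of the hurdle model, conditional on the
#' subject's random intercepts `(tau0, tau1)`: a zero response contributes
#' `log(1 - p)` and a positive response contributes
#' `log p + log f_SN(log y; mu, sigma, delta)` with
#' `p = prob_positive(x1, beta1, tau0, link)` and
#' `mu = x2' beta2 + tau1`. The severity density is taken on the log-scale
#' response (no 1/y Jacobian), which is the scale on which nested
#' log-normal and log-skew-normal severity fits are compared; the constant
#' Jacobian would cancel in every such comparison.
#'
#' @param y non-negative response (vectorized).
#' @param x1,x2 covariate vectors, or matrices with `length(y)` rows.
#' @param pars an [snhurdle_pars()] object.
#' @param tau0,tau1 random intercepts of the two parts.
#' @param link `"probit"` or `"logit"`.
#' @return log-density, one value per response.
#' @export
obs_logdensity <- function(y, x1, x2, pars, tau0 = 0, tau1 = 0,
                           link = c("probit", "logit")) {
  link <- match.arg(link)
  stopifnot(inherits(pars, "snhurdle_pars"))
  if (any(!is.finite(y)) || any(y < 0)) stop("responses must be finite and non-negative")
  if (!is.matrix(x1)) x1 <- matrix(x1, nrow = 1)[rep(1L, length(y)), , drop = FALSE]
  if (!is.matrix(x2)) x2 <- matrix(x2, nrow = 1)[rep(1L, length(y)), , drop = FALSE]
  eta <- drop(x1 %*% pars$beta1) + tau0
  lp1 <- if (link == "probit") pnorm(eta, log.p = TRUE) else plogis(eta, log.p = TRUE)
  lp0 <- if (link == "probit") pnorm(-eta, log.p = TRUE) else plogis(-eta, log.p = TRUE)
  mu <- drop(x2 %*% pars$beta2) + tau1
  out <- lp0
  pos <- y > 0
  if (any(pos))
    out[pos] <- lp1[pos] +
      dskewnorm(log(y[pos]), mu[pos], pars$sigma, pars$delta, log = TRUE)
  out
}

# --- two-part formula handling -------------------------------------------

# split `y ~ a + b | c + d` into component formulas; a single right-hand
# side is shared by both parts
split_two_part_formula <- function(formula) {
  if (length(formula) != 3L) stop("formula must have a response")
  rhs <- formula[[3]]
  env <- environment(formula)
  if (is.call(rhs) && identical(rhs[[1]], as.name("|"))) {
    f1 <- formula; f1[[3]] <- rhs[[2]]
    f2 <- formula; f2[[3]] <- rhs[[3]]
  } else {
    f1 <- f2 <- formula
  }
  environment(f1) <- environment(f2) <- env
  list(f1 = f1, f2 = f2)
}

# construct response, design matrices and subject index from data;
# rows are reordered so that each subject's observations are contiguous
build_model_data <- function(formula, data, subject) {
  if (!is.character(subject) || length(subject) != 1L)
    stop("'subject' must be the name of a column in 'data'")
  if (!subject %in% names(data)) stop("unknown subject column: ", subject)
  ff <- split_two_part_formula(formula)
  mf1 <- model.frame(ff$f1, data = data, na.action = na.fail)
  mf2 <- model.frame(ff$f2, data = data, na.action = na.fail)
  y <- model.response(mf1)
  if (any(!is.finite(y)) || any(y < 0))
    stop("response must be finite and non-negative (drop missing rows upstream)")
  X1 <- model.matrix(ff$f1, mf1)
  X2 <- model.matrix(ff$f2, mf2)
  id <- data[[subject]]
  ord <- order(match(id, unique(id)))
  y <- y[ord]; X1 <- X1[ord, , drop = FALSE]; X2 <- X2[ord, , drop = FALSE]
  id <- id[ord]
  runs <- rle(as.character(id))
  len <- runs$lengths
  start <- cumsum(c(0L, len[-length(len)]))
  list(y = as.numeric(y), logy = ifelse(y > 0, log(pmax(y, 1e-300)), 0),
       X1 = X1, X2 = X2, subject = as.character(id),
       subjects = runs$values, sub_start = as.integer(start),
       sub_len = as.integer(len), order = ord,
       formula = formula, f1 = ff$f1, f2 = ff$f2)
}

#' @importFrom stats model.response
NULL
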