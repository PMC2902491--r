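#' Wald tests for all parameters of a fitted snhurdle model
#'
#' Computes `z = estimate / se` and the two-sided normal p-value for every
#' reported parameter. Parameters whose standard error is unavailable
#' (e.g. a fixed skewness parameter, or after a singular Hessian) are
#' flagged with `NA`.
#'
#' @param fit a fitted [snhurdle()] model.
#' @return data frame with columns `parameter`, `estimate`, `se`, `z`,
#'   `p` and `stars`.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "snhurdle"))
  est <- fit$estimates
  se <- fit$se
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  data.frame(parameter = names(est), estimate = unname(est),
             se = unname(se), z = unname(z), p = unname(p),
             stars = star_code(unname(p)), stringsAsFactors = FALSE)
}

#' Likelihood-ratio test for zero skewness
#'
#' Tests \eqn{H_0: \delta = 0} by comparing the full skew-normal fit
#' against the nested probit/log-normal submodel (obtained with
#' `snhurdle(..., delta = 0)`) fitted to the same data with the same
#' quadrature settings. The statistic is the difference in -2
#' log-likelihood, referred to a chi-square distribution with one degree
#' of freedom. In the Sahu-Dey-Branco parameterization the likelihood is
#' regular at \eqn{\delta = 0} (no singular information), so the regular
#' chi-square reference is used; with other skew-normal
#' parameterizations this test could require boundary corrections.
#'
#' @param fit_sn the full model fit (free `delta`).
#' @param fit_lognormal the `delta = 0` submodel fit on the same data.
#' @return list with `statistic`, `df` and `p`.
#' @export
lrt_delta_zero <- function(fit_sn, fit_lognormal) {
  stopifnot(inherits(fit_sn, "snhurdle"), inherits(fit_lognormal, "snhurdle"))
  if (!isTRUE(all.equal(fit_sn$data_fingerprint,
                        fit_lognormal$data_fingerprint)))
    stop("the two fits are not on the same data")
  if (is.null(fit_lognormal$fixed_delta) ||
      fit_lognormal$fixed_delta != 0)
    stop("'fit_lognormal' must be the delta = 0 submodel")
  stat <- fit_lognormal$neg2ll - fit_sn$neg2ll
  list(statistic = stat, df = 1L,
       p = pchisq(max(stat, 0), df = 1, lower.tail = FALSE))
}

#' Information criteria for a maximized marginal likelihood
#'
#' `AIC = -2LL + 2k` and `BIC = -2LL + k log(n)` where `k` is the number
#' of free parameters and `n` is the number of subjects (the independent
#' sampling units of the marginal likelihood), not the number of
#' observations.
#'
#' @param neg2ll minimized -2 log-likelihood.
#' @param n_params number of free parameters.
#' @param n_subjects number of subjects.
#' @return named vector `c(aic = , bic = )`.
#' @examples
#' information_criteria(14056, 21, 190)  # aic 14098, bic ~14166
#' @export
information_criteria <- function(neg2ll, n_params, n_subjects) {
  stopifnot(n_params >= 0, n_subjects >= 1)
  c(aic = neg2ll + 2 * n_params, bic = neg2ll + n_params * log(n_subjects))
}
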