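test_that("Wald tests are estimate/se referred to the standard normal", {
  fit <- fake_fit(estimates = c(b_virus = 2.459, b_null = 0, b_male = -0.1286),
                  se = c(0.126, 0.5, 0.076))
  wt <- wald_tests(fit)
  expect_equal(wt$z[1], 2.459 / 0.126, tolerance = 1e-12)
  expect_equal(wt$z[1], 19.52, tolerance = 1e-3)
  expect_lt(wt$p[1], 1e-4)
  expect_equal(wt$stars[1], "***")
  expect_equal(wt$p[2], 1)
  expect_equal(wt$p[3], 0.0906, tolerance = 2e-3)
  expect_equal(wt$stars[3], "*")
  # missing se flagged rather than invented
  fit2 <- fake_fit(estimates = c(a = 1), se = NA_real_)
  expect_true(is.na(wald_tests(fit2)$p))
})

test_that("likelihood-ratio test arithmetic and contracts", {
  sn <- fake_fit(c(d = -1), neg2ll = 14056)
  ln <- fake_fit(c(d = 0), neg2ll = 14066, fixed_delta = 0)
  lr <- lrt_delta_zero(sn, ln)
  expect_equal(lr$statistic, 10)
  expect_equal(lr$df, 1L)
  expect_lt(lr$p, 0.005)
  expect_equal(lr$p, pchisq(10, 1, lower.tail = FALSE), tolerance = 1e-12)
  # identical models give statistic 0, p 1
  same <- lrt_delta_zero(fake_fit(c(d = 0), neg2ll = 100),
                         fake_fit(c(d = 0), neg2ll = 100, fixed_delta = 0))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # mismatched data fingerprints are a contract error
  other <- fake_fit(c(d = 0), neg2ll = 50, fixed_delta = 0,
                    fingerprint = c(n_obs = 2, n_subjects = 1, sum_y = 1,
                                    sum_pos = 1))
  expect_error(lrt_delta_zero(sn, other), "same data")
  expect_error(lrt_delta_zero(sn, sn), "delta = 0")
})

test_that("information criteria use 2k and k log(n subjects)", {
  expect_equal(unname(information_criteria(14056, 21, 190)["aic"]), 14098)
  expect_equal(round(unname(information_criteria(14056, 21, 190)["bic"])), 14166)
  expect_equal(unname(information_criteria(14066, 20, 190)["aic"]), 14106)
  expect_equal(round(unname(information_criteria(14066, 20, 190)["bic"])), 14171)
  expect_equal(unname(information_criteria(123.4, 0, 50)["aic"]), 123.4)
  expect_equal(unname(information_criteria(123.4, 0, 50)["bic"]), 123.4)
})

test_that("freezing delta at zero reproduces a direct probit/log-normal fit", {
  d <- small_sn_data(101, n_subjects = 25, n_occasions = 6, delta = -0.6)
  ctl <- snhurdle_control(points = 41, adaptive = FALSE, se = FALSE,
                          warmup = FALSE)
  fit0 <- snhurdle(y ~ x | x, data = d, subject = "subject", delta = 0,
                   control = ctl)
  expect_true(fit0$converged)
  expect_equal(fit0$n_params, 8L)  # 2 + 2 + sigma + 3 covariance entries
  # independent plain-R implementation of the log-normal submodel,
  # started from crude moment-based values
  g <- glm(I(y > 0) ~ x, binomial("probit"), data = d)
  l <- lm(log(y) ~ x, data = d[d$y > 0, ])
  start <- c(coef(g), coef(l), log(summary(l)$sigma),
             log(0.5), log(0.5), 0)
  oracle <- fit_lognormal_oracle(d, points = 41, start = unname(start))
  expect_lt(abs(fit0$neg2ll - oracle$neg2ll), 1e-6)
  # the free-delta fit is nested above the submodel
  fit1 <- snhurdle(y ~ x | x, data = d, subject = "subject", control = ctl)
  expect_lte(fit1$neg2ll, fit0$neg2ll + 1e-6)
  lr <- lrt_delta_zero(fit1, fit0)
  expect_gte(lr$statistic, -1e-6)
})

test_that("the optimum is stable across starting values", {
  d <- small_sn_data(202, n_subjects = 40, n_occasions = 8)
  f1 <- snhurdle(y ~ x | x, data = d, subject = "subject",
                 control = fast_control())
  start <- snhurdle_pars(c(-0.6, 1.7), c(-0.35, 0.8), 0.7, -1.0,
                         0.6, 0.3, 0.1)
  f2 <- snhurdle(y ~ x | x, data = d, subject = "subject", start = start,
                 control = fast_control())
  expect_true(f1$converged && f2$converged)
  expect_lt(abs(f1$neg2ll - f2$neg2ll), 1e-4)
})

test_that("reported fit statistics satisfy their defining identities", {
  d <- small_sn_data(303, n_subjects = 30, n_occasions = 6)
  fit <- snhurdle(y ~ x | x, data = d, subject = "subject",
                  control = fast_control(se = TRUE))
  expect_equal(fit$aic, fit$neg2ll + 2 * fit$n_params)
  expect_equal(fit$bic, fit$neg2ll + fit$n_params * log(fit$n_subjects))
  expect_equal(unname(fit$se), unname(sqrt(diag(fit$vcov))), tolerance = 1e-10)
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
  expect_equal(unname(coef(fit)["s11"]) > 0, TRUE)
  expect_s3_class(summary(fit), "summary.snhurdle")
  expect_output(print(summary(fit)), "-2 Log Likelihood")
  expect_equal(as.numeric(logLik(fit)), -fit$neg2ll / 2)
})

test_that("predictions follow the closed forms and marginal shrinkage", {
  d <- small_sn_data(404, n_subjects = 20, n_occasions = 4)
  fit <- snhurdle(y ~ x | x, data = d, subject = "subject",
                  control = fast_control())
  # white-box substitution of exact parameter values for closed-form checks
  fit$pars <- snhurdle_pars(c(0, 0), c(0.3, 0), 0.8, -0.5, 1, 0.2, 0)
  nd <- data.frame(x = 0)
  pc <- predict(fit, nd, mode = "conditional")
  expect_equal(pc$p_positive, 0.5)
  expect_equal(pc$p_symptom_free, 0.5)
  expect_equal(pc$mean_log_severity, 0.3 - 0.5 * sqrt(2 / pi))
  # marginal probability at eta = -1, s11 = 1 is Phi(-1/sqrt(2)) = 0.2398
  fit$pars <- snhurdle_pars(c(-1, 0), c(0.3, 0), 0.8, -0.5, 1, 0.2, 0)
  pm <- predict(fit, nd, mode = "marginal")
  expect_equal(pm$p_positive, pnorm(-1 / sqrt(2)), tolerance = 1e-6)
  expect_equal(round(pm$p_positive, 4), 0.2398)
  # marginalization pulls probabilities towards 1/2
  nd2 <- data.frame(x = c(0, 1))
  fit$pars <- snhurdle_pars(c(-1, 2.5), c(0, 0.7), 0.8, -0.5, 1, 0.2, 0)
  pc2 <- predict(fit, nd2, mode = "conditional")
  pm2 <- predict(fit, nd2, mode = "marginal")
  expect_true(all(abs(pm2$p_positive - 0.5) < abs(pc2$p_positive - 0.5)))
  expect_error(predict(fit, data.frame(z = 1)), "z|covariates|object")
})

test_that("the likelihood-ratio test for zero skewness is calibrated under the null", {
  reps <- 200
  crit <- qchisq(0.95, df = 1)
  rej <- logical(reps)
  ok <- logical(reps)
  for (r in seq_len(reps)) {
    d <- simulate_snhurdle_data(n_subjects = 50, n_occasions = 8,
                                beta1 = c(-0.3, 1), beta2 = c(0, 0.5),
                                sigma = 0.7, delta = 0,
                                s11 = 0.6, s22 = 0.2, s12 = 0.1,
                                p_x = 0.3, seed = 42000 + r)
    res <- tryCatch({
      f0 <- snhurdle(y ~ x | x, data = d, subject = "subject", delta = 0,
                     control = fast_control())
      f1 <- snhurdle(y ~ x | x, data = d, subject = "subject",
                     control = fast_control())
      if (!(f0$converged && f1$converged)) NULL else
        lrt_delta_zero(f1, f0)$statistic
    }, error = function(e) NULL)
    if (!is.null(res)) {
      ok[r] <- TRUE
      rej[r] <- max(res, 0) > crit
    }
  }
  expect_gte(sum(ok), 0.9 * reps)
  rate <- mean(rej[ok])
  tol <- 3 * sqrt(0.05 * 0.95 / sum(ok))
  expect_lt(abs(rate - 0.05), tol + 1e-12)
})
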