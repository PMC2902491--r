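test_that("beta skewness formula: reference values, symmetry, antisymmetry", {
  expect_equal(round(beta_skewness(130, 70), 4), -0.0883)
  expect_equal(round(beta_skewness(70, 130), 4), 0.0883)
  expect_equal(beta_skewness(100, 100), 0)
  set.seed(8)
  for (i in 1:20) {
    a <- runif(1, 0.2, 50); b <- runif(1, 0.2, 50)
    expect_equal(beta_skewness(a, b), -beta_skewness(b, a))
    expect_equal(sign(beta_skewness(a, b)), sign(b - a))
  }
  # matches the moments of the Beta law (via known central moments)
  a <- 3; b <- 7
  m3 <- 2 * (b - a) * sqrt(a + b + 1) / ((a + b + 2) * sqrt(a * b))
  x <- rbeta(2e5, a, b)
  expect_equal(mean((x - mean(x))^3) / sd(x)^3, m3, tolerance = 0.05)
  expect_error(beta_skewness(0, 1), "positive")
  expect_error(beta_skewness(1, -2), "positive")
})

test_that("the probit/log-beta generator obeys its construction", {
  # scale = 0: all positives of a subject with the same x are identical,
  # and with negligible severity heterogeneity equal exp(alpha1 + beta1 x)
  scn <- sim_scenario(scale = 0, s22 = 1e-12, s12 = 0, p_x = 0.3,
                      n_subjects = 30, n_occasions = 20)
  d <- simulate_probit_logbeta(scn, seed = 5)
  pos <- d[d$y > 0, ]
  expect_gt(nrow(pos), 0)
  expect_equal(pos$y, exp(scn$alpha1 + scn$beta1 * pos$x), tolerance = 1e-4)
  # positivity rate at x = 0 marginal over tau0 ~ N(0,1): Phi(-1/sqrt(2));
  # one occasion per subject so the binomial standard error is exact
  scn2 <- sim_scenario(p_x = 0, n_subjects = 1e6, n_occasions = 1)
  d2 <- simulate_probit_logbeta(scn2, seed = 6)
  p <- mean(d2$y > 0)
  closed <- pnorm(-1 / sqrt(2))
  expect_lt(abs(p - closed), 3 * sqrt(closed * (1 - closed) / 1e6))
  # mean of log(Y | Y > 0) at x = 0, tau1 = 0: -20 + 30 * 130/200 = -0.5
  scn3 <- sim_scenario(p_x = 0, s22 = 1e-12, s12 = 0,
                       n_subjects = 1e5, n_occasions = 1)
  d3 <- simulate_probit_logbeta(scn3, seed = 7)
  lpos <- log(d3$y[d3$y > 0])
  expect_equal(-20 + 30 * 130 / 200, -0.5)
  expect_lt(abs(mean(lpos) - (-0.5)), 3 * sd(lpos) / sqrt(length(lpos)))
  # reproducibility
  expect_identical(simulate_probit_logbeta(scn, seed = 11),
                   simulate_probit_logbeta(scn, seed = 11))
})

test_that("scenario validation and packaged scenarios", {
  expect_error(sim_scenario(a = -1), "a > 0")
  expect_error(sim_scenario(s12 = 2), "positive definite")
  i <- builtin_scenario("i"); ii <- builtin_scenario("ii"); iii <- builtin_scenario("iii")
  expect_lt(beta_skewness(i$a, i$b), 0)
  expect_equal(beta_skewness(ii$a, ii$b), 0)
  expect_gt(beta_skewness(iii$a, iii$b), 0)
  expect_equal(i$n_subjects, 200)
  expect_equal(i$n_occasions, 50)
  expect_equal(i$n_reps, 200)
  expect_equal(i$p_x, 0.03)
})

test_that("study summarization: stub fitter, archive identity, determinism", {
  scn <- sim_scenario(n_subjects = 5, n_occasions = 4, n_reps = 8)
  truth <- c("b1_.Intercept." = scn$alpha0, "b1_x" = scn$beta0,
             "b2_.Intercept." = 0.2, "b2_x" = scn$beta1,
             sigma = 0.8, delta = -0.5,
             s11 = scn$s11, s22 = scn$s22, s12 = scn$s12)
  # stub returning exact truth: zero bias and zero MSE
  stub_truth <- function(data, control) list(estimates = truth, converged = TRUE)
  st <- run_scenario(scn, seed = 3, fitter = stub_truth)
  expect_true(all(st$table$bias == 0))
  expect_true(all(st$table$mse == 0))
  expect_equal(st$n_converged, 8)
  # severity intercept excluded from the table (not comparable), probit kept
  expect_false("b2_.Intercept." %in% st$table$parameter)
  expect_true("b1_.Intercept." %in% st$table$parameter)
  # noisy deterministic stub: mse = bias^2 + var*(R-1)/R identity
  stub_noisy <- function(data, control) {
    list(estimates = truth + sin(seq_along(truth) * sum(data$y)),
         converged = TRUE)
  }
  st2 <- run_scenario(scn, seed = 3, fitter = stub_noisy)
  for (k in seq_len(nrow(st2$table))) {
    p <- st2$table$parameter[k]
    e <- st2$archive[[p]][st2$archive$converged]
    R <- length(e)
    expect_equal(st2$table$mse[k],
                 st2$table$bias[k]^2 + var(e) * (R - 1) / R,
                 tolerance = 1e-12)
    expect_gte(st2$table$mse[k], st2$table$bias[k]^2)
  }
  # bit-identical reruns under the same master seed
  st3 <- run_scenario(scn, seed = 3, fitter = stub_noisy)
  expect_identical(st2$table, st3$table)
  expect_identical(st2$archive, st3$archive)
  # extending the replicate count preserves earlier replicate streams
  st4 <- run_scenario(scn, reps = 4, seed = 3, fitter = stub_noisy)
  expect_identical(st4$archive, st2$archive[1:4, ])
  # all-failure is an explicit error
  expect_error(run_scenario(scn, seed = 3,
                            fitter = function(d, c) stop("boom")),
               "no replicate")
})

test_that("the skew-normal companion generator hits its zero fraction", {
  # marginal positivity at x = 0: Phi(beta1_0 / sqrt(1 + s11))
  d <- simulate_snhurdle_data(n_subjects = 2e4, n_occasions = 1,
                              p_x = 0, seed = 17)
  p <- mean(d$y > 0)
  closed <- pnorm(-1 / sqrt(2))
  expect_lt(abs(p - closed), 3 * sqrt(closed * (1 - closed) / 2e4))
  # about 75% zeros at the study design, like the cohort it mirrors
  d2 <- simulate_snhurdle_data(seed = 18)
  expect_gt(mean(d2$y == 0), 0.70)
  expect_lt(mean(d2$y == 0), 0.80)
})
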