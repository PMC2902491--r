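# toy two-subject dataset used by several quadrature tests
toy_data <- function() {
  data.frame(subject = rep(1:2, each = 3),
             occasion = rep(1:3, 2),
             y = c(0, 1.4, 0.5, 0, 0, 2.1),
             x = c(0, 1, 0, 0, 1, 1))
}
toy_pars <- snhurdle_pars(c(-0.3, 1.2), c(0.1, 0.6), 0.7, -0.5,
                          s11 = 1, s22 = 0.2, s12 = 0.2)

test_that("the quadrature rule has normalized weights and polynomial exactness", {
  for (n in c(5, 9, 21)) {
    r <- gh_rule(n)
    expect_equal(sum(r$weights), 1, tolerance = 1e-12)
    # exact standard-normal moments up to degree 2n - 1
    moments <- c(1, 0, 1, 0, 3, 0, 15, 0, 105)
    for (k in seq_len(min(2 * n - 1, 8))) {
      expect_equal(sum(r$weights * r$nodes^k), moments[k + 1],
                   tolerance = 1e-8, label = sprintf("moment %d at n=%d", k, n))
    }
  }
})

test_that("degenerate random effects recover the fixed-effects density", {
  d <- data.frame(subject = 1, occasion = 1, y = 0, x = 0)
  pars <- snhurdle_pars(c(0, 1), c(0, 1), 1, 0, 1e-12, 1e-12, 0)
  ll <- two_part_loglik(pars, d, y ~ x | x, "subject", rule = gh_rule(15))
  expect_equal(ll, log(0.5), tolerance = 1e-4)
})

test_that("quadrature matches brute-force Monte-Carlo integration on the toy", {
  d <- toy_data()
  X <- cbind(1, d$x)
  set.seed(31415)
  mc <- vapply(1:2, function(i) {
    rows <- d$subject == i
    mc_subject_loglik(d$y[rows], X[rows, ], X[rows, ], toy_pars$beta1,
                      toy_pars$beta2, toy_pars$sigma, toy_pars$delta,
                      toy_pars$S, n_draws = 1e6)
  }, numeric(1))
  for (r in list(gh_rule(25), gh_rule(7, adaptive = TRUE))) {
    got <- two_part_loglik(toy_pars, d, y ~ x | x, "subject",
                           rule = r, by_subject = TRUE)
    expect_lt(max(abs(unname(got) - mc)), 1e-3)
  }
})

test_that("quadrature is self-convergent and error decreases with the point count", {
  d <- toy_data()
  ll <- function(n) two_part_loglik(toy_pars, d, y ~ x | x, "subject",
                                    rule = gh_rule(n))
  expect_lt(abs(ll(25) - ll(50)), 1e-6)
  ref <- ll(51)
  err <- abs(vapply(c(5, 11, 21, 31), ll, numeric(1)) - ref)
  expect_true(all(diff(err) <= 1e-9))  # monotone up to the noise floor
})

test_that("the total log-likelihood is a subject-wise sum with the expected invariances", {
  d <- toy_data()
  base <- two_part_loglik(toy_pars, d, y ~ x | x, "subject")
  bys <- two_part_loglik(toy_pars, d, y ~ x | x, "subject", by_subject = TRUE)
  expect_equal(sum(bys), base, tolerance = 1e-12)
  # permutation invariance
  perm <- d[c(4:6, 1:3), ]
  expect_lt(abs(two_part_loglik(toy_pars, perm, y ~ x | x, "subject") - base),
            1e-12)
  # duplicating every subject doubles the log-likelihood
  dup <- rbind(d, transform(d, subject = subject + 10))
  expect_equal(two_part_loglik(toy_pars, dup, y ~ x | x, "subject"),
               2 * base, tolerance = 1e-10)
  expect_error(two_part_loglik(toy_pars, d[0, ], y ~ x | x, "subject"))
})

test_that("vanishing random-effect variances recover the no-random-effects likelihood", {
  d <- toy_data()
  X <- cbind(1, d$x)
  pars0 <- snhurdle_pars(toy_pars$beta1, toy_pars$beta2, toy_pars$sigma,
                         toy_pars$delta, 1e-10, 1e-10, 0)
  fixed <- sum(obs_logdensity(d$y, X, X, pars0))
  got <- two_part_loglik(pars0, d, y ~ x | x, "subject", rule = gh_rule(15))
  expect_lt(abs(got - fixed), 1e-4)
})

test_that("an all-zero subject's likelihood does not depend on the severity variance", {
  d <- data.frame(subject = 1, occasion = 1:4, y = 0, x = c(0, 1, 0, 0))
  ll <- function(s22) {
    p <- snhurdle_pars(toy_pars$beta1, toy_pars$beta2, toy_pars$sigma,
                       toy_pars$delta, s11 = 1, s22 = s22, s12 = 0)
    two_part_loglik(p, d, y ~ x | x, "subject", rule = gh_rule(15))
  }
  expect_lt(abs(ll(0.2) - ll(0.9)), 1e-10)
})

test_that("the compiled engine agrees with the plain-R engine on both links", {
  d <- small_sn_data(7, n_subjects = 8, n_occasions = 5)
  pars <- snhurdle_pars(c(-0.4, 1.3), c(-0.2, 0.5), 0.65, -0.6,
                        0.7, 0.3, 0.1)
  for (link in c("probit", "logit")) {
    for (r in list(gh_rule(9), gh_rule(5, adaptive = TRUE))) {
      a <- two_part_loglik(pars, d, y ~ x | x, "subject", rule = r,
                           link = link, engine = "cpp")
      b <- two_part_loglik(pars, d, y ~ x | x, "subject", rule = r,
                           link = link, engine = "R")
      expect_equal(a, b, tolerance = 1e-12)
    }
  }
})

test_that("the analytic gradient matches central finite differences", {
  d <- small_sn_data(13, n_subjects = 10, n_occasions = 6)
  md <- snhurdle:::build_model_data(y ~ x | x, d, "subject")
  theta <- c(-0.6, 1.4, -0.25, 0.55, log(0.62), -0.7, log(0.75), log(0.22), 0.25)
  for (link in c("probit", "logit")) {
    rule <- gh_rule(7, adaptive = TRUE)
    pl <- snhurdle:::place_nodes(md, snhurdle:::theta_to_pars(theta, 2, 2),
                                 rule, link)
    f <- function(th)
      snhurdle:::eval_loglik(md, th, 2, 2, pl, rule, link)$loglik
    g <- snhurdle:::eval_loglik(md, theta, 2, 2, pl, rule, link,
                                want_grad = TRUE)$grad
    ng <- vapply(seq_along(theta), function(j) {
      h <- 1e-6 * max(1, abs(theta[j]))
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      (f(tp) - f(tm)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - ng) / (1 + abs(ng))), 1e-6)
  }
})
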