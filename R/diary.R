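#' Daily lower-respiratory-tract symptom score
#'
#' Sums six LRT symptom ratings, each on the 0 (none) to 4 (very severe)
#' scale, into a daily total in `[0, 24]`. A day with any missing
#' component is treated as a missing daily score (an incomplete symptom
#' panel cannot be summed conservatively).
#'
#' @param scores numeric vector of six ratings, or a matrix/data frame
#'   with six columns (one row per day). Values must be integers in
#'   0..4 or `NA`.
#' @return daily total(s); `NA` where any component is missing.
#' @export
daily_lrt_score <- function(scores) {
  m <- if (is.data.frame(scores)) as.matrix(scores) else scores
  if (!is.matrix(m)) m <- matrix(m, nrow = 1)
  if (ncol(m) != 6L) stop("expected six symptom scores")
  v <- m[is.finite(m)]
  if (any(v < 0 | v > 4 | v != round(v)))
    stop("symptom scores must be integers in 0..4")
  out <- rowSums(m)  # NA propagates when any component is missing
  if (length(out) == 1L) unname(out) else out
}

#' Weekly average of daily scores with the missing-data rule
#'
#' Averages up to seven daily scores aligned to one Sunday-to-Saturday
#' window. If more than two of the seven days are missing the weekly
#' average is missing; otherwise it is the mean of the observed days.
#' (Imputing each missing day by the weekly average and then averaging
#' leaves the mean unchanged, so the mean of observed days is exactly the
#' impute-then-average rule.)
#'
#' @param x numeric vector of length at most 7, `NA` for missing days;
#'   days absent from the record should be supplied as `NA` so the count
#'   of missing days is correct.
#' @return the weekly average, or `NA`.
#' @export
weekly_average <- function(x) {
  if (length(x) > 7L) stop("more than 7 daily values for one week")
  n_miss <- 7L - sum(is.finite(x))
  if (n_miss > 2L) return(NA_real_)
  mean(x, na.rm = TRUE)
}

#' Map 2004 calendar dates to study week indices
#'
#' Week 1 starts Sunday 2004-01-04 (the first Sunday of January 2004) and
#' each week runs Sunday to Saturday, giving 51 weeks for the year. Dates
#' before 2004-01-04, after the end of week 51 (2004-12-25), or outside
#' 2004 entirely, map to `NA` (out of window).
#'
#' @param dates a `Date` vector (or strings coercible to dates).
#' @return integer week indices in 1..51, `NA` if out of window.
#' @examples
#' study_week_2004(as.Date("2004-01-04"))  # 1
#' @export
study_week_2004 <- function(dates) {
  dates <- as.Date(dates)
  wk <- as.integer(floor(as.numeric(dates - as.Date("2004-01-04")) / 7)) + 1L
  wk[wk < 1L | wk > 51L] <- NA_integer_
  wk
}

#' Aggregate a daily symptom diary into weekly long format
#'
#' Computes daily LRT scores with [daily_lrt_score()], maps dates to study
#' weeks with [study_week_2004()], applies the weekly-averaging missing-data
#' rule of [weekly_average()] (days absent from the record count as
#' missing), defines the week-level viral status as positive if any day of
#' the week is viral positive (a week with no record defaults to
#' negative), and carries subject-level covariates through.
#'
#' @param daily data frame with columns `subject`, `date`, six symptom
#'   columns `s1`..`s6`, optionally `viral` (0/1 per day) and any
#'   subject-constant covariate columns (e.g. `asthma`, `sex`, `age`).
#' @param drop_missing logical; drop weeks whose average is missing (the
#'   model requires complete rows)?
#' @return weekly long-format data frame with columns `subject`, `week`,
#'   `y`, `viral` and the covariates.
#' @export
aggregate_diary <- function(daily, drop_missing = TRUE) {
  need <- c("subject", "date", paste0("s", 1:6))
  if (!all(need %in% names(daily)))
    stop("daily diary must contain columns: ", paste(need, collapse = ", "))
  daily$week <- study_week_2004(daily$date)
  daily <- daily[!is.na(daily$week), , drop = FALSE]
  daily$score <- daily_lrt_score(daily[paste0("s", 1:6)])
  covars <- setdiff(names(daily),
                    c(need, "week", "score", "viral"))
  key <- interaction(daily$subject, daily$week, drop = TRUE)
  first <- !duplicated(key)
  out <- data.frame(subject = daily$subject[first],
                    week = daily$week[first])
  out$y <- as.numeric(tapply(daily$score, key, function(s) {
    if (length(s) < 7L) s <- c(s, rep(NA_real_, 7L - length(s)))
    weekly_average(s)
  })[as.character(key[first])])
  out$viral <- if ("viral" %in% names(daily)) {
    as.integer(tapply(daily$viral, key, function(v) any(v == 1, na.rm = TRUE))
               [as.character(key[first])])
  } else 0L
  for (cv in covars) out[[cv]] <- daily[[cv]][first]
  out <- out[order(match(out$subject, unique(out$subject)), out$week), ]
  rownames(out) <- NULL
  if (drop_missing) out <- out[!is.na(out$y), , drop = FALSE]
  out
}

# allocate `total` integer score units over `n` cells with capacity `cap`
# (used for days within a week, cap 24, and symptoms within a day, cap 4)
allocate_units <- function(total, n, cap) {
  total <- min(total, n * cap)
  if (total == 0) return(integer(n))
  tabulate(sample(rep(seq_len(n), each = cap), total), nbins = n)
}

#' Synthesize a cohort-like daily symptom diary
#'
#' Generates a synthetic one-year daily diary whose weekly aggregation has
#' the structure of the cohort the model targets: around 70-75% zero
#' weekly average scores, right-skewed positive scores, a rare (~3%)
#' week-level viral-positivity covariate, a seasonal (quadratic-in-week)
#' trend and correlated subject heterogeneity in both parts. The
#' week-level outcome is drawn from the two-part probit/log-skew-normal
#' family itself -- a week is symptomatic with probability
#' \eqn{\Phi(\eta)} and a symptomatic week's average score is
#' `exp(SN)` -- and is then disaggregated into a plausible diary week: a
#' run of 1-7 symptomatic days (symptoms cluster into multi-day episodes
#' rather than isolated days) whose integer daily totals sum to the
#' week's total, each day's total split across the six 0-4 symptom
#' ratings. This generator emulates the statistical structure needed to
#' exercise the pipeline; it does not clone any real cohort's raw diary
#' noise.
#'
#' @param n_subjects number of children.
#' @param asthma_frac fraction with asthma.
#' @param viral_rate week-level probability of a viral-positive week.
#' @param baseline_zero_week target marginal probability that a
#'   viral-negative week is entirely symptom free. The weekly probit
#'   baseline is calibrated by root-finding over the design distribution
#'   (asthma mix, seasonal trend, random-intercept spread); with zero
#'   effects and zero heterogeneity it is simply
#'   \eqn{\Phi^{-1}(1 - p_0)}.
#' @param viral_probit,viral_sev viral effects on the weekly probit
#'   scale and on the log-severity scale.
#' @param asthma_probit asthma effect on the weekly probit scale.
#' @param week_quad amplitude of the seasonal quadratic trend (probit
#'   scale; 0 disables it).
#' @param sev_intercept baseline of the log weekly-average severity.
#' @param sigma,delta severity skew-normal scale and skewness.
#' @param s11,s22,s12 subject random-intercept covariance (both set to 0
#'   for a heterogeneity-free diary).
#' @param missing_rate per-day probability of a missing symptom panel.
#' @param seed integer seed; a fixed seed gives a bit-identical table.
#' @return daily diary data frame with columns `subject`, `date`,
#'   `s1`..`s6`, `viral`, `asthma`, `sex`, `age`.
#' @export
synthesize_diary <- function(n_subjects = 190, asthma_frac = 135 / 190,
                             viral_rate = 0.03, baseline_zero_week = 0.75,
                             viral_probit = 1.5, viral_sev = 0.7,
                             asthma_probit = 0.4, week_quad = 0.3,
                             sev_intercept = 0.7, sigma = 0.6, delta = -0.8,
                             s11 = 0.5, s22 = 0.2, s12 = 0.15,
                             missing_rate = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(baseline_zero_week > 0, baseline_zero_week < 1)
  dates <- seq(as.Date("2004-01-04"), as.Date("2004-12-25"), by = "day")
  weeks <- study_week_2004(dates)
  # calibrate the weekly probit baseline so that the marginal fraction of
  # all-zero (viral-negative) weeks matches baseline_zero_week
  wkc_u <- ((1:51) - 26) / 25
  season <- week_quad * (wkc_u^2 - mean(wkc_u^2))
  gh <- gh_rule(15, adaptive = FALSE)
  tau_nodes <- gh$nodes * sqrt(max(s11, 0))
  zero_week_prob <- function(eta0) {
    pz <- 0
    for (a in 0:1) {
      wa <- if (a == 1) asthma_frac else 1 - asthma_frac
      eta <- outer(season + eta0 + asthma_probit * a, tau_nodes, "+")
      pz <- pz + wa * sum(gh$weights * colMeans(pnorm(-eta)))
    }
    pz
  }
  eta0 <- uniroot(function(e) zero_week_prob(e) - baseline_zero_week,
                  c(-8, 4), tol = 1e-10)$root
  asthma <- rbinom(n_subjects, 1, asthma_frac)
  sex <- rbinom(n_subjects, 1, 0.5)
  age <- sample(5:11, n_subjects, replace = TRUE)
  if (s11 > 0 || s22 > 0) {
    S <- matrix(c(max(s11, 1e-10), s12, s12, max(s22, 1e-10)), 2, 2)
    L <- chol2_lower(S)
    z <- matrix(rnorm(2 * n_subjects), n_subjects, 2)
    tau0 <- L[1] * z[, 1]; tau1 <- L[2] * z[, 1] + L[3] * z[, 2]
  } else tau0 <- tau1 <- numeric(n_subjects)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    viral_week <- rbinom(51, 1, viral_rate)
    eta <- eta0 + viral_probit * viral_week + asthma_probit * asthma[i] +
      season + tau0[i]
    pos_week <- rbinom(51, 1, pnorm(eta)) == 1
    avg <- numeric(51)
    if (any(pos_week))
      avg[pos_week] <- exp(rskewnorm(sum(pos_week),
                                     sev_intercept +
                                       viral_sev * viral_week[pos_week] +
                                       tau1[i], sigma, delta))
    sm <- matrix(0L, length(dates), 6)
    for (w in which(pos_week)) {
      total <- max(1L, min(168L, as.integer(round(7 * avg[w]))))
      # symptoms cluster in an episode of consecutive days
      n_days <- max(1L, min(7L, ceiling(total / 10) + sample(0:4, 1)))
      start <- sample(seq_len(7 - n_days + 1), 1)
      daily <- allocate_units(total, n_days, 24L)
      rows <- (w - 1L) * 7L + start + seq_len(n_days) - 1L
      for (k in seq_len(n_days))
        sm[rows[k], ] <- allocate_units(daily[k], 6L, 4L)
    }
    miss <- runif(length(dates)) < missing_rate
    sm[miss, ] <- NA_integer_
    df <- data.frame(subject = i, date = dates, sm)
    names(df)[3:8] <- paste0("s", 1:6)
    df$viral <- viral_week[weeks]
    df$asthma <- asthma[i]; df$sex <- sex[i]; df$age <- age[i]
    out[[i]] <- df
  }
  do.call(rbind, out)
}
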