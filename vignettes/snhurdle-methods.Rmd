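---
title: "Two-part skew-normal hurdle models for zero-inflated repeated measures"
author: "snhurdle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-part skew-normal hurdle models for zero-inflated repeated measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(snhurdle)
```

## The data problem

Weekly symptom scores from a cohort followed over a year are a typical
*semicontinuous* outcome: a large point mass at exactly zero (weeks with no
symptoms — often 70–75% of all subject-weeks) and a right-skewed continuous
distribution over the positive values (severity when symptoms are present).
Repeated measurements on the same child are correlated: some children are
intrinsically prone to symptoms, others rarely report any. Neither a Tobit-style
censored model (one process for both features) nor an ordinary mixed model fits
this structure; the established approach is a *two-part (hurdle) mixed model*
with one regression for whether the outcome is positive and another for how
large it is when positive.

## The model

For subject $i$ at occasion $j$, with response $Y_{ij} \ge 0$:

* **Binary part.** $P(Y_{ij} > 0 \mid \tau_{0i}) =
  g^{-1}\!\left(x_{1ij}^\top \beta_{1} + \tau_{0i}\right)$ with a probit link
  $g^{-1} = \Phi$ (a logit link is also available). Note the convention: the
  linear predictor drives the probability of *having* symptoms; a positive
  coefficient means a covariate makes symptoms more likely and the probability
  of being symptom free, $1 - \Phi(\cdot)$, smaller. This direction is what
  makes a strongly positive viral-infection coefficient mean "much less likely
  to be symptom free in an infected week", consistently with how such effects
  are reported in the field.

* **Severity part.** Given $Y_{ij} > 0$,
  $\log Y_{ij} \sim \mathrm{SN}(\mu_{ij}, \sigma, \delta)$ with
  $\mu_{ij} = x_{2ij}^\top \beta_{2} + \tau_{1i}$, where SN is the skew-normal
  distribution in the Sahu–Dey–Branco (SDB) parameterization, defined by the
  convolution $V = \mu + \delta |Z_0| + \sigma Z_1$ with independent standard
  normals $Z_0, Z_1$. Its density is
  $f(v) = \tfrac{2}{\omega}\,\phi\!\big(\tfrac{v-\mu}{\omega}\big)\,
  \Phi\!\big(\tfrac{\delta}{\sigma}\tfrac{v-\mu}{\omega}\big)$,
  $\omega = \sqrt{\sigma^2 + \delta^2}$.

* **Random effects.** $(\tau_{0i}, \tau_{1i}) \sim \mathrm{BVN}(0, S)$ with
  $S = \begin{pmatrix} s_{11} & s_{12}\\ s_{12} & s_{22}\end{pmatrix}$,
  allowing the propensity to have symptoms and their severity to be
  correlated across subjects. A positive $s_{12}$ means children who are more
  often symptomatic also tend to have more severe symptoms.

Two modelling conventions deserve emphasis:

* **Why the SDB parameterization.** At $\delta = 0$ the SN is exactly
  $N(\mu, \sigma^2)$, so the model nests the familiar two-part log-normal
  model. Under the common direct (Azzalini) parameterization the Fisher
  information is singular at zero skewness, which breaks Wald and
  likelihood-ratio inference exactly where it is most wanted; the SDB form is
  regular there, so the test of $H_0{:}\ \delta = 0$ can be referred to a
  regular $\chi^2_1$. The package documents this caveat with the test: the
  regular reference is a property of this parameterization, not of skew-normal
  models in general.

* **Log-scale severity density.** The likelihood uses the density of
  $\log Y$ for positive responses, without the $1/y$ Jacobian back to the
  original scale. Every model comparison the package performs (log-normal vs
  log-skew-normal severity, AIC/BIC, LRT) is between models of the same
  log-scale response, so the constant Jacobian cancels; dropping it reproduces
  the conventional $-2$LL/AIC/BIC bookkeeping for such models.

## Maximum marginal likelihood

Subject $i$'s likelihood contribution integrates the conditional likelihood
over the random effects,
$L_i = \iint \prod_j f(y_{ij} \mid \tau_0, \tau_1)\,
\varphi_2(\tau_0, \tau_1; S)\, d\tau_0\, d\tau_1,$
and the total log-likelihood $\sum_i \log L_i$ is maximized. The integral is
approximated by a tensor-product Gauss–Hermite rule.

**Quadrature placement.** `snhurdle_control(points = 7, adaptive = TRUE)` is
the default: the rule is recentred per subject at the posterior mode of
$(\tau_0, \tau_1)$ and scaled by the local curvature (a 2-D Newton iteration
per subject; the two observation parts touch $\tau_0$ and $\tau_1$ separately,
so the conditional Hessian is diagonal up to the prior). The reason adaptivity
is the default rather than an option: with ~50 occasions per subject the
integrand concentrates in a region much narrower than the prior scale, and a
prior-centred rule needs several dozen points per dimension to reach the
accuracy a 7-point recentred rule achieves. The test suite verifies the
recentred rule against brute-force Monte-Carlo integration; a prior-centred
(non-adaptive) rule with a user-chosen point count remains available, and is
the right tool for small cluster sizes or for matching a reference computation
at a fixed rule.

**Fixed-node cycles with exact gradients.** Within one optimization cycle the
quadrature nodes are held *fixed in random-effects space*. The covariance
parameters then enter only through the bivariate-normal prior density at the
nodes, and the analytic gradient of the approximated log-likelihood (computed
in C++ together with the objective, with log-sum-exp accumulation so that
51-observation subjects do not underflow) is exact for the objective being
optimized. After the inner quasi-Newton solve (`stats::nlminb()`) the nodes
are re-placed at the new parameter value and the solve repeats until the
$-2$LL change between cycles is below `outer_tol`; a cheap 5-point warm-up
cycle precedes the full rule by default. Convergence is reported only when
the inner solver succeeds and the scaled gradient norm is below `grad_tol`
(default $10^{-6}$).

**Parameterization and constraints.** Optimization runs unconstrained in
$(\beta_1, \beta_2, \log\sigma, \delta, \log s_{11}, \log s_{22},
\operatorname{atanh}\rho)$ with $s_{12} = \rho\sqrt{s_{11} s_{22}}$, so every
iterate has a positive scale and a positive-definite covariance by
construction. Estimates are reported on the natural scale with delta-method
standard errors from a central-finite-difference Hessian of the marginal
log-likelihood (differencing the analytic gradient, step
$\propto \varepsilon_{\mathrm{mach}}^{1/3}$). A singular Hessian yields
missing standard errors with a warning, never fabricated ones.

**Starting values.** Stage one fits the no-random-effects probit /
log-skew-normal model (probit part by `glm.fit`, severity part by direct
likelihood maximization seeded from least squares and the residual skewness);
stage two starts the random-effects parameters at $s_{11} = s_{22} = 0.5$,
$s_{12} = 0$.

**Information criteria.** $\mathrm{AIC} = -2LL + 2k$ and
$\mathrm{BIC} = -2LL + k \log n$ with $n$ the number of *subjects* — the
independent sampling units of the marginal likelihood — not the number of
observations.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `points` | 7 | quadrature points per dimension (49 nodes); increase for very small cluster sizes with `adaptive = FALSE` |
| `adaptive` | `TRUE` | posterior-mode recentring per subject |
| `link` | `"probit"` | binary-part link; `"logit"` available |
| `outer_tol` | `1e-8` | relative $-2$LL stability across recentring cycles |
| `grad_tol` | `1e-6` | scaled gradient norm required to report convergence |
| `delta` | free | fix the skewness (e.g. `delta = 0` for the log-normal submodel) |

## The robustness simulation

To probe sensitivity to the severity distribution, data are generated from a
*different* family and the skew-normal model is fitted to them. The generator
(`simulate_probit_logbeta()`) keeps the probit binary part and random
intercepts but draws
$\log(Y \mid Y > 0) = \Theta + \mathit{scale}\cdot\varepsilon$ with
$\varepsilon \sim \mathrm{Beta}(a, b)$ and
$\Theta = \alpha_1 + \beta_1 x_{ij} + \tau_{1i}$ — a four-parameter beta on
$(\Theta, \Theta + \mathit{scale})$. The beta's skewness
$2(b-a)\sqrt{a+b+1}\,/\,\big((a+b+2)\sqrt{ab}\big)$ pins the shape ordering:
$(a, b) = (130, 70)$ is negatively skewed ($-0.0883$), $(100, 100)$ symmetric,
$(70, 130)$ positively skewed ($+0.0883$).

The reference scenario uses 200 subjects, 50 occasions, probit intercept $-1$
and slope $2.5$ on a rare binary covariate ($P(x_{ij}=1) = 0.03$, mimicking
weekly viral positivity), $\alpha_1 = -20$, $\beta_1 = 0.75$,
$\mathit{scale} = 30$ (positive values spanning $\approx e^{-20}$ to
$e^{10}$, i.e. effectively a continuous outcome bounded below at zero), and
$s_{11} = 1$, $s_{22} = 0.2$, $s_{12} = 0.2$. `run_scenario()` simulates,
fits, and reports per-parameter bias and MSE together with the count of
non-converged replicates (which are excluded and reported, since how to
handle them is otherwise undefined). The severity intercept is archived but
not tabulated: the four-parameter-beta location and the skew-normal location
are not on a common scale, while the slope of $x$ is a difference of
conditional means in both families and therefore comparable.

Replicate streams are seeded as `master_seed * 1000 + rep`, so a study can be
extended without re-running earlier replicates and reruns are bit-identical.

Two behaviors of this study are worth understanding before reading its
output (both are exercised by the packaged tests, which compute the
quantities below):

* **The binary part is correctly specified in the generator**, so with
  accurate integration the probit coefficients and $s_{11}$ are estimated
  with negligible bias; misspecification of the severity law mainly
  affects the severity-part parameters and the fitted skewness. A
  bias in $s_{11}$ under this design indicates integration or
  optimization error, not model misspecification.
* **A symmetric severity law makes the skewness sign unidentified in a
  weak sense**: the skew-normal can approximate a symmetric light-tailed
  target about equally well with a positive or a negative $\delta$ of
  moderate size, so per-replicate $\hat\delta$ lands on either side
  depending on the sample, and the mean across replicates is near zero
  with a large spread. The scientifically meaningful summary for the
  symmetric scenario is therefore "mean $\hat\delta$ not significantly
  different from zero", which is what the test suite asserts; for the
  negatively skewed scenario the mean $\hat\delta$ is clearly negative.

**Problem sizes in the test suite.** The packaged tests exercise this
machinery at sizes chosen for a single-CPU run: 50 replicates of the
parameter-recovery check and of the negatively skewed scenario, 25 of the
symmetric scenario, always at the full 200-subject × 50-occasion design.
All comparisons use Monte-Carlo bands computed from the run itself
($\pm 3\sqrt{\mathrm{MSE}/R}$ style), so reducing $R$ widens the band
honestly rather than silently. Full 200-replicate studies of any scenario are
one call (`run_scenario(builtin_scenario("i"))`) or one CLI invocation
(`snhurdle study --scenario i`); they are multi-hour runs on one CPU.

## The synthetic diary generator

The daily-diary tooling (scoring six 0–4 symptom ratings, Sunday-to-Saturday
weekly averaging with the "more than two missing days → missing week" rule,
week-level viral status as an OR over days) needs realistic input to be
testable, and the cohort data it was designed around is not publicly
deposited. `synthesize_diary()` therefore generates a *synthetic* daily diary
from the fitted-model family itself: a daily two-part process whose baseline
is calibrated so a null week is all-zero with probability
`baseline_zero_week` (a week is zero iff its seven days are zero, hence the
daily probability $1 - p_0^{1/7}$), with viral and asthma effects on the
probit scale, a quadratic seasonal trend, correlated subject heterogeneity,
skew-normal daily severity split across the six symptoms (each capped at 4),
and missing panels at a configurable rate.

What it emulates: the zero-inflation level (~70–75% zero weeks), right-skewed
positive scores, rare (~3%) viral weeks, seasonality, heterogeneity,
missingness. What it does not: the raw diary noise of any real cohort,
enrollment/dropout patterns, reporting-mode effects, or within-week symptom
autocorrelation. Tests passing on synthetic diaries therefore demonstrate
that the pipeline is correct and that configured effect directions are
recovered — not that any particular cohort's coefficients are reproduced,
which without the original data is not a checkable claim. The weekly-average
rule is implemented as the mean of observed days, which is *identical* to
"impute missing days by the weekly average, then average": imputing a mean
by itself leaves the mean unchanged.

## Numerical choices

* Gaussian CDF factors are evaluated on the log scale throughout (via
  `pnorm(log.p = TRUE)` in R; via `erfc` with an asymptotic tail expansion
  below $-8$ in C++), so tail log-densities and rare-branch contributions do
  not underflow.
* At $\delta = 0$ the skew-normal density *bitwise* equals the normal
  density (the collapse is special-cased), so the log-normal submodel is the
  exact $\delta = 0$ slice of the model, not merely a close approximation.
* The random-effects integral transform uses the lower Cholesky factor of
  $S$; any optimizer iterate yields a valid bivariate normal.
* Per-subject mode finding uses Newton with step halving and falls back to
  prior-centred placement for a subject whose curvature is not usable.
* Degenerate inputs fail loudly: non-PD covariance, negative responses,
  mismatched design dimensions and empty datasets are contract errors, not
  silent coercions.

## Known limitations

* Random intercepts only: no random time slope (which would make the
  integral three-dimensional), no serial correlation beyond what the
  intercepts induce; a lagged response can be added as a covariate by the
  analyst.
* Zeros are treated as true zeros; interval-censored zeros (detection-limit
  settings) are out of scope.
* No Box–Cox severity transformation; the skew-normal handles asymmetry on
  the log scale.
* Model building (which covariates, which interactions, GAM-style scale
  exploration for continuous covariates) is the analyst's loop; the package
  fits the model it is given. Design columns for interactions and polynomial
  terms come from the standard formula machinery (e.g.
  `y ~ asthma * week + I(week^2) | age * week`).
* The likelihood surface can be multimodal in small or nearly-degenerate
  datasets; the two-stage start plus the optimizer-invariance checks in the
  test suite cover the simulated designs, but fitting from several starts is
  sensible practice on new data.
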