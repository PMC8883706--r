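---
title: "Distributional regression for two-arm trials: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributional regression for two-arm trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Classical analysis of a continuous trial outcome assumes
\(y_i \mid t_i, x_i \sim \mathcal N(\mu_i, \sigma^2)\) with a linear model
for the mean only. `distreg` fits the location–scale–shape generalization:

\[
y_i \sim \mathcal D(\mu_i, \sigma_i, \nu_i, \tau_i), \qquad
g_k(\theta_{ki}) = \beta_0^{\theta_k} + \beta_t^{\theta_k} t_i +
\beta_1^{\theta_k} x_{i1} + \cdots
\]

where \(\mathcal D\) is a parametric response distribution with up to four
parameters, each of which may carry its own link-linear predictor in the
treatment indicator \(t_i\) and covariates. A treatment effect is therefore
no longer confined to the mean: a coefficient \(\beta_t^{\sigma}\) on a
log-linked \(\sigma\) multiplies the scale by
\(\exp(\beta_t^{\sigma})\) — a direct model for treatment effects on
outcome *variability* (e.g. blood-pressure variability), which the
classical model cannot express.

Four response families are registered:

* **NO** — normal, parameters (mean, SD); the classical benchmark.
* **JSU** — Johnson's \(S_u\), reparameterized by moment matching so that
  \(\mu\) *is* the mean and \(\sigma\) the SD (so its location/scale
  coefficients are directly comparable to the normal's), with \(\nu\)
  controlling skewness (\(\nu = 0\) symmetric) and \(\tau\) tail weight
  (\(\tau \to \infty\) approaches the normal). Suitable for real-line
  outcomes such as change in systolic blood pressure.
* **BCT** — Box–Cox \(t\): positive support; the Box–Cox power transform
  \(z = ((y/\mu)^\nu - 1)/(\sigma\nu)\) (log form at \(\nu = 0\)) is
  modelled as a truncated \(t_\tau\), with the normalizing constant
  \(F_T(1/(\sigma|\nu|))\) accounting for truncation to \(y > 0\). Here
  \(\mu\) is approximately the median and \(\sigma\) approximately the
  coefficient of variation. Suitable for positively skewed, sharply peaked
  biomarkers.
* **SN** — the Azzalini three-parameter skew normal,
  \(f(y) = (2/\sigma)\varphi(z)\Phi(\nu z)\). The literature also uses
  two-piece variants; the Azzalini form is the common default and is what
  the selection candidate set uses here.

Links are `identity` and `log`; defaults are `log` for strictly positive
parameters (\(\sigma\), \(\tau\), and \(\mu\) for positive-support
families). A note on scale conventions: some presentations write the
heteroscedastic normal with \(\log \sigma^2\) on the left-hand side. This
package models \(\log \sigma\); a coefficient on \(\log \sigma^2\) is
exactly twice the corresponding \(\log\sigma\) coefficient, and the
multiplicative effect \(\exp(\hat\beta_t^{\sigma})\) is then a ratio of
standard deviations (e.g. \(\exp(-0.048) = 0.953\), a 4.7% SD reduction).

## Censoring at a detection limit

Assay outcomes such as plasma MR-proADM have a detection limit (0.05
nmol/L); values below it are known only to lie below it. `censor_left()`
wraps any family so that a censored record contributes \(F(c)\) (the base
CDF at the cutoff) to the likelihood while uncensored records contribute
the density. If no observation lies at or below the cutoff the censored
and uncensored log-likelihoods coincide exactly — a property the tests
assert. Quantiles and random generation remain those of the base
distribution; the *data generator* applies censoring by storing censored
draws at the cutoff with a flag, mirroring how detection-limit data are
entered in practice.

## Estimation

All coefficient blocks are maximized jointly: BFGS from data-driven
starting values, then Newton polishing with numerically differentiated
gradient and Hessian. Standard errors come from the inverse of the
observed information (numeric Hessian at the optimum). Design choices:

* **Starting values.** The \(\mu\) block from least squares on the
  link-transformed response; the \(\sigma\) intercept from the residual
  spread; \(\nu\) at 0 (0.5 for BCT); \(\tau\) at 10 (BCT) or 4 (JSU) —
  mild shapes that keep the first iterations in a well-behaved region.
* **Inadmissible parameters** (e.g. \(\sigma \le 0\) under an identity
  link) make the log-likelihood \(-\infty\) with a flag rather than an
  exception, so the optimizer can back off.
* **Convergence.** Relative function tolerance 1e-12 in BFGS, then
  polishing until \(\max_j |\partial \ell / \partial \beta_j| <
  10^{-5}\max(1, |\ell|)\). The tolerance is relative because with
  log-likelihoods of order \(10^3\)–\(10^4\) an absolute gradient
  criterion is not meaningful under numeric differentiation.
* **df accounting.** Every estimated scalar counts 1, including the
  random-intercept SD; `AIC = -2 loglik + 2 df`.
* **No penalization.** All fitted predictors here are linear; smooth/spline
  terms, spatial effects and Bayesian estimation are out of scope.

`select_distribution()` refits a template under each candidate family and
ranks by AIC. Following the asymmetric convention of the selection
procedure, the normal candidate keeps treatment on \(\mu\) only with
constant \(\sigma\) (the "reduced normal"), while non-normal candidates
model treatment on \(\mu\) and \(\sigma\); the API lets users override
this. Candidates whose support excludes an observed response (BCT with a
non-positive value) are skipped with a recorded reason.

## Random intercepts

Longitudinal observations are handled with a Gaussian subject intercept
added to the \(\mu\) predictor. The marginal likelihood integrates it out
per subject with *adaptive* Gauss–Hermite quadrature (default 15 nodes):
per-subject modes are found by a vectorized Newton search and the nodes
are re-centred and re-scaled by the local curvature, which makes the rule
exact for the Gaussian family (the tests verify agreement with
`lme4::lmer` ML fits to 1e-4) and accurate for the skewed families. The
fit warm-starts from the fixed-effects-only fit; without that, quasi-Newton
search frequently stalls on the flat shape directions of the JSU.

Two numerical caveats are worth documenting. First, with all-singleton
subjects the intercept SD is weakly identified; the fit proceeds with a
warning. Second, at small subject counts (a few hundred) the longitudinal
JSU likelihood is genuinely degenerate in \(\nu\): the MLE can drift to
extreme skewness with marginally higher likelihood (we verified against
brute-force integration that this is a property of the likelihood, not of
the quadrature). From roughly 600 subjects upward the fits are stable —
the desk-scale study profile below respects that.

## Diagnostics and tests

*Normalized quantile residuals*: \(r_i = \Phi^{-1}(F(y_i \mid
\hat\theta_i))\), standard normal under a correct model whatever the
family. Censored records are randomized, \(u_i \sim \mathrm{U}(0,
F(c \mid \hat\theta_i))\), \(r_i = \Phi^{-1}(u_i)\), reproducible given a
seed; a censored residual never exceeds \(\Phi^{-1}(F(c))\). CDF values
numerically 0 or 1 clamp the residual at \(\pm 8.2\) with a warning.
`qq_table()` emits plain theoretical/empirical coordinates so any plotting
layer can render them; the core has no graphics dependency.

*Wald tests* use \(z = \hat\beta/\widehat{\mathrm{se}}\) against the
standard normal (the z-convention of ML output, not a \(t\) reference).
The joint hypothesis of no treatment effect on \(\mu\) and \(\sigma\)
(H02) uses the likelihood ratio against the refitted null, \(\chi^2_2\).
No multiplicity adjustment is applied; per-coefficient p-values are
reported unadjusted.

## The synthetic-trial generator

Individual patient data from the motivating statin trial are not publicly
deposited, so every analysis is exercised on synthetic data with the same
statistical structure. The
generator draws treatment as Bernoulli(0.5) independent of baseline,
optionally sex as Bernoulli(0.8) (the trial population was predominantly
male), a positive baseline covariate, pushes the shipped coefficient sets
(`trial_coefs`) through the links row by row, draws the response from the
family, and censors last. Invented-by-necessity defaults, all
configurable:

* baseline biomarker: log-normal with median 0.65 nmol/L and log-scale SD
  0.25 (a plausible MR-proADM-like marker; the original analyses reused
  the empirical baselines of 6,539 participants, which are unavailable —
  any power-type quantity therefore depends on this stand-in);
* baseline SBP: normal(138, 17) truncated to positive values;
* permuted-block allocation is *not* emulated (independent Bernoulli).

The longitudinal generator adds one shared Gaussian intercept per subject
on the \(\mu\) predictor and visit indicators in \(\mu\) and \(\sigma\);
it emulates neither dropout nor visit missingness. Consequently, passing
tests demonstrate correctness of the estimation machinery under the
assumed structure — not robustness to real-data features such as
informative missingness or non-Gaussian subject effects.

## Desk-scale study profile

The Monte Carlo checks in the test suite and `scripts/acceptance.R` use
the following problem sizes, chosen as a desk-scale profile that keeps
binomial/bias tolerances meaningful while running routinely:

* coverage under the heteroscedastic-normal generator: 500 replicates of
  n = 2000 (95% CI coverage asserted within [0.93, 0.97]);
* AIC selection under the Box-Cox-t generator: 100 replicates of n = 2000;
* coefficient recovery: 30–40 replicates at n = 2000 for the
  cross-sectional sets, 8 replicates at 600 subjects for the longitudinal
  set, with mean bias required to be below the mean reported SE for every
  coefficient. For the longitudinal set, whose reference scale is 5000
  participants, the bound is rescaled by \(\sqrt{5000/600}\): ML bias
  shrinks as \(1/n\) while the SE shrinks as \(1/\sqrt n\), so
  bias \(<\) SE at the reference scale is equivalent to bias
  \(< \sqrt{n_{\mathrm{ref}}/n}\,\cdot\) SE at the smaller \(n\). A
  censored fit at n = 5000 checks the detection-limit path;
* test size: 100–300 null replicates at n = 600; power ordering of the
  extended Box-Cox-t versus reduced-normal analyses: 40 replicates at
  n = 2000.

Replicate seeds derive deterministically from a master seed, so studies
replay byte-identically and replicates are independent of execution
order. Failed replicate fits are excluded from aggregates, counted and
reported alongside.

## A worked example

```{r, eval = FALSE}
library(distreg)

d <- gen_trial(n = 2000, coefs = trial_coefs$biomarker_bct, seed = 1)

sel <- select_distribution(d, links = c(mu = "log", sigma = "log"))
sel[, c("family", "aic", "df")]

fit <- fit_ml(d, model_spec("BCT",
                            mu = ~ treatment + log(baseline),
                            sigma = ~ treatment + log(baseline),
                            cutoff = 0.05))
summary(fit)
effect_ratio(coef(fit)["mu.treatment"])

r <- quantile_residuals(fit, d, seed = 17)
head(qq_table(r))
```

## Known limitations

* Only left-censoring is implemented (no right/interval censoring), and
  only linear terms (no splines/smooths), matching the fitted models in
  scope.
* Identity-link \(\sigma\) is allowed but offers no positivity guarantee;
  the optimizer treats excursions as inadmissible rather than
  reparameterizing.
* JSU/SN fits on data that are effectively normal sit on a flat kurtosis
  ridge; the AIC is reliable there but individual shape SEs may be
  reported unavailable (singular observed information).
* The skew-normal CDF uses Owen's T by adaptive quadrature; it is accurate
  but slower than the closed-form CDFs of the other families, so SN
  quantiles/residuals on very large data cost noticeably more.
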