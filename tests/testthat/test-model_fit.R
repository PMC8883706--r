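toy_data <- function(n = 200, seed = 10) {
  set.seed(seed)
  d <- data.frame(treatment = rbinom(n, 1, 0.5),
                  baseline = rlnorm(n, log(0.65), 0.25))
  d$response <- exp(0.7 + 0.3 * log(d$baseline) - 0.01 * d$treatment +
                      rnorm(n, 0, 0.15))
  d$censored <- 0L
  d
}

test_that("links invert exactly and design matrices have the stated layout", {
  for (nm in c("identity", "log")) {
    lk <- get_link(nm)
    x <- c(0.01, 0.5, 2, 40)
    expect_lt(max(abs(lk$linkinv(lk$linkfun(x)) - x)), 1e-12)
  }
  expect_true(all(get_link("log")$linkinv(c(-50, 0, 50)) > 0))
  expect_error(get_link("logit"))

  d <- toy_data(3)
  sp <- model_spec("NO", mu = ~ treatment + log(baseline))
  X <- build_design(d, sp)
  expect_equal(dim(X$mu), c(3, 3))
  expect_equal(unname(X$mu[, 1]), rep(1, 3))
  expect_equal(unname(X$mu[, 3]), log(d$baseline))
  expect_equal(ncol(X$sigma), 1)
  expect_equal(unname(X$sigma[, 1]), rep(1, 3))

  sp2 <- model_spec("NO", mu = ~ treatment + sexx)
  expect_error(build_design(d, sp2), "sexx")
  d$bad <- c(1, -1, 2)
  sp3 <- model_spec("NO", mu = ~ log(bad))
  expect_error(build_design(d, sp3), "rows")
})

test_that("model_spec validates its inputs", {
  expect_error(model_spec("NOPE"), "unknown family")
  expect_warning(model_spec("NO", nu = ~treatment), "no such parameter")
  expect_error(model_spec("NO", links = c(nu = "log")), "unknown parameter")
  expect_error(model_spec("NO", random_intercept = 3), "column name")
  sp <- model_spec("BCT", mu = ~treatment, cutoff = 0.05)
  expect_s3_class(sp$family, "dr_censored_family")
})

test_that("the log-likelihood matches closed forms and flags inadmissibility", {
  d <- data.frame(response = c(1, 2, 3), treatment = c(0, 1, 0), censored = 0L)
  sp <- model_spec("NO", mu = ~1, links = c(sigma = "identity"))
  ll <- model_loglik(d, sp, c(2, 1))
  expect_equal(as.numeric(ll), -1.5 * log(2 * pi) - 1, tolerance = 1e-9)
  # sigma <= 0 under the identity link: -Inf with a flag, not an error
  bad <- model_loglik(d, sp, c(2, -1))
  expect_identical(as.numeric(bad), -Inf)
  expect_false(attr(bad, "admissible"))
  expect_error(model_loglik(d, sp, c(2, 1, 0)), "length")
})

test_that("homoscedastic normal ML equals least squares, including SEs", {
  d <- toy_data(300, seed = 11)
  d$logresp <- log(d$response)
  f <- fit_ml(d, model_spec("NO", mu = ~ treatment + log(baseline),
                            links = c(mu = "log")))
  ols <- lm(logresp ~ treatment + log(baseline), d)
  # log-link mu on a lognormal response == linear model for log(response)
  # only in the small-sigma limit; use the exact identity-link case instead
  d2 <- d; d2$response <- d$logresp
  f2 <- fit_ml(d2, model_spec("NO", mu = ~ treatment + log(baseline)))
  expect_lt(max(abs(coef(f2)[1:3] - coef(ols))), 1e-6)
  n <- nrow(d2); p <- 3
  se_ols <- sqrt(diag(vcov(ols)))
  expect_rel_equal(f2$se[1:3] * sqrt(n / (n - p)), se_ols, 1e-6)
  expect_true(f2$converged)
  expect_equal(f2$aic, -2 * f2$loglik + 2 * f2$df)
  expect_equal(aic(f2), f2$aic)
  # covariance is symmetric positive semi-definite
  expect_equal(f2$vcov, t(f2$vcov))
  expect_true(all(eigen(f2$vcov, symmetric = TRUE)$values > -1e-10))
})

test_that("fits are deterministic and nested models never lose log-likelihood", {
  d <- toy_data(250, seed = 12)
  spr <- model_spec("NO", mu = ~ treatment, links = c(mu = "log"))
  spe <- model_spec("NO", mu = ~ treatment + log(baseline),
                    sigma = ~ treatment, links = c(mu = "log"))
  fr <- fit_ml(d, spr); fr2 <- fit_ml(d, spr); fe <- fit_ml(d, spe)
  expect_identical(coef(fr), coef(fr2))
  expect_gte(fe$loglik, fr$loglik)
  # local optimum: random perturbations never improve the log-likelihood
  set.seed(13)
  ll0 <- as.numeric(model_loglik(d, spr, fr$par))
  for (i in 1:20) {
    expect_lte(as.numeric(model_loglik(d, spr, fr$par + rnorm(3, 0, 0.01))),
               ll0 + 1e-10)
  }
})

test_that("covariate rescaling moves coefficients without moving the fit", {
  d <- toy_data(250, seed = 14)
  d$logbase <- log(d$baseline)
  d$logbase10 <- 10 * d$logbase
  f1 <- fit_ml(d, model_spec("NO", mu = ~ treatment + logbase,
                             links = c(mu = "log")))
  f2 <- fit_ml(d, model_spec("NO", mu = ~ treatment + logbase10,
                             links = c(mu = "log")))
  expect_equal(unname(coef(f2)["mu.logbase10"]),
               unname(coef(f1)["mu.logbase"]) / 10, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  # Wald z for the rescaled covariate is unchanged
  z1 <- coef(f1)["mu.logbase"] / f1$se["mu.logbase"]
  z2 <- coef(f2)["mu.logbase10"] / f2$se["mu.logbase10"]
  expect_equal(unname(z1), unname(z2), tolerance = 1e-4)
})

test_that("JSU coefficients generated at trial magnitudes are recovered", {
  d <- gen_trial(2500, trial_coefs$sbp_jsu, seed = 15)
  f <- suppressWarnings(
    fit_ml(d, model_spec("JSU", mu = ~ treatment + baseline,
                         sigma = ~ treatment + baseline,
                         nu = ~ baseline, tau = ~1)))
  truth <- c(79.722, 0.042, -0.589, 2.473, -0.067, 0.003, 4.018, -0.018, 1.160)
  expect_true(f$converged)
  expect_true(all(abs(coef(f) - truth) < 4 * f$se))
})

test_that("censored fits on uncensored data equal uncensored fits exactly", {
  d <- toy_data(300, seed = 16)
  spu <- model_spec("BCT", mu = ~ treatment + log(baseline))
  spc <- model_spec("BCT", mu = ~ treatment + log(baseline), cutoff = 1e-8)
  fu <- fit_ml(d, spu); fc <- fit_ml(d, spc)
  expect_identical(unname(coef(fu)), unname(coef(fc)))
  expect_identical(fu$loglik, fc$loglik)
  expect_equal(fc$n_censored, 0)
})

test_that("errors: too few observations, positive support violated", {
  d <- toy_data(4)
  expect_error(fit_ml(d, model_spec("JSU", mu = ~ treatment + log(baseline))),
               "exceed")
  d2 <- toy_data(50); d2$response[1] <- -1
  expect_error(fit_ml(d2, model_spec("BCT", mu = ~treatment)), "positive support")
})

test_that("Gaussian random-intercept fits match the classical mixed model", {
  skip_if_not_installed("lme4")
  d <- gen_longitudinal(120, seed = 17)
  f <- fit_ml(d, model_spec("NO", mu = ~ treatment + baseline + month72,
                            random_intercept = "id"))
  m <- lme4::lmer(response ~ treatment + baseline + month72 + (1 | id), d,
                  REML = FALSE)
  expect_rel_equal(unname(coef(f)[1:4]), unname(lme4::fixef(m)), 1e-4)
  expect_rel_equal(unname(coef(f)["ranef.sd"]),
                   sqrt(unname(unlist(lme4::VarCorr(m)))), 1e-4)
  expect_rel_equal(f$loglik, as.numeric(stats::logLik(m)), 1e-6)
  expect_equal(f$df, 6)  # 4 fixed + residual sigma + random-intercept SD
})

test_that("random-intercept edge cases behave", {
  # data generated without any subject effect: estimated SD collapses
  d <- gen_longitudinal(100, ranef_sd = 0, seed = 18)
  f <- suppressWarnings(
    fit_ml(d, model_spec("JSU", mu = ~ treatment + baseline + month72,
                         sigma = ~ treatment + baseline + month72,
                         nu = ~ baseline, random_intercept = "id")))
  sig <- exp(mean(log(fitted_params(f, d)$sigma)))
  expect_lt(unname(coef(f)["ranef.sd"]), 0.25 * sig)
  # singleton subjects: fit proceeds with a warning
  d2 <- gen_trial(80, trial_coefs$biomarker_normal, cutoff = NULL, seed = 19)
  expect_warning(
    fit_ml(d2, model_spec("NO", mu = ~ treatment + log(baseline),
                          links = c(mu = "log"), random_intercept = "id")),
    "weakly identified")
})
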