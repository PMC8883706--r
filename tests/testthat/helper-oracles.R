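# Shared fixtures and independent numerical oracles used across tests.

# parameter grids per family: admissible, spanning mild to fairly extreme
# shapes (kurtosis/skew values like those seen in the fitted trial models)
family_grid <- list(
  NO = list(list(mu = 0, sigma = 1), list(mu = -3, sigma = 0.2)),
  JSU = list(list(mu = 5, sigma = 2, nu = 1, tau = 3),
             list(mu = 0, sigma = 1, nu = 0, tau = 2),
             list(mu = -2, sigma = 0.5, nu = -1.5, tau = 5)),
  BCT = list(list(mu = 1, sigma = 0.2, nu = 1, tau = 10),
             list(mu = 0.63, sigma = 0.11, nu = 1.0, tau = 1.6),
             list(mu = 2, sigma = 0.3, nu = -0.5, tau = 5),
             list(mu = 1.5, sigma = 0.15, nu = 0, tau = 8)),
  SN = list(list(mu = 1, sigma = 2, nu = 3),
            list(mu = 0, sigma = 1, nu = -2),
            list(mu = -1, sigma = 0.5, nu = 0)))

# quadrature oracle: integral of g over the family support
support_integral <- function(fam, g, rel.tol = 1e-10) {
  lo <- if (fam$support[1] == 0) 0 else -Inf
  stats::integrate(g, lo, Inf, rel.tol = rel.tol, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}

# representative interior quantile points for identity checks
probe_quantiles <- c(0.01, 0.1, 0.25, 0.5, 0.75, 0.9, 0.99)

# a minimal stand-in fit for testing pure test arithmetic (lr_test etc.)
fake_fit <- function(loglik, df, n_obs = 100) {
  structure(list(loglik = loglik, df = df, n_obs = n_obs,
                 aic = -2 * loglik + 2 * df, converged = TRUE),
            class = "dr_fit")
}

# homoscedastic-normal generating set (log-mu link, constant sigma): the
# benchmark case in which the plain normal model is correctly specified
coefs_homoscedastic <- within(distreg::trial_coefs$biomarker_normal, {
  sigma <- c("(Intercept)" = -1.9)
})

expect_rel_equal <- function(x, y, tol) {
  testthat::expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
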