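test_that("closed-form density and CDF values are reproduced", {
  no <- get_family("NO")
  expect_equal(fam_pdf(no, 0, list(mu = 0, sigma = 1)), 1 / sqrt(2 * pi),
               tolerance = 1e-7)
  expect_equal(fam_cdf(no, 2, list(mu = 2, sigma = 3)), 0.5)
  expect_equal(fam_quantile(no, 0.5, list(mu = 3, sigma = 2)), 3)

  # JSU with nu = 0 is symmetric about mu (and mu is the mean)
  jsu <- get_family("JSU")
  pr <- list(mu = 2, sigma = 1, nu = 0, tau = 2)
  expect_equal(fam_pdf(jsu, 2 - 0.7, pr), fam_pdf(jsu, 2 + 0.7, pr),
               tolerance = 1e-12)
  expect_equal(fam_cdf(jsu, 2, pr), 0.5, tolerance = 1e-12)
  qs <- fam_quantile(jsu, c(0.025, 0.975), list(mu = 5, sigma = 2, nu = 0, tau = 2))
  expect_equal(qs[1] - 5, -(qs[2] - 5), tolerance = 1e-10)
})

test_that("every family integrates to 1 and obeys the quantile/CDF identity", {
  for (fname in list_families()) {
    fam <- get_family(fname)
    for (pr in family_grid[[fname]]) {
      I <- support_integral(fam, function(y) fam$d(y, pr))
      expect_equal(I, 1, tolerance = 1e-6,
                   label = paste(fname, "density integral"))
      q <- fam_quantile(fam, probe_quantiles, pr)
      expect_lt(max(abs(fam_cdf(fam, q, pr) - probe_quantiles)), 1e-8)
      y <- fam_quantile(fam, c(0.2, 0.5, 0.8), pr)
      back <- fam_quantile(fam, fam_cdf(fam, y, pr), pr)
      expect_lt(max(abs(back - y) / pmax(abs(y), 1)), 1e-7)
      # CDF is non-decreasing with the right limits
      grid <- fam_quantile(fam, seq(0.001, 0.999, length.out = 50), pr)
      expect_true(all(diff(fam_cdf(fam, grid, pr)) >= -1e-12))
      lo <- if (fam$support[1] == 0) 1e-10 else -1e6
      expect_lt(fam_cdf(fam, lo, pr), 1e-3)
      expect_gt(fam_cdf(fam, 1e6, pr), 1 - 1e-3)
    }
  }
})

test_that("density equals the numerical derivative of the CDF", {
  h <- 1e-5
  for (fname in list_families()) {
    fam <- get_family(fname)
    pr <- family_grid[[fname]][[1]]
    y <- fam_quantile(fam, c(0.2, 0.5, 0.9), pr)
    num <- (fam_cdf(fam, y + h, pr) - fam_cdf(fam, y - h, pr)) / (2 * h)
    expect_lt(max(abs(num - fam_pdf(fam, y, pr))), 1e-5)
  }
})

test_that("JSU is parameterized in mean and standard deviation", {
  fam <- get_family("JSU")
  for (pr in family_grid$JSU) {
    m <- support_integral(fam, function(y) y * fam$d(y, pr))
    v <- support_integral(fam, function(y) (y - pr$mu)^2 * fam$d(y, pr))
    expect_equal(m, pr$mu, tolerance = 1e-6)
    expect_equal(sqrt(v), pr$sigma, tolerance = 1e-6)
  }
  # moment contract holds for simulated draws too
  y <- fam_rvs(fam, 1e6, list(mu = 5, sigma = 2, nu = 1, tau = 3), seed = 42)
  expect_lt(abs(mean(y) - 5), 4 * 2 / sqrt(1e6))
  expect_lt(abs(sd(y) - 2), 0.02)
})

test_that("BCT has positive support, mu near the median, and a log-t special case", {
  fam <- get_family("BCT")
  pr <- list(mu = 1, sigma = 0.2, nu = 1, tau = 10)
  expect_equal(fam_quantile(fam, 0.5, pr), 1, tolerance = 1e-3)
  y <- fam_rvs(fam, 5000, list(mu = 0.63, sigma = 0.11, nu = 1, tau = 1.6),
               seed = 3)
  expect_true(all(y > 0))
  # nu = 0: log(y/mu)/sigma is exactly t with tau df
  pr0 <- list(mu = 1.5, sigma = 0.15, nu = 0, tau = 8)
  z <- log(fam_rvs(fam, 20000, pr0, seed = 4) / pr0$mu) / pr0$sigma
  ks <- suppressWarnings(stats::ks.test(z, stats::pt, df = 8))
  expect_gt(ks$p.value, 0.01)
  expect_error(fam_pdf(fam, -1, pr), "support")
})

test_that("random generation is seed-reproducible and matches the CDF", {
  for (fname in list_families()) {
    fam <- get_family(fname)
    pr <- family_grid[[fname]][[1]]
    a <- fam_rvs(fam, 1000, pr, seed = 99)
    b <- fam_rvs(fam, 1000, pr, seed = 99)
    expect_identical(a, b)
    y <- fam_rvs(fam, 20000, pr, seed = 100)
    ks <- suppressWarnings(stats::ks.test(y, function(q) fam_cdf(fam, q, pr)))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("inadmissible parameters and probabilities are rejected by name", {
  fam <- get_family("JSU")
  expect_error(fam_pdf(fam, 0, list(mu = 0, sigma = -1, nu = 0, tau = 2)),
               "sigma")
  expect_error(fam_pdf(fam, 0, list(mu = 0, sigma = 1, nu = 0, tau = 0)),
               "tau")
  expect_error(fam_pdf(fam, 0, list(mu = 0, sigma = 1, nu = 0)), "tau")
  expect_error(fam_quantile(fam, 1.2, family_grid$JSU[[1]]), "\\(0, 1\\)")
  expect_error(fam_rvs(get_family("BCT"), 5,
                       list(mu = -1, sigma = 0.1, nu = 1, tau = 5)), "mu")
})

test_that("left-censoring contributes the CDF at the cutoff and nothing else", {
  cf <- censor_left("NO", 0)
  pr <- list(mu = rep(0, 1), sigma = rep(1, 1))
  ll <- distreg:::censored_loglik_contrib(cf, 0, TRUE, pr)
  expect_equal(ll, log(0.5), tolerance = 1e-12)

  # no record at/below the cutoff: identical to the uncensored log-likelihood
  d <- gen_trial(300, trial_coefs$biomarker_bct, cutoff = NULL, seed = 5)
  d$censored <- 0L
  spc <- model_spec("BCT", mu = ~ treatment + log(baseline), cutoff = 1e-9)
  spu <- model_spec("BCT", mu = ~ treatment + log(baseline))
  theta <- c(-0.1, 0, 0.9, -2, 0.5, 2)
  expect_identical(as.numeric(model_loglik(d, spc, theta)),
                   as.numeric(model_loglik(d, spu, theta)))

  # censoring conservation: P(censored) + integral above cutoff = 1
  fam <- get_family("BCT")
  pr2 <- list(mu = 0.2, sigma = 0.6, nu = 0.5, tau = 5)
  pc <- fam_cdf(fam, 0.05, pr2)
  upper <- stats::integrate(function(y) fam$d(y, pr2), 0.05, Inf,
                            rel.tol = 1e-10)$value
  expect_equal(pc + upper, 1, tolerance = 1e-6)
  # generated censoring fraction approximates the CDF at the cutoff
  cset <- list(family = "BCT", links = c(mu = "log", sigma = "log",
                                         nu = "identity", tau = "log"),
               mu = c("(Intercept)" = log(0.2)),
               sigma = c("(Intercept)" = log(0.6)),
               nu = c("(Intercept)" = 0.5), tau = c("(Intercept)" = log(5)),
               baseline_law = list(dist = "lognormal", meanlog = 0, sdlog = 0.1),
               cutoff = 0.05)
  dd <- gen_trial(20000, cset, seed = 6)
  expect_lt(abs(mean(dd$censored) - pc), 4 * sqrt(pc * (1 - pc) / 20000))

  expect_error(censor_left("BCT", -1), "interior")
  expect_error(censor_left(censor_left("NO", 0), 0), "already")
})
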