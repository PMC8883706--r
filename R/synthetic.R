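#' Shipped generating coefficient sets
#'
#' Named coefficient sets for the two study scenarios the package
#' emulates, used as defaults by [gen_trial()] and [gen_longitudinal()]:
#'
#' * `biomarker_normal` — heteroscedastic normal model for a positively
#'   skewed plasma biomarker at follow-up (log link on `mu` and `sigma`;
#'   baseline enters on the log scale; sex affects the spread).
#' * `biomarker_bct` — Box-Cox t model for the same outcome, with
#'   treatment effects on `mu`, `sigma` and `nu` and baseline effects on
#'   all four parameters.
#' * `sbp_jsu` — Johnson's Su model for change in systolic blood pressure
#'   (SBP, mmHg) at follow-up: identity link on the mean, log link on the
#'   SD, treatment effect on the SD.
#' * `sbp_longitudinal` — the longitudinal version with a visit indicator
#'   (`month72`) in `mu` and `sigma` and a subject random intercept
#'   (SD 10.712 mmHg) on `mu`.
#'
#' Each element lists the `family`, per-parameter link names, per-parameter
#' named coefficient vectors (names are expressions evaluated in the
#' generated data, e.g. `log(baseline)`), the baseline covariate law, and
#' scenario extras (`sex_prev`, `cutoff`, `ranef_sd`).
#'
#' @format A named list of generating configurations.
#' @export
trial_coefs <- list(
  biomarker_normal = list(
    family = "NO",
    links = c(mu = "log", sigma = "log"),
    mu = c("(Intercept)" = 0.745, "treatment" = -0.005, "log(baseline)" = 0.319),
    sigma = c("(Intercept)" = -1.890, "log(baseline)" = -0.230, "sex" = -0.154),
    baseline_law = list(dist = "lognormal", meanlog = log(0.65), sdlog = 0.25),
    sex_prev = 0.8, cutoff = 0.05),
  biomarker_bct = list(
    family = "BCT",
    links = c(mu = "log", sigma = "log", nu = "identity", tau = "log"),
    mu = c("(Intercept)" = -0.088, "treatment" = -0.018,
           "log(baseline)" = 0.879, "sex" = -0.017),
    sigma = c("(Intercept)" = -2.796, "treatment" = 0.073,
              "log(baseline)" = -1.426, "sex" = -0.158),
    nu = c("(Intercept)" = 1.109, "treatment" = 0.124, "log(baseline)" = 0.153),
    tau = c("(Intercept)" = -0.029, "log(baseline)" = -1.184),
    baseline_law = list(dist = "lognormal", meanlog = log(0.65), sdlog = 0.25),
    sex_prev = 0.8, cutoff = 0.05),
  sbp_jsu = list(
    family = "JSU",
    links = c(mu = "identity", sigma = "log", nu = "identity", tau = "log"),
    mu = c("(Intercept)" = 79.722, "treatment" = 0.042, "baseline" = -0.589),
    sigma = c("(Intercept)" = 2.473, "treatment" = -0.067, "baseline" = 0.003),
    nu = c("(Intercept)" = 4.018, "baseline" = -0.018),
    tau = c("(Intercept)" = 1.160),
    baseline_law = list(dist = "truncnorm", mean = 138, sd = 17, lower = 1),
    sex_prev = NULL, cutoff = NULL),
  sbp_longitudinal = list(
    family = "JSU",
    links = c(mu = "identity", sigma = "log", nu = "identity", tau = "log"),
    mu = c("(Intercept)" = 79.238, "treatment" = 0.200,
           "baseline" = -0.592, "month72" = 0.747),
    sigma = c("(Intercept)" = 1.862, "treatment" = -0.048,
              "baseline" = 0.005, "month72" = 0.042),
    nu = c("(Intercept)" = 5.354, "baseline" = -0.026),
    tau = c("(Intercept)" = 0.950),
    baseline_law = list(dist = "truncnorm", mean = 138, sd = 17, lower = 1),
    sex_prev = NULL, cutoff = NULL, ranef_sd = 10.712)
)

#' Zero out the treatment coefficients of a generating set
#'
#' Convenience for null (no-treatment-effect) simulations: every
#' `treatment` entry in every parameter block is set to 0.
#'
#' @param coefs A generating set, e.g. an element of [trial_coefs].
#' @return The modified set.
#' @export
zero_treatment <- function(coefs) {
  for (pn in c("mu", "sigma", "nu", "tau")) {
    if (!is.null(coefs[[pn]]) && "treatment" %in% names(coefs[[pn]])) {
      coefs[[pn]]["treatment"] <- 0
    }
  }
  coefs
}

#' Generate a positive baseline covariate
#'
#' Draws the baseline biomarker (or baseline measurement) from a
#' positive-support law: `"lognormal"` (`meanlog`, `sdlog`), `"gamma"`
#' (`shape`, `rate`), or `"truncnorm"` (normal with `mean`, `sd` truncated
#' below at `lower` > 0, drawn by inversion). A scale of zero degenerates
#' to the constant median/mean.
#'
#' @param n Number of draws.
#' @param law List with `dist` and the law's parameters.
#' @param seed Optional integer seed.
#' @return Positive numeric vector of length `n`.
#' @examples
#' x <- gen_baseline(1000, seed = 1)
#' median(x)  # close to 0.65
#' @export
gen_baseline <- function(n, law = list(dist = "lognormal",
                                       meanlog = log(0.65), sdlog = 0.25),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dist <- match.arg(law$dist, c("lognormal", "gamma", "truncnorm"))
  x <- switch(dist,
    lognormal = stats::rlnorm(n, law$meanlog, law$sdlog),
    gamma = stats::rgamma(n, shape = law$shape, rate = law$rate),
    truncnorm = {
      lo <- if (is.null(law$lower)) 0 else law$lower
      if (lo < 0) stop("baseline law must have positive support")
      if (law$sd == 0) rep(law$mean, n) else {
        plo <- stats::pnorm(lo, law$mean, law$sd)
        stats::qnorm(stats::runif(n, plo, 1), law$mean, law$sd)
      }
    })
  if (any(x <= 0)) stop("baseline law must have positive support")
  x
}

# evaluate a named coefficient vector as a linear predictor over data
eval_predictor <- function(coefs_vec, df) {
  eta <- rep(0, nrow(df))
  for (nm in names(coefs_vec)) {
    v <- if (nm == "(Intercept)") 1 else {
      eval(str2lang(nm), df, baseenv())
    }
    eta <- eta + coefs_vec[[nm]] * v
  }
  eta
}

# parameters for every row of df from a generating set; errors name the
# offending row and parameter
generating_params <- function(coefs, df) {
  fam <- get_family(coefs$family)
  params <- list()
  for (pn in fam$param_names) {
    if (is.null(coefs[[pn]])) stop("generating set lacks coefficients for ", pn)
    eta <- eval_predictor(coefs[[pn]], df)
    theta <- get_link(coefs$links[[pn]])$linkinv(eta)
    bad <- which(!is.finite(theta) | !fam$constraints[[pn]](theta))
    if (length(bad)) {
      stop("link inverse gives an inadmissible value for parameter '", pn,
           "' in generated row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    }
    params[[pn]] <- theta
  }
  params
}

#' Generate a synthetic two-arm trial dataset
#'
#' Emulates a cross-sectional two-arm trial: treatment is Bernoulli
#' (`allocation`), independent of everything else; sex is Bernoulli
#' (`sex_prev`) when the generating set uses it; the positive baseline
#' covariate comes from [gen_baseline()]; per-row distribution parameters
#' are computed by pushing the generating coefficients through the links;
#' the response is drawn from the family; and left-censoring at the
#' detection limit is applied last — censored responses are stored at the
#' cutoff with `censored = 1`, mirroring detection-limit data entry.
#'
#' @param n Number of participants.
#' @param coefs Generating set (see [trial_coefs]).
#' @param allocation P(treatment = 1).
#' @param baseline_law Override of the set's baseline law.
#' @param sex_prev Override of the set's sex prevalence.
#' @param cutoff Detection limit; `NULL` disables censoring. Defaults to
#'   the generating set's value.
#' @param seed Integer seed.
#' @return Data frame with columns `id`, `treatment`, (`sex`,) `baseline`,
#'   `response`, `censored`.
#' @examples
#' d <- gen_trial(500, trial_coefs$biomarker_bct, seed = 7)
#' mean(d$censored)
#' @export
gen_trial <- function(n, coefs = trial_coefs$biomarker_bct, allocation = 0.5,
                      baseline_law = NULL, sex_prev = NULL,
                      cutoff = coefs$cutoff, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(baseline_law)) baseline_law <- coefs$baseline_law
  if (is.null(sex_prev)) sex_prev <- coefs$sex_prev
  fam <- get_family(coefs$family)
  df <- data.frame(id = seq_len(n),
                   treatment = stats::rbinom(n, 1, allocation))
  uses_sex <- any(vapply(fam$param_names, function(pn)
    "sex" %in% names(coefs[[pn]]), logical(1)))
  if (uses_sex) {
    if (is.null(sex_prev)) sex_prev <- 0.8
    df$sex <- stats::rbinom(n, 1, sex_prev)
  }
  df$baseline <- gen_baseline(n, baseline_law)
  params <- generating_params(coefs, df)
  df$response <- fam$r(n, params)
  if (!is.null(cutoff)) {
    df$censored <- as.integer(df$response <= cutoff)
    df$response[df$censored == 1] <- cutoff
  } else {
    df$censored <- 0L
  }
  df
}

#' Generate a synthetic longitudinal two-arm trial dataset
#'
#' Each participant is observed at every visit in `months`; indicator
#' columns `month<m>` (all visits after the first) enter the predictors
#' via the generating coefficients. One shared Gaussian intercept per
#' subject, with SD `ranef_sd`, is added to the subject's `mu` predictor
#' across all of that subject's rows, inducing within-subject correlation;
#' `ranef_sd = 0` gives independent rows.
#'
#' @param n_subjects Number of participants.
#' @param coefs Generating set (default the longitudinal SBP set).
#' @param months Visit labels (at least two).
#' @param ranef_sd Random-intercept SD (>= 0).
#' @inheritParams gen_trial
#' @return Data frame with columns `id`, `visit`, `treatment`, `baseline`,
#'   `month<m>` indicators, `response`, `censored`.
#' @examples
#' d <- gen_longitudinal(100, seed = 3)
#' @export
gen_longitudinal <- function(n_subjects, coefs = trial_coefs$sbp_longitudinal,
                             months = c(48, 72),
                             ranef_sd = coefs$ranef_sd, allocation = 0.5,
                             baseline_law = NULL, cutoff = coefs$cutoff,
                             seed = NULL) {
  if (length(months) < 2) stop("at least two visit months are required")
  if (is.null(ranef_sd) || is.na(ranef_sd)) ranef_sd <- 0
  if (ranef_sd < 0) stop("ranef_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(baseline_law)) baseline_law <- coefs$baseline_law
  fam <- get_family(coefs$family)
  subj <- data.frame(id = seq_len(n_subjects),
                     treatment = stats::rbinom(n_subjects, 1, allocation),
                     baseline = gen_baseline(n_subjects, baseline_law))
  b <- if (ranef_sd > 0) stats::rnorm(n_subjects, 0, ranef_sd) else
    rep(0, n_subjects)
  df <- subj[rep(seq_len(n_subjects), each = length(months)), ]
  df$visit <- rep(months, times = n_subjects)
  rownames(df) <- NULL
  for (m in months[-1]) df[[paste0("month", m)]] <- as.integer(df$visit == m)
  params <- generating_params(coefs, df)
  mu_link <- get_link(coefs$links[["mu"]])
  eta_mu <- mu_link$linkfun(params$mu) + b[df$id]
  params$mu <- mu_link$linkinv(eta_mu)
  df$response <- fam$r(nrow(df), params)
  if (!is.null(cutoff)) {
    df$censored <- as.integer(df$response <= cutoff)
    df$response[df$censored == 1] <- cutoff
  } else {
    df$censored <- 0L
  }
  df
}
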