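# ---- likelihood machinery --------------------------------------------------

# split a flat coefficient vector into per-parameter blocks
split_par <- function(par, idx) lapply(idx, function(i) par[i])

# per-record distribution parameters from designs + coefficients via links
compute_params <- function(designs, beta, links) {
  out <- lapply(names(designs), function(pn) {
    eta <- as.numeric(designs[[pn]] %*% beta[[pn]])
    get_link(links[[pn]])$linkinv(eta)
  })
  names(out) <- names(designs)
  out
}

# TRUE if every per-record parameter satisfies the family constraints
params_admissible <- function(family, params) {
  fam <- base_family(family)
  for (pn in fam$param_names) {
    v <- params[[pn]]
    if (any(!is.finite(v)) || !all(fam$constraints[[pn]](v))) return(FALSE)
  }
  TRUE
}

# censoring indicator for a dataset under a (possibly censored) family
censor_flags <- function(family, data) {
  if (!inherits(family, "dr_censored_family")) {
    return(rep(FALSE, nrow(data)))
  }
  if (!is.null(data$censored)) {
    as.logical(data$censored)
  } else {
    data$response <= family$cutoff
  }
}

#' Log-likelihood of a model specification at given coefficients
#'
#' Sum of per-record log densities; for a left-censored family, records
#' flagged censored (column `censored`, else `response <= cutoff`)
#' contribute the log CDF at the cutoff instead. Coefficients yielding an
#' inadmissible parameter for any record (e.g. a non-positive `sigma` under
#' an identity link) give `-Inf` with attribute `admissible = FALSE`
#' rather than an error, so optimizers can recover.
#'
#' @param data Data frame with a `response` column and the spec's
#'   covariates.
#' @param spec A [model_spec()]; random intercepts are not handled here
#'   (see [fit_random_intercept()]).
#' @param coefficients Either a flat numeric vector in design order or a
#'   named list of per-parameter coefficient vectors.
#' @return Scalar log-likelihood with attribute `admissible`.
#' @export
model_loglik <- function(data, spec, coefficients) {
  data <- as.data.frame(data)
  has_ri <- !is.null(spec$random_intercept)
  designs <- build_design(data, spec)
  idx <- par_index(designs, random_intercept = has_ri)
  if (is.list(coefficients)) {
    coefficients <- unlist(coefficients, use.names = FALSE)
  }
  if (length(coefficients) != attr(idx, "n_par")) {
    stop("coefficient vector has length ", length(coefficients),
         " but the design requires ", attr(idx, "n_par"))
  }
  if (has_ri) {
    # marginal likelihood, random intercept SD supplied as log(sd) last
    llfun <- make_ri_loglik(data, spec, designs, idx, quad_points = 15)
    ll <- llfun(coefficients)
    return(structure(as.numeric(ll), admissible = is.finite(ll)))
  }
  beta <- split_par(coefficients, idx)
  params <- compute_params(designs, beta, spec$links)
  if (!params_admissible(spec$family, params)) {
    return(structure(-Inf, admissible = FALSE))
  }
  cen <- censor_flags(spec$family, data)
  ll <- sum(censored_loglik_contrib(spec$family, data$response, cen, params))
  if (!is.finite(ll)) return(structure(-Inf, admissible = FALSE))
  structure(ll, admissible = TRUE)
}

# fast closure version used inside optimization (designs prebuilt)
make_loglik <- function(y, cen, designs, spec, idx) {
  family <- spec$family
  links <- spec$links
  function(par) {
    beta <- split_par(par, idx)
    params <- compute_params(designs, beta, links)
    if (!params_admissible(family, params)) return(-Inf)
    ll <- sum(censored_loglik_contrib(family, y, cen, params))
    if (!is.finite(ll)) -Inf else ll
  }
}

# ---- starting values -------------------------------------------------------

start_values <- function(y, designs, spec) {
  fam <- base_family(spec$family)
  mu_link <- get_link(spec$links[["mu"]])
  yw <- if (spec$links[["mu"]] == "log") log(pmax(y, 1e-8)) else y
  b_mu <- stats::lm.fit(designs$mu, yw)$coefficients
  b_mu[is.na(b_mu)] <- 0
  res <- yw - drop(designs$mu %*% b_mu)
  s0 <- max(stats::sd(res), 1e-4)
  start <- list(mu = b_mu)
  if ("sigma" %in% fam$param_names) {
    b_s <- numeric(ncol(designs$sigma))
    b_s[1] <- if (spec$links[["sigma"]] == "log") log(s0) else s0
    start$sigma <- b_s
  }
  if ("nu" %in% fam$param_names) {
    b_n <- numeric(ncol(designs$nu))
    b_n[1] <- switch(fam$name, BCT = 0.5, 0)
    start$nu <- b_n
  }
  if ("tau" %in% fam$param_names) {
    b_t <- numeric(ncol(designs$tau))
    tau0 <- switch(fam$name, BCT = 10, JSU = 4, 4)
    b_t[1] <- if (spec$links[["tau"]] == "log") log(tau0) else tau0
    start$tau <- b_t
  }
  unlist(start[names(designs)], use.names = FALSE)
}

# ---- fitting ---------------------------------------------------------------

#' Fit a distributional regression model by maximum likelihood
#'
#' All coefficient blocks (one per distribution parameter) are maximized
#' jointly: quasi-Newton (BFGS) search from data-driven starting values,
#' followed by Newton polishing steps using numerically differentiated
#' gradient and Hessian until the scaled gradient falls below `gtol`.
#' Standard errors come from the inverse of the observed information
#' matrix (negative Hessian of the log-likelihood at the optimum). The fit
#' is deterministic given the data and options.
#'
#' If the specification carries a random intercept the marginal likelihood
#' is used (see [fit_random_intercept()]).
#'
#' @param data Data frame with `response` plus all covariates named in the
#'   spec (and `censored` for censored fits, if available).
#' @param spec A [model_spec()].
#' @param start Optional starting coefficient vector (flat, design order).
#' @param maxit Maximum BFGS iterations.
#' @param gtol Convergence tolerance: the fit is flagged converged when the
#'   maximum absolute gradient component is below `gtol * max(1, |loglik|)`.
#' @param polish Maximum number of Newton polishing steps.
#' @param quad_points Gauss-Hermite nodes for the random-intercept marginal
#'   likelihood.
#' @return A `dr_fit` object with components `coefficients`, `se`, `vcov`,
#'   `loglik`, `df`, `aic`, `converged`, `max_grad`, `n_obs`, `n_censored`,
#'   `spec`.
#' @examples
#' d <- gen_trial(n = 300, coefs = trial_coefs$biomarker_normal, seed = 1)
#' f <- fit_ml(d, model_spec("NO", mu = ~ treatment + log(baseline)))
#' coef(f)
#' @export
fit_ml <- function(data, spec, start = NULL, maxit = 500, gtol = 1e-5,
                   polish = 8, quad_points = 15) {
  stopifnot(inherits(spec, "dr_spec"))
  if (!is.null(spec$random_intercept)) {
    return(fit_random_intercept(data, spec, start = start, maxit = maxit,
                                gtol = gtol, polish = polish,
                                quad_points = quad_points))
  }
  data <- as.data.frame(data)
  if (is.null(data$response)) stop("data must contain a 'response' column")
  y <- data$response
  designs <- build_design(data, spec)
  idx <- par_index(designs)
  n_par <- attr(idx, "n_par")
  if (nrow(data) <= n_par) {
    stop("number of observations (", nrow(data),
         ") must exceed the number of coefficients (", n_par, ")")
  }
  cen <- censor_flags(spec$family, data)
  if (inherits(spec$family, "dr_family") &&
      base_family(spec$family)$support[1] == 0 && any(y <= 0)) {
    stop("family ", base_family(spec$family)$name,
         " has positive support but the response contains values <= 0")
  }
  llfun <- make_loglik(y, cen, designs, spec, idx)
  if (is.null(start)) start <- start_values(y, designs, spec)
  fit <- optimize_loglik(llfun, start, maxit = maxit, gtol = gtol,
                         polish = polish)
  finish_fit(fit, spec, designs, idx, n_obs = nrow(data),
             n_censored = sum(cen), random_intercept = FALSE)
}

# shared BFGS + Newton-polish driver; llfun returns a log-likelihood
optimize_loglik <- function(llfun, start, maxit, gtol, polish) {
  nll <- function(par) {
    v <- llfun(par)
    if (!is.finite(v)) 1e10 else -v
  }
  gr <- function(par) pracma::grad(nll, par)
  opt <- stats::optim(start, nll, gr = gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  par <- opt$par
  val <- opt$value
  g <- gr(par)
  H <- NULL
  tol <- function(v) gtol * max(1, abs(v))
  for (k in seq_len(polish)) {
    if (max(abs(g)) < tol(val)) break
    H <- pracma::hessian(nll, par)
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H + diag(1e-8, nrow(H)), -g),
                     error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      cand <- par + lam * step
      vc <- nll(cand)
      if (vc <= val + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-6) { cand <- par; vc <- val; break }
    }
    if (identical(cand, par)) break
    par <- cand; val <- vc; g <- gr(par); H <- NULL
  }
  if (is.null(H)) {
    H <- pracma::hessian(nll, par)
    H <- (H + t(H)) / 2
  }
  list(par = par, loglik = -val, grad = g, hess = H,
       converged = (opt$convergence == 0 || max(abs(g)) < tol(val)) &&
         max(abs(g)) < tol(val))
}

finish_fit <- function(fit, spec, designs, idx, n_obs, n_censored,
                       random_intercept) {
  n_par <- attr(idx, "n_par")
  vc <- tryCatch({
    V <- solve(fit$hess)
    V <- (V + t(V)) / 2
    if (any(!is.finite(V)) || any(diag(V) < 0)) NULL else V
  }, error = function(e) NULL)
  if (is.null(vc)) {
    warning("observed information is singular; standard errors unavailable")
    vc <- matrix(NA_real_, n_par, n_par)
  }
  nm <- flat_par_names(designs, random_intercept)
  cf <- fit$par
  se <- sqrt(diag(vc))
  if (random_intercept) {
    # report the random-intercept SD on its natural scale (delta method)
    k <- n_par
    sd_b <- exp(cf[k])
    se[k] <- sd_b * se[k]
    cf[k] <- sd_b
    nm[k] <- "ranef.sd"
  }
  names(cf) <- nm
  names(se) <- nm
  dimnames(vc) <- list(nm, nm)
  df <- n_par
  out <- list(coefficients = cf, se = se, vcov = vc,
              loglik = fit$loglik, df = df,
              aic = -2 * fit$loglik + 2 * df,
              converged = fit$converged, max_grad = max(abs(fit$grad)),
              n_obs = n_obs, n_censored = n_censored,
              par = fit$par, index = idx, spec = spec)
  class(out) <- "dr_fit"
  out
}

#' Akaike information criterion of a fit
#'
#' `-2 * loglik + 2 * df`, where `df` counts every estimated coefficient
#' plus the random-intercept SD when present.
#'
#' @param fit A `dr_fit`.
#' @return Scalar AIC.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "dr_fit"))
  -2 * fit$loglik + 2 * fit$df
}

#' Fitted per-record distribution parameters
#'
#' @param fit A `dr_fit`.
#' @param data Data frame to evaluate the linear predictors on (defaults
#'   must be supplied; the fit does not store its data).
#' @return Named list of per-record parameter vectors (`mu`, `sigma`, ...).
#' @export
fitted_params <- function(fit, data) {
  designs <- build_design(data, fit$spec)
  beta <- split_par(fit$par, fit$index)
  compute_params(designs, beta, fit$spec$links)
}

# ---- methods ---------------------------------------------------------------

#' @export
print.dr_fit <- function(x, ...) {
  cat("Distributional regression fit: family ", x$spec$family$name,
      if (!is.null(x$spec$random_intercept)) " + random intercept", "\n",
      sep = "")
  cat("  n = ", x$n_obs, " (", x$n_censored, " censored), df = ", x$df,
      ", logLik = ", formatC(x$loglik, format = "f", digits = 2),
      ", AIC = ", formatC(x$aic, format = "f", digits = 2), "\n", sep = "")
  if (!x$converged) cat("  WARNING: fit did not converge (max |grad| = ",
                        format(x$max_grad), ")\n", sep = "")
  print(round(coef_table(x), 4))
  invisible(x)
}

#' Coefficient table with standard errors, z and p values
#'
#' Wald z statistics use the standard normal reference distribution.
#'
#' @param fit A `dr_fit`.
#' @return Data frame with columns `estimate`, `se`, `z`, `p`.
#' @export
coef_table <- function(fit) {
  z <- fit$coefficients / fit$se
  data.frame(estimate = fit$coefficients, se = fit$se, z = z,
             p = 2 * stats::pnorm(-abs(z)), row.names = names(fit$coefficients))
}

#' @export
coef.dr_fit <- function(object, ...) object$coefficients

#' @export
vcov.dr_fit <- function(object, ...) object$vcov

#' @export
logLik.dr_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n_obs,
            class = "logLik")
}

#' @export
summary.dr_fit <- function(object, ...) {
  print(object)
  invisible(coef_table(object))
}
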