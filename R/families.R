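# ---- internal constructors -------------------------------------------------

new_family <- function(name, param_names, support, default_links,
                       constraints, d, p, q, r, label) {
  structure(list(
    name = name,
    n_params = length(param_names),
    param_names = param_names,
    support = support,           # c(lower, upper), open interval
    default_links = default_links,
    constraints = constraints,   # named list of predicate functions
    d = d, p = p, q = q, r = r,
    label = label),
    class = "dr_family")
}

#' @export
print.dr_family <- function(x, ...) {
  cat("<dr_family> ", x$name, " (", x$label, ")\n", sep = "")
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  cat("  support: (", x$support[1], ", ", x$support[2], ")\n", sep = "")
  cat("  default links:",
      paste(names(x$default_links), x$default_links, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

recycle_params <- function(params, n) {
  lapply(params, function(v) rep_len(as.numeric(v), n))
}

#' Validate a parameter set against a family's constraints
#'
#' Checks that every parameter the family requires is present and lies in
#' its admissible range (e.g. `sigma > 0`). Violations raise an error naming
#' the offending parameter; this runs before any density evaluation.
#'
#' @param family A [get_family()] object.
#' @param params Named list of parameter values (vectors are allowed and are
#'   checked element-wise).
#' @return Invisibly, the validated parameter list.
#' @export
validate_params <- function(family, params) {
  if (inherits(family, "dr_censored_family")) family <- family$base
  missing <- setdiff(family$param_names, names(params))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  for (pn in family$param_names) {
    v <- params[[pn]]
    if (any(!is.finite(v)) || !all(family$constraints[[pn]](v))) {
      stop("inadmissible value for parameter '", pn, "' in family ",
           family$name, call. = FALSE)
    }
  }
  invisible(params)
}

check_support <- function(family, y) {
  if (any(y <= family$support[1] | y >= family$support[2])) {
    stop("response value outside the support (", family$support[1], ", ",
         family$support[2], ") of family ", family$name, call. = FALSE)
  }
}

pos <- function(v) v > 0
anyreal <- function(v) rep(TRUE, length(v))

# ---- normal ----------------------------------------------------------------

family_NO <- function() {
  new_family(
    name = "NO", param_names = c("mu", "sigma"),
    support = c(-Inf, Inf),
    default_links = c(mu = "identity", sigma = "log"),
    constraints = list(mu = anyreal, sigma = pos),
    d = function(y, pr, log = FALSE) stats::dnorm(y, pr$mu, pr$sigma, log = log),
    p = function(y, pr) stats::pnorm(y, pr$mu, pr$sigma),
    q = function(u, pr) stats::qnorm(u, pr$mu, pr$sigma),
    r = function(n, pr) stats::rnorm(n, pr$mu, pr$sigma),
    label = "normal (mean, sd)")
}

# ---- Johnson's Su, mean/sd parameterization --------------------------------

# mu is the mean and sigma the standard deviation; nu controls skewness
# (nu = 0 gives a distribution symmetric about mu) and tau the tail weight
# (tau -> Inf approaches the normal). Obtained from Johnson's original Su by
# moment matching: if Z ~ N(0,1) then
#   y = mu + c*sigma*( sqrt(w)*sinh(Omega) + sinh((Z + nu)/tau) ),
# with w = exp(1/tau^2), Omega = -nu/tau and
# c = [ (w-1)(w*cosh(2*Omega)+1)/2 ]^{-1/2}.
jsu_const <- function(pr) {
  rt <- 1 / pr$tau
  w <- exp(rt^2)
  omega <- -pr$nu * rt
  # expm1 keeps c accurate as tau -> Inf (w -> 1)
  cc <- (0.5 * expm1(rt^2) * (w * cosh(2 * omega) + 1))^(-0.5)
  list(rt = rt, w = w, omega = omega, cc = cc,
       xi = pr$mu + cc * pr$sigma * sqrt(w) * sinh(omega))
}

family_JSU <- function() {
  dj <- function(y, pr, log = FALSE) {
    k <- jsu_const(pr)
    z <- (y - k$xi) / (k$cc * pr$sigma)
    r <- -pr$nu + asinh(z) / k$rt
    ll <- -log(pr$sigma) - log(k$cc) - log(k$rt) - 0.5 * log1p(z^2) -
      0.5 * log(2 * pi) - 0.5 * r^2
    if (log) ll else exp(ll)
  }
  pj <- function(y, pr) {
    k <- jsu_const(pr)
    z <- (y - k$xi) / (k$cc * pr$sigma)
    stats::pnorm(-pr$nu + asinh(z) / k$rt)
  }
  qj <- function(u, pr) {
    k <- jsu_const(pr)
    k$xi + k$cc * pr$sigma * sinh(k$rt * (stats::qnorm(u) + pr$nu))
  }
  new_family(
    name = "JSU", param_names = c("mu", "sigma", "nu", "tau"),
    support = c(-Inf, Inf),
    default_links = c(mu = "identity", sigma = "log", nu = "identity", tau = "log"),
    constraints = list(mu = anyreal, sigma = pos, nu = anyreal, tau = pos),
    d = dj, p = pj, q = qj,
    r = function(n, pr) {
      pr <- recycle_params(pr, n)
      k <- jsu_const(pr)
      k$xi + k$cc * pr$sigma * sinh(k$rt * (stats::rnorm(n) + pr$nu))
    },
    label = "Johnson's Su (mean, sd, skew, kurtosis)")
}

# ---- Box-Cox t -------------------------------------------------------------

# Positive support; mu is (approximately) the median, sigma the approximate
# coefficient of variation, nu the skewness (Box-Cox power) and tau the
# degrees of freedom of the t kernel. The Box-Cox transform
#   z = ((y/mu)^nu - 1)/(sigma*nu)   (nu != 0),  z = log(y/mu)/sigma (nu = 0)
# is modelled as truncated t with tau df; the normalizing constant
# F_T(1/(sigma*|nu|)) accounts for the truncation to positive y.
bct_z <- function(y, pr) {
  ifelse(abs(pr$nu) > 1e-12,
         ((y / pr$mu)^pr$nu - 1) / (pr$nu * pr$sigma),
         log(y / pr$mu) / pr$sigma)
}

family_BCT <- function() {
  db <- function(y, pr, log = FALSE) {
    pr <- recycle_params(pr, length(y))
    z <- bct_z(y, pr)
    lc <- stats::pt(1 / (pr$sigma * abs(pr$nu)), pr$tau, log.p = TRUE) # nu=0 -> log(1)=0
    ll <- (pr$nu - 1) * log(y) - pr$nu * log(pr$mu) - log(pr$sigma) +
      stats::dt(z, pr$tau, log = TRUE) - lc
    if (log) ll else exp(ll)
  }
  pb <- function(y, pr) {
    pr <- recycle_params(pr, length(y))
    z <- bct_z(y, pr)
    C <- stats::pt(1 / (pr$sigma * abs(pr$nu)), pr$tau)
    F2 <- ifelse(pr$nu > 1e-12, 1 - C, 0)
    pmin(pmax((stats::pt(z, pr$tau) - F2) / C, 0), 1)
  }
  qb <- function(u, pr) {
    pr <- recycle_params(pr, length(u))
    C <- stats::pt(1 / (pr$sigma * abs(pr$nu)), pr$tau)
    z <- ifelse(pr$nu > 1e-12,
                stats::qt(1 - (1 - u) * C, pr$tau),
                stats::qt(u * C, pr$tau))
    ifelse(abs(pr$nu) > 1e-12,
           pr$mu * pmax(pr$nu * pr$sigma * z + 1, 0)^(1 / pr$nu),
           pr$mu * exp(pr$sigma * z))
  }
  new_family(
    name = "BCT", param_names = c("mu", "sigma", "nu", "tau"),
    support = c(0, Inf),
    default_links = c(mu = "log", sigma = "log", nu = "identity", tau = "log"),
    constraints = list(mu = pos, sigma = pos, nu = anyreal, tau = pos),
    d = db, p = pb, q = qb,
    r = function(n, pr) {
      pr <- recycle_params(pr, n)
      C <- stats::pt(1 / (pr$sigma * abs(pr$nu)), pr$tau)
      u <- stats::runif(n)
      z <- ifelse(pr$nu > 1e-12,
                  stats::qt(1 - (1 - u) * C, pr$tau),
                  stats::qt(u * C, pr$tau))
      ifelse(abs(pr$nu) > 1e-12,
             pr$mu * pmax(pr$nu * pr$sigma * z + 1, 0)^(1 / pr$nu),
             pr$mu * exp(pr$sigma * z))
    },
    label = "Box-Cox t (median, cv, skew, df)")
}

# ---- skew normal (Azzalini direct parameterization) ------------------------

# density 2/sigma * phi(z) * Phi(nu * z), z = (y - mu)/sigma. The CDF uses
# Owen's T function, computed by adaptive quadrature.
owen_t <- function(h, a) {
  # T(h, a) = (1/2pi) * int_0^a exp(-h^2(1+x^2)/2)/(1+x^2) dx; odd in a
  mapply(function(h1, a1) {
    if (a1 == 0) return(0)
    s <- sign(a1); a1 <- abs(a1)
    val <- stats::integrate(function(x) exp(-0.5 * h1^2 * (1 + x^2)) / (1 + x^2),
                            0, a1, rel.tol = 1e-10, abs.tol = 1e-12)$value
    s * val / (2 * pi)
  }, h, a)
}

family_SN <- function() {
  ds <- function(y, pr, log = FALSE) {
    z <- (y - pr$mu) / pr$sigma
    ll <- log(2) - log(pr$sigma) + stats::dnorm(z, log = TRUE) +
      stats::pnorm(pr$nu * z, log.p = TRUE)
    if (log) ll else exp(ll)
  }
  ps <- function(y, pr) {
    pr <- recycle_params(pr, length(y))
    z <- (y - pr$mu) / pr$sigma
    pmin(pmax(stats::pnorm(z) - 2 * owen_t(z, pr$nu), 0), 1)
  }
  new_family(
    name = "SN", param_names = c("mu", "sigma", "nu"),
    support = c(-Inf, Inf),
    default_links = c(mu = "identity", sigma = "log", nu = "identity"),
    constraints = list(mu = anyreal, sigma = pos, nu = anyreal),
    d = ds, p = ps,
    q = function(u, pr) {
      pr_n <- recycle_params(pr, length(u))
      mapply(function(u1, m, s, nu) {
        f <- function(y) ps(y, list(mu = m, sigma = s, nu = nu)) - u1
        lo <- m - 12 * s; hi <- m + 12 * s
        stats::uniroot(f, c(lo, hi), tol = 1e-10, extendInt = "upX")$root
      }, u, pr_n$mu, pr_n$sigma, pr_n$nu)
    },
    r = function(n, pr) {
      pr <- recycle_params(pr, n)
      delta <- pr$nu / sqrt(1 + pr$nu^2)
      u1 <- stats::rnorm(n); u2 <- stats::rnorm(n)
      pr$mu + pr$sigma * (delta * abs(u1) + sqrt(1 - delta^2) * u2)
    },
    label = "skew normal (location, scale, shape)")
}

# ---- registry and generic front-ends ---------------------------------------

#' Look up a response family by name
#'
#' The registry holds the four continuous response distributions used for
#' two-arm trial outcomes: `"NO"` (normal), `"JSU"` (Johnson's Su,
#' parameterized so that `mu` is the mean and `sigma` the standard
#' deviation), `"BCT"` (Box-Cox t, positive support, `mu` approximately the
#' median and `sigma` approximately the coefficient of variation) and
#' `"SN"` (Azzalini skew normal).
#'
#' @param name Family code, one of `"NO"`, `"JSU"`, `"BCT"`, `"SN"`, or an
#'   existing `dr_family` object (returned unchanged).
#' @return A `dr_family` object with density/CDF/quantile/random components.
#' @examples
#' fam <- get_family("JSU")
#' fam_pdf(fam, 5, list(mu = 5, sigma = 2, nu = 0, tau = 3))
#' @export
get_family <- function(name) {
  if (inherits(name, "dr_family")) return(name)
  switch(toupper(name),
         NO = family_NO(), NORMAL = family_NO(),
         JSU = family_JSU(),
         BCT = family_BCT(),
         SN = family_SN(),
         stop("unknown family '", name, "'; available: ",
              paste(list_families(), collapse = ", ")))
}

#' @rdname get_family
#' @export
list_families <- function() c("NO", "JSU", "BCT", "SN")

#' Density, CDF, quantile and random generation for a family
#'
#' Front-ends that validate the parameter set against the family's
#' constraints and the response values against its support before
#' dispatching to the family's own functions. All are vectorized over `y`
#' (or `u`) and recycle parameter vectors.
#'
#' @param family A family from [get_family()] (a censored family delegates
#'   to its base distribution).
#' @param y,u Response values / probabilities in (0,1).
#' @param params Named list of parameter values (`mu`, `sigma`, ...).
#' @param log Return the log density?
#' @param n Number of draws.
#' @param seed Optional integer seed for reproducible draws.
#' @return Numeric vector.
#' @export
fam_pdf <- function(family, y, params, log = FALSE) {
  family <- get_family(base_family(family))
  validate_params(family, params)
  check_support(family, y)
  family$d(y, recycle_params(params, length(y)), log = log)
}

#' @rdname fam_pdf
#' @export
fam_cdf <- function(family, y, params) {
  family <- get_family(base_family(family))
  validate_params(family, params)
  check_support(family, y)
  family$p(y, recycle_params(params, length(y)))
}

#' @rdname fam_pdf
#' @export
fam_quantile <- function(family, u, params) {
  family <- get_family(base_family(family))
  validate_params(family, params)
  if (any(u <= 0 | u >= 1)) stop("probabilities must lie strictly in (0, 1)")
  family$q(u, recycle_params(params, length(u)))
}

#' @rdname fam_pdf
#' @export
fam_rvs <- function(family, n, params, seed = NULL) {
  family <- get_family(base_family(family))
  validate_params(family, params)
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  family$r(n, params)
}

# returns the base family of a (possibly censored) family
base_family <- function(family) {
  if (inherits(family, "dr_censored_family")) family$base else family
}
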