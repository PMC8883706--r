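#' Normalized (randomized) quantile residuals
#'
#' For uncensored records the residual is `qnorm(F(y | fitted params))`,
#' which is standard normal under the true model. Censored records are
#' known only to lie below the cutoff, so their residual is randomized:
#' `u ~ Uniform(0, F(cutoff | fitted params))`, residual `qnorm(u)` —
#' hence a censored residual can never exceed `qnorm(F(cutoff))`.
#' Fitted CDF values indistinguishable from 0 or 1 are clamped to keep the
#' residual at +/- 8.2 (with a warning).
#'
#' @param fit A converged `dr_fit`.
#' @param data The dataset the model was fitted to.
#' @param seed Integer seed making the censored-record randomization
#'   reproducible.
#' @return A `dr_residuals` data frame with columns `residual` and
#'   `randomized` (1 for censored records), and attribute `seed`.
#' @export
quantile_residuals <- function(fit, data, seed = 1) {
  stopifnot(inherits(fit, "dr_fit"))
  if (!fit$converged) warning("fit did not converge; residuals may be unreliable")
  data <- as.data.frame(data)
  params <- fitted_params(fit, data)
  fam <- base_family(fit$spec$family)
  cen <- censor_flags(fit$spec$family, data)
  u <- fam$p(data$response, params)
  if (any(cen)) {
    set.seed(seed)
    pc <- lapply(params, function(v) v[cen])
    Fc <- fam$p(rep(fit$spec$family$cutoff, sum(cen)), pc)
    u[cen] <- stats::runif(sum(cen), 0, Fc)
  }
  lim <- stats::pnorm(8.2)
  if (any(u >= lim | u <= 1 - lim)) {
    warning("some fitted CDF values are numerically 0 or 1; residuals clamped at +/- 8.2")
    u <- pmin(pmax(u, 1 - lim), lim)
  }
  out <- data.frame(residual = stats::qnorm(u), randomized = as.integer(cen))
  attr(out, "seed") <- seed
  class(out) <- c("dr_residuals", "data.frame")
  out
}

#' Theoretical-vs-empirical quantile table for a QQ plot
#'
#' Coordinates only (no graphics): empirical quantiles of the residuals
#' against standard-normal quantiles at the usual plotting positions
#' `(i - 0.5)/n`. Any plotting layer can render them.
#'
#' @param residuals A `dr_residuals` object or numeric vector.
#' @return Data frame with columns `theoretical` and `empirical`.
#' @export
qq_table <- function(residuals) {
  r <- if (is.data.frame(residuals)) residuals$residual else residuals
  n <- length(r)
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             empirical = sort(r))
}

#' Wald test of a single coefficient
#'
#' `z = estimate / se`, two-sided p-value from the standard normal (the
#' z-value convention of maximum-likelihood output, not a t reference).
#'
#' @param estimate Coefficient estimate.
#' @param se Its standard error (positive).
#' @param hypothesis Label stored in the result.
#' @return A `dr_test` list: `statistic`, `p_value`, `hypothesis`.
#' @examples
#' wald_test(-0.067, 0.031)  # p approximately 0.031
#' @export
wald_test <- function(estimate, se, hypothesis = "H0: coefficient = 0") {
  if (!is.numeric(se) || any(se <= 0)) stop("se must be positive")
  z <- estimate / se
  structure(list(statistic = z, df = NA_integer_,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 hypothesis = hypothesis, type = "Wald"),
            class = "dr_test")
}

#' Likelihood-ratio test of nested fits
#'
#' `2 * (loglik_alt - loglik_null)` referred to chi-square with `df`
#' degrees of freedom. The null specification must be nested in the
#' alternative and both fitted to the same data; a materially negative
#' statistic signals an optimizer failure and raises an error.
#'
#' @param fit_null,fit_alt Fitted models (`dr_fit`).
#' @param df Degrees of freedom; defaults to the difference in model df.
#' @param hypothesis Label stored in the result.
#' @return A `dr_test` list: `statistic`, `df`, `p_value`, `hypothesis`.
#' @export
lr_test <- function(fit_null, fit_alt, df = NULL,
                    hypothesis = "H0: nested restriction") {
  stopifnot(inherits(fit_null, "dr_fit"), inherits(fit_alt, "dr_fit"))
  if (fit_null$n_obs != fit_alt$n_obs) {
    stop("fits are on different numbers of observations")
  }
  if (is.null(df)) df <- fit_alt$df - fit_null$df
  if (df < 1) stop("alternative model must have more free coefficients than the null")
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  if (stat < -1e-6 * max(1, abs(fit_alt$loglik))) {
    stop("negative likelihood-ratio statistic (", format(stat),
         "): the null fit found a higher likelihood; check convergence")
  }
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 hypothesis = hypothesis, type = "LR"),
            class = "dr_test")
}

#' @export
print.dr_test <- function(x, ...) {
  cat(x$type, "test —", x$hypothesis, "\n")
  cat("  statistic =", formatC(x$statistic, digits = 4, format = "g"))
  if (!is.na(x$df)) cat(", df =", x$df)
  cat(", p =", formatC(x$p_value, digits = 4, format = "g"), "\n")
  invisible(x)
}

#' Multiplicative effect of a coefficient on a log-linked parameter
#'
#' A coefficient `b` on a log-linked parameter multiplies that parameter by
#' `exp(b)`; the value 1 is consistent with no effect. Confidence-interval
#' endpoints are exponentiated likewise (order preserved).
#'
#' @param coefficient Coefficient on the log scale.
#' @param ci Optional numeric vector `c(lower, upper)`.
#' @return `exp(coefficient)`, or a list with `ratio` and `ci` when `ci`
#'   is given.
#' @examples
#' effect_ratio(-0.048)  # 0.953: a 4.7% decrease in the parameter
#' @export
effect_ratio <- function(coefficient, ci = NULL) {
  if (is.null(ci)) return(exp(coefficient))
  list(ratio = exp(coefficient), ci = exp(ci))
}

#' AIC-based selection of the response distribution
#'
#' Fits each candidate family to the same data and ranks them by AIC
#' (ascending). Following the asymmetric convention of the selection
#' procedure, the treatment indicator enters only the `mu` predictor for
#' the normal candidate (which also keeps `sigma` constant), while
#' non-normal candidates model treatment on both `mu` and `sigma`;
#' `normal_reduced = FALSE` makes the normal use the same template as the
#' others. Candidates whose support excludes an observed response (e.g.
#' BCT with non-positive data) are skipped with a recorded reason, as are
#' candidates that fail to converge. An error is raised only when no
#' candidate yields a usable fit.
#'
#' @param data Trial dataset.
#' @param candidates Character vector of family names (at least 2).
#' @param mu,sigma Template formulas for the predictors.
#' @param normal_reduced Fit the normal with treatment on `mu` only and
#'   constant `sigma`?
#' @param links Optional named link overrides applied to every candidate
#'   (e.g. `c(mu = "log", sigma = "log")` for a positive outcome).
#' @param cutoff Optional left-censoring cutoff applied to every candidate.
#' @param ... Passed to [fit_ml()].
#' @return A `dr_selection` data frame with columns `family`, `aic`,
#'   `loglik`, `df`, `converged`, sorted by AIC; skipped candidates appear
#'   with `NA` AIC and a `reason`. The fits are in `attr(, "fits")`.
#' @export
select_distribution <- function(data, candidates = c("NO", "JSU", "BCT", "SN"),
                                mu = ~ treatment + log(baseline),
                                sigma = ~ treatment + log(baseline),
                                normal_reduced = TRUE, links = NULL,
                                cutoff = NULL, ...) {
  if (length(candidates) < 2) stop("at least two candidate families are required")
  data <- as.data.frame(data)
  y <- data$response
  rows <- list()
  fits <- list()
  for (cand in candidates) {
    fam <- get_family(cand)
    if (fam$support[1] == 0 && any(y <= 0)) {
      rows[[cand]] <- data.frame(family = cand, aic = NA_real_,
                                 loglik = NA_real_, df = NA_integer_,
                                 converged = FALSE,
                                 reason = "support excludes observed responses")
      next
    }
    lk <- if (is.null(links)) NULL else
      links[intersect(names(links), fam$param_names)]
    if (length(lk) == 0) lk <- NULL
    sp <- if (cand == "NO" && normal_reduced) {
      model_spec(cand, mu = mu, sigma = ~1, links = lk, cutoff = cutoff)
    } else {
      model_spec(cand, mu = mu, sigma = sigma, links = lk, cutoff = cutoff)
    }
    ft <- tryCatch(fit_ml(data, sp, ...), error = function(e) e)
    if (inherits(ft, "error")) {
      rows[[cand]] <- data.frame(family = cand, aic = NA_real_,
                                 loglik = NA_real_, df = NA_integer_,
                                 converged = FALSE, reason = conditionMessage(ft))
      next
    }
    fits[[cand]] <- ft
    rows[[cand]] <- data.frame(family = cand, aic = ft$aic, loglik = ft$loglik,
                               df = ft$df, converged = ft$converged,
                               reason = if (ft$converged) "" else "did not converge")
  }
  tab <- do.call(rbind, rows)
  usable <- !is.na(tab$aic) & tab$converged
  if (!any(usable)) {
    stop("no candidate produced a converged fit; reasons: ",
         paste(tab$family, tab$reason, sep = ": ", collapse = "; "))
  }
  tab <- tab[order(!usable, tab$aic), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  class(tab) <- c("dr_selection", "data.frame")
  tab
}
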