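#' Specify a distributional regression model
#'
#' A model specification pairs a response family with one link-linear
#' predictor per distribution parameter. Each predictor is given as a
#' one-sided formula over columns of the trial dataset (an intercept is
#' always included; terms may be transformed, e.g. `log(baseline)`).
#' Parameters without a formula get an intercept-only predictor.
#'
#' @param family Family name or object from [get_family()]; when `cutoff`
#'   is supplied the family is left-censored via [censor_left()].
#' @param mu,sigma,nu,tau One-sided formulas for the corresponding
#'   parameter (ignored, with a warning, if the family lacks the
#'   parameter).
#' @param links Optional named character vector overriding the family's
#'   default links, e.g. `c(mu = "log")`.
#' @param random_intercept Optional name of a subject-identifier column; a
#'   Gaussian random intercept is then added to the `mu` predictor (only
#'   `mu` carries a random intercept).
#' @param cutoff Optional left-censoring detection limit.
#' @return A `dr_spec` object.
#' @examples
#' sp <- model_spec("BCT", mu = ~ treatment + log(baseline),
#'                  sigma = ~ treatment + log(baseline), cutoff = 0.05)
#' @export
model_spec <- function(family, mu = ~1, sigma = ~1, nu = ~1, tau = ~1,
                       links = NULL, random_intercept = NULL, cutoff = NULL) {
  family <- get_family(family)
  if (!is.null(cutoff)) family <- censor_left(family, cutoff)
  formulas <- list(mu = mu, sigma = sigma, nu = nu, tau = tau)
  is_int_only <- vapply(formulas, function(f)
    identical(paste(deparse(f), collapse = ""), "~1"), logical(1))
  supplied <- names(formulas)[!is_int_only]
  extra <- setdiff(supplied, family$param_names)
  if (length(extra)) {
    warning("formula(s) for ", paste(extra, collapse = ", "),
            " ignored: family ", family$name, " has no such parameter")
  }
  formulas <- formulas[family$param_names]
  for (f in formulas) {
    if (!inherits(f, "formula") || length(f) != 2) {
      stop("parameter formulas must be one-sided, e.g. ~ treatment + log(baseline)")
    }
  }
  lk <- family$default_links
  if (!is.null(links)) {
    bad <- setdiff(names(links), family$param_names)
    if (length(bad)) stop("link supplied for unknown parameter: ",
                          paste(bad, collapse = ", "))
    lk[names(links)] <- links
  }
  for (l in lk) get_link(l)  # validate names
  if (!is.null(random_intercept) &&
      (!is.character(random_intercept) || length(random_intercept) != 1)) {
    stop("random_intercept must be a single column name (subject identifier)")
  }
  structure(list(family = family, formulas = formulas, links = lk,
                 random_intercept = random_intercept),
            class = "dr_spec")
}

#' @export
print.dr_spec <- function(x, ...) {
  cat("<dr_spec> family:", x$family$name, "\n")
  for (pn in names(x$formulas)) {
    cat("  ", format(pn, width = 5), "[", x$links[[pn]], "] ~ ",
        paste(deparse(x$formulas[[pn]][[2]]), collapse = ""), "\n", sep = "")
  }
  if (!is.null(x$random_intercept)) {
    cat("  random intercept on mu: ", x$random_intercept, "\n", sep = "")
  }
  invisible(x)
}

#' Build per-parameter design matrices
#'
#' Expands the specification's formulas against a dataset, returning one
#' model matrix per distribution parameter. The first column of every
#' matrix is the intercept; remaining columns follow the order of terms in
#' the formula, with requested transformations (e.g. `log(baseline)`)
#' applied.
#'
#' @param data A data frame (see [read_trial_csv()]).
#' @param spec A [model_spec()].
#' @return Named list of numeric matrices, one per family parameter.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(spec, "dr_spec"))
  out <- lapply(names(spec$formulas), function(pn) {
    f <- spec$formulas[[pn]]
    vars <- all.vars(f)
    missing <- setdiff(vars, names(data))
    if (length(missing)) {
      stop("unknown column(s) in ", pn, " formula: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    X <- stats::model.matrix(f, stats::model.frame(f, data, na.action = NULL))
    bad <- which(!is.finite(X), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("non-finite design values for parameter ", pn, " (e.g. log of a ",
           "non-positive covariate) in rows: ",
           paste(utils::head(sort(unique(bad[, 1])), 10), collapse = ", "),
           call. = FALSE)
    }
    X
  })
  names(out) <- names(spec$formulas)
  out
}

# index map: positions of each parameter block inside the flat coefficient
# vector (random-intercept log-SD, when present, is appended last)
par_index <- function(designs, random_intercept = FALSE) {
  sizes <- vapply(designs, ncol, integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  idx <- Map(seq, starts, ends)
  names(idx) <- names(designs)
  attr(idx, "n_par") <- ends[[length(ends)]] + as.integer(random_intercept)
  idx
}

flat_par_names <- function(designs, random_intercept = FALSE) {
  nm <- unlist(lapply(names(designs), function(pn)
    paste(pn, colnames(designs[[pn]]), sep = ".")), use.names = FALSE)
  if (random_intercept) nm <- c(nm, "ranef.sd(log)")
  nm
}
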