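#' Read a two-arm trial dataset from CSV
#'
#' Expects a comma-separated file with a header row; required columns are
#' `response` and `treatment` (values 0/1 only). Optional columns:
#' `baseline` and other covariates, `sex`, `id`, `visit`, `censored`
#' (defaulted to all-zero when absent). Rows with a missing response are
#' dropped and counted (attribute `n_dropped`, plus a message).
#'
#' @param path Path to the CSV file.
#' @param required Additional column names to require.
#' @return Data frame; attribute `n_dropped` gives the number of dropped
#'   rows.
#' @export
read_trial_csv <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- unique(c("response", "treatment", required))
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(!(d$treatment %in% c(0, 1)))
  if (length(bad)) {
    stop("treatment must be 0/1; offending row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  drop <- is.na(d$response)
  if (any(drop)) {
    message("dropped ", sum(drop), " row(s) with missing response")
    d <- d[!drop, , drop = FALSE]
  }
  if (is.null(d$censored)) d$censored <- 0L
  if (any(is.na(d))) stop("missing values remain after ingestion")
  attr(d, "n_dropped") <- sum(drop)
  d
}

# serializable description of a fit
fit_as_list <- function(fit) {
  sp <- fit$spec
  list(family = sp$family$name,
       base_family = base_family(sp$family)$name,
       cutoff = if (inherits(sp$family, "dr_censored_family"))
         sp$family$cutoff else NULL,
       formulas = lapply(sp$formulas, function(f) paste(deparse(f), collapse = "")),
       links = as.list(sp$links),
       random_intercept = sp$random_intercept,
       coefficients = as.list(fit$coefficients),
       se = as.list(fit$se),
       loglik = fit$loglik, df = fit$df, aic = fit$aic,
       converged = fit$converged, max_grad = fit$max_grad,
       n_obs = fit$n_obs, n_censored = fit$n_censored)
}

#' Write a fitted model, residuals or study result to disk
#'
#' Fits and study aggregates are serialized as JSON at full double
#' precision; per-replicate records and residual tables as CSV. Each
#' writer round-trips losslessly through the matching reader.
#'
#' @param x A `dr_fit`, `dr_residuals` or `dr_study`.
#' @param path Output path (JSON for fits/studies, CSV for residuals).
#' @param per_replicate_path For a study: optional CSV path for the
#'   per-replicate records.
#' @return Invisibly, the path written.
#' @export
write_results <- function(x, path, per_replicate_path = NULL) {
  if (inherits(x, "dr_fit")) {
    # 17 significant digits: lossless for IEEE doubles
    jsonlite::write_json(fit_as_list(x), path, auto_unbox = TRUE,
                         digits = I(17), null = "null")
  } else if (inherits(x, "dr_residuals")) {
    utils::write.csv(cbind(row = seq_len(nrow(x)), as.data.frame(x)),
                     path, row.names = FALSE)
  } else if (inherits(x, "dr_study")) {
    if (nrow(x$per_replicate) == 0) stop("empty study result: nothing to write")
    jsonlite::write_json(
      list(generator = x$generator, n_reps = x$n_reps,
           master_seed = x$master_seed, aggregates = x$aggregates),
      path, auto_unbox = TRUE, digits = I(17), null = "null")
    if (!is.null(per_replicate_path)) {
      utils::write.csv(x$per_replicate, per_replicate_path, row.names = FALSE)
    }
  } else {
    stop("don't know how to write an object of class ",
         paste(class(x), collapse = "/"))
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_fit_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Write a run manifest alongside an output file
#'
#' Records the command, a checksum of the configuration, the seed, the
#' package version, a timestamp and the input/output paths, so a run can
#' be identified and replayed. Reruns with identical manifest inputs
#' produce identical outputs.
#'
#' @param command Subcommand name.
#' @param config Configuration object (serialized into the digest).
#' @param seed Integer seed of the run.
#' @param inputs,outputs Character vectors of paths.
#' @param path Manifest path; defaults to `<first output>.manifest.json`.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(command, config, seed, inputs, outputs,
                           path = paste0(outputs[1], ".manifest.json")) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  digest <- unname(tools::md5sum(tmp))
  jsonlite::write_json(
    list(command = command, config_digest = digest, seed = seed,
         package_version = as.character(utils::packageVersion("distreg")),
         timestamp = format(Sys.time(), tz = "UTC"),
         inputs = inputs, outputs = outputs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
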