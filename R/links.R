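#' Link functions for distribution parameters
#'
#' Every distribution parameter is modelled on an unconstrained predictor
#' scale through a monotone differentiable link. Two links are provided:
#' `identity` for parameters that live on the whole real line and `log` for
#' strictly positive parameters (scale, kurtosis, positive-support
#' locations). The log link guarantees positivity of the fitted parameter
#' for any real predictor value.
#'
#' @param name `"identity"` or `"log"`.
#' @return A `dr_link` object: a list with elements `name`,
#'   `linkfun` (parameter -> predictor) and `linkinv` (predictor -> parameter).
#' @examples
#' lg <- get_link("log")
#' lg$linkinv(lg$linkfun(2.5))  # 2.5
#' @export
get_link <- function(name) {
  name <- match.arg(name, c("identity", "log"))
  out <- switch(name,
    identity = list(name = "identity",
                    linkfun = function(theta) theta,
                    linkinv = function(eta) eta),
    log = list(name = "log",
               linkfun = function(theta) {
                 if (any(theta <= 0)) stop("log link requires a positive parameter value")
                 log(theta)
               },
               linkinv = function(eta) exp(eta)))
  class(out) <- "dr_link"
  out
}
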