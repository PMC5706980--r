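#' Complementary log-log transform and its inverse
#'
#' The complementary log-log (cloglog) link maps a probability
#' \eqn{p \in (0,1)} to \eqn{\log(-\log(1-p))}. It is the natural link for
#' discrete-time hazard models when the underlying time scale is continuous:
#' an additive shift on the cloglog scale corresponds to a proportional shift
#' of the underlying continuous-time hazard, so exponentiated coefficients are
#' reported as hazard ratios.
#'
#' @param p numeric vector of probabilities, strictly inside (0, 1).
#' @param eta numeric vector on the cloglog scale (any real value).
#'
#' @return `cloglog()` returns the transformed values; `inv_cloglog()` returns
#'   probabilities in (0, 1).
#'
#' @examples
#' inv_cloglog(0.4812)          # ~0.80
#' cloglog(inv_cloglog(-1.5))   # -1.5
#' @export
cloglog <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  }
  log(-log1p(-p))
}

#' @rdname cloglog
#' @export
inv_cloglog <- function(eta) {
  if (!is.numeric(eta)) stop("`eta` must be numeric", call. = FALSE)
  -expm1(-exp(eta))
}
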