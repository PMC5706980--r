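# Model-based predicted functions: cloglog[h(t)], h(t), S(t) and hazard
# ratios versus a reference condition, per covariate condition and
# presentation.

#' Predicted hazard, survivor and hazard-ratio functions
#'
#' Evaluates the linear predictor \eqn{\eta(t)} of a cloglog hazard model at
#' each presentation for each covariate condition, and back-transforms:
#' \eqn{h(t) = 1 - \exp(-\exp(\eta))}, \eqn{S(t) = \prod_{j\le t}(1-h(j))},
#' and \eqn{HR(t) = \exp(\eta(t) - \eta_{ref}(t))} against a reference
#' condition. Accepts a fitted model or an externally supplied coefficient
#' vector (e.g. a transcribed published table).
#'
#' @param object a [fit_hazard_model()] result, or a named coefficient
#'   vector (then `spec` is required).
#' @param conditions data frame of covariate assignments, one row per
#'   condition; must contain every covariate the specification names. An
#'   optional `condition` column labels the rows.
#' @param horizon number of presentations to evaluate (default 10).
#' @param spec a [hazard_spec()] when `object` is a coefficient vector.
#' @param reference row index of the reference condition for hazard ratios
#'   (default 1).
#' @return data frame with `condition`, `TIME`, `eta`, `hazard`, `survivor`,
#'   `hazard_ratio`.
#' @examples
#' sp <- hazard_spec(baseline_degree = 0, terms = "Manmade")
#' predict_functions(c(Intercept = 0.48, Manmade = -0.33),
#'                   conditions = data.frame(Manmade = c(0, 1)),
#'                   horizon = 3, spec = sp)
#' @export
predict_functions <- function(object, conditions, horizon = 10L, spec = NULL,
                              reference = 1L) {
  if (inherits(object, "dthaz_fit")) {
    spec <- object$spec
    beta <- object$coefficients
  } else {
    if (is.null(spec)) {
      stop("`spec` is required when `object` is a coefficient vector",
           call. = FALSE)
    }
    beta <- resolve_coefficients(spec, object)
  }
  conditions <- as.data.frame(conditions)
  missing <- setdiff(spec_covariates(spec), names(conditions))
  if (length(missing)) {
    stop("conditions lack covariate(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  labels <- if ("condition" %in% names(conditions)) {
    as.character(conditions$condition)
  } else {
    covs <- spec_covariates(spec)
    if (length(covs)) {
      apply(conditions[, covs, drop = FALSE], 1, function(r) {
        paste(paste0(covs, "=", r), collapse = ",")
      })
    } else {
      rep("baseline", nrow(conditions))
    }
  }
  horizon <- as.integer(horizon)
  eta <- sapply(seq_len(horizon), function(t) {
    eta_at(spec, beta, conditions, t)
  })
  eta <- matrix(eta, nrow = nrow(conditions))
  h <- inv_cloglog(eta)
  S <- t(apply(1 - h, 1, cumprod))
  S <- matrix(S, nrow = nrow(conditions))
  hr <- exp(sweep(eta, 2, eta[reference, ], "-"))
  out <- data.frame(condition = rep(labels, each = horizon),
                    TIME = rep(seq_len(horizon), times = nrow(conditions)),
                    eta = as.vector(t(eta)), hazard = as.vector(t(h)),
                    survivor = as.vector(t(S)),
                    hazard_ratio = as.vector(t(hr)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
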