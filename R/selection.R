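# Backward elimination under the hierarchical principle: at each step the
# removable term (one whose covariate product and time power are not
# contained in any retained term) with the largest Wald p-value is dropped,
# provided p exceeds the criterion; the intercept is never dropped. One term
# is removed per step, ties broken by higher time power first, then name.

#' Backward model selection for cloglog hazard models
#'
#' Repeatedly refits the model, dropping at each step the removable term
#' (see [removable_terms()]) with the largest Wald p-value above
#' `alpha_crit`. P-values use the cluster-robust standard errors, matching
#' the inference reported for the retained terms.
#'
#' @param pp person-period data frame.
#' @param full_spec the starting [hazard_spec()].
#' @param alpha_crit retention threshold (default 0.05).
#' @param cluster clustering column for the sandwich estimator.
#' @param ... passed to [fit_hazard_model()].
#' @return list of class `"dthaz_selection"`: `trace` (data frame with
#'   `step`, `term`, `p_value`, `loglik_after`), `final_spec`, `final_fit`.
#' @export
backward_select <- function(pp, full_spec, alpha_crit = 0.05,
                            cluster = "participant_id", ...) {
  stopifnot(inherits(full_spec, "hazard_spec"))
  spec <- full_spec
  fit <- tryCatch(fit_hazard_model(pp, spec, cluster = cluster, ...),
                  error = function(e) {
                    stop("fit failure on the full model: ",
                         conditionMessage(e), call. = FALSE)
                  })
  trace <- data.frame(step = integer(0), term = character(0),
                      p_value = numeric(0), loglik_after = numeric(0),
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    cand <- removable_terms(spec)
    if (length(cand) == 0) break
    w <- fit$wald[fit$wald$term %in% cand, , drop = FALSE]
    w <- w[order(-w$p_value,
                 -vapply(w$term, function(t) parse_term(t)$power, integer(1)),
                 match(w$term, sort(w$term, method = "radix"))), ,
           drop = FALSE]
    if (w$p_value[1] <= alpha_crit) break
    victim <- w$term[1]
    step <- step + 1L
    spec <- drop_term(spec, victim)
    fit <- tryCatch(fit_hazard_model(pp, spec, cluster = cluster, ...),
                    error = function(e) {
                      stop("fit failure at selection step ", step,
                           " (after removing ", victim, "): ",
                           conditionMessage(e), call. = FALSE)
                    })
    trace <- rbind(trace,
                   data.frame(step = step, term = victim,
                              p_value = w$p_value[1], loglik_after = fit$loglik,
                              stringsAsFactors = FALSE))
  }
  structure(list(trace = trace, final_spec = spec, final_fit = fit),
            class = "dthaz_selection")
}

#' @export
print.dthaz_selection <- function(x, ...) {
  cat("Backward selection under the hierarchical principle\n")
  if (nrow(x$trace) == 0) {
    cat("  no terms removed\n")
  } else {
    tr <- x$trace
    tr$p_value <- signif(tr$p_value, 3)
    tr$loglik_after <- round(tr$loglik_after, 3)
    print(tr, row.names = FALSE)
  }
  cat("  final model:", nrow(x$final_spec$terms), "terms, loglik",
      format(x$final_fit$loglik, digits = 8), "\n")
  invisible(x)
}
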