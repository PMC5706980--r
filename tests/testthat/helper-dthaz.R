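# Shared fixtures, built in code.

# person-period table realizing given at-risk / event counts per presentation
pp_from_counts <- function(n_at_risk, n_events) {
  stopifnot(length(n_at_risk) == length(n_events), all(n_events <= n_at_risk))
  do.call(rbind, lapply(seq_along(n_at_risk), function(t) {
    data.frame(TIME = rep(t, n_at_risk[t]),
               EVENT = rep(c(1L, 0L), c(n_events[t], n_at_risk[t] - n_events[t])))
  }))
}

# one-row trial record with the full raw-design schema
trial_row <- function(participant_id = "C01", trial_index = 1L,
                      object_id = "O001", category = "natural",
                      symmetric = 0L, complex = 0L, fragment_type = "SP",
                      repetition = 0L, event_presentation = NA_integer_,
                      censored = NULL, is_patient = 0L) {
  if (is.null(censored)) censored <- as.integer(is.na(event_presentation))
  data.frame(participant_id = participant_id, is_patient = is_patient,
             trial_index = trial_index, object_id = object_id,
             category = category, symmetric = symmetric, complex = complex,
             fragment_type = fragment_type, repetition = repetition,
             event_presentation = event_presentation, censored = censored,
             stringsAsFactors = FALSE)
}

# likelihood coded independently of the package internals, for oracle fits
indep_negloglik <- function(X, y) {
  function(b) {
    h <- 1 - exp(-exp(X %*% b))
    -sum(stats::dbinom(y, 1, pmin(pmax(h, 1e-12), 1 - 1e-12), log = TRUE))
  }
}

oracle_fit <- function(X, y, start = rep(0, ncol(X))) {
  nll <- indep_negloglik(X, y)
  if (ncol(X) == 1) {
    o <- list(par = stats::optimize(function(b) nll(matrix(b)),
                                    c(-10, 10), tol = 1e-12)$minimum)
  } else {
    o <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 20000))
  }
  stats::optim(o$par, nll, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 2000))$par
}
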