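# Person-period expansion: one row per presentation at risk. A trial with
# its event at presentation k contributes k rows with EVENT = (0,...,0,1); a
# censored trial contributes max_presentations rows, all EVENT = 0. Discrete-
# time hazard models are then ordinary binary regressions on this table.

#' Expand trial outcomes to person-period format
#'
#' @param trials data frame of trial outcomes (see [simulate_buildup()] /
#'   [read_trials()]); must carry `participant_id`, `trial_index`,
#'   `event_presentation` (NA when censored) and `censored`.
#' @param max_presentations presentation horizon; censored trials contribute
#'   this many rows.
#' @return data frame with `participant_id`, `trial_id`, `TIME`, `EVENT`,
#'   the model covariate dummies (`Patient`, `Manmade`, `Symmetry`,
#'   `Complex`, `MP`, `Repetition`) when the raw design columns are present,
#'   and any remaining covariate columns copied to every row.
#' @examples
#' tr <- data.frame(participant_id = "C01", is_patient = 0, trial_index = 1,
#'                  object_id = "O001", category = "natural", symmetric = 0,
#'                  complex = 0, fragment_type = "SP", repetition = 0,
#'                  event_presentation = 3, censored = 0)
#' expand_person_period(tr, 10)$EVENT  # 0 0 1
#' @export
expand_person_period <- function(trials, max_presentations = 10L) {
  validate_trials(trials, max_presentations)
  n_rows <- ifelse(trials$censored == 1, max_presentations,
                   trials$event_presentation)
  idx <- rep(seq_len(nrow(trials)), n_rows)
  pp <- trials[idx, setdiff(names(trials), c("event_presentation", "censored")),
               drop = FALSE]
  pp$TIME <- sequence(n_rows)
  pp$EVENT <- as.integer(!is.na(trials$event_presentation[idx]) &
                           pp$TIME == trials$event_presentation[idx])
  pp$trial_id <- paste(pp$participant_id, pp$trial_index, sep = ":")
  rownames(pp) <- NULL
  if (all(c("is_patient", "category", "symmetric", "complex", "fragment_type",
            "repetition") %in% names(pp))) {
    pp <- cbind(pp, design_dummies(pp))
  }
  front <- c("participant_id", "trial_id", "TIME", "EVENT")
  pp[, c(front, setdiff(names(pp), front)), drop = FALSE]
}

#' Collapse a person-period table back to trial outcomes
#'
#' Inverse of [expand_person_period()]: for each trial the event presentation
#' is the `TIME` of its `EVENT = 1` row, and trials with no event row are
#' censored. Used to verify round-trip identity of the expansion.
#'
#' @param pp person-period data frame.
#' @return data frame with one row per `trial_id`: `participant_id`,
#'   `trial_id`, `event_presentation`, `censored`, `n_periods`.
#' @export
collapse_person_period <- function(pp) {
  stopifnot(all(c("trial_id", "TIME", "EVENT") %in% names(pp)))
  ord <- order(pp$trial_id, pp$TIME)
  pp <- pp[ord, , drop = FALSE]
  sp <- split(seq_len(nrow(pp)), pp$trial_id)
  out <- lapply(sp, function(ix) {
    ev <- which(pp$EVENT[ix] == 1)
    if (length(ev) > 1 || (length(ev) == 1 && ev != length(ix))) {
      stop("data error: EVENT=1 must occur once, on a trial's last row",
           call. = FALSE)
    }
    data.frame(participant_id = pp$participant_id[ix[1]],
               trial_id = pp$trial_id[ix[1]],
               event_presentation = if (length(ev)) pp$TIME[ix[ev]] else NA_integer_,
               censored = as.integer(length(ev) == 0),
               n_periods = length(ix), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the model design matrix from a person-period table
#'
#' Each specification term (covariate product, time power \eqn{p}) becomes a
#' column holding the covariate product times \eqn{(TIME - c)^p}, with
#' \eqn{c} the centring presentation; the intercept is a constant column.
#'
#' @param pp person-period data frame carrying `TIME` and every covariate
#'   named in `spec`.
#' @param spec a [hazard_spec()].
#' @return numeric matrix with one column per term, column names equal to the
#'   specification's term names.
#' @export
build_design_matrix <- function(pp, spec) {
  stopifnot(inherits(spec, "hazard_spec"), "TIME" %in% names(pp))
  missing <- setdiff(spec_covariates(spec), names(pp))
  if (length(missing)) {
    stop("specification names covariate(s) absent from the table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab <- spec$terms
  tc <- pp$TIME - spec$center
  X <- matrix(0, nrow(pp), nrow(tab), dimnames = list(NULL, tab$name))
  for (i in seq_len(nrow(tab))) {
    x <- rep(1, nrow(pp))
    for (v in tab$covariates[[i]]) x <- x * pp[[v]]
    X[, i] <- x * tc^tab$power[i]
  }
  X
}

#' Read and write person-period CSV files
#'
#' Plain CSV with columns `participant_id,trial_id,TIME,EVENT,<covariates>`.
#'
#' @param pp person-period data frame.
#' @param path file path.
#' @export
write_person_period <- function(pp, path) {
  utils::write.csv(pp, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_person_period
#' @export
read_person_period <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
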