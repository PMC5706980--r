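# Nonparametric life-table estimation on person-period data: at each
# presentation t, hazard = events / at-risk, and the survivor function is the
# cumulative product of (1 - hazard).

#' Estimate discrete-time hazard and survivor functions
#'
#' For each presentation \eqn{t}, \eqn{\hat h(t)} is the number of events at
#' \eqn{t} divided by the number of trials still at risk, and
#' \eqn{\hat S(t) = \prod_{j \le t} (1 - \hat h(j))}. Presentations with an
#' empty risk set get `NA` hazards (with a warning) and survivor estimation
#' stops at the last estimable presentation.
#'
#' @param pp person-period data frame with `TIME` and `EVENT`.
#' @param by optional character vector of grouping columns; use
#'   `condition_preset()` for the patient-by-stimulus condition grid.
#' @return data frame with (group columns,) `TIME`, `n_at_risk`, `n_events`,
#'   `hazard`, `survivor`.
#' @examples
#' pp <- data.frame(TIME = c(1, 1, 1, 1, 2, 2), EVENT = c(1, 1, 0, 0, 1, 0))
#' estimate_lifetable(pp)
#' @export
estimate_lifetable <- function(pp, by = NULL) {
  stopifnot(all(c("TIME", "EVENT") %in% names(pp)))
  if (nrow(pp) == 0) stop("data error: empty person-period table", call. = FALSE)
  if (is.null(by)) {
    return(lifetable_one(pp))
  }
  missing <- setdiff(by, names(pp))
  if (length(missing)) {
    stop("grouping column(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  groups <- split(pp, pp[, by, drop = FALSE], drop = TRUE)
  out <- lapply(names(groups), function(g) {
    lt <- lifetable_one(groups[[g]])
    keys <- groups[[g]][1, by, drop = FALSE]
    rownames(keys) <- NULL
    cbind(keys, lt, row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

lifetable_one <- function(pp) {
  horizon <- max(pp$TIME)
  tt <- seq_len(horizon)
  n_at_risk <- vapply(tt, function(t) sum(pp$TIME == t), integer(1))
  n_events <- vapply(tt, function(t) sum(pp$EVENT[pp$TIME == t]), integer(1))
  hazard <- ifelse(n_at_risk > 0, n_events / n_at_risk, NA_real_)
  if (anyNA(hazard)) {
    warning("empty risk set at presentation(s) ",
            paste(tt[is.na(hazard)], collapse = ", "),
            "; hazard reported as missing")
  }
  survivor <- cumprod(1 - hazard)  # NA propagates past the first empty bin
  data.frame(TIME = tt, n_at_risk = n_at_risk, n_events = n_events,
             hazard = hazard, survivor = survivor)
}

#' Condition grid of the build-up design
#'
#' The covariate columns that define the plotted experimental conditions:
#' patient status crossed with object category, symmetry, complexity and
#' fragmentation type.
#'
#' @return character vector of column names.
#' @export
condition_preset <- function() {
  c("Patient", "Manmade", "Symmetry", "Complex", "MP")
}
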