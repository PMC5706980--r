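# Synthetic build-up experiment: geometric fragmentation schedule, stimulus
# set, per-participant randomized trial design with the no-adjacent-object
# constraint, and simulation of identification outcomes from a generating
# cloglog hazard model with right-censoring at the presentation horizon.

#' Geometric fragmentation schedule
#'
#' In the build-up paradigm an object outline is revealed over repeated
#' presentations; the percentage of contour shown at level \eqn{x} of
#' \eqn{n} follows the geometric rule \eqn{100\,\alpha^{(n-x)}} so that less
#' contour is added early and more late, slowing recognition relative to a
#' linear ramp. Percentages are rounded half-up to whole percent; the final
#' level is always the intact outline (100).
#'
#' @param alpha decay factor, strictly in (0, 1). The default 0.77 starts the
#'   build-up at 10\% contour over 10 levels.
#' @param n_levels number of presentation levels (>= 1).
#' @return object of class `"fragmentation_schedule"`: list with `alpha`,
#'   `n_levels` and the integer vector `percentages`.
#' @examples
#' fragment_percentages(0.77, 10)$percentages
#' # 10 12 16 21 27 35 46 59 77 100
#' @export
fragment_percentages <- function(alpha = 0.77, n_levels = 10L) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number strictly in (0, 1)", call. = FALSE)
  }
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 1) {
    stop("`n_levels` must be an integer >= 1", call. = FALSE)
  }
  x <- seq_len(n_levels)
  pct <- as.integer(floor(100 * alpha^(n_levels - x) + 0.5))  # round half-up
  if (any(diff(pct) <= 0)) {
    warning("rounded percentages are not strictly increasing; ",
            "consider a smaller `alpha` or fewer levels")
  }
  structure(list(alpha = alpha, n_levels = n_levels, percentages = pct),
            class = "fragmentation_schedule")
}

#' @export
print.fragmentation_schedule <- function(x, ...) {
  cat("Fragmentation schedule: 100 * ", x$alpha, "^(", x$n_levels,
      " - x), x = 1..", x$n_levels, "\n  % contour: ",
      paste(x$percentages, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Configuration of a synthetic build-up experiment
#'
#' Bundles the design constants of the emulated study: seven control
#' participants plus one patient, 100 object outlines (51 manmade, 49
#' natural), symmetry more common among manmade outlines (probability 0.51
#' vs 0.31), complexity split at random, each object shown once per
#' fragmentation type (MP and SP) for 200 trials per participant, and a
#' 10-presentation horizon after which trials are right-censored.
#'
#' Complexity is drawn Bernoulli(0.5) independently of category: the original
#' dichotomization of the outline-homogeneity measure is not recoverable from
#' published summaries, so an even split is used.
#'
#' @param n_controls number of control participants.
#' @param include_patient add one patient participant (covariate `Patient`).
#' @param n_objects number of distinct object outlines.
#' @param n_manmade how many of the objects are manmade (rest natural).
#' @param p_symmetric length-2 named vector: probability an outline is
#'   globally symmetric, per category.
#' @param p_complex probability an outline is complex.
#' @param max_presentations presentation horizon (censoring point).
#' @param alpha fragmentation decay factor (see [fragment_percentages()]).
#' @return list of class `"buildup_config"`.
#' @export
buildup_config <- function(n_controls = 7L, include_patient = TRUE,
                           n_objects = 100L, n_manmade = round(0.51 * n_objects),
                           p_symmetric = c(manmade = 0.51, natural = 0.31),
                           p_complex = 0.5, max_presentations = 10L,
                           alpha = 0.77) {
  n_objects <- as.integer(n_objects)
  n_manmade <- as.integer(n_manmade)
  if (n_objects < 1) stop("`n_objects` must be >= 1", call. = FALSE)
  if (n_manmade < 0 || n_manmade > n_objects) {
    stop("`n_manmade` must lie in [0, n_objects]", call. = FALSE)
  }
  probs <- c(p_symmetric, p_complex)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_controls = as.integer(n_controls),
                 include_patient = isTRUE(include_patient),
                 n_objects = n_objects, n_manmade = n_manmade,
                 p_symmetric = p_symmetric, p_complex = p_complex,
                 max_presentations = as.integer(max_presentations),
                 alpha = alpha),
            class = "buildup_config")
}

# stimulus set: object_id, category, symmetric, complex (one draw per dataset)
make_stimuli <- function(config) {
  n <- config$n_objects
  category <- rep(c("manmade", "natural"),
                  c(config$n_manmade, n - config$n_manmade))
  p_sym <- unname(config$p_symmetric[ifelse(category == "manmade",
                                            "manmade", "natural")])
  data.frame(object_id = sprintf("O%03d", seq_len(n)),
             category = category,
             symmetric = as.integer(stats::runif(n) < p_sym),
             complex = as.integer(stats::runif(n) < config$p_complex),
             stringsAsFactors = FALSE)
}

# constrained shuffle: no object on two consecutive trials. Rejection with
# local swap repair; re-shuffles if repair stalls.
shuffle_no_adjacent <- function(ids) {
  n <- length(ids)
  if (length(unique(ids)) == 1 && n > 1) {
    stop("design error: no-adjacent-repeat ordering impossible with a single object",
         call. = FALSE)
  }
  for (attempt in 1:100) {
    ord <- sample.int(n)
    cur <- ids[ord]
    for (pass in 1:200) {
      bad <- which(cur[-1] == cur[-n]) + 1L
      if (length(bad) == 0) return(ord)
      for (i in bad) {
        j <- sample.int(n, 1)
        tmp <- ord[i]; ord[i] <- ord[j]; ord[j] <- tmp
      }
      cur <- ids[ord]
    }
  }
  stop("design error: could not satisfy the adjacency constraint", call. = FALSE)
}

#' Generate the randomized trial design
#'
#' Each participant sees every object twice, once MP-fragmented and once
#' SP-fragmented, in an order randomized per participant under the constraint
#' that the same object never occupies two consecutive trials. The
#' `repetition` flag is 0 on the first occurrence of an object and 1 on its
#' second.
#'
#' @param config a [buildup_config()].
#' @param seed optional integer seed for reproducible designs.
#' @return data frame with one row per trial slot: `participant_id`,
#'   `is_patient`, `trial_index`, `object_id`, `category`, `symmetric`,
#'   `complex`, `fragment_type`, `repetition`.
#' @export
build_trial_design <- function(config = buildup_config(), seed = NULL) {
  stopifnot(inherits(config, "buildup_config"))
  if (!is.null(seed)) set.seed(seed)
  stimuli <- make_stimuli(config)
  participants <- c(sprintf("C%02d", seq_len(config$n_controls)),
                    if (config$include_patient) "PAT")
  slots <- merge(data.frame(object_id = stimuli$object_id),
                 data.frame(fragment_type = c("MP", "SP")))
  out <- vector("list", length(participants))
  for (k in seq_along(participants)) {
    ord <- shuffle_no_adjacent(slots$object_id)
    d <- slots[ord, , drop = FALSE]
    d$participant_id <- participants[k]
    d$is_patient <- as.integer(participants[k] == "PAT")
    d$trial_index <- seq_len(nrow(d))
    d$repetition <- as.integer(duplicated(d$object_id))
    out[[k]] <- d
  }
  design <- do.call(rbind, out)
  design <- merge(design, stimuli, by = "object_id", sort = FALSE)
  design <- design[order(design$participant_id, design$trial_index), ,
                   drop = FALSE]
  rownames(design) <- NULL
  design[, c("participant_id", "is_patient", "trial_index", "object_id",
             "category", "symmetric", "complex", "fragment_type",
             "repetition")]
}

# covariate dummies used by the hazard model, from raw design columns
design_dummies <- function(design) {
  data.frame(Patient = as.integer(design$is_patient),
             Manmade = as.integer(design$category == "manmade"),
             Symmetry = as.integer(design$symmetric),
             Complex = as.integer(design$complex),
             MP = as.integer(design$fragment_type == "MP"),
             Repetition = as.integer(design$repetition))
}

#' Simulate identification outcomes under a cloglog hazard model
#'
#' For each trial the presentations \eqn{t = 1, \dots,} `max_presentations`
#' are visited in order; at each, a correct identification occurs with
#' probability \eqn{h(t) = 1 - \exp(-\exp(\eta(t)))}, where \eqn{\eta(t)} is
#' the linear predictor of the generating model evaluated at the trial's
#' covariates. The first success sets `event_presentation = t`; a trial with
#' no success by the horizon is right-censored. One pseudo-random stream is
#' used, with draws consumed in trial order, so equal seeds give identical
#' datasets.
#'
#' @param config a [buildup_config()].
#' @param spec generating [hazard_spec()].
#' @param coefficients named numeric vector of generating coefficients; names
#'   must match `spec` term names (missing terms default to 0).
#' @param seed optional integer seed.
#' @param design optionally, a precomputed [build_trial_design()] output.
#' @return data frame of trial outcomes: the design columns plus
#'   `event_presentation` (NA when censored) and `censored` (0/1).
#' @examples
#' cfg <- buildup_config(n_controls = 2, include_patient = FALSE, n_objects = 10)
#' sim <- simulate_buildup(cfg, hazard_spec(0), c(Intercept = 0.48), seed = 1)
#' table(sim$censored)
#' @export
simulate_buildup <- function(config = buildup_config(), spec = final_model_spec(),
                             coefficients = final_model()$coefficients,
                             seed = NULL, design = NULL) {
  stopifnot(inherits(config, "buildup_config"), inherits(spec, "hazard_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(design)) design <- build_trial_design(config)
  beta <- resolve_coefficients(spec, coefficients)
  if (any(!is.finite(beta))) {
    stop("simulation error: non-finite coefficient for term(s) ",
         paste(names(beta)[!is.finite(beta)], collapse = ", "), call. = FALSE)
  }
  horizon <- config$max_presentations
  covs <- design_dummies(design)
  missing <- setdiff(spec_covariates(spec), names(covs))
  if (length(missing)) {
    stop("simulation error: unresolvable term covariate(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  # hazard per trial x presentation
  eta <- matrix(0, nrow(design), horizon)
  for (t in seq_len(horizon)) {
    eta[, t] <- eta_at(spec, beta, covs, t)
  }
  if (any(!is.finite(eta))) {
    stop("simulation error: non-finite linear predictor", call. = FALSE)
  }
  h <- inv_cloglog(eta)
  event <- rep(NA_integer_, nrow(design))
  for (i in seq_len(nrow(design))) {        # draws consumed in trial order
    for (t in seq_len(horizon)) {
      if (stats::runif(1) < h[i, t]) { event[i] <- t; break }
    }
  }
  design$event_presentation <- event
  design$censored <- as.integer(is.na(event))
  design
}

resolve_coefficients <- function(spec, coefficients) {
  beta <- stats::setNames(numeric(nrow(spec$terms)), spec$terms$name)
  if (is.null(names(coefficients)) && length(coefficients) == length(beta)) {
    names(coefficients) <- names(beta)
  }
  unknown <- setdiff(names(coefficients), names(beta))
  if (length(unknown)) {
    stop("coefficients name terms absent from the specification: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  beta[names(coefficients)] <- coefficients
  beta
}

# linear predictor at presentation t for covariate data (data frame of dummies)
eta_at <- function(spec, beta, covs, t) {
  tab <- spec$terms
  tc <- t - spec$center
  out <- numeric(nrow(covs))
  for (i in seq_len(nrow(tab))) {
    x <- rep(1, nrow(covs))
    for (v in tab$covariates[[i]]) x <- x * covs[[v]]
    out <- out + beta[[tab$name[i]]] * x * tc^tab$power[i]
  }
  out
}

#' Read and write trial-outcome CSV files
#'
#' The on-disk format is one row per trial with header
#' `participant_id,is_patient,trial_index,object_id,category,symmetric,
#' complex,fragment_type,repetition,event_presentation,censored`; the
#' `event_presentation` field is empty for censored trials.
#'
#' @param trials data frame as returned by [simulate_buildup()].
#' @param path file path.
#' @return `read_trials()` returns the trials data frame; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  cols <- c("participant_id", "is_patient", "trial_index", "object_id",
            "category", "symmetric", "complex", "fragment_type", "repetition",
            "event_presentation", "censored")
  missing <- setdiff(cols, names(trials))
  if (length(missing)) {
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(trials[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  tr$event_presentation <- suppressWarnings(as.integer(tr$event_presentation))
  validate_trials(tr)
  tr
}

validate_trials <- function(trials, max_presentations = NULL) {
  ev <- trials$event_presentation
  cz <- trials$censored
  if (any(is.na(ev) != (cz == 1))) {
    stop("data error: exactly one of event_presentation / censored=1 must hold",
         call. = FALSE)
  }
  if (!is.null(max_presentations) && any(ev > max_presentations, na.rm = TRUE)) {
    stop("data error: event_presentation exceeds the presentation horizon",
         call. = FALSE)
  }
  invisible(trials)
}
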