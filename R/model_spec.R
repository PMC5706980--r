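# Term representation: every model term is a covariate product (possibly
# empty) times a power of centred time, (TIME - center)^power. Canonical
# names follow "VAR1*VAR2:PT^k"; ":PT^0" is elided, power 1 prints as ":PT".
# Baseline (covariate-empty) terms print as "Intercept", "PT", "PT^2", ...

format_term <- function(covariates, power) {
  covariates <- sort(unique(as.character(covariates)), method = "radix")
  pt <- if (power == 0) "" else if (power == 1) "PT" else paste0("PT^", power)
  if (length(covariates) == 0) {
    if (power == 0) "Intercept" else pt
  } else {
    base <- paste(covariates, collapse = "*")
    if (power == 0) base else paste0(base, ":", pt)
  }
}

parse_term <- function(name) {
  name <- trimws(name)
  if (name == "Intercept" || name == "(Intercept)") {
    return(list(covariates = character(0), power = 0L))
  }
  power <- 0L
  covs <- name
  if (grepl(":", name, fixed = TRUE)) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed term name: ", name, call. = FALSE)
    covs <- parts[1]
    power <- parse_pt(parts[2], name)
  } else if (grepl("^PT(\\^[0-9]+)?$", name)) {
    return(list(covariates = character(0), power = parse_pt(name, name)))
  }
  list(covariates = sort(strsplit(covs, "*", fixed = TRUE)[[1]],
                         method = "radix"), power = power)
}

parse_pt <- function(pt, context) {
  if (pt == "PT") return(1L)
  if (!grepl("^PT\\^[0-9]+$", pt)) {
    stop("malformed time part in term name: ", context, call. = FALSE)
  }
  as.integer(sub("^PT\\^", "", pt))
}

#' Specify a discrete-time cloglog hazard model
#'
#' A hazard model specification consists of a polynomial baseline in centred
#' time plus covariate terms, each a product of 0/1 covariates optionally
#' multiplied by a power of centred time. On the complementary log-log scale
#' the linear predictor at presentation \eqn{t} is
#' \deqn{\eta(t) = \alpha_0 + \alpha_1 (t-c) + \dots + \alpha_d (t-c)^d +
#'   \sum_j \beta_j x_j (t-c)^{p_j},}
#' where \eqn{c} is the centring presentation, so that coefficients of terms
#' without a time power describe effects at presentation \eqn{c}.
#'
#' Terms are written `"VAR1*VAR2:PT^k"`: a `*`-joined covariate product,
#' optionally followed by `:PT` (linear time interaction) or `:PT^k`.
#' Baseline terms are `"Intercept"`, `"PT"`, `"PT^2"`, and so on; they are
#' generated from `baseline_degree` and need not be listed.
#'
#' @param baseline_degree order of the baseline time polynomial (>= 0).
#' @param center presentation number the time polynomial is centred on
#'   (integer >= 1). With `center = 1`, main effects refer to the first
#'   presentation.
#' @param terms character vector of covariate term names (baseline terms are
#'   added automatically and must not be repeated here).
#' @return an object of class `"hazard_spec"`: a list with elements
#'   `baseline_degree`, `center`, and `terms` (a data frame with columns
#'   `name`, `covariates` (list column) and `power`).
#' @examples
#' hazard_spec(baseline_degree = 2, terms = c("Manmade", "Manmade:PT"))
#' @export
hazard_spec <- function(baseline_degree = 4L, center = 1L, terms = character()) {
  baseline_degree <- as.integer(baseline_degree)
  center <- as.integer(center)
  if (is.na(baseline_degree) || baseline_degree < 0) {
    stop("`baseline_degree` must be a non-negative integer", call. = FALSE)
  }
  if (is.na(center) || center < 1) {
    stop("`center` must be a positive integer presentation number", call. = FALSE)
  }
  parsed <- lapply(as.character(terms), parse_term)
  covs <- c(vector("list", baseline_degree + 1L), lapply(parsed, `[[`, "covariates"))
  covs[seq_len(baseline_degree + 1L)] <- list(character(0))
  pow <- c(0L:baseline_degree, vapply(parsed, `[[`, integer(1), "power"))
  name <- mapply(format_term, covs, pow)
  if (anyDuplicated(name)) {
    stop("duplicated terms in specification: ",
         paste(unique(name[duplicated(name)]), collapse = ", "), call. = FALSE)
  }
  tab <- data.frame(name = name, power = as.integer(pow), stringsAsFactors = FALSE)
  tab$covariates <- covs
  structure(list(baseline_degree = baseline_degree, center = center, terms = tab),
            class = "hazard_spec")
}

#' @export
print.hazard_spec <- function(x, ...) {
  cat("Discrete-time cloglog hazard model specification\n")
  cat("  baseline: polynomial of degree", x$baseline_degree,
      "in (TIME -", paste0(x$center, ")\n"))
  cat("  terms (", nrow(x$terms), "):\n", sep = "")
  cat(strwrap(paste(x$terms$name, collapse = ", "), width = 76,
              indent = 4, exdent = 4), sep = "\n")
  invisible(x)
}

spec_covariates <- function(spec) {
  unique(unlist(spec$terms$covariates))
}

# term i is contained in term j (i marginal to j)
term_contained <- function(covs_i, pow_i, covs_j, pow_j) {
  if (identical(covs_i, covs_j) && pow_i == pow_j) return(FALSE)
  all(covs_i %in% covs_j) && pow_i <= pow_j
}

#' Terms removable under the hierarchical principle
#'
#' A term may be dropped only if no retained term contains it, i.e. no other
#' term has a superset covariate product together with an equal-or-higher
#' time power. The intercept is never removable.
#'
#' @param spec a [hazard_spec()].
#' @return character vector of removable term names.
#' @examples
#' sp <- hazard_spec(0, terms = c("A", "B", "A*B"))
#' removable_terms(sp)  # only "A*B"
#' @export
removable_terms <- function(spec) {
  stopifnot(inherits(spec, "hazard_spec"))
  tab <- spec$terms
  n <- nrow(tab)
  keep <- vapply(seq_len(n), function(i) {
    if (tab$name[i] == "Intercept") return(FALSE)
    for (j in seq_len(n)) {
      if (j != i && term_contained(tab$covariates[[i]], tab$power[i],
                                   tab$covariates[[j]], tab$power[j])) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  tab$name[keep]
}

#' Check hierarchical closure of a model specification
#'
#' A specification is hierarchically closed when, for every term, every
#' marginal term (same or subset covariate product with the same or lower
#' time power) is itself in the specification.
#'
#' @param spec a [hazard_spec()].
#' @return `TRUE` or `FALSE`.
#' @export
is_hierarchical <- function(spec) {
  stopifnot(inherits(spec, "hazard_spec"))
  tab <- spec$terms
  have <- tab$name
  for (i in seq_len(nrow(tab))) {
    covs <- tab$covariates[[i]]
    for (p in 0:tab$power[i]) {
      subsets <- cov_subsets(covs)
      for (s in subsets) {
        if (!format_term(s, p) %in% have) return(FALSE)
      }
    }
  }
  TRUE
}

cov_subsets <- function(covs) {
  n <- length(covs)
  if (n == 0) return(list(character(0)))
  idx <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  lapply(seq_len(nrow(idx)), function(i) covs[unlist(idx[i, ])])
}

drop_term <- function(spec, name) {
  stopifnot(name %in% spec$terms$name)
  tab <- spec$terms[spec$terms$name != name, , drop = FALSE]
  rownames(tab) <- NULL
  if (startsWith(name, "PT") || name == "Intercept") {
    # dropping a pure-time term lowers the stated baseline degree if it was
    # the top power; term table is authoritative either way
    base_pows <- tab$power[lengths(tab$covariates) == 0]
    spec$baseline_degree <- if (length(base_pows)) max(base_pows) else 0L
  }
  spec$terms <- tab
  spec
}

# power set of time powers present for each covariate product, used by recentring
product_key <- function(covs) paste(covs, collapse = "*")

#' Full factorial model for the build-up identification design
#'
#' Builds the customary starting model for backward selection: all covariate
#' main effects, all interaction products up to `interaction_order`, each
#' crossed with time powers 0..`time_degree`, a baseline time polynomial of
#' degree `baseline_degree`, and (optionally) a time-invariant trial
#' repetition effect.
#'
#' @param covariates character vector of 0/1 covariate names.
#' @param interaction_order highest order of covariate products (2 = all
#'   pairwise interactions).
#' @param baseline_degree degree of the baseline time polynomial.
#' @param time_degree highest power of time crossed with each covariate
#'   product.
#' @param repetition include a time-invariant `Repetition` control term.
#' @param center centring presentation.
#' @return a [hazard_spec()].
#' @export
buildup_full_spec <- function(covariates = c("Manmade", "Symmetry", "Complex",
                                             "MP", "Patient"),
                              interaction_order = 2L, baseline_degree = 3L,
                              time_degree = 2L, repetition = TRUE,
                              center = 1L) {
  prods <- list()
  for (k in seq_len(min(interaction_order, length(covariates)))) {
    cmb <- utils::combn(sort(covariates, method = "radix"), k,
                        simplify = FALSE)
    prods <- c(prods, cmb)
  }
  terms <- unlist(lapply(prods, function(cv) {
    vapply(0:time_degree, function(p) format_term(cv, p), character(1))
  }))
  if (repetition) terms <- c("Repetition", terms)
  hazard_spec(baseline_degree = baseline_degree, center = center,
              terms = unique(terms))
}
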