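# Recentring: re-expressing polynomial time effects around another
# presentation. Writing (t - c1)^p = ((t - c2) + (c2 - c1))^p and expanding
# binomially shows that a fit centred at c1 maps exactly onto one centred at
# c2 by a linear reparameterization within each covariate-product group:
#   beta2[(C, j)] = sum_{p >= j} choose(p, j) (c2 - c1)^{p-j} beta1[(C, p)].
# Log-likelihood and every predicted function are unchanged; only the
# coefficients (now "effects at presentation c2") and their covariances move.

recenter_matrix <- function(spec, new_center) {
  tab <- spec$terms
  d <- new_center - spec$center
  n <- nrow(tab)
  keys <- vapply(tab$covariates, product_key, character(1))
  A <- matrix(0, n, n, dimnames = list(tab$name, tab$name))
  for (i in seq_len(n)) {        # row: target term (C, j) at new centre
    j <- tab$power[i]
    donors <- which(keys == keys[i] & tab$power >= j)
    # exactness requires all lower powers of each product to be present
    need <- which(keys == keys[i] & tab$power < j)
    if (length(need) < j) {
      stop("recentring is not an exact reparameterization: term group '",
           keys[i], "' lacks lower time powers; refit with the new centre instead",
           call. = FALSE)
    }
    for (k in donors) {
      p <- tab$power[k]
      A[i, k] <- choose(p, j) * d^(p - j)
    }
  }
  A
}

#' Recentre the time polynomial of a specification or fitted model
#'
#' For a fitted model this is an exact linear reparameterization (identical
#' log-likelihood and predicted functions); coefficients of terms without a
#' time power afterwards describe effects at the new centring presentation,
#' which is how "what does this effect amount to at presentation 5?" is read
#' off directly, with its own standard error and Wald test.
#'
#' @param x a [hazard_spec()] or a [fit_hazard_model()] result.
#' @param new_center presentation number to centre on.
#' @return object of the same class as `x`, recentred.
#' @examples
#' sp <- hazard_spec(baseline_degree = 2)
#' recenter(sp, 3)$center
#' @export
recenter <- function(x, new_center) UseMethod("recenter")

#' @export
recenter.hazard_spec <- function(x, new_center) {
  x$center <- as.integer(new_center)
  x
}

#' @export
recenter.dthaz_fit <- function(x, new_center) {
  new_center <- as.integer(new_center)
  if (new_center == x$spec$center) return(x)
  A <- recenter_matrix(x$spec, new_center)
  beta <- drop(A %*% x$coefficients)
  names(beta) <- names(x$coefficients)
  vm <- A %*% x$vcov_model %*% t(A)
  vc <- A %*% x$vcov_cluster %*% t(A)
  dimnames(vm) <- dimnames(vc) <- dimnames(x$vcov_model)
  x$coefficients <- beta
  x$vcov_model <- (vm + t(vm)) / 2
  x$vcov_cluster <- (vc + t(vc)) / 2
  se_model <- sqrt(pmax(diag(x$vcov_model), 0))
  se_robust <- sqrt(pmax(diag(x$vcov_cluster), 0))
  stat <- (beta / se_robust)^2
  x$wald <- data.frame(term = names(beta), estimate = unname(beta),
                       se_model = unname(se_model),
                       se_robust = unname(se_robust), statistic = unname(stat),
                       p_value = stats::pchisq(unname(stat), 1,
                                               lower.tail = FALSE),
                       stringsAsFactors = FALSE)
  x$spec$center <- new_center
  x
}

#' Recentre a plain coefficient vector
#'
#' Applies the same exact polynomial-shift reparameterization to a named
#' coefficient vector (e.g. a transcribed published table) without refitting.
#'
#' @param coefficients named numeric vector matching `spec` term names.
#' @param spec the [hazard_spec()] the coefficients belong to.
#' @param new_center presentation number to centre on.
#' @return named numeric vector of recentred coefficients.
#' @export
recenter_coefficients <- function(coefficients, spec, new_center) {
  beta <- resolve_coefficients(spec, coefficients)
  A <- recenter_matrix(spec, as.integer(new_center))
  stats::setNames(drop(A %*% beta), names(beta))
}
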