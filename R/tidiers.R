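#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the coefficient table of a fitted count model
#'
#' One row per estimated parameter with Wald inference: standard errors are
#' square roots of the diagonal of the inverse observed information,
#' `statistic = estimate / std.error` against a standard normal, p-values
#' two-sided. The `part` column separates the count model (log scale), the
#' zero model (zero-link scale) and the dispersion parameter `alpha`
#' (reported on its natural scale with a delta-method standard error; no
#' Wald test is reported for `alpha` because its null lies on the boundary).
#'
#' @param x A `count_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `part`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.count_fit <- function(x, ...) {
  kx <- x$kx
  kz <- x$kz
  part <- c(rep("count", kx), rep("zero", kz), rep("dispersion", x$ka))
  term <- c(colnames(x$X), if (kz > 0) colnames(x$Z), if (x$ka > 0) "alpha")
  est <- unname(x$par)
  se <- unname(x$se)
  if (x$ka > 0) {
    i <- x$k
    est[i] <- exp(est[i])           # alpha = exp(log_alpha)
    se[i] <- est[i] * se[i]         # delta method
  }
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  if (x$ka > 0) {
    z[x$k] <- NA_real_
    p[x$k] <- NA_real_
  }
  tibble::tibble(part = part, term = term, estimate = est,
                 std.error = se, statistic = z, p.value = p)
}

#' One-row model summary of a fitted count model
#'
#' @param x A `count_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `family`, `logLik`, `AIC`, `BIC`, `nobs`,
#'   `k`, `converged`, `boundary`, `reason`, `n_iter`.
#' @export
glance.count_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, logLik = x$loglik, AIC = x$aic, BIC = x$bic,
    nobs = x$n, k = x$k, converged = x$converged,
    boundary = paste(x$boundary, collapse = ","),
    reason = x$reason, n_iter = x$n_iter
  )
}

#' @export
logLik.count_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
vcov.count_fit <- function(object, ...) object$vcov

#' @export
coef.count_fit <- function(object, ...) object$par
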