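#' Control parameters for the quasi-Newton fitter
#'
#' @param maxit Iteration cap for the BFGS optimizer.
#' @param reltol Relative convergence tolerance on the log-likelihood.
#' @return A list of class `count_control`.
#' @export
count_control <- function(maxit = 500, reltol = 1e-10) {
  structure(list(maxit = maxit, reltol = reltol), class = "count_control")
}

# bounds used to keep the unconstrained parameterization finite:
# log(alpha) is clamped to +/- .log_alpha_cap; hitting it is a dispersion
# boundary (alpha -> 0 or Inf) and is coded non-converged. The zero-part
# linear predictor cap (.zero_eta_cap) marks a mixture-weight boundary
# (phi -> 0 or 1), a valid boundary MLE coded converged-with-boundary.
.log_alpha_cap <- 15

#' Fit a count regression model by maximum likelihood
#'
#' Fits one of the Poisson, NB, ZIP or ZINB regression models by
#' quasi-Newton (BFGS) maximization of the log-likelihood with analytic
#' gradients, over an unconstrained parameterization: count-part
#' coefficients `beta` (log link), zero-part coefficients `gamma` (logit,
#' probit or cloglog link; zero-inflated families only) and `log(alpha)`
#' (NB-type families only). Standard errors come from the inverse of the
#' observed information at the optimum; AIC and BIC count all estimated
#' parameters including `alpha` and the zero part.
#'
#' A fit is reported as converged when the optimizer met its tolerance
#' within the iteration cap, all estimates are finite, and the observed
#' information is positive definite with finite standard errors. Two
#' boundary situations are coded explicitly: a zero part driven to a
#' degenerate mixture weight (`phi` at 0 or 1, e.g. when the sample has no
#' excess zeros) is flagged `"zero_boundary"` and still counted as
#' converged, with the information check applied to the remaining
#' parameters and infinite zero-part standard errors reported as-is; a
#' dispersion parameter driven to its cap (`alpha -> 0` on equidispersed
#' data, where NB and ZINB degenerate to their Poisson counterparts) is
#' counted as non-converged. Non-convergence never raises an error: the
#' returned object carries `converged = FALSE` and a `reason` code.
#'
#' @param data A data frame containing the response and covariates.
#' @param formula Count-part formula, e.g. `y ~ x1 + x2` (log link).
#' @param family `"poisson"`, `"nb"`, `"zip"` or `"zinb"`.
#' @param zero One-sided formula for the zero part of ZIP/ZINB models
#'   (default intercept only, `~ 1`). Ignored with a warning otherwise.
#' @param zero_link Link for the zero part: `"logit"` (default),
#'   `"probit"` or `"cloglog"`.
#' @param control A [count_control()] list.
#' @return An object of class `count_fit`; see [tidy.count_fit()],
#'   [glance.count_fit()], [predict.count_fit()], [pearson_dispersion()].
#' @examples
#' d <- sim_counts(family = "nb", alpha = 1, n = 500, seed = 42)
#' fit <- fit_count(d, y ~ x1 + x2, family = "nb")
#' glance(fit)
#' @export
fit_count <- function(data, formula, family = "poisson", zero = ~1,
                      zero_link = "logit", control = count_control()) {
  family <- .check_family(family)
  zero_link <- match.arg(zero_link, c("logit", "probit", "cloglog"))
  data <- as.data.frame(data)

  mf <- model.frame(formula, data)
  y <- model.response(mf)
  .check_counts(y, arg = deparse(formula[[2]]))
  X <- model.matrix(formula, mf)
  .check_full_rank(X, "count")
  n <- length(y)

  Z <- NULL
  if (.has_phi(family)) {
    zf <- stats::update.formula(zero, ~.)
    Z <- model.matrix(zf, model.frame(zf, data))
    .check_full_rank(Z, "zero")
  } else if (!identical(deparse(zero), "~1")) {
    warn(sprintf("`zero` is ignored for family \"%s\".", family))
  }
  k <- ncol(X) + if (.has_phi(family)) ncol(Z) else 0L
  k <- k + if (.has_alpha(family)) 1L else 0L
  if (n <= k) abort(sprintf("need n > %d observations to fit %d parameters.", k, k))

  out <- .fit_engine(y, X, Z, family, zero_link, control)
  out$call <- match.call()
  out$formula <- formula
  out$zero_formula <- if (.has_phi(family)) zero else NULL
  out$terms_count <- terms(formula, data = data)
  out$terms_zero <- if (.has_phi(family)) terms(stats::update.formula(zero, ~.), data = data) else NULL
  out
}

# the optimizer core; y/X/Z already validated
.fit_engine <- function(y, X, Z, family, zero_link, control) {
  n <- length(y)
  kx <- ncol(X)
  kz <- if (.has_phi(family)) ncol(Z) else 0L
  ka <- if (.has_alpha(family)) 1L else 0L
  k <- kx + kz + ka
  par_names <- c(
    paste0("count_", colnames(X)),
    if (kz > 0) paste0("zero_", colnames(Z)),
    if (ka > 0) "log_alpha"
  )

  base <- list(
    family = family, zero_link = zero_link, y = y, X = X, Z = Z,
    n = n, k = k, kx = kx, kz = kz, ka = ka, par_names = par_names,
    control = control
  )

  # likelihood degenerates when every response is zero: mu -> 0 under
  # poisson/nb, and (beta, phi -> 1) is unidentified under zip/zinb
  if (all(y == 0)) {
    return(.fit_failure(base, "all_zero_response"))
  }

  nll <- .make_nll(family, y, X, Z, zero_link)
  gr <- .make_gr(family, y, X, Z, zero_link)

  if (.has_phi(family) && !any(y == 0)) {
    # no zeros in the sample: the zero-part MLE is exactly the phi = 0
    # boundary and the count part reduces to the nested count-only family;
    # optimizing the flat zero direction numerically would only stall
    nested <- if (family == "zip") "poisson" else "nb"
    bfit <- .fit_engine(y, X, NULL, nested, zero_link, control)
    if (!bfit$converged) return(.fit_failure(base, bfit$reason))
    par <- c(unname(bfit$coefficients$count),
             -.zero_eta_cap, rep(0, kz - 1),
             if (ka > 0) log(bfit$coefficients$alpha))
    opt <- list(par = par, value = nll(par), convergence = 0L,
                counts = c(bfit$n_iter, NA))
  } else {
    start <- .start_values(family, y, X, Z, zero_link, control)
    opt <- tryCatch(
      optim(start, nll, gr, method = "BFGS",
            control = list(maxit = control$maxit, reltol = control$reltol)),
      error = function(e) NULL
    )
  }
  if (is.null(opt)) return(.fit_failure(base, "optimizer_error"))
  if (opt$convergence != 0 || any(!is.finite(opt$par))) {
    return(.fit_failure(base, "optimizer_not_converged", opt))
  }

  par <- opt$par
  boundary <- character()
  if (ka > 0) {
    la <- par[kx + kz + 1]
    if (abs(la) >= .log_alpha_cap - 0.1) {
      return(.fit_failure(base, "dispersion_boundary", opt))
    }
  }
  phi_hat <- NULL
  if (kz > 0) {
    etaz <- drop(Z %*% par[(kx + 1):(kx + kz)])
    phi_hat <- .zero_prob(etaz, zero_link)
    if (any(abs(etaz) >= .zero_eta_cap - 1e-6)) boundary <- "zero_boundary"
  }

  H <- tryCatch(stats::optimHess(par, nll, gr), error = function(e) NULL)
  if (is.null(H)) return(.fit_failure(base, "hessian_error", opt))
  H <- (H + t(H)) / 2

  zero_idx <- if (kz > 0) (kx + 1):(kx + kz) else integer()
  vc <- .safe_inverse(H)
  if (is.null(vc) && kz > 0 && length(boundary) == 0 &&
      (max(phi_hat) <= 0.01 || min(phi_hat) >= 0.99)) {
    # mixture weight has drifted to a degenerate boundary without reaching
    # the linear-predictor cap: the information is singular in the zero-part
    # direction, a boundary MLE, not a failed optimization
    boundary <- "zero_boundary"
  }
  if (is.null(vc)) {
    if (length(boundary) > 0 && length(zero_idx) > 0) {
      keep <- setdiff(seq_len(k), zero_idx)
      vc_sub <- .safe_inverse(H[keep, keep, drop = FALSE])
      if (is.null(vc_sub)) return(.fit_failure(base, "information_not_pd", opt))
      vc <- matrix(NA_real_, k, k)
      vc[keep, keep] <- vc_sub
      vc[zero_idx, ] <- NA_real_
      vc[, zero_idx] <- NA_real_
      diag(vc)[zero_idx] <- Inf
    } else {
      return(.fit_failure(base, "information_not_pd", opt))
    }
  }
  dimnames(vc) <- list(par_names, par_names)

  se <- sqrt(diag(vc))
  if (any(!is.finite(se) & !(seq_len(k) %in% zero_idx & length(boundary) > 0))) {
    return(.fit_failure(base, "nonfinite_se", opt))
  }

  ll <- -opt$value
  beta <- setNames(par[1:kx], colnames(X))
  gamma <- if (kz > 0) setNames(par[zero_idx], colnames(Z)) else NULL
  alpha <- if (ka > 0) exp(par[k]) else NULL
  structure(c(base, list(
    coefficients = list(count = beta, zero = gamma, alpha = alpha),
    par = setNames(par, par_names), loglik = ll,
    aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n),
    converged = TRUE, boundary = boundary, reason = NA_character_,
    n_iter = unname(opt$counts[1]), vcov = vc, se = setNames(se, par_names)
  )), class = "count_fit")
}

.fit_failure <- function(base, reason, opt = NULL) {
  k <- base$k
  par <- if (!is.null(opt)) setNames(opt$par, base$par_names) else
    setNames(rep(NA_real_, k), base$par_names)
  structure(c(base, list(
    coefficients = list(count = NULL, zero = NULL, alpha = NULL),
    par = par, loglik = NA_real_, aic = NA_real_, bic = NA_real_,
    converged = FALSE, boundary = character(), reason = reason,
    n_iter = if (!is.null(opt)) unname(opt$counts[1]) else 0L,
    vcov = NULL, se = setNames(rep(NA_real_, k), base$par_names)
  )), class = "count_fit")
}

.check_full_rank <- function(M, part) {
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    dropped <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    abort(sprintf("%s-part design matrix is rank deficient; collinear column(s): %s.",
                  part, paste(dropped, collapse = ", ")))
  }
  invisible(M)
}

.safe_inverse <- function(H) {
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  chol2inv(ch)
}

# quadratic pull-back beyond the log(alpha) cap: the likelihood is flat in
# the clamped region, so without this a line search can wander arbitrarily far
.la_penalty <- function(la) {
  ex <- abs(la) - .log_alpha_cap
  if (ex > 0) 100 * ex^2 else 0
}
.la_penalty_grad <- function(la) {
  ex <- abs(la) - .log_alpha_cap
  if (ex > 0) 200 * ex * sign(la) else 0
}

# negative log-likelihoods over the packed parameter vector ---------------

.make_nll <- function(family, y, X, Z, zero_link) {
  kx <- ncol(X)
  z0 <- y == 0
  lfac <- lgamma(y + 1)
  guard <- function(v) if (is.finite(v)) v else 1e10
  switch(family,
    poisson = function(par) {
      eta <- drop(X %*% par)
      guard(-sum(y * eta - exp(eta) - lfac))
    },
    nb = function(par) {
      la <- par[kx + 1]
      theta <- exp(-min(max(la, -.log_alpha_cap), .log_alpha_cap))
      mu <- exp(drop(X %*% par[1:kx]))
      guard(-sum(.nb_logpmf(y, mu, theta)) + .la_penalty(la))
    },
    zip = function(par) {
      kz <- ncol(Z)
      mu <- exp(drop(X %*% par[1:kx]))
      phi <- .zero_prob(drop(Z %*% par[(kx + 1):(kx + kz)]), zero_link)
      l0 <- .logsumexp2(log(phi[z0]), log1p(-phi[z0]) - mu[z0])
      l1 <- log1p(-phi[!z0]) + y[!z0] * log(mu[!z0]) - mu[!z0] - lfac[!z0]
      guard(-(sum(l0) + sum(l1)))
    },
    zinb = function(par) {
      kz <- ncol(Z)
      mu <- exp(drop(X %*% par[1:kx]))
      phi <- .zero_prob(drop(Z %*% par[(kx + 1):(kx + kz)]), zero_link)
      la <- par[kx + kz + 1]
      theta <- exp(-min(max(la, -.log_alpha_cap), .log_alpha_cap))
      lg0 <- theta * (log(theta) - log(theta + mu[z0]))
      l0 <- .logsumexp2(log(phi[z0]), log1p(-phi[z0]) + lg0)
      l1 <- log1p(-phi[!z0]) + .nb_logpmf(y[!z0], mu[!z0], theta)
      guard(-(sum(l0) + sum(l1)) + .la_penalty(la))
    }
  )
}

.make_gr <- function(family, y, X, Z, zero_link) {
  kx <- ncol(X)
  z0 <- y == 0
  switch(family,
    poisson = function(par) {
      mu <- exp(drop(X %*% par))
      -drop(crossprod(X, y - mu))
    },
    nb = function(par) {
      la_raw <- par[kx + 1]
      la <- min(max(la_raw, -.log_alpha_cap), .log_alpha_cap)
      theta <- exp(-la)
      mu <- exp(drop(X %*% par[1:kx]))
      dbeta <- drop(crossprod(X, theta * (y - mu) / (theta + mu)))
      dth <- sum(digamma(y + theta) - digamma(theta) + log(theta) + 1 -
                   log(theta + mu) - (theta + y) / (theta + mu))
      dla <- if (la_raw == la) theta * dth else 0
      c(-dbeta, dla + .la_penalty_grad(la_raw))
    },
    zip = function(par) {
      kz <- ncol(Z)
      mu <- exp(drop(X %*% par[1:kx]))
      etaz <- drop(Z %*% par[(kx + 1):(kx + kz)])
      phi <- .zero_prob(etaz, zero_link)
      dphi_deta <- .zero_prob_deriv(etaz, zero_link)
      p0 <- phi + (1 - phi) * exp(-mu)
      deta <- ifelse(z0, -(1 - phi) * exp(-mu) * mu / p0, y - mu)
      dphi <- ifelse(z0, (1 - exp(-mu)) / p0, -1 / (1 - phi))
      -c(drop(crossprod(X, deta)), drop(crossprod(Z, dphi * dphi_deta)))
    },
    zinb = function(par) {
      kz <- ncol(Z)
      mu <- exp(drop(X %*% par[1:kx]))
      etaz <- drop(Z %*% par[(kx + 1):(kx + kz)])
      phi <- .zero_prob(etaz, zero_link)
      dphi_deta <- .zero_prob_deriv(etaz, zero_link)
      la_raw <- par[kx + kz + 1]
      la <- min(max(la_raw, -.log_alpha_cap), .log_alpha_cap)
      theta <- exp(-la)
      g0 <- exp(theta * (log(theta) - log(theta + mu)))
      p0 <- phi + (1 - phi) * g0
      deta <- ifelse(z0, -(1 - phi) * g0 * theta * mu / ((theta + mu) * p0),
                     theta * (y - mu) / (theta + mu))
      dphi <- ifelse(z0, (1 - g0) / p0, -1 / (1 - phi))
      dth_nz <- digamma(y + theta) - digamma(theta) + log(theta) + 1 -
        log(theta + mu) - (theta + y) / (theta + mu)
      dth_z <- (1 - phi) * g0 * (log(theta) - log(theta + mu) + mu / (theta + mu)) / p0
      dtheta <- sum(ifelse(z0, dth_z, dth_nz))
      dla <- if (la_raw == la) theta * dtheta else 0
      c(-drop(crossprod(X, deta)), -drop(crossprod(Z, dphi * dphi_deta)),
        dla + .la_penalty_grad(la_raw))
    }
  )
}

# starting values: count part from a Poisson fit (itself started at the log
# mean response), zero intercept from the link-transformed excess-zero
# fraction, dispersion from a Pearson moment estimate (floored at 0.5)
.start_values <- function(family, y, X, Z, zero_link, control) {
  kx <- ncol(X)
  s0 <- c(log(mean(y) + 0.01), rep(0, kx - 1))
  if (family == "poisson") return(s0)
  pnll <- .make_nll("poisson", y, X, NULL, zero_link)
  pgr <- .make_gr("poisson", y, X, NULL, zero_link)
  pois <- tryCatch(
    optim(s0, pnll, pgr, method = "BFGS",
          control = list(maxit = control$maxit, reltol = control$reltol)),
    error = function(e) list(par = s0)
  )
  beta0 <- pois$par
  mu0 <- exp(drop(X %*% beta0))
  # NB2 moment start: V = mu(1 + alpha mu) => alpha ~ mean((r^2 - mu)/mu^2)
  alpha0 <- min(max(mean(((y - mu0)^2 - mu0) / mu0^2), 0.5), 100)
  if (family == "nb") return(c(beta0, log(alpha0)))
  p0_obs <- mean(y == 0)
  p0_pois <- mean(exp(-mu0))
  excess <- min(max(p0_obs - p0_pois, 0.05), 0.95)
  g0 <- c(stats::make.link(zero_link)$linkfun(excess), rep(0, ncol(Z) - 1))
  if (family == "zip") return(c(beta0, g0))
  c(beta0, g0, log(alpha0))
}

# methods -----------------------------------------------------------------

#' @export
print.count_fit <- function(x, ...) {
  cat(sprintf("<count_fit> %s regression, n = %d, k = %d\n",
              toupper(x$family), x$n, x$k))
  if (x$converged) {
    cat(sprintf("  logLik %.3f  AIC %.2f  BIC %.2f  (%d iterations%s)\n",
                x$loglik, x$aic, x$bic, x$n_iter,
                if (length(x$boundary) > 0) paste0("; boundary: ",
                                                   paste(x$boundary, collapse = ", ")) else ""))
    print(tidy(x), n = Inf)
  } else {
    cat(sprintf("  NOT converged (reason: %s)\n", x$reason))
  }
  invisible(x)
}

#' Predicted unconditional means from a fitted count model
#'
#' Returns `E(Y | x) = mu_i` for Poisson/NB fits and `mu_i (1 - phi_i)` for
#' ZIP/ZINB fits (the dispersion parameter does not enter the mean).
#'
#' @param object A converged `count_fit`.
#' @param newdata Optional data frame; defaults to the training data's
#'   design matrices.
#' @param ... Unused.
#' @return A numeric vector of predicted means.
#' @export
predict.count_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) abort("cannot predict from a non-converged fit.")
  if (is.null(newdata)) {
    X <- object$X
    Z <- object$Z
  } else {
    X <- model.matrix(delete.response(object$terms_count), newdata)
    Z <- if (!is.null(object$terms_zero)) {
      model.matrix(delete.response(object$terms_zero), newdata)
    }
  }
  mu <- exp(drop(X %*% object$coefficients$count))
  if (!.has_phi(object$family)) return(mu)
  phi <- .zero_prob(drop(Z %*% object$coefficients$zero), object$zero_link)
  mu * (1 - phi)
}

#' Pearson dispersion statistic of a fitted count model
#'
#' The Pearson chi-square statistic divided by its residual degrees of
#' freedom: `sum((y_i - E_i)^2 / V_i) / (n - k)`, with `E_i` and `V_i` the
#' fitted family's conditional mean and variance. Values well above 1
#' indicate overdispersion relative to the fitted model (or
#' misspecification).
#'
#' @param fit A converged `count_fit`.
#' @return A length-one numeric.
#' @export
pearson_dispersion <- function(fit) {
  stopifnot(inherits(fit, "count_fit"))
  if (!fit$converged) abort("Pearson dispersion requires a converged fit.")
  if (fit$n <= fit$k) abort("no residual degrees of freedom.")
  mu <- exp(drop(fit$X %*% fit$coefficients$count))
  phi <- if (.has_phi(fit$family)) {
    .zero_prob(drop(fit$Z %*% fit$coefficients$zero), fit$zero_link)
  } else {
    0
  }
  alpha <- fit$coefficients$alpha %||% 0
  E <- mu * (1 - phi)
  V <- switch(fit$family,
    poisson = mu,
    nb = mu * (1 + alpha * mu),
    zip = E * (1 + phi * mu),
    zinb = E * (1 + (alpha + phi) * mu)
  )
  sum((fit$y - E)^2 / V) / (fit$n - fit$k)
}
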