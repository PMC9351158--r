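#' Log-likelihoods of the four count regression families
#'
#' Evaluate the log-likelihood of a Poisson, negative binomial (NB2),
#' zero-inflated Poisson (ZIP) or zero-inflated negative binomial (ZINB)
#' regression model at given parameter values. These are the objective
#' functions maximized by [fit_count()]; they are exported so that the
#' likelihood surface itself can be inspected and tested.
#'
#' The count part uses a log link, `mu_i = exp(x_i' beta)`. The NB2
#' dispersion parameterization is `V(Y|x) = mu (1 + alpha mu)` with gamma
#' shape `theta = 1/alpha`, so `alpha -> 0` recovers the Poisson model. The
#' zero-inflated families mix a degenerate point mass at zero (probability
#' `phi_i = F(z_i' gamma)`, with `F` the inverse zero link) with a Poisson or
#' NB count process; the zero branch is computed on the log scale with
#' log-sum-exp stabilization.
#'
#' @param beta Numeric vector of count-part coefficients, one per column of
#'   `X` (intercept first).
#' @param y Nonnegative integer response vector.
#' @param X Count-part design matrix (including the intercept column).
#' @param alpha NB2 dispersion parameter, strictly positive.
#' @param gamma Zero-part coefficients, one per column of `Z`.
#' @param Z Zero-part design matrix.
#' @param zero_link One of `"logit"`, `"probit"`, `"cloglog"`: the link whose
#'   inverse maps `z_i' gamma` to the structural-zero probability `phi_i`.
#'
#' @return The log-likelihood as a length-one numeric. For
#'   `loglik_poisson()` and `loglik_nb()` the score vector (gradient with
#'   respect to `beta`, and for the NB also `alpha`) is attached as attribute
#'   `"score"`.
#'
#' @examples
#' X <- cbind(1, c(0.5, -0.2, 1))
#' y <- c(0L, 2L, 1L)
#' loglik_poisson(c(0.1, 0.3), y, X)
#' loglik_nb(c(0.1, 0.3), alpha = 1, y, X)
#' @name loglik
NULL

#' @rdname loglik
#' @export
loglik_poisson <- function(beta, y, X) {
  .check_counts(y)
  X <- .check_design(X, beta, length(y))
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  ll <- sum(y * eta - mu - lgamma(y + 1))
  structure(ll, score = drop(crossprod(X, y - mu)))
}

#' @rdname loglik
#' @export
loglik_nb <- function(beta, alpha, y, X) {
  .check_counts(y)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0) {
    abort("`alpha` must be > 0; for the alpha -> 0 limit use `loglik_poisson()`.")
  }
  X <- .check_design(X, beta, length(y))
  eta <- drop(X %*% beta)
  mu <- exp(eta)
  theta <- 1 / alpha
  ll <- sum(.nb_logpmf(y, mu, theta))
  score_beta <- drop(crossprod(X, theta * (y - mu) / (theta + mu)))
  # d ell / d alpha = -theta^2 * d ell / d theta
  dtheta <- sum(digamma(y + theta) - digamma(theta) + log(theta) + 1 -
                  log(theta + mu) - (theta + y) / (theta + mu))
  structure(ll, score = c(score_beta, alpha = -theta^2 * dtheta))
}

#' @rdname loglik
#' @export
loglik_zip <- function(beta, gamma, y, X, Z, zero_link = "logit") {
  .check_counts(y)
  X <- .check_design(X, beta, length(y))
  Z <- .check_design(Z, gamma, length(y), arg = "Z")
  mu <- exp(drop(X %*% beta))
  phi <- .zero_prob(drop(Z %*% gamma), zero_link)
  z0 <- y == 0
  # zero branch: log(phi + (1-phi) exp(-mu)) via log-sum-exp
  l0 <- .logsumexp2(log(phi[z0]), log1p(-phi[z0]) - mu[z0])
  l1 <- log1p(-phi[!z0]) + y[!z0] * log(mu[!z0]) - mu[!z0] - lgamma(y[!z0] + 1)
  sum(l0) + sum(l1)
}

#' @rdname loglik
#' @export
loglik_zinb <- function(beta, gamma, alpha, y, X, Z, zero_link = "logit") {
  .check_counts(y)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0) {
    abort("`alpha` must be > 0; for the alpha -> 0 limit use `loglik_zip()`.")
  }
  X <- .check_design(X, beta, length(y))
  Z <- .check_design(Z, gamma, length(y), arg = "Z")
  mu <- exp(drop(X %*% beta))
  phi <- .zero_prob(drop(Z %*% gamma), zero_link)
  theta <- 1 / alpha
  z0 <- y == 0
  lg0 <- theta * (log(theta) - log(theta + mu[z0]))
  l0 <- .logsumexp2(log(phi[z0]), log1p(-phi[z0]) + lg0)
  l1 <- log1p(-phi[!z0]) + .nb_logpmf(y[!z0], mu[!z0], theta)
  sum(l0) + sum(l1)
}

#' Probability mass functions of the four count families
#'
#' Density of the Poisson, NB2, ZIP or ZINB distribution at fixed
#' `mu`, `alpha`, `phi` (no regression structure). Used for normalization
#' and distributional checks.
#'
#' @param x Vector of nonnegative integers at which to evaluate the pmf.
#' @param mu Count-process mean (of the non-degenerate component).
#' @param family One of `"poisson"`, `"nb"`, `"zip"`, `"zinb"`.
#' @param alpha NB2 dispersion (families `"nb"`, `"zinb"`).
#' @param phi Structural-zero probability in `[0, 1)` (families `"zip"`,
#'   `"zinb"`).
#' @return Numeric vector of probabilities.
#' @examples
#' sum(dcount(0:100, mu = 3, family = "zip", phi = 0.4))
#' @export
dcount <- function(x, mu, family = "poisson", alpha = NULL, phi = NULL) {
  family <- .check_family(family)
  .check_scalar(mu, "mu", positive = TRUE)
  base <- switch(family,
    poisson = ,
    zip = dpois(x, mu),
    nb = ,
    zinb = {
      .check_scalar(alpha, "alpha", positive = TRUE)
      exp(.nb_logpmf(x, mu, 1 / alpha))
    }
  )
  if (!.has_phi(family)) return(base)
  .check_prob(phi, "phi", open = FALSE)
  (1 - phi) * base + phi * (x == 0)
}

# internals --------------------------------------------------------------

.check_design <- function(X, coef, n, arg = "X") {
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X)) abort(sprintf("`%s` must be a numeric matrix without NAs.", arg))
  if (nrow(X) != n) abort(sprintf("`%s` must have one row per observation.", arg))
  if (ncol(X) != length(coef)) {
    abort(sprintf("`%s` has %d columns but %d coefficients were supplied.",
                  arg, ncol(X), length(coef)))
  }
  X
}

# NB2 log pmf with gamma shape theta = 1/alpha, log-gamma arithmetic only
.nb_logpmf <- function(y, mu, theta) {
  lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    theta * (log(theta) - log(theta + mu)) +
    y * (log(mu) - log(theta + mu))
}

# elementwise log(exp(a) + exp(b)) without overflow
.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(pmin(a, b) - m)))
}

# inverse zero link with the +/-30 linear-predictor guard used throughout
.zero_eta_cap <- 30

.zero_prob <- function(eta, zero_link = "logit") {
  zero_link <- match.arg(zero_link, c("logit", "probit", "cloglog"))
  if (anyNA(eta) || any(!is.finite(eta))) {
    abort(sprintf("non-finite zero-part linear predictor at row %s.",
                  which(!is.finite(eta))[1]))
  }
  eta <- pmin(pmax(eta, -.zero_eta_cap), .zero_eta_cap)
  stats::make.link(zero_link)$linkinv(eta)
}

# derivative d phi / d eta on the capped scale
.zero_prob_deriv <- function(eta, zero_link = "logit") {
  eta <- pmin(pmax(eta, -.zero_eta_cap), .zero_eta_cap)
  stats::make.link(zero_link)$mu.eta(eta)
}
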