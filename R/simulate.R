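#' Generate the study covariates
#'
#' Draws the two predictors used throughout the simulation study: a
#' continuous covariate `x1` (an age-like variable, Normal with mean 57.3
#' years and variance 306.25) and a binary covariate `x2` (a sex indicator,
#' Bernoulli with success probability 0.43).
#'
#' @param n Number of observations (positive integer).
#' @param x1_mean,x1_var Mean and variance of the continuous covariate.
#' @param x2_p Success probability of the binary covariate, in (0, 1).
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG stream is left untouched.
#' @return A tibble with columns `x1` (double) and `x2` (0/1 integer).
#' @examples
#' sim_covariates(5, seed = 1)
#' @export
sim_covariates <- function(n, x1_mean = 57.3, x1_var = 306.25, x2_p = 0.43,
                           seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    abort("`n` must be a positive integer.")
  }
  .check_scalar(x1_mean, "x1_mean")
  .check_scalar(x1_var, "x1_var", positive = TRUE)
  .check_prob(x2_p, "x2_p")
  with_seed_or_stream(seed, {
    tibble::tibble(
      x1 = rnorm(n, x1_mean, sqrt(x1_var)),
      x2 = rbinom(n, 1L, x2_p)
    )
  })
}

#' Simulate count outcomes under one of the four regression processes
#'
#' Draws a count response under the Poisson, NB, ZIP or ZINB regression
#' process with log-linear mean `mu_i = exp(x_i' beta)`. Negative binomial
#' counts are generated through the gamma--Poisson heterogeneity mixture
#' (`tau_i ~ Gamma(theta, theta)` with `theta = 1/alpha`, then
#' `Poisson(mu_i tau_i)`). For the zero-inflated families a Bernoulli(`phi`)
#' structural-zero mask is drawn first and recorded, so structural and
#' sampling zeros can be told apart downstream.
#'
#' @param data Optional data frame of covariates. If omitted, `n`
#'   observations are drawn with [sim_covariates()] defaults. Covariate
#'   columns used are those named in `covariates`.
#' @param family `"poisson"`, `"nb"`, `"zip"` or `"zinb"`.
#' @param beta Count-part coefficients: intercept followed by one slope per
#'   covariate column. Default `c(2.1, -0.001, 0.03)` gives a mean response
#'   of about 8 at the covariate means.
#' @param alpha NB2 dispersion (>= 0 interpretation: required, > 0, for
#'   families `"nb"` and `"zinb"`; must be absent otherwise).
#' @param phi Structural-zero probability in `[0, 1)`; required for
#'   `"zip"`/`"zinb"`, absent otherwise. Constant across observations.
#' @param n Number of observations when `data` is not supplied.
#' @param covariates Character vector naming the covariate columns, in the
#'   order matching `beta[-1]`.
#' @param seed Optional integer seed (see [sim_covariates()]).
#' @param scenario_id Optional label stored with the dataset.
#' @return A tibble with the covariates plus `y` (counts), `true_mean` (the
#'   unconditional mean `E(Y|x)`, i.e. `mu_i` or `mu_i (1 - phi)`), and for
#'   zero-inflated families `structural_zero` (logical). The generating
#'   truth (family, beta, alpha, phi, seed, scenario_id) is attached as
#'   attribute `"truth"`.
#' @examples
#' d <- sim_counts(family = "zip", phi = 0.3, n = 100, seed = 7)
#' mean(d$y == 0)
#' @export
sim_counts <- function(data = NULL, family = "poisson",
                       beta = c(2.1, -0.001, 0.03),
                       alpha = NULL, phi = NULL, n = NULL,
                       covariates = c("x1", "x2"),
                       seed = NULL, scenario_id = NA_character_) {
  family <- .check_family(family)
  if (.has_alpha(family)) {
    .check_scalar(alpha, "alpha", positive = TRUE)
  } else if (!is.null(alpha)) {
    abort(sprintf("`alpha` must be absent for family \"%s\".", family))
  }
  if (.has_phi(family)) {
    .check_prob(phi, "phi", open = FALSE)
  } else if (!is.null(phi)) {
    abort(sprintf("`phi` must be absent for family \"%s\".", family))
  }
  with_seed_or_stream(seed, {
    if (is.null(data)) {
      if (is.null(n)) abort("supply either `data` or `n`.")
      data <- sim_covariates(n)
    }
    data <- tibble::as_tibble(data)
    missing_cov <- setdiff(covariates, names(data))
    if (length(missing_cov) > 0) {
      abort(sprintf("covariate column(s) not found in `data`: %s.",
                    paste(missing_cov, collapse = ", ")))
    }
    X <- cbind(`(Intercept)` = 1, as.matrix(data[covariates]))
    if (ncol(X) != length(beta)) {
      abort(sprintf("`beta` must have length %d (intercept + covariates).", ncol(X)))
    }
    eta <- drop(X %*% beta)
    if (any(eta >= 700)) {
      abort(sprintf("linear predictor overflows exp() at row %s.",
                    which(eta >= 700)[1]))
    }
    mu <- exp(eta)
    m <- nrow(data)
    y_count <- switch(family,
      poisson = ,
      zip = rpois(m, mu),
      nb = ,
      zinb = {
        theta <- 1 / alpha
        rpois(m, mu * rgamma(m, shape = theta, rate = theta))
      }
    )
    out <- data
    if (.has_phi(family)) {
      sz <- rbinom(m, 1L, phi) == 1L
      out$y <- ifelse(sz, 0L, y_count)
      out$true_mean <- mu * (1 - phi)
      out$structural_zero <- sz
    } else {
      out$y <- y_count
      out$true_mean <- mu
    }
    attr(out, "truth") <- list(
      family = family, beta = unname(beta), alpha = alpha, phi = phi,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      scenario_id = scenario_id, covariates = covariates
    )
    out
  })
}

#' Simulate a hospital length-of-stay style table
#'
#' Emulates the marginal shape of an asthma-cohort hospital length-of-stay
#' (LOS) extract: a right-skewed, overdispersed count outcome (mean about 8
#' days, variance about 43, range 0--40) with demographic covariates. This
#' is a synthetic stand-in for an access-controlled clinical dataset; it
#' reproduces marginal summaries, not patient-level structure.
#'
#' The outcome is negative binomial on the log scale with small covariate
#' effects (age slope -0.001, female 0.03, insurance and admission-type
#' contrasts of the order seen in count models of LOS), dispersion solved
#' from the moment relation `V = mu (1 + alpha mu)` at mean 8 and variance
#' 43.10 (`alpha` about 0.548), and the intercept chosen in-sample so the
#' mean of `mu_i` equals `mean_los`. Draws above `max_los` are redrawn.
#'
#' @param n Number of admissions (default 2167).
#' @param mean_los Target mean of the LOS outcome, days.
#' @param var_los Target marginal variance used to solve the dispersion.
#' @param max_los Upper bound of the LOS range; larger draws are resampled.
#' @param seed Optional integer seed.
#' @return A tibble with columns `los` (integer days), `age` (years), `sex`
#'   (`male`/`female`), `insurance` (government, medicaid, medicare,
#'   private, self_pay) and `admission_type` (elective, emergency, urgent).
#' @examples
#' los <- sim_los(500, seed = 3)
#' mean(los$los); var(los$los)
#' @export
sim_los <- function(n = 2167, mean_los = 8, var_los = 43.10, max_los = 40,
                    seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    abort("`n` must be a positive integer.")
  }
  .check_scalar(mean_los, "mean_los", positive = TRUE)
  if (var_los <= mean_los) abort("`var_los` must exceed `mean_los` (overdispersion).")
  alpha <- (var_los / mean_los - 1) / mean_los
  with_seed_or_stream(seed, {
    age <- rnorm(n, 62.3, 20)
    sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.3987, 0.6013))
    insurance <- sample(
      c("government", "medicaid", "medicare", "private", "self_pay"), n,
      replace = TRUE, prob = c(0.0443, 0.1403, 0.4435, 0.3641, 0.0078)
    )
    admission <- sample(
      c("elective", "emergency", "urgent"), n,
      replace = TRUE, prob = c(0.1744, 0.8066, 0.0189)
    )
    ins_eff <- c(government = 0.32, medicaid = 0.49, medicare = 0.46,
                 private = 0.40, self_pay = 0)
    adm_eff <- c(elective = -0.30, emergency = -0.16, urgent = 0)
    lp <- -0.001 * age + 0.03 * (sex == "female") +
      ins_eff[insurance] + adm_eff[admission]
    intercept <- log(mean_los) - log(mean(exp(lp)))
    mu <- exp(intercept + lp)
    theta <- 1 / alpha
    draw <- function(m, mu) rnbinom(m, size = theta, mu = mu)
    los <- draw(n, mu)
    for (i in 1:50) {
      over <- los > max_los
      if (!any(over)) break
      los[over] <- draw(sum(over), mu[over])
    }
    los[los > max_los] <- max_los
    tibble::tibble(
      los = as.integer(los), age = age, sex = sex,
      insurance = insurance, admission_type = admission
    )
  })
}

#' Write and read a simulated count dataset with its generating truth
#'
#' `write_count_data()` writes the dataset to CSV and its generating truth
#' (family, coefficients, dispersion, structural-zero probability, seed) to
#' a JSON sidecar at `<path>.json`; `read_count_data()` reverses this,
#' restoring the `"truth"` attribute when the sidecar is present.
#'
#' @param data A tibble from [sim_counts()] (or any data frame).
#' @param path CSV file path.
#' @return `write_count_data()` returns `path` invisibly;
#'   `read_count_data()` returns a tibble.
#' @export
write_count_data <- function(data, path) {
  readr::write_csv(data, path)
  truth <- attr(data, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_count_data
#' @export
read_count_data <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(out, "truth") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  out
}
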