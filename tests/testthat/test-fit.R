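test_that("poisson fit recovers the generating coefficients", {
  truth <- c(2.1, -0.001, 0.03)
  d <- sim_counts(family = "poisson", beta = truth, n = 5000, seed = 13)
  fit <- fit_count(d, y ~ x1 + x2, family = "poisson")
  expect_true(fit$converged)
  est <- tidy(fit)
  expect_true(all(abs(est$estimate - truth) < 3 * est$std.error))
  # score vanishes at the optimum
  sc <- attr(loglik_poisson(fit$coefficients$count, d$y, fit$X), "score")
  expect_lt(max(abs(sc)), 1e-4 * fit$n)
})

test_that("aic and bic satisfy their definitions exactly", {
  for (fam in c("poisson", "nb", "zip", "zinb")) {
    d <- small_data(fam, n = 300)
    fit <- fit_count(d, y ~ x1 + x2, family = fam)
    expect_true(fit$converged)
    expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$k)
    expect_equal(fit$bic, -2 * fit$loglik + fit$k * log(fit$n))
    expect_equal(fit$aic - fit$bic, 2 * fit$k - fit$k * log(fit$n))
  }
})

test_that("maximized poisson and nb log-likelihoods match the reference GLM", {
  d <- small_data("nb", n = 20, seed = 2024)
  fit_p <- fit_count(d, y ~ x1 + x2, family = "poisson")
  ref_p <- stats::glm(y ~ x1 + x2, poisson, data = d)
  expect_equal(fit_p$loglik, as.numeric(logLik(ref_p)), tolerance = 1e-6)
  expect_equal(unname(fit_p$coefficients$count), unname(coef(ref_p)),
               tolerance = 1e-3)

  skip_if_not_installed("MASS")
  fit_n <- fit_count(d, y ~ x1 + x2, family = "nb")
  ref_n <- MASS::glm.nb(y ~ x1 + x2, data = d)
  expect_equal(fit_n$loglik, as.numeric(logLik(ref_n)), tolerance = 1e-6)
})

test_that("maximized zip and zinb log-likelihoods match an independent mixture fitter", {
  skip_if_not_installed("glmmTMB")
  d <- small_data("zinb", n = 200, seed = 515)
  fit_zip <- fit_count(d, y ~ x1 + x2, family = "zip")
  ref_zip <- glmmTMB::glmmTMB(y ~ x1 + x2, ziformula = ~1,
                              family = stats::poisson, data = d)
  expect_equal(fit_zip$loglik, as.numeric(logLik(ref_zip)), tolerance = 1e-4)

  fit_zinb <- fit_count(d, y ~ x1 + x2, family = "zinb")
  ref_zinb <- glmmTMB::glmmTMB(y ~ x1 + x2, ziformula = ~1,
                               family = glmmTMB::nbinom2, data = d)
  expect_equal(fit_zinb$loglik, as.numeric(logLik(ref_zinb)), tolerance = 1e-4)
})

test_that("nesting: flexible families attain at least the nested maximized likelihood", {
  d <- small_data("zinb", n = 400, seed = 99)
  ll <- vapply(c("poisson", "nb", "zip", "zinb"), function(f) {
    fit_count(d, y ~ x1 + x2, family = f)$loglik
  }, numeric(1))
  tol <- 1e-4
  expect_gte(ll["nb"], ll["poisson"] - tol)
  expect_gte(ll["zip"], ll["poisson"] - tol)
  expect_gte(ll["zinb"], ll["zip"] - tol)
  expect_gte(ll["zinb"], ll["nb"] - tol)
})

test_that("each family recovers its own slope without systematic bias", {
  # 60 replications per family at n = 1200; mean bias of the x1 slope
  # within 3 Monte Carlo standard errors of zero
  for (fam in c("poisson", "nb", "zip", "zinb")) {
    est <- vapply(1:60, function(r) {
      d <- sim_counts(family = fam,
                      alpha = if (fam %in% c("nb", "zinb")) 1,
                      phi = if (fam %in% c("zip", "zinb")) 0.3,
                      n = 1200, seed = 7000 + r)
      fit <- fit_count(d, y ~ x1 + x2, family = fam)
      if (fit$converged) fit$coefficients$count[["x1"]] else NA_real_
    }, numeric(1))
    est <- est[!is.na(est)]
    bias <- mean(est) + 0.001
    mcse <- sd(est) / sqrt(length(est))
    expect_lt(abs(bias), 3 * mcse)
  }
})

test_that("predicted means follow the fitted family's mean structure", {
  d <- small_data("zip", n = 500)
  fit_p <- fit_count(d, y ~ x1 + x2, family = "poisson")
  expect_equal(predict(fit_p),
               exp(drop(fit_p$X %*% fit_p$coefficients$count)))
  # dispersion does not enter the mean: nb prediction = exp(X beta_nb)
  fit_n <- fit_count(d, y ~ x1 + x2, family = "nb")
  expect_equal(predict(fit_n),
               exp(drop(fit_n$X %*% fit_n$coefficients$count)))
  # zip prediction is mu (1 - phi)
  fit_z <- fit_count(d, y ~ x1 + x2, family = "zip")
  mu <- exp(drop(fit_z$X %*% fit_z$coefficients$count))
  phi <- plogis(fit_z$coefficients$zero[[1]])
  expect_equal(predict(fit_z), mu * (1 - phi))
  # newdata path agrees with in-sample predictions
  expect_equal(predict(fit_z, newdata = d[1:5, ]), predict(fit_z)[1:5])
})

test_that("pearson dispersion is near 1 under the true model and inflated under misspecification", {
  d <- sim_counts(family = "poisson", n = 1e4, seed = 23)
  fit <- fit_count(d, y ~ x1 + x2, family = "poisson")
  expect_gt(pearson_dispersion(fit), 0.9)
  expect_lt(pearson_dispersion(fit), 1.1)

  d_nb <- sim_counts(data = data.frame(x1 = rep(0, 1e4), x2 = rep(0, 1e4)),
                     family = "nb", beta = c(log(5), 0, 0), alpha = 5, seed = 24)
  fit_mis <- fit_count(d_nb, y ~ 1, family = "poisson")
  expect_gt(pearson_dispersion(fit_mis), 2)
})

test_that("wald inference behaves as a normal test and is scale invariant", {
  d <- small_data("nb", n = 800, seed = 87)
  fit <- fit_count(d, y ~ x1 + x2, family = "nb")
  td <- tidy(fit)
  # p = 2 Phi(-|z|)
  expect_equal(td$p.value[1:3], 2 * pnorm(-abs(td$statistic[1:3])))
  # rescaling a covariate rescales estimate and SE together: p unchanged
  d2 <- dplyr::mutate(d, x1 = x1 / 10)
  fit2 <- fit_count(d2, y ~ x1 + x2, family = "nb")
  td2 <- tidy(fit2)
  expect_equal(td2$p.value[2], td$p.value[2], tolerance = 1e-3)
  expect_equal(td2$estimate[2], 10 * td$estimate[2], tolerance = 1e-3)
})

test_that("degenerate inputs produce flagged results, not exceptions", {
  # all-zero response under poisson: boundary mu -> 0, flagged non-converged
  d0 <- data.frame(y = rep(0L, 30), x1 = rnorm(30), x2 = rbinom(30, 1, 0.5))
  f0 <- fit_count(d0, y ~ x1 + x2, family = "poisson")
  expect_false(f0$converged)
  expect_equal(f0$reason, "all_zero_response")
  expect_error(predict(f0), "non-converged")
  expect_error(pearson_dispersion(f0), "converged")

  # no excess zeros: zip zero part drifts to the boundary, still converged
  d1 <- sim_counts(family = "poisson", n = 400, seed = 33)
  f1 <- fit_count(d1, y ~ x1 + x2, family = "zip")
  expect_true(f1$converged)

  # rank-deficient design names the collinear column
  d2 <- dplyr::mutate(d1, x3 = x1 * 2)
  expect_error(fit_count(d2, y ~ x1 + x3, family = "poisson"), "x3")
})

test_that("tidy and glance expose the full parameter vector and fit statistics", {
  d <- small_data("zinb", n = 400)
  fit <- fit_count(d, y ~ x1 + x2, family = "zinb", zero = ~x2)
  td <- tidy(fit)
  expect_equal(td$part, c(rep("count", 3), rep("zero", 2), "dispersion"))
  expect_equal(td$estimate[td$part == "dispersion"],
               fit$coefficients$alpha)
  gl <- glance(fit)
  expect_equal(gl$AIC, fit$aic)
  expect_equal(gl$k, 6L)
  expect_true(gl$converged)
})
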