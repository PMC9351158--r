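test_that("covariate generator matches its target moments and is reproducible", {
  d <- sim_covariates(1e5, seed = 11)
  expect_lt(abs(mean(d$x1) - 57.3), 0.5)
  expect_lt(abs(var(d$x1) - 306.25), 5)
  expect_lt(abs(mean(d$x2) - 0.43), 0.01)
  expect_true(all(d$x2 %in% c(0L, 1L)))
  expect_identical(d, sim_covariates(1e5, seed = 11))
})

test_that("covariate generator validates its arguments", {
  expect_error(sim_covariates(0), "positive integer")
  expect_error(sim_covariates(10, x1_var = -1), "x1_var")
  expect_error(sim_covariates(10, x2_p = 1.2), "x2_p")
})

test_that("count generator enforces family-specific parameter presence", {
  expect_error(sim_counts(family = "poisson", alpha = 1, n = 10), "alpha")
  expect_error(sim_counts(family = "poisson", phi = 0.2, n = 10), "phi")
  expect_error(sim_counts(family = "nb", n = 10), "alpha")
  expect_error(sim_counts(family = "zip", phi = 1.2, n = 10), "phi")
  expect_error(sim_counts(family = "zinb", alpha = -1, phi = 0.1, n = 10), "alpha")
})

test_that("linear predictor overflow is caught with the offending row", {
  d <- data.frame(x1 = c(1, 900), x2 = c(0, 0))
  expect_error(
    sim_counts(d, family = "poisson", beta = c(0, 1, 0)),
    "row 2"
  )
})

test_that("structural zeros are recorded and force y = 0", {
  for (fam in c("zip", "zinb")) {
    d <- sim_counts(family = fam, phi = 0.5,
                    alpha = if (fam == "zinb") 2, n = 5000, seed = 21)
    expect_true(all(d$y[d$structural_zero] == 0))
    expect_equal(d$true_mean, exp(cbind(1, d$x1, d$x2) %*% c(2.1, -0.001, 0.03))[, 1] * 0.5)
  }
})

test_that("zip zero fraction dominates the structural-zero probability", {
  phi <- 0.3
  n <- 20000
  d <- sim_counts(family = "zip", phi = phi, n = n, seed = 31)
  expect_gte(mean(d$y == 0), phi - 3 * sqrt(phi * (1 - phi) / n))
})

test_that("zip with phi = 0 is distributionally identical to poisson", {
  d_zip <- sim_counts(family = "zip", phi = 0, n = 1e5, seed = 41)
  d_pois <- sim_counts(family = "poisson", n = 1e5, seed = 42)
  expect_gt(chisq_two_sample(d_zip$y, d_pois$y), 0.001)
})

test_that("zip mean matches mu (1 - phi): constant mu = 3, phi = 0.5", {
  d <- sim_counts(
    data = data.frame(x1 = rep(0, 1e5), x2 = rep(0, 1e5)),
    family = "zip", beta = c(log(3), 0, 0), phi = 0.5, seed = 51
  )
  expect_lt(abs(mean(d$y) - 1.5), 0.05)
})

test_that("nb variance matches mu (1 + alpha mu): mu = 2, alpha = 5", {
  d <- sim_counts(
    data = data.frame(x1 = rep(0, 1e5), x2 = rep(0, 1e5)),
    family = "nb", beta = c(log(2), 0, 0), alpha = 5, seed = 61
  )
  expect_lt(abs(var(d$y) - 22), 1.0)
})

test_that("nb at tiny dispersion is indistinguishable from poisson", {
  d_nb <- sim_counts(family = "nb", alpha = 1e-6, n = 1e5, seed = 71)
  d_pois <- sim_counts(family = "poisson", n = 1e5, seed = 72)
  expect_gt(chisq_two_sample(d_nb$y, d_pois$y), 0.001)
})

test_that("sample mean of y converges to the mean of the true means", {
  for (fam in c("poisson", "nb", "zip", "zinb")) {
    d <- sim_counts(
      data = data.frame(x1 = rep(0, 1e6), x2 = rep(0, 1e6)),
      family = fam, beta = c(log(4), 0, 0),
      alpha = if (fam %in% c("nb", "zinb")) 1,
      phi = if (fam %in% c("zip", "zinb")) 0.3,
      seed = 81
    )
    expect_lt(abs(mean(d$y) - mean(d$true_mean)) / mean(d$true_mean), 0.02)
  }
})

test_that("gamma-Poisson mixture sampling agrees with direct NB2 sampling", {
  d <- sim_counts(
    data = data.frame(x1 = rep(0, 1e5), x2 = rep(0, 1e5)),
    family = "nb", beta = c(log(5), 0, 0), alpha = 2, seed = 91
  )
  direct <- withr::with_seed(92, rnbinom(1e5, size = 0.5, mu = 5))
  expect_gt(chisq_two_sample(d$y, direct), 0.001)
})

test_that("count datasets round-trip through CSV with their truth sidecar", {
  d <- sim_counts(family = "zinb", alpha = 1, phi = 0.3, n = 50, seed = 7,
                  scenario_id = "demo")
  path <- withr::local_tempfile(fileext = ".csv")
  write_count_data(d, path)
  expect_true(file.exists(paste0(path, ".json")))
  d2 <- read_count_data(path)
  expect_equal(as.data.frame(d2), as.data.frame(d))
  truth <- attr(d2, "truth")
  expect_equal(truth$family, "zinb")
  expect_equal(truth$beta, c(2.1, -0.001, 0.03))
  expect_equal(truth$phi, 0.3)
  expect_equal(truth$seed, 7)
})

test_that("LOS emulator matches the marginal shape it emulates", {
  d <- sim_los(2167, seed = 1)
  expect_equal(nrow(d), 2167)
  expect_gte(mean(d$los), 7)
  expect_lte(mean(d$los), 9)
  expect_gt(var(d$los), mean(d$los))
  expect_gte(min(d$los), 0)
  expect_lte(max(d$los), 40)
  expect_gt(mean((d$los - mean(d$los))^3) / sd(d$los)^3, 0)  # right skew
  expect_setequal(unique(d$insurance),
                  c("government", "medicaid", "medicare", "private", "self_pay"))
  expect_setequal(unique(d$admission_type), c("elective", "emergency", "urgent"))
  expect_identical(d, sim_los(2167, seed = 1))
  expect_error(sim_los(0), "positive integer")
})
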