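# Design construction, likelihood components against independent density
# oracles, priors, and the model-reduction rule.

test_that("build_design applies the stage-conditional inclusion rule", {
  co <- simulate_cohort(cohort_design(seed = 8), default_params())
  spec <- default_submodels()[["g2_surv_pupal"]]
  bd <- build_design(co, spec)
  expected_rows <- sum(co$generation == 2L & co$died_24h %in% FALSE &
                         co$died_larval %in% FALSE)
  expect_identical(nrow(bd$X), expected_rows)
  expect_identical(length(bd$y), expected_rows)
  # nobody dead before the pupal stage contributes
  expect_true(all(co$died_larval[bd$rows] %in% FALSE))

  # rows with missing maternal mass are retained and flagged, not dropped
  n_missing <- sum(is.na(co$maternal_mass10_mg[bd$rows]))
  expect_gt(n_missing, 0)
  expect_identical(sum(bd$missing_maternal), n_missing)
})

test_that("intercept-only spec yields a single all-ones column", {
  co <- make_gen1_cohort(c(TRUE, FALSE, FALSE, TRUE))
  spec <- submodel_spec("g1_surv_24h", "died_24h", "mortality-logit",
                        "intercept", generation = 1)
  bd <- build_design(co, spec)
  expect_identical(dim(bd$X), c(4L, 1L))
  expect_true(all(bd$X == 1))
  expect_equal(bd$y, c(1, 0, 0, 1))
})

test_that("gen-2 development-time columns follow the canonical order", {
  co <- simulate_cohort(cohort_design(seed = 8), default_params())
  bd <- build_design(co, default_submodels()[["g2_devtime"]])
  expect_identical(colnames(bd$X),
                   c("intercept", "within", "male", "male:trans", "trans",
                     "within:trans", "maternal_mass"))
  # interaction columns are elementwise products
  expect_equal(bd$X[, "male:trans"], bd$X[, "male"] * bd$X[, "trans"])
  expect_equal(bd$X[, "within:trans"], bd$X[, "within"] * bd$X[, "trans"])
})

test_that("absent covariates and outcomes raise schema errors", {
  co <- simulate_cohort(cohort_design(seed = 8), default_params())
  spec <- submodel_spec("x", "no_such_column", "normal", "intercept", 1)
  expect_error(build_design(co, spec), class = "sublethal_schema_error")
  bad <- co
  bad$sex[which(bad$generation == 1L & bad$died_pupal %in% FALSE)[1]] <- NA
  expect_error(build_design(bad, default_submodels()[["g1_devtime"]]),
               class = "sublethal_schema_error")
  expect_error(submodel_spec("x", "y", "normal", c("intercept", "banana"), 1),
               "unknown covariate")
  expect_error(submodel_spec("x", "y", "normal",
                             c("intercept", "male:trans", "male"), 1),
               "both main effects")
})

test_that("mortality log-likelihood matches the Bernoulli oracle", {
  # all-zero coefficients: n * log(1/2)
  X <- cbind(intercept = rep(1, 7))
  expect_equal(loglik_mortality(0, X, rep(c(0, 1), length.out = 7)),
               7 * log(0.5), tolerance = 1e-12)

  # 3-row enumeration oracle with hand-set coefficients
  X3 <- cbind(1, c(0, 1, 1), c(4.2, 3.1, 5.0))
  coef <- c(-0.5, 0.8, -0.2)
  death <- c(1, 0, 1)
  oracle <- sum(dbinom(death, 1, plogis(drop(X3 %*% coef)), log = TRUE))
  expect_equal(loglik_mortality(coef, X3, death), oracle,
               tolerance = 1e-10)

  # one control death under the published total-larval coefficients
  expect_equal(
    loglik_mortality(c(-0.96, 0.07), cbind(1, 0), 1),
    log(plogis(-0.96)), tolerance = 1e-12)
})

test_that("gaussian log-likelihood matches dnorm/dlnorm oracles", {
  sigma <- 1.7
  X <- cbind(1, c(0.5, -1, 2, 0, 1))
  coef <- c(2, -0.6)
  y <- c(1.2, 2.5, 0.4, 1.9, 3.3)
  eta <- drop(X %*% coef)
  expect_equal(loglik_gaussian(coef, sigma, X, y),
               sum(dnorm(y, eta, sigma, log = TRUE)), tolerance = 1e-10)
  expect_equal(loglik_gaussian(coef, sigma, X, y, log_transform = TRUE),
               sum(dlnorm(y, eta, sigma, log = TRUE)), tolerance = 1e-10)
  # y exactly at the predictor
  expect_equal(loglik_gaussian(2, 0.5, cbind(1), 2),
               -log(0.5 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(loglik_gaussian(log(30), 0.5, cbind(1), 30,
                               log_transform = TRUE),
               -log(0.5 * sqrt(2 * pi)) - log(30), tolerance = 1e-12)
})

test_that("development-time intercept implies the published median", {
  # lognormal: median is exp(mean on the log scale)
  params <- no_death_params()
  params <- set_coef(params, "g1_devtime", "within", 0)
  set.seed(19)
  g1 <- simulate_gen1(cohort_design(n_gen1_larvae = 4000,
                                    n_gen2_larvae = 0), params)
  females <- g1$dev_time_days[g1$sex == "female"]
  expect_equal(median(females), exp(3.38), tolerance = 0.01)
})

test_that("beta log-likelihood matches the dbeta oracle", {
  # mu = 1/2, phi = 2 is the uniform: log-density 0 everywhere in (0,1)
  expect_equal(loglik_beta(0, 2, cbind(1), 0.37), 0, tolerance = 1e-12)
  expect_equal(loglik_beta(c(0, 0), 2, cbind(rep(1, 3), c(0, 1, -1)),
                           c(0.1, 0.9, 0.5)), 0, tolerance = 1e-12)

  X <- cbind(1, c(0, 1, 0, 1), c(0.2, -0.3, 0.5, 0))
  coef <- c(-1.42, 0.06, 0.4)
  phi <- 35
  y <- c(0.21, 0.18, 0.25, 0.30)
  mu <- plogis(drop(X %*% coef))
  oracle <- sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  expect_equal(loglik_beta(coef, phi, X, y), oracle, tolerance = 1e-10)

  # published sex effect: male mean lipid fraction above female
  expect_gt(plogis(-1.42 + 0.06), plogis(-1.42))
  expect_equal(plogis(-1.42), 0.195, tolerance = 0.002)
})

test_that("boundary smoothing pulls proportions off 0 and 1", {
  y <- c(0, 0.5, 1)
  s <- smooth_fractions(y)
  expect_true(all(s > 0 & s < 1))
  expect_equal(s[2], 0.5)
  # applied by build_design only when the data touch the boundary
  co <- simulate_cohort(cohort_design(seed = 4), default_params())
  bd <- build_design(co, default_submodels()[["g2_lipid"]])
  expect_equal(bd$y, co$lipid_frac[bd$rows])
})

test_that("log_prior matches independent density sums", {
  pr10 <- prior_spec(coef_scale = 10)
  p <- list(g1_surv_larval = c(intercept = 0, within = 0))
  expect_equal(log_prior(p, pr10), -2 * log(10 * sqrt(2 * pi)),
               tolerance = 1e-12)

  # a gen-1 posterior plugged in as prior: mode value at its mean
  ov <- prior_spec(overrides = list(
    "g1_mass_emergence.within" = c(-0.39, 2.205)))
  p2 <- list(g1_mass_emergence = c(within = -0.39))
  expect_equal(log_prior(p2, ov), dnorm(-0.39, -0.39, 2.205, log = TRUE),
               tolerance = 1e-12)
  expect_equal(log_prior(p2, ov), -log(2.205 * sqrt(2 * pi)),
               tolerance = 1e-12)

  # joint prior of a 3-parameter toy equals the brute-force sum of logs
  # (wide intercept prior, scale-2.5 effect priors)
  p3 <- list(g2_surv_24h = c(intercept = 0.3, within = -1.1, trans = 2))
  brute <- dnorm(0.3, 0, 10, log = TRUE) +
    sum(dnorm(c(-1.1, 2), 0, 2.5, log = TRUE))
  expect_equal(log_prior(p3, prior_spec()), brute, tolerance = 1e-12)

  # scale parameters: half-normal on sigma, gamma on phi
  p4 <- list(g1_devtime = c(sigma = 0.7), g2_lipid = c(phi = 12))
  expect_equal(log_prior(p4, prior_spec()),
               log(2) + dnorm(0.7, 0, 10, log = TRUE) +
                 dgamma(12, 0.01, rate = 0.01, log = TRUE),
               tolerance = 1e-12)
})

test_that("priors_from_summary maps posterior summaries onto overrides", {
  s <- data.frame(parameter = c("a.b", "c.d"), mean = c(1, -2),
                  sd = c(0.5, 3))
  ov <- priors_from_summary(s)
  expect_equal(ov[["a.b"]], c(1, 0.5))
  expect_equal(ov[["c.d"]], c(-2, 3))
})

test_that("reduce_model errors when an interaction summary is absent", {
  specs <- default_submodels()
  ref <- reference_estimates()
  ref <- ref[ref$parameter != "g2_devtime.male:trans", ]
  expect_error(reduce_model(ref, specs), "g2_devtime.male:trans")
})
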