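# Sampler correctness: determinism, no-data and quadrature limits,
# within-chain imputation, and diagnostics.

intercept_only_spec <- function() {
  list(g1_surv_24h = submodel_spec("g1_surv_24h", "died_24h",
                                   "mortality-logit", "intercept",
                                   generation = 1))
}

test_that("identical seed, config and data give bit-identical draws", {
  set.seed(1)
  co <- simulate_cohort(cohort_design(n_gen1_larvae = 80, n_sires = 2,
                                      n_gen2_larvae = 100, seed = 21),
                        default_params())
  f1 <- sample_posterior(co, config = quick_cfg(seed = 5))
  f2 <- sample_posterior(co, config = quick_cfg(seed = 5))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$imputed, f2$imputed)
  f3 <- sample_posterior(co, config = quick_cfg(seed = 6))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("with no data the posterior reproduces the prior", {
  co <- make_gen1_cohort(logical(0))
  fit <- sample_posterior(co, specs = intercept_only_spec(),
                          config = mcmc_config(burn_in = 4000, keep = 4000,
                                               thin = 2, seed = 3))
  b <- fit$draws[, "g1_surv_24h.intercept"]
  ess <- diagnostics(fit)$summary$ess[1]
  se_mean <- 10 / sqrt(ess)
  expect_lt(abs(mean(b) - 0), 3 * se_mean)
  se_sd <- 10 / sqrt(2 * ess)
  expect_lt(abs(sd(b) - 10), 3 * se_sd)
})

test_that("intercept-only toy matches 1-D grid quadrature", {
  # 2 deaths / 8 survivors; oracle: grid integration of the posterior
  co <- make_gen1_cohort(rep(c(TRUE, FALSE), c(2, 8)))
  grid <- seq(-15, 15, by = 0.002)
  logpost <- 2 * plogis(grid, log.p = TRUE) +
    8 * plogis(-grid, log.p = TRUE) + dnorm(grid, 0, 10, log = TRUE)
  w <- exp(logpost - max(logpost))
  truth <- sum(plogis(grid) * w) / sum(w)

  fit <- sample_posterior(co, specs = intercept_only_spec(),
                          config = mcmc_config(seed = 9))
  p_draws <- plogis(fit$draws[, "g1_surv_24h.intercept"])
  ess <- diagnostics(fit)$summary$ess[1]
  mc_se <- sd(p_draws) / sqrt(ess)
  expect_lt(abs(mean(p_draws) - truth), 3 * mc_se)
})

test_that("two-parameter logistic toy matches 2-D grid quadrature", {
  death <- rep(c(TRUE, FALSE, TRUE, FALSE), c(3, 7, 6, 4))
  within <- rep(c("control", "insecticide"), each = 10)
  co <- make_gen1_cohort(death, within)
  spec <- list(g1_surv_24h = submodel_spec(
    "g1_surv_24h", "died_24h", "mortality-logit",
    c("intercept", "within"), generation = 1))

  g <- seq(-6, 6, by = 0.04)
  ll <- function(b0, b1) {
    3 * plogis(b0, log.p = TRUE) + 7 * plogis(-b0, log.p = TRUE) +
      6 * plogis(b0 + b1, log.p = TRUE) +
      4 * plogis(-(b0 + b1), log.p = TRUE) +
      dnorm(b0, 0, 10, log = TRUE) + dnorm(b1, 0, 2.5, log = TRUE)
  }
  lp <- outer(g, g, ll)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  truth_mean <- c(sum(rowSums(w) * g), sum(colSums(w) * g))
  truth_var <- c(sum(rowSums(w) * g^2), sum(colSums(w) * g^2)) -
    truth_mean^2

  fit <- sample_posterior(co, specs = spec, config = mcmc_config(seed = 4))
  dg <- diagnostics(fit)$summary
  for (j in 1:2) {
    x <- fit$draws[, j]
    mc_se <- sd(x) / sqrt(dg$ess[j])
    expect_lt(abs(mean(x) - truth_mean[j]), 3 * mc_se)
    se_var <- var(x) * sqrt(2 / dg$ess[j])
    expect_lt(abs(var(x) - truth_var[j]), 3 * se_var)
  }
})

# A small cohort with one dam whose 10-day mass is missing: six fully
# observed gen-1 females inform the mass model, the dam died as an adult,
# and her offspring carry the flagged missing covariate.
imputation_cohort <- function(n_off = 10, offspring_dead = FALSE) {
  g1 <- blank_cohort(7)
  g1$died_24h <- FALSE
  g1$died_larval <- FALSE
  g1$died_pupal <- FALSE
  g1$died_adult <- c(rep(FALSE, 6), TRUE)
  g1$sex <- "female"
  g1$dev_time_days <- 29
  g1$mass_emergence_mg <- 120
  g1$mass_day10_mg <- c(155, 160, 165, 170, 158, 168, NA)
  g2 <- blank_cohort(n_off, generation = 2L)
  g2$mother_id <- g1$id[7]
  g2$family_id <- "F001"
  g2$maternal_treatment <- "control"
  g2$died_24h <- offspring_dead
  g2$died_larval <- if (offspring_dead) NA else TRUE
  rbind(g1, g2)
}

test_that("a model without missing values has nothing to impute", {
  co <- simulate_cohort(cohort_design(n_gen1_larvae = 60, n_sires = 1,
                                      dams_per_sire = 2,
                                      n_gen2_larvae = 40, seed = 2),
                        no_death_params())
  model <- mcmc_model(co)
  expect_length(model$imputed_dams, 0)
  res <- impute_missing(model, sweeps = 3)
  expect_length(res$imputed, 0)
})

test_that("uninformative offspring make imputation draw from the gen-1 predictive", {
  co <- imputation_cohort(offspring_dead = FALSE)
  model <- mcmc_model(co)
  expect_length(model$imputed_dams, 1)
  state <- list(coef = list(g1_mass_day10 = c(165, 7, -31)),
                scale = list(g1_mass_day10 = 20))
  # maternal-mass coefficients are zero in the default starting state, so
  # the offspring likelihood ratio is identically 1
  set.seed(12)
  res <- impute_missing(model, state = state, sweeps = 5000)
  expect_equal(res$accept, 1)
  draws <- res$draws[, 1]
  # dam is a control female: predictive is N(165, 20)
  ks <- suppressWarnings(stats::ks.test(draws, "pnorm", 165, 20))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(draws) - 165), 3 * 20 / sqrt(5000))
})

test_that("dead offspring pull an imputed mass above the predictive mean", {
  co <- imputation_cohort(n_off = 12, offspring_dead = TRUE)
  model <- mcmc_model(co)
  state <- list(coef = list(
    g1_mass_day10 = c(165, 7, -31),
    # death logit rises with maternal mass, centred so that death is a
    # coin flip at the predictive mean (maximally informative)
    g2_surv_24h = c(-8.25, 0, 0, 0.05, 0)),
    scale = list(g1_mass_day10 = 20))
  set.seed(13)
  res <- impute_missing(model, state = state, sweeps = 5000)
  expect_gt(mean(res$draws[, 1]), 165 + 2)
  # and observed masses are untouched by construction: the imputation
  # only ever writes the flagged latent entries
  expect_identical(model$blocks[[match("g1_mass_day10",
                                       names(model$specs))]]$y[1:6],
                   c(155, 160, 165, 170, 158, 168))
})

test_that("diagnostics behave on known processes and degenerate input", {
  set.seed(77)
  n <- 2000
  iid <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "iid"))
  d1 <- diagnostics(iid)
  expect_lt(abs(d1$summary$lag1), 2 / sqrt(n))
  expect_gt(d1$summary$ess, n / 2)

  rho <- 0.95
  ar <- numeric(n)
  for (i in 2:n) ar[i] <- rho * ar[i - 1] + rnorm(1) * sqrt(1 - rho^2)
  d2 <- diagnostics(matrix(ar, dimnames = list(NULL, "ar1")))
  expect_lt(abs(d2$summary$lag1 - rho), 0.05)
  expect_equal(d2$summary$flag, "low_ess")

  const <- matrix(1, nrow = 200, ncol = 1, dimnames = list(NULL, "c"))
  d3 <- diagnostics(const)
  expect_identical(d3$summary$flag, "degenerate")
  expect_error(diagnostics(matrix(rnorm(50), ncol = 1)), "at least 100")
})

test_that("acceptance rates stay in the adapted random-walk range", {
  co <- simulate_cohort(cohort_design(n_gen1_larvae = 100, n_sires = 2,
                                      n_gen2_larvae = 150, seed = 6),
                        default_params())
  fit <- sample_posterior(co, config = quick_cfg(seed = 2))
  acc <- unlist(fit$accept)
  expect_true(all(acc > 0.1 & acc < 0.6))
})
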