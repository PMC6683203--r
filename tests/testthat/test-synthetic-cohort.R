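# Synthetic cohort generator: design validation, stage-conditional fates,
# mating design, missingness, and the generator's distributional behaviour.

test_that("cohort_design enforces its invariants", {
  expect_s3_class(cohort_design(), "cohort_design")
  expect_error(cohort_design(dams_per_sire = 3), "even")
  expect_error(cohort_design(treatment_allocation = 1), "strictly inside")
  expect_error(cohort_design(n_gen1_larvae = 0), "positive")
  expect_silent(cohort_design(n_gen2_larvae = 0))
})

test_that("degenerate no-death limit: every individual survives all stages", {
  set.seed(42)
  d <- cohort_design(n_gen1_larvae = 120, n_sires = 2, n_gen2_larvae = 150)
  co <- simulate_cohort(d, no_death_params())
  for (col in c("died_24h", "died_larval", "died_pupal", "died_adult")) {
    expect_true(all(co[[col]] %in% FALSE))
  }
  # complete survival means complete measurement
  expect_false(anyNA(co$dev_time_days))
  expect_false(anyNA(co$sex))
  g2 <- co[co$generation == 2L, ]
  expect_false(anyNA(g2$lipid_frac))
  expect_false(anyNA(g2$maternal_mass10_mg))
  validate_cohort(co)
})

test_that("simulated 24 h control-arm survival matches the closed-form average", {
  # oracle: E[1 - expit(b0 + e * m)] over the truncated-normal mass law
  params <- default_params()
  b0 <- params$g1_surv_24h[["intercept"]]
  eps <- params$g1_surv_24h[["larval_mass"]]
  f <- function(m) plogis(-(b0 + eps * m)) * dnorm(m, 4, 1)
  expected <- integrate(f, 0, Inf)$value / (1 - pnorm(0, 4, 1))

  set.seed(101)
  d <- cohort_design(n_gen1_larvae = 245)
  n_rep <- 2000
  surv <- vapply(seq_len(n_rep), function(i) {
    g1 <- simulate_gen1(d, params)
    ctrl <- g1$within_treatment == "control"
    c(sum(!g1$died_24h[ctrl]), sum(ctrl))
  }, numeric(2))
  p_hat <- sum(surv[1, ]) / sum(surv[2, ])
  mc_se <- sqrt(expected * (1 - expected) / sum(surv[2, ]))
  expect_lt(abs(p_hat - expected), 3 * mc_se)
})

test_that("male emergence mass reflects the sex coefficient", {
  # intercept 122.77 + male effect -18.38, no treatment effect
  params <- no_death_params()
  params <- set_coef(params, "g1_mass_emergence", "intercept", 122.77)
  params <- set_coef(params, "g1_mass_emergence", "within", 0)
  params <- set_coef(params, "g1_mass_emergence", "male", -18.38)
  set.seed(7)
  d <- cohort_design(n_gen1_larvae = 4000, n_sires = 2, n_gen2_larvae = 0)
  g1 <- simulate_gen1(d, params)
  sigma <- params$g1_mass_emergence[["sigma"]]
  m_male <- mean(g1$mass_emergence_mg[g1$sex == "male"])
  m_female <- mean(g1$mass_emergence_mg[g1$sex == "female"])
  expect_lt(abs(m_male - 104.39), 3 * sigma / sqrt(sum(g1$sex == "male")))
  expect_lt(abs(m_female - 122.77),
            3 * sigma / sqrt(sum(g1$sex == "female")))
})

test_that("mate_design builds the split-brood structure", {
  set.seed(5)
  d <- cohort_design(n_gen1_larvae = 600, n_sires = 14, dams_per_sire = 4,
                     n_gen2_larvae = 0)
  g1 <- simulate_gen1(d, no_death_params())
  fam <- mate_design(g1, d)
  expect_identical(nrow(fam), 56L)
  expect_identical(length(unique(fam$sire_id)), 14L)
  expect_true(all(table(fam$sire_id) == 4))
  # each sire: two control dams, two insecticide dams
  split_ok <- tapply(fam$maternal_treatment, fam$sire_id,
                     function(x) sum(x == "control") == 2)
  expect_true(all(split_ok))
  expect_false(any(duplicated(fam$dam_id)))

  # minimal design: 1 sire, 2 dams, one from each arm
  d1 <- cohort_design(n_gen1_larvae = 600, n_sires = 1, dams_per_sire = 2,
                      n_gen2_larvae = 0)
  fam1 <- mate_design(g1, d1)
  expect_identical(nrow(fam1), 2L)
  expect_setequal(fam1$maternal_treatment, c("control", "insecticide"))
})

test_that("mating shortfall raises an explicit error with counts", {
  # 24 insecticide females emerged: short of the 28 the design needs
  df <- blank_cohort(80)
  df$within_treatment <- rep(c("control", "insecticide"), each = 40)
  df$died_24h <- FALSE
  df$died_larval <- FALSE
  df$died_pupal <- FALSE
  df$died_adult <- FALSE
  df$sex <- c(rep("male", 20), rep("female", 20),
              rep("male", 16), rep("female", 24))
  df$dev_time_days <- 29
  df$mass_emergence_mg <- 120
  df$mass_day10_mg <- 160
  d <- cohort_design(n_gen1_larvae = 80, n_sires = 14, dams_per_sire = 4)
  err <- tryCatch(mate_design(df, d), condition = identity)
  expect_s3_class(err, "sublethal_shortfall_error")
  expect_match(conditionMessage(err), "need 28 insecticide dams, have 24")
})

test_that("all-zero survival block gives death probability exactly 1/2", {
  params <- no_death_params(zero_params())
  params <- set_coef(params, "g2_surv_larval", "intercept", 0)  # expit(0)
  fam <- data.frame(family_id = "F001", sire_id = "s", dam_id = "d",
                    maternal_treatment = "control",
                    maternal_mass10_mg = 160, stringsAsFactors = FALSE)
  set.seed(11)
  d <- cohort_design(n_gen1_larvae = 10, n_sires = 1, dams_per_sire = 2,
                     n_gen2_larvae = 6000)
  g2 <- simulate_gen2(fam, d, params)
  p_hat <- mean(g2$died_larval %in% TRUE)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / nrow(g2)))
})

test_that("maternal-exposure survival odds ratio matches its closed form", {
  # only the transgenerational term of total larval survival is active:
  # survival odds for insecticide-dam offspring = exp(0.56) x control
  params <- no_death_params(zero_params())
  params <- set_coef(params, "g2_surv_larval", "intercept", 0)
  params <- set_coef(params, "g2_surv_larval", "trans", -0.56)
  fam <- data.frame(family_id = c("F001", "F002"), sire_id = "s",
                    dam_id = c("d1", "d2"),
                    maternal_treatment = c("control", "insecticide"),
                    maternal_mass10_mg = c(160, 160),
                    stringsAsFactors = FALSE)
  set.seed(23)
  d <- cohort_design(n_gen1_larvae = 10, n_sires = 1, dams_per_sire = 2,
                     n_gen2_larvae = 200000)
  g2 <- simulate_gen2(fam, d, params)
  tab <- table(trans = g2$maternal_treatment,
               died = g2$died_larval %in% TRUE)
  # survival odds ratio insecticide-dam vs control-dam offspring
  or_surv <- (tab["insecticide", "FALSE"] / tab["insecticide", "TRUE"]) /
    (tab["control", "FALSE"] / tab["control", "TRUE"])
  se_log <- sqrt(sum(1 / tab))
  expect_lt(abs(log(or_surv) - 0.56), 3 * se_log)
})

test_that("apply_missingness blanks by stage of death and is idempotent", {
  set.seed(31)
  co <- simulate_cohort(cohort_design(seed = 31), default_params())
  expect_identical(apply_missingness(co), co)
  expect_identical(apply_missingness(apply_missingness(co)),
                   apply_missingness(co))

  dead_first <- co[which(co$died_24h)[1], ]
  expect_true(is.na(dead_first$died_larval))
  expect_true(is.na(dead_first$sex))
  expect_true(all(is.na(dead_first[c("dev_time_days", "mass_emergence_mg",
                                     "mass_day10_mg", "lipid_frac")])))
  expect_false(is.na(dead_first$within_treatment))

  g2_complete <- co[co$generation == 2L & co$died_adult %in% FALSE &
                      !is.na(co$maternal_mass10_mg), ][1, ]
  expect_false(anyNA(g2_complete[c("sex", "dev_time_days",
                                   "mass_emergence_mg", "mass_day7_mg",
                                   "mass_day14_mg", "fresh_mg", "dry_mg",
                                   "lean_mg", "lipid_frac", "water_frac",
                                   "drymass_frac")]))

  # a hand-damaged frame is repaired to the canonical pattern
  broken <- co
  i <- which(broken$died_24h)[1]
  broken$mass_day10_mg[i] <- 150
  fixed <- apply_missingness(broken)
  expect_true(is.na(fixed$mass_day10_mg[i]))
})

test_that("stage conservation: entrants = survivors + deaths at every stage", {
  co <- simulate_cohort(cohort_design(seed = 17), default_params())
  for (g in 1:2) {
    sub <- co[co$generation == g, ]
    entrants <- nrow(sub)
    for (col in c("died_24h", "died_larval", "died_pupal", "died_adult")) {
      deaths <- sum(sub[[col]] %in% TRUE)
      survivors <- sum(sub[[col]] %in% FALSE)
      expect_identical(deaths + survivors, entrants)
      entrants <- survivors
    }
  }
})

test_that("raising a death-logit coefficient never increases survival (coupling)", {
  d <- cohort_design(n_gen1_larvae = 400, n_gen2_larvae = 0)
  base <- default_params()
  for (term in c("within", "intercept")) {
    bumped <- set_coef(base, "g1_surv_larval", term,
                       base$g1_surv_larval[[term]] + 1.5)
    set.seed(99)
    g_base <- simulate_gen1(d, base)
    set.seed(99)
    g_bump <- simulate_gen1(d, bumped)
    # same individuals died at 24 h; larval deaths are a superset
    expect_identical(g_base$died_24h, g_bump$died_24h)
    died_base <- which(g_base$died_larval %in% TRUE)
    died_bump <- which(g_bump$died_larval %in% TRUE)
    expect_true(all(died_base %in% died_bump))
    # survivors at every later stage are a subset of the baseline's
    for (col in c("died_larval", "died_pupal", "died_adult")) {
      expect_true(all(which(g_bump[[col]] %in% FALSE) %in%
                        which(g_base[[col]] %in% FALSE)))
    }
  }
})

test_that("cohort CSV round trip is lossless, including missingness", {
  co <- simulate_cohort(cohort_design(seed = 13), default_params())
  attr(co, "families") <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_identical(back, co)
})

test_that("design sidecar round trips design and true parameters", {
  d <- cohort_design(seed = 3)
  p <- default_params()
  path <- withr::local_tempfile(fileext = ".json")
  write_design_sidecar(d, p, path)
  back <- read_design_sidecar(path)
  expect_identical(back$design, d)
  expect_equal(flatten_params(back$params), flatten_params(p))
})

test_that("validate_cohort rejects schema and invariant violations", {
  co <- simulate_cohort(cohort_design(seed = 2), default_params())
  bad <- co[, -match("sex", names(co))]
  expect_error(validate_cohort(bad), class = "sublethal_schema_error")
  bad2 <- co
  i <- which(bad2$died_24h)[1]
  bad2$dev_time_days[i] <- 30   # trait present after death
  expect_error(validate_cohort(bad2), class = "sublethal_schema_error")
  bad3 <- co
  j <- which(!is.na(bad3$lipid_frac))[1]
  bad3$lean_mg[j] <- bad3$fresh_mg[j] * 2   # weight ordering broken
  expect_error(validate_cohort(bad3), class = "sublethal_schema_error")
})

test_that("incomplete parameter set names the missing block", {
  p <- default_params()
  p_bad <- unclass(p)
  p_bad$g1_surv_pupal <- NULL
  expect_error(simulate_gen1(cohort_design(), p_bad), "g1_surv_pupal")
})
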