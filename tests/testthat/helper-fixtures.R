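# Fixtures are built in code: blank-but-valid cohort frames, parameter sets
# with known structure, and a fast MCMC schedule for toy posteriors.

blank_cohort <- function(n, generation = 1L) {
  m <- max(n, 1L)
  data.frame(
    id = sprintf("I%d_%04d", generation, seq_len(m)),
    generation = as.integer(generation),
    family_id = NA_character_, mother_id = NA_character_,
    within_treatment = "control",
    maternal_treatment = if (generation == 2L) "control" else NA_character_,
    sex = NA_character_,
    larval_mass_mg = if (generation == 1L) 4 else NA_real_,
    maternal_mass10_mg = NA_real_,
    died_24h = FALSE, died_larval = NA, died_pupal = NA, died_adult = NA,
    dev_time_days = NA_real_, mass_emergence_mg = NA_real_,
    mass_day7_mg = NA_real_, mass_day10_mg = NA_real_,
    mass_day14_mg = NA_real_, fresh_mg = NA_real_, dry_mg = NA_real_,
    lean_mg = NA_real_, lipid_frac = NA_real_, water_frac = NA_real_,
    drymass_frac = NA_real_, stringsAsFactors = FALSE)[seq_len(n), ,
                                                       drop = FALSE]
}

# gen-1 cohort with given 24 h fates; survivors die as larvae so that later
# stages stay empty and the frame remains schema-valid
make_gen1_cohort <- function(death24,
                             within = rep("control", length(death24))) {
  df <- blank_cohort(length(death24))
  df$within_treatment <- within
  df$died_24h <- death24
  df$died_larval <- ifelse(death24, NA, TRUE)
  df
}

zero_params <- function(sigma = 1, phi = 2) {
  p <- default_params()
  for (bn in names(p)) {
    b <- p[[bn]]
    b[] <- 0
    if ("sigma" %in% names(b)) b["sigma"] <- sigma
    if ("phi" %in% names(b)) b["phi"] <- phi
    p[[bn]] <- b
  }
  param_set(p)
}

set_coef <- function(params, block, term, value) {
  params[[block]][term] <- value
  params
}

# immortal variant: no deaths at any stage
no_death_params <- function(params = default_params()) {
  for (bn in grep("surv", names(params), value = TRUE)) {
    params <- set_coef(params, bn, "intercept", -Inf)
  }
  params
}

quick_cfg <- function(seed = 1L, ...) {
  mcmc_config(burn_in = 3000L, keep = 500L, thin = 2L, seed = seed, ...)
}
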