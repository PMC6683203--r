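# Synthetic two-generation cohorts from the generative model: split-brood
# mating design, stage-conditional Bernoulli mortality (death = 1 on the
# logit scale), lognormal development time, normal body masses, and beta
# composition fractions, with stage-conditional missingness.

#' Column schema of a cohort table
#'
#' One row per individual. Missing values (`NA`) encode both genuinely
#' unobserved traits and fields undefined for the individual (e.g. stage
#' fates after death, gen-1-only covariates on gen-2 rows).
#' @return Character vector of column names in canonical order.
#' @export
cohort_columns <- function() {
  c("id", "generation", "family_id", "mother_id", "within_treatment",
    "maternal_treatment", "sex", "larval_mass_mg", "maternal_mass10_mg",
    "died_24h", "died_larval", "died_pupal", "died_adult", "dev_time_days",
    "mass_emergence_mg", "mass_day7_mg", "mass_day10_mg", "mass_day14_mg",
    "fresh_mg", "dry_mg", "lean_mg", "lipid_frac", "water_frac",
    "drymass_frac")
}

.empty_cohort <- function(n = 0L) {
  df <- data.frame(
    id = character(n), generation = integer(n), family_id = NA_character_,
    mother_id = NA_character_, within_treatment = NA_character_,
    maternal_treatment = NA_character_, sex = NA_character_,
    larval_mass_mg = NA_real_, maternal_mass10_mg = NA_real_,
    died_24h = NA, died_larval = NA, died_pupal = NA, died_adult = NA,
    dev_time_days = NA_real_, mass_emergence_mg = NA_real_,
    mass_day7_mg = NA_real_, mass_day10_mg = NA_real_,
    mass_day14_mg = NA_real_, fresh_mg = NA_real_, dry_mg = NA_real_,
    lean_mg = NA_real_, lipid_frac = NA_real_, water_frac = NA_real_,
    drymass_frac = NA_real_, stringsAsFactors = FALSE)
  df[seq_len(n), , drop = FALSE]
}

# Covariate value of a model term on cohort rows. Reference levels:
# control = 0 / insecticide = 1, female = 0 / male = 1.
.term_value <- function(term, df) {
  switch(term,
    intercept = rep(1, nrow(df)),
    within = as.numeric(df$within_treatment == "insecticide"),
    trans = as.numeric(df$maternal_treatment == "insecticide"),
    male = as.numeric(df$sex == "male"),
    maternal_mass = df$maternal_mass10_mg,
    larval_mass = df$larval_mass_mg,
    "within:trans" = as.numeric(df$within_treatment == "insecticide") *
      as.numeric(df$maternal_treatment == "insecticide"),
    "male:trans" = as.numeric(df$sex == "male") *
      as.numeric(df$maternal_treatment == "insecticide"),
    stop("unknown model term: '", term, "'", call. = FALSE)
  )
}

# Linear predictor of one block's coefficients on cohort rows.
.linpred <- function(df, coefs) {
  terms <- setdiff(names(coefs), c("sigma", "phi"))
  eta <- numeric(nrow(df))
  for (tm in terms) eta <- eta + coefs[[tm]] * .term_value(tm, df)
  eta
}

# Sequential stage-conditional mortality. Stage uniforms are drawn up-front
# in one matrix so that two runs under a common seed are coupled: raising a
# death-logit coefficient can only turn survivors into deaths, never the
# reverse (used by the monotonicity property test).
.draw_fates <- function(df, params, block_names) {
  n <- nrow(df)
  u <- matrix(runif(n * length(block_names)), nrow = n)
  alive <- rep(TRUE, n)
  fates <- list()
  for (k in seq_along(block_names)) {
    p <- plogis(.linpred(df, params[[block_names[k]]]))
    died <- rep(NA, n)
    died[alive] <- u[alive, k] < p[alive]
    alive <- alive & !(died %in% TRUE)
    fates[[k]] <- died
  }
  names(fates) <- c("died_24h", "died_larval", "died_pupal", "died_adult")
  fates
}

#' Simulate the first generation of a cohort
#'
#' Draws pre-treatment larval masses, randomizes larvae to control and
#' insecticide arms at the design's allocation fraction, draws the four
#' stage-conditional fates from the gen-1 mortality logits, and draws sex,
#' development time and body masses for the individuals alive at each
#' measurement age. Stage-conditional missingness is applied before
#' returning, so the result is an observable data set.
#'
#' @param design a [cohort_design()].
#' @param params a [param_set()] (or named list covering the gen-1 blocks).
#' @param larval_mass_mean,larval_mass_sd mean and SD (mg) of the
#'   pre-treatment larval mass distribution (normal, truncated at 0); the
#'   original study does not report it.
#' @return A cohort data frame ([cohort_columns()]) with
#'   `design$n_gen1_larvae` rows.
#' @export
simulate_gen1 <- function(design, params, larval_mass_mean = 4,
                          larval_mass_sd = 1) {
  stopifnot(inherits(design, "cohort_design"))
  blocks <- c("g1_surv_24h", "g1_surv_larval", "g1_surv_pupal",
              "g1_surv_adult", "g1_devtime", "g1_mass_emergence",
              "g1_mass_day10")
  .check_params_for(params, blocks)
  n <- design$n_gen1_larvae
  df <- .empty_cohort(n)
  df$id <- sprintf("G1_%04d", seq_len(n))
  df$generation <- 1L
  n_ins <- round(n * design$treatment_allocation)
  trt <- rep("control", n)
  trt[sample.int(n, n_ins)] <- "insecticide"
  df$within_treatment <- trt
  mass <- rnorm(n, larval_mass_mean, larval_mass_sd)
  while (any(bad <- mass <= 0)) {
    mass[bad] <- rnorm(sum(bad), larval_mass_mean, larval_mass_sd)
  }
  df$larval_mass_mg <- mass

  fates <- .draw_fates(df, params, blocks[1:4])
  for (nm in names(fates)) df[[nm]] <- fates[[nm]]

  emerged <- which(df$died_pupal %in% FALSE)
  if (length(emerged)) {
    df$sex[emerged] <- ifelse(runif(length(emerged)) < 0.5, "male", "female")
    sub <- df[emerged, , drop = FALSE]
    pdt <- params[["g1_devtime"]]
    df$dev_time_days[emerged] <-
      exp(rnorm(length(emerged), .linpred(sub, pdt), pdt[["sigma"]]))
    pm0 <- params[["g1_mass_emergence"]]
    df$mass_emergence_mg[emerged] <-
      rnorm(length(emerged), .linpred(sub, pm0), pm0[["sigma"]])
  }
  alive10 <- which(df$died_adult %in% FALSE)
  if (length(alive10)) {
    pm10 <- params[["g1_mass_day10"]]
    df$mass_day10_mg[alive10] <-
      rnorm(length(alive10), .linpred(df[alive10, , drop = FALSE], pm10),
            pm10[["sigma"]])
  }
  apply_missingness(df)
}

#' Build the split-brood mating design from gen-1 survivors
#'
#' Each sire is a control male that survived the gen-1 adult stage; each
#' sire is paired with `dams_per_sire` dams, half drawn from control females
#' and half from insecticide-exposed females. Dams are females that reached
#' adult emergence; a dam that died during the adult stage (before the
#' 10-day weighing) carries a missing 10-day mass, which is the source of
#' the missing maternal-mass covariate downstream.
#'
#' @param gen1_survivors a gen-1 cohort data frame (from [simulate_gen1()]).
#' @param design a [cohort_design()].
#' @return Data frame of family records: `family_id`, `sire_id`, `dam_id`,
#'   `maternal_treatment`, `maternal_mass10_mg` (possibly `NA`).
#' @export
mate_design <- function(gen1_survivors, design) {
  stopifnot(inherits(design, "cohort_design"))
  g1 <- gen1_survivors
  sire_pool <- g1$id[g1$sex %in% "male" & g1$within_treatment == "control" &
                       g1$died_adult %in% FALSE]
  dams_per_arm <- design$n_sires * design$dams_per_sire / 2L
  dam_pool <- lapply(c(control = "control", insecticide = "insecticide"),
                     function(arm) {
                       g1$id[g1$sex %in% "female" &
                               g1$within_treatment == arm &
                               g1$died_pupal %in% FALSE]
                     })
  shortfall <- character()
  if (length(sire_pool) < design$n_sires) {
    shortfall <- c(shortfall, sprintf(
      "need %d surviving control sires, have %d", design$n_sires,
      length(sire_pool)))
  }
  for (arm in names(dam_pool)) {
    if (length(dam_pool[[arm]]) < dams_per_arm) {
      shortfall <- c(shortfall, sprintf(
        "need %d %s dams, have %d", dams_per_arm, arm,
        length(dam_pool[[arm]])))
    }
  }
  if (length(shortfall)) {
    stop(errorCondition(
      paste0("not enough surviving gen-1 adults for the mating design: ",
             paste(shortfall, collapse = "; ")),
      class = c("sublethal_shortfall_error", "error", "condition")))
  }
  sires <- sample(sire_pool, design$n_sires)
  dams <- lapply(dam_pool, sample, size = dams_per_arm)
  half <- design$dams_per_sire / 2L
  fam_dams <- character(0)
  fam_sires <- character(0)
  for (i in seq_len(design$n_sires)) {
    idx <- ((i - 1L) * half + 1L):(i * half)
    fam_dams <- c(fam_dams, dams$control[idx], dams$insecticide[idx])
    fam_sires <- c(fam_sires, rep(sires[i], design$dams_per_sire))
  }
  dam_rows <- match(fam_dams, g1$id)
  data.frame(
    family_id = sprintf("F%03d", seq_along(fam_dams)),
    sire_id = fam_sires,
    dam_id = fam_dams,
    maternal_treatment = g1$within_treatment[dam_rows],
    maternal_mass10_mg = g1$mass_day10_mg[dam_rows],
    stringsAsFactors = FALSE)
}

#' Simulate the second generation of a cohort
#'
#' Offspring are allocated near-uniformly across families, inherit the
#' maternal treatment and maternal 10-day mass, and are re-randomized to
#' within-generation treatments. Fates come from the gen-2 mortality logits
#' (including maternal-mass and treatment-interaction terms); development
#' time, masses and the three composition fractions are drawn for survivors
#' of the relevant ages. When a dam's 10-day mass is missing, a latent mass
#' is drawn from the gen-1 mass model for her covariates and used as the
#' true covariate; the observable column stays missing.
#'
#' @param families family records from [mate_design()].
#' @param design a [cohort_design()].
#' @param params a [param_set()].
#' @return A cohort data frame with `design$n_gen2_larvae` rows.
#' @export
simulate_gen2 <- function(families, design, params) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(families) || nrow(families) == 0L) {
    stop("`families` must contain at least one family record", call. = FALSE)
  }
  blocks <- c("g2_surv_24h", "g2_surv_larval", "g2_surv_pupal",
              "g2_surv_adult", "g2_devtime", "g2_mass_emergence",
              "g2_mass_day7", "g2_mass_day14", "g2_lipid", "g2_water",
              "g2_drymass")
  .check_params_for(params, c(blocks, "g1_mass_day10"))
  n <- design$n_gen2_larvae
  if (n == 0L) return(.empty_cohort(0L))
  nf <- nrow(families)

  # latent maternal mass: observed when available, otherwise one draw per
  # dam from the gen-1 day-10 mass model (dam is female).
  pm10 <- params[["g1_mass_day10"]]
  dam_df <- .empty_cohort(nf)
  dam_df$within_treatment <- families$maternal_treatment
  dam_df$sex <- "female"
  latent <- families$maternal_mass10_mg
  miss <- is.na(latent)
  if (any(miss)) {
    latent[miss] <- rnorm(sum(miss),
                          .linpred(dam_df[miss, , drop = FALSE], pm10),
                          pm10[["sigma"]])
  }

  base <- n %/% nf
  counts <- rep(base, nf)
  rem <- n - base * nf
  if (rem > 0L) counts[sample.int(nf, rem)] <- base + 1L
  fam_idx <- sample(rep(seq_len(nf), counts))

  df <- .empty_cohort(n)
  df$id <- sprintf("G2_%04d", seq_len(n))
  df$generation <- 2L
  df$family_id <- families$family_id[fam_idx]
  df$mother_id <- families$dam_id[fam_idx]
  df$maternal_treatment <- families$maternal_treatment[fam_idx]
  df$maternal_mass10_mg <- latent[fam_idx]  # latent truth while simulating
  n_ins <- round(n * design$treatment_allocation)
  trt <- rep("control", n)
  trt[sample.int(n, n_ins)] <- "insecticide"
  df$within_treatment <- trt

  fates <- .draw_fates(df, params, blocks[1:4])
  for (nm in names(fates)) df[[nm]] <- fates[[nm]]

  emerged <- which(df$died_pupal %in% FALSE)
  if (length(emerged)) {
    df$sex[emerged] <- ifelse(runif(length(emerged)) < 0.5, "male", "female")
    sub <- df[emerged, , drop = FALSE]
    pdt <- params[["g2_devtime"]]
    df$dev_time_days[emerged] <-
      exp(rnorm(length(emerged), .linpred(sub, pdt), pdt[["sigma"]]))
    pm0 <- params[["g2_mass_emergence"]]
    df$mass_emergence_mg[emerged] <-
      rnorm(length(emerged), .linpred(sub, pm0), pm0[["sigma"]])
  }
  alive14 <- which(df$died_adult %in% FALSE)
  if (length(alive14)) {
    sub <- df[alive14, , drop = FALSE]
    pm7 <- params[["g2_mass_day7"]]
    df$mass_day7_mg[alive14] <-
      rnorm(length(alive14), .linpred(sub, pm7), pm7[["sigma"]])
    pm14 <- params[["g2_mass_day14"]]
    df$mass_day14_mg[alive14] <-
      rnorm(length(alive14), .linpred(sub, pm14), pm14[["sigma"]])

    # composition fractions: lipid and dry-mass fractions define the weight
    # arithmetic (lean = dry - lipid * fresh); water is modelled directly
    # because the published formula for it is not a consistent identity.
    draw_frac <- function(block) {
      pb <- params[[block]]
      mu <- plogis(.linpred(sub, pb))
      rbeta(length(alive14), mu * pb[["phi"]], (1 - mu) * pb[["phi"]])
    }
    dryf <- draw_frac("g2_drymass")
    lipf <- draw_frac("g2_lipid")
    for (it in seq_len(100)) {
      bad <- lipf >= dryf
      if (!any(bad)) break
      pb <- params[["g2_lipid"]]
      mu <- plogis(.linpred(sub[bad, , drop = FALSE], pb))
      lipf[bad] <- rbeta(sum(bad), mu * pb[["phi"]], (1 - mu) * pb[["phi"]])
    }
    lipf <- pmin(lipf, dryf * 0.999)  # guard for pathological parameters
    watf <- draw_frac("g2_water")
    fresh <- df$mass_day14_mg[alive14]
    df$fresh_mg[alive14] <- fresh
    df$dry_mg[alive14] <- dryf * fresh
    df$lean_mg[alive14] <- (dryf - lipf) * fresh
    df$lipid_frac[alive14] <- lipf
    df$water_frac[alive14] <- watf
    df$drymass_frac[alive14] <- dryf
  }

  # swap the latent covariate back to its observable value
  obs <- families$maternal_mass10_mg[fam_idx]
  df$maternal_mass10_mg <- obs
  apply_missingness(df)
}

#' Apply stage-conditional missingness to a cohort
#'
#' Blanks every field whose definition or measurement age postdates an
#' individual's death: later stage fates are undefined after death, sex is
#' known only at adult emergence, development time and emergence mass
#' require emergence, and the day-7/10/14 masses and composition traits
#' require surviving the adult stage. For gen-2 rows whose dam appears in
#' the same table, the maternal-mass covariate is blanked when the dam's own
#' 10-day mass is missing. Idempotent.
#'
#' @param individuals a cohort data frame.
#' @return The cohort with missingness applied.
#' @export
apply_missingness <- function(individuals) {
  df <- individuals
  dead24 <- df$died_24h %in% TRUE
  deadlarv <- df$died_larval %in% TRUE
  deadpup <- df$died_pupal %in% TRUE
  deadad <- df$died_adult %in% TRUE
  df$died_larval[dead24] <- NA
  df$died_pupal[dead24 | deadlarv] <- NA
  not_emerged <- dead24 | deadlarv | deadpup
  df$died_adult[not_emerged] <- NA
  df$sex[not_emerged] <- NA_character_
  df$dev_time_days[not_emerged] <- NA_real_
  df$mass_emergence_mg[not_emerged] <- NA_real_
  gone <- not_emerged | deadad
  for (col in c("mass_day7_mg", "mass_day10_mg", "mass_day14_mg", "fresh_mg",
                "dry_mg", "lean_mg", "lipid_frac", "water_frac",
                "drymass_frac")) {
    df[[col]][gone] <- NA_real_
  }
  dam_row <- match(df$mother_id, df$id)
  known_dam <- !is.na(dam_row)
  if (any(known_dam)) {
    blank <- known_dam & is.na(df$mass_day10_mg[dam_row])
    df$maternal_mass10_mg[blank] <- NA_real_
  }
  df
}

#' Simulate a complete two-generation cohort
#'
#' Runs [simulate_gen1()], [mate_design()] and [simulate_gen2()] under the
#' design's seed and returns the combined cohort; the family records are
#' attached as attribute `"families"`.
#'
#' @inheritParams simulate_gen1
#' @param seed optional seed overriding `design$seed`.
#' @return Cohort data frame of `n_gen1_larvae + n_gen2_larvae` rows.
#' @examples
#' design <- cohort_design(n_gen1_larvae = 60, n_sires = 2,
#'                         n_gen2_larvae = 80, seed = 7)
#' cohort <- simulate_cohort(design, default_params())
#' table(cohort$generation)
#' @export
simulate_cohort <- function(design, params, seed = NULL, ...) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(if (is.null(seed)) design$seed else as.integer(seed))
  g1 <- simulate_gen1(design, params, ...)
  if (design$n_gen2_larvae > 0L) {
    fam <- mate_design(g1, design)
    g2 <- simulate_gen2(fam, design, params)
    out <- rbind(g1, g2)
  } else {
    fam <- data.frame(family_id = character(), sire_id = character(),
                      dam_id = character(), maternal_treatment = character(),
                      maternal_mass10_mg = numeric(),
                      stringsAsFactors = FALSE)
    out <- g1
  }
  rownames(out) <- NULL
  attr(out, "families") <- fam
  out
}
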