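# Posterior-predictive checking: replicate cohorts simulated from retained
# posterior draws with observed covariates held fixed, compared to the data
# through stage-wise death counts and trait means.

#' Rebuild a parameter set from one posterior draw
#'
#' @param fit a `posterior_draws` object.
#' @param i draw index (row of `fit$draws`).
#' @return Named list of per-block coefficient vectors (a reduced model
#'   yields reduced vectors).
#' @export
params_from_draw <- function(fit, i) {
  stopifnot(inherits(fit, "posterior_draws"), i >= 1, i <= nrow(fit$draws))
  idx <- fit$param_index
  draw <- fit$draws[i, ]
  blocks <- split(seq_len(nrow(idx)), idx$block)
  out <- lapply(blocks, function(rows) {
    setNames(as.numeric(draw[rows]), idx$term[rows])
  })
  out[unique(idx$block)]
}

# Outcome-free copy of a cohort: covariates kept, responses blanked.
.strip_outcomes <- function(cohort) {
  df <- cohort
  for (col in c("died_24h", "died_larval", "died_pupal", "died_adult")) {
    df[[col]] <- NA
  }
  df$sex <- NA_character_
  for (col in c("dev_time_days", "mass_emergence_mg", "mass_day7_mg",
                "mass_day10_mg", "mass_day14_mg", "fresh_mg", "dry_mg",
                "lean_mg", "lipid_frac", "water_frac", "drymass_frac")) {
    df[[col]] <- NA_real_
  }
  df
}

# Simulate all outcomes of an existing cohort under `params`, holding
# treatments, family structure, larval masses and maternal masses fixed.
# `imputed` supplies latent masses (named by dam id) for dams whose 10-day
# mass is missing.
.resimulate <- function(cohort, params, imputed = NULL) {
  df <- .strip_outcomes(cohort)
  g1 <- which(df$generation == 1L)
  g2 <- which(df$generation == 2L)

  draw_continuous <- function(rows, block) {
    pb <- params[[block]]
    rnorm(length(rows), .linpred(df[rows, , drop = FALSE], pb),
          pb[["sigma"]])
  }

  if (length(g1)) {
    sub <- df[g1, , drop = FALSE]
    fates <- .draw_fates(sub, params, c("g1_surv_24h", "g1_surv_larval",
                                        "g1_surv_pupal", "g1_surv_adult"))
    for (nm in names(fates)) df[[nm]][g1] <- fates[[nm]]
    emerged <- g1[df$died_pupal[g1] %in% FALSE]
    if (length(emerged)) {
      df$sex[emerged] <- ifelse(runif(length(emerged)) < 0.5, "male",
                                "female")
      pdt <- params[["g1_devtime"]]
      df$dev_time_days[emerged] <-
        exp(rnorm(length(emerged),
                  .linpred(df[emerged, , drop = FALSE], pdt),
                  pdt[["sigma"]]))
      df$mass_emergence_mg[emerged] <- draw_continuous(emerged,
                                                       "g1_mass_emergence")
    }
    alive10 <- g1[df$died_adult[g1] %in% FALSE]
    if (length(alive10)) {
      df$mass_day10_mg[alive10] <- draw_continuous(alive10, "g1_mass_day10")
    }
  }

  if (length(g2)) {
    # latent maternal-mass covariate: observed value, else supplied
    # imputation, else a fresh draw from the gen-1 mass model
    mm <- df$maternal_mass10_mg[g2]
    miss <- is.na(mm)
    if (any(miss)) {
      dams <- df$mother_id[g2][miss]
      vals <- if (!is.null(imputed)) unname(imputed[dams]) else NA_real_
      need <- is.na(vals)
      if (any(need)) {
        pm10 <- params[["g1_mass_day10"]]
        dam_df <- .empty_cohort(sum(need))
        dam_df$within_treatment <- df$maternal_treatment[g2][miss][need]
        dam_df$sex <- "female"
        vals[need] <- rnorm(sum(need), .linpred(dam_df, pm10),
                            pm10[["sigma"]])
      }
      mm[miss] <- vals
    }
    df$maternal_mass10_mg[g2] <- mm
    sub <- df[g2, , drop = FALSE]
    fates <- .draw_fates(sub, params, c("g2_surv_24h", "g2_surv_larval",
                                        "g2_surv_pupal", "g2_surv_adult"))
    for (nm in names(fates)) df[[nm]][g2] <- fates[[nm]]
    emerged <- g2[df$died_pupal[g2] %in% FALSE]
    if (length(emerged)) {
      df$sex[emerged] <- ifelse(runif(length(emerged)) < 0.5, "male",
                                "female")
      pdt <- params[["g2_devtime"]]
      df$dev_time_days[emerged] <-
        exp(rnorm(length(emerged),
                  .linpred(df[emerged, , drop = FALSE], pdt),
                  pdt[["sigma"]]))
      df$mass_emergence_mg[emerged] <- draw_continuous(emerged,
                                                       "g2_mass_emergence")
    }
    alive14 <- g2[df$died_adult[g2] %in% FALSE]
    if (length(alive14)) {
      df$mass_day7_mg[alive14] <- draw_continuous(alive14, "g2_mass_day7")
      df$mass_day14_mg[alive14] <- draw_continuous(alive14, "g2_mass_day14")
      sub14 <- df[alive14, , drop = FALSE]
      draw_frac <- function(block) {
        pb <- params[[block]]
        mu <- plogis(.linpred(sub14, pb))
        rbeta(length(alive14), mu * pb[["phi"]], (1 - mu) * pb[["phi"]])
      }
      dryf <- draw_frac("g2_drymass")
      lipf <- pmin(draw_frac("g2_lipid"), dryf * 0.999)
      fresh <- df$mass_day14_mg[alive14]
      df$fresh_mg[alive14] <- fresh
      df$dry_mg[alive14] <- dryf * fresh
      df$lean_mg[alive14] <- (dryf - lipf) * fresh
      df$lipid_frac[alive14] <- lipf
      df$water_frac[alive14] <- draw_frac("g2_water")
      df$drymass_frac[alive14] <- dryf
    }
  }
  df <- apply_missingness(df)
  # the maternal-mass covariate is held fixed at its observed pattern
  df$maternal_mass10_mg <- cohort$maternal_mass10_mg
  df
}

# Discrepancy statistics: stage-wise death counts and trait means.
.cohort_stats <- function(cohort) {
  out <- numeric(0)
  for (g in 1:2) {
    sub <- cohort[cohort$generation == g, , drop = FALSE]
    if (!nrow(sub)) next
    for (st in c("24h", "larval", "pupal", "adult")) {
      col <- paste0("died_", sub("24h", "24h", st))
      out[sprintf("g%d_deaths_%s", g, st)] <- sum(sub[[col]] %in% TRUE)
    }
    out[sprintf("g%d_mean_devtime", g)] <-
      mean(sub$dev_time_days, na.rm = TRUE)
    out[sprintf("g%d_mean_mass_emergence", g)] <-
      mean(sub$mass_emergence_mg, na.rm = TRUE)
  }
  g2 <- cohort[cohort$generation == 2L, , drop = FALSE]
  if (nrow(g2)) {
    out["g2_mean_mass_day14"] <- mean(g2$mass_day14_mg, na.rm = TRUE)
    out["g2_mean_lipid"] <- mean(g2$lipid_frac, na.rm = TRUE)
  }
  out
}

#' Posterior-predictive replicate cohorts and discrepancy table
#'
#' For each replicate one retained posterior draw is selected and the whole
#' cohort is re-simulated from it with observed covariates (treatments,
#' family structure, larval and maternal masses) held fixed; missing
#' maternal masses use the same draw's imputed values. The discrepancy
#' table compares stage-wise death counts and trait means between the
#' observed cohort and the replicate distribution (central 95% by normal
#' approximation, `mean +/- 1.96 sd`).
#'
#' @param fit a `posterior_draws` object from a full-model fit.
#' @param cohort the observed cohort the model was fitted to.
#' @param n_rep number of replicate data sets (default 10).
#' @param seed optional seed for replicate selection and simulation.
#' @return List of class `ppc_result`: `replicates` (list of cohorts),
#'   `discrepancy` (data frame: statistic, observed, rep_mean, rep_sd,
#'   rep_lo, rep_hi, inside) and `draw_index`.
#' @export
posterior_predictive <- function(fit, cohort, n_rep = 10L, seed = NULL) {
  stopifnot(inherits(fit, "posterior_draws"), n_rep >= 1L)
  needed <- c("g1_surv_24h", "g1_surv_larval", "g1_surv_pupal",
              "g1_surv_adult", "g1_devtime", "g1_mass_emergence",
              "g1_mass_day10")
  if (any(cohort$generation == 2L)) {
    needed <- c(needed, "g2_surv_24h", "g2_surv_larval", "g2_surv_pupal",
                "g2_surv_adult", "g2_devtime", "g2_mass_emergence",
                "g2_mass_day7", "g2_mass_day14", "g2_lipid", "g2_water",
                "g2_drymass")
  }
  have <- unique(fit$param_index$block)
  missing_blocks <- setdiff(needed, have)
  if (length(missing_blocks)) {
    stop("posterior predictive simulation needs submodel(s): ",
         paste(missing_blocks, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_draws <- nrow(fit$draws)
  draw_index <- sample.int(n_draws, n_rep, replace = n_rep > n_draws)
  reps <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    params <- params_from_draw(fit, draw_index[r])
    imputed <- if (length(fit$imputed_dams)) {
      setNames(fit$imputed[draw_index[r], ], fit$imputed_dams)
    } else {
      NULL
    }
    reps[[r]] <- .resimulate(cohort, params, imputed)
  }
  obs <- .cohort_stats(cohort)
  rep_stats <- t(vapply(reps, .cohort_stats, obs))
  disc <- data.frame(
    statistic = names(obs), observed = unname(obs),
    rep_mean = colMeans(rep_stats), rep_sd = apply(rep_stats, 2, sd),
    stringsAsFactors = FALSE, row.names = NULL)
  disc$rep_lo <- disc$rep_mean - 1.96 * disc$rep_sd
  disc$rep_hi <- disc$rep_mean + 1.96 * disc$rep_sd
  disc$inside <- disc$observed >= disc$rep_lo & disc$observed <= disc$rep_hi
  structure(list(replicates = reps, discrepancy = disc,
                 draw_index = draw_index),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat("<ppc_result>", length(x$replicates), "replicate cohorts\n")
  print(x$discrepancy, digits = 4)
  invisible(x)
}
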