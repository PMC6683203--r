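# End-to-end pipeline: simulate, fit (full + reduced), posterior-predictive
# check, and the parameter-recovery experiment. Every run can write a
# manifest sufficient to reproduce its deterministic stages.

.write_manifest <- function(out_dir, name, payload) {
  path <- file.path(out_dir, paste0(name, "_manifest.json"))
  payload$package_version <- as.character(utils::packageVersion("sublethal"))
  payload$r_version <- R.version.string
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.log_info <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
}

#' Simulate a cohort and write it with its design sidecar
#'
#' Deterministic under a fixed seed (repeated runs produce byte-identical
#' files). Logs arm sizes and stage-wise death counts.
#'
#' @param design a [cohort_design()].
#' @param params true generator parameters (default: published posterior
#'   means with the package's default scales).
#' @param out_dir output directory (created if needed).
#' @param seed optional override of `design$seed`.
#' @param verbose log progress via `message()`.
#' @return Invisibly, list with `cohort`, `families` and the file paths.
#' @export
run_simulate <- function(design = cohort_design(), params = default_params(),
                         out_dir, seed = NULL, verbose = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(seed)) design$seed <- as.integer(seed)
  cohort <- simulate_cohort(design, params)
  cohort_path <- file.path(out_dir, "cohort.csv")
  sidecar_path <- file.path(out_dir, "design.json")
  write_cohort(cohort, cohort_path)
  write_design_sidecar(design, params, sidecar_path)
  for (g in unique(cohort$generation)) {
    sub <- cohort[cohort$generation == g, , drop = FALSE]
    .log_info(verbose, "gen-%d: %d individuals (%d insecticide), deaths %s",
              g, nrow(sub), sum(sub$within_treatment == "insecticide"),
              paste(sprintf("%s=%d", c("24h", "larval", "pupal", "adult"),
                            c(sum(sub$died_24h %in% TRUE),
                              sum(sub$died_larval %in% TRUE),
                              sum(sub$died_pupal %in% TRUE),
                              sum(sub$died_adult %in% TRUE))),
                    collapse = " "))
  }
  .write_manifest(out_dir, "simulate",
                  list(design = unclass(design),
                       cohort_md5 = unname(tools::md5sum(cohort_path))))
  invisible(list(cohort = cohort, families = attr(cohort, "families"),
                 cohort_path = cohort_path, sidecar_path = sidecar_path))
}

#' Fit the joint model: full, then reduced
#'
#' Fits the full model, applies the model-reduction rule (non-treatment
#' interactions whose 95% interval contains 0 are dropped; treatment
#' interactions are always kept), refits the reduced model, and returns
#' both fits with their summary tables.
#'
#' @param cohort a cohort data frame or a path to a cohort CSV.
#' @param specs full-model submodel specs.
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @param out_dir optional output directory for draws and summary CSVs.
#' @param reduce apply the model-reduction step and refit.
#' @param verbose log progress.
#' @return List with `fit_full`, `summary_full`, `specs_reduced` and (when
#'   `reduce` and a term was dropped) `fit_reduced`, `summary_reduced`.
#' @export
run_fit <- function(cohort, specs = default_submodels(),
                    priors = prior_spec(), config = mcmc_config(),
                    out_dir = NULL, reduce = TRUE, verbose = TRUE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  validate_cohort(cohort)
  .log_info(verbose, "fitting full model: %d submodels, %d rows, seed %d",
            length(specs), nrow(cohort), config$seed)
  fit_full <- sample_posterior(cohort, specs, priors, config)
  summary_full <- summarize_draws(fit_full)
  out <- list(fit_full = fit_full, summary_full = summary_full,
              specs_reduced = specs)
  if (reduce) {
    reduced <- reduce_model(summary_full, specs)
    dropped <- sum(vapply(specs, function(s) length(s$covariates),
                          integer(1))) -
      sum(vapply(reduced, function(s) length(s$covariates), integer(1)))
    out$specs_reduced <- reduced
    if (dropped > 0L) {
      .log_info(verbose, "reduction dropped %d interaction term(s); refitting",
                dropped)
      out$fit_reduced <- sample_posterior(cohort, reduced, priors, config)
      out$summary_reduced <- summarize_draws(out$fit_reduced)
    } else {
      .log_info(verbose, "reduction dropped no terms; full fit is final")
      out$fit_reduced <- fit_full
      out$summary_reduced <- summary_full
    }
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    draws_path <- file.path(out_dir, "draws.csv")
    write.csv(as.data.frame(fit_full$draws), draws_path, row.names = FALSE)
    write_summary_csv(summary_full, file.path(out_dir, "summary_full.csv"))
    if (!is.null(out$summary_reduced)) {
      write_summary_csv(out$summary_reduced,
                        file.path(out_dir, "summary_reduced.csv"))
    }
    tab <- render_table1(summary_full)
    write_summary_csv(tab, file.path(out_dir, "coefficient_table.csv"))
    .write_manifest(out_dir, "fit", list(
      seed = config$seed, config = unclass(config),
      accept = lapply(fit_full$accept, as.list)))
  }
  out
}

#' Posterior-predictive check of a fitted model
#'
#' @param fit a `posterior_draws` object.
#' @param cohort the observed cohort.
#' @param n_rep replicate count (default 10).
#' @param seed seed for replicate selection/simulation.
#' @param out_dir optional directory for the discrepancy CSV.
#' @return A `ppc_result` (see [posterior_predictive()]).
#' @export
run_ppc <- function(fit, cohort, n_rep = 10L, seed = 1L, out_dir = NULL) {
  ppc <- posterior_predictive(fit, cohort, n_rep = n_rep, seed = seed)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_summary_csv(ppc$discrepancy, file.path(out_dir, "ppc.csv"))
  }
  ppc
}

#' Parameter-recovery experiment
#'
#' Simulates `R` cohorts from known truth, fits each, and scores the
#' estimates: per-parameter mean bias, RMSE, the mean posterior SD and the
#' coverage of the 95% equal-tail intervals. Cohorts whose random mortality
#' leaves too few gen-1 adults for the mating design are re-simulated under
#' the next derived seed (the count is reported).
#'
#' @param truth true [param_set()] (default: published posterior means).
#' @param design a [cohort_design()].
#' @param specs,priors,config passed to [sample_posterior()].
#' @param R number of replicate cohorts.
#' @param seed base seed; replicate r simulates with `seed + r` offsets.
#' @param out_dir optional directory for the report CSV.
#' @param verbose log progress.
#' @return List of class `recovery_report`: `report` (data frame with one
#'   row per parameter: true, mean_est, bias, rmse, mean_sd, coverage,
#'   star_rate), `R`, `n_resimulated`.
#' @export
run_recover <- function(truth = default_params(), design = cohort_design(),
                        specs = default_submodels(), priors = prior_spec(),
                        config = mcmc_config(), R = 50L, seed = 1L,
                        out_dir = NULL, verbose = TRUE) {
  truth_flat <- flatten_params(param_set(truth))
  est <- list()
  n_resim <- 0L
  sim_seed <- as.integer(seed)
  for (r in seq_len(R)) {
    cohort <- NULL
    for (attempt in seq_len(25L)) {
      sim_seed <- sim_seed + 1L
      cohort <- tryCatch(simulate_cohort(design, truth, seed = sim_seed),
                         sublethal_shortfall_error = function(e) NULL)
      if (!is.null(cohort)) break
      n_resim <- n_resim + 1L
    }
    if (is.null(cohort)) {
      stop("could not simulate a cohort satisfying the mating design in 25 ",
           "attempts", call. = FALSE)
    }
    cfg <- config
    cfg$seed <- as.integer(config$seed + r)
    fit <- sample_posterior(cohort, specs, priors, cfg)
    est[[r]] <- summarize_draws(fit)
    .log_info(verbose, "recovery replicate %d/%d done", r, R)
  }
  params <- est[[1L]]$parameter
  rows <- lapply(params, function(p) {
    vals <- vapply(est, function(s) {
      i <- match(p, s$parameter)
      c(s$mean[i], s$sd[i], s$lo[i], s$hi[i])
    }, numeric(4))
    truev <- if (p %in% names(truth_flat)) truth_flat[[p]] else NA_real_
    covered <- if (is.na(truev)) NA_real_ else {
      mean(vals[3, ] <= truev & truev <= vals[4, ])
    }
    data.frame(
      parameter = p, true = truev, mean_est = mean(vals[1, ]),
      bias = if (is.na(truev)) NA_real_ else mean(vals[1, ]) - truev,
      rmse = if (is.na(truev)) NA_real_ else {
        sqrt(mean((vals[1, ] - truev)^2))
      },
      mean_sd = mean(vals[2, ]), coverage = covered,
      star_rate = mean(vals[3, ] > 0 | vals[4, ] < 0),
      stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_summary_csv(report, file.path(out_dir, "recovery.csv"))
    .write_manifest(out_dir, "recover", list(
      R = R, seed = seed, config = unclass(config),
      design = unclass(design), n_resimulated = n_resim))
  }
  structure(list(report = report, R = R, n_resimulated = n_resim),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$R, "replicates")
  if (x$n_resimulated > 0L) {
    cat(" (", x$n_resimulated, " cohort(s) re-simulated)", sep = "")
  }
  cat("\n")
  surv <- x$report[grepl("surv", x$report$parameter), , drop = FALSE]
  cat("survival-block coverage range:",
      sprintf("%.2f-%.2f", min(surv$coverage), max(surv$coverage)), "\n")
  invisible(x)
}
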