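# R-side interface to the blockwise adaptive Metropolis sampler: model
# preparation (design matrices, priors, initialization, imputation
# bookkeeping), the sampler driver, and convergence diagnostics.

#' MCMC schedule configuration
#'
#' The `"study"` preset reproduces the original analysis schedule
#' (2,000,000 burn-in iterations, 5,000,000 further iterations keeping
#' every 500th draw for a posterior sample of 10,000 from a single chain).
#' The `"desk"` preset (default) is the scaled-down schedule used for
#' testing and recovery experiments: 20,000 burn-in, 2,000 retained draws
#' at thinning 10.
#'
#' @param preset `"desk"` or `"study"`.
#' @param burn_in,keep,thin overrides of the preset schedule.
#' @param n_chains number of independent chains (the original analysis used
#'   one; a second chain enables a split-chain sanity diagnostic).
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param adapt adapt proposals during burn-in (frozen afterwards).
#' @param target_accept blockwise acceptance-rate target of the adaptive
#'   scaling (within the usual 0.23-0.44 random-walk range).
#' @param init `"auto"` (data-based least-squares/logit starting values) or
#'   `"prior"` (prior means with jitter).
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(preset = c("desk", "study"), burn_in = NULL,
                        keep = NULL, thin = NULL, n_chains = 1L, seed = 1L,
                        adapt = TRUE, target_accept = 0.3,
                        init = c("auto", "prior")) {
  preset <- match.arg(preset)
  init <- match.arg(init)
  base <- switch(preset,
                 desk = list(burn_in = 20000L, keep = 2000L, thin = 10L),
                 study = list(burn_in = 2000000L, keep = 10000L,
                              thin = 500L))
  cfg <- list(
    burn_in = as.integer(if (is.null(burn_in)) base$burn_in else burn_in),
    keep = as.integer(if (is.null(keep)) base$keep else keep),
    thin = as.integer(if (is.null(thin)) base$thin else thin),
    n_chains = as.integer(n_chains), seed = as.integer(seed),
    adapt = isTRUE(adapt), target_accept = target_accept, init = init)
  stopifnot(cfg$burn_in >= 0L, cfg$keep >= 1L, cfg$thin >= 1L,
            cfg$n_chains >= 1L, target_accept > 0, target_accept < 1)
  structure(cfg, class = "mcmc_config")
}

.family_code <- function(family) {
  switch(family, "mortality-logit" = 0L, normal = 1L, lognormal = 1L,
         "beta-logit" = 2L)
}

# Data-based starting values (least squares / logit of the outcome mean),
# robust to empty or rank-deficient designs.
.init_block <- function(bd, priors, pr, init_mode) {
  spec <- bd$spec
  k <- ncol(bd$X)
  fam <- spec$family
  z <- if (fam == "lognormal") log(bd$y) else bd$y
  coef <- rep(0, k)
  scale <- NA_real_
  if (init_mode == "prior") {
    coef <- pr$mean + 0.1 * seq(-1, 1, length.out = k)
    if (fam %in% c("normal", "lognormal")) {
      scale <- priors$sigma_scale * sqrt(2 / pi)
    } else if (fam == "beta-logit") {
      scale <- max(priors$phi_shape / priors$phi_rate, 1)
    }
  } else if (fam %in% c("normal", "lognormal")) {
    if (length(z) > k) {
      fit <- lm.fit(bd$X, z)
      coef <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      scale <- sd(fit$residuals)
    } else if (length(z) > 0L) {
      coef[1L] <- mean(z)
      scale <- if (length(z) > 1L) sd(z) else 1
    }
    if (!is.finite(scale) || is.na(scale) || scale < 1e-6) scale <- 1
  } else if (fam == "beta-logit") {
    if (length(z) > 0L) coef[1L] <- qlogis(mean(z))
    scale <- 20
  } else if (length(z) > 0L) {
    p <- mean(bd$y)
    coef[1L] <- qlogis(min(max(p, 1 / (length(z) + 2)),
                           1 - 1 / (length(z) + 2)))
  }
  list(coef = coef, scale = scale)
}

# Scale-aware initial proposal SDs; the Haario adaptation refines them.
.init_prop_sd <- function(bd, init, pr) {
  n <- nrow(bd$X)
  k <- ncol(bd$X)
  has_scale <- bd$spec$family != "mortality-logit"
  if (n == 0L) {
    psd <- pr$sd
    if (has_scale) psd <- c(psd, 1)
    return(pmin(psd, 50))
  }
  rms <- sqrt(colMeans(bd$X^2))
  rms[rms < 1e-8] <- 1
  base <- switch(bd$spec$family,
                 "mortality-logit" = 2.5,
                 "beta-logit" = 0.5,
                 init$scale)
  psd <- pmin(pmax(base / (rms * sqrt(n)), 1e-6), pr$sd)
  if (has_scale) psd <- c(psd, max(1 / sqrt(2 * n), 0.02))
  psd
}

# Assemble sampler inputs: per-block design/prior/init lists plus the
# imputation bookkeeping for missing maternal masses.
.prepare_model <- function(cohort, specs, priors, init_mode = "auto") {
  stopifnot(inherits(priors, "prior_spec"))
  if (is.null(names(specs))) names(specs) <- vapply(specs, `[[`, "", "name")
  designs <- lapply(specs, function(s) build_design(cohort, s))

  # starting value for imputed maternal masses (refined by the sampler)
  mass_idx0 <- match("g1_mass_day10", names(specs))
  imp_start <- if (!is.na(mass_idx0) && length(designs[[mass_idx0]]$y)) {
    mean(designs[[mass_idx0]]$y)
  } else {
    160
  }

  blocks <- vector("list", length(specs))
  param_index <- list()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    bd <- designs[[i]]
    pr <- .coef_priors(spec, priors)
    fam <- spec$family
    if (any(bd$missing_maternal)) {
      bd$X[bd$missing_maternal, "maternal_mass"] <- imp_start
    }
    init <- .init_block(bd, priors, pr, init_mode)
    scale_prior <- switch(fam, "mortality-logit" = 0L, "beta-logit" = 2L, 1L)
    sp <- switch(fam,
                 "mortality-logit" = c(0, 0),
                 "beta-logit" = c(priors$phi_shape, priors$phi_rate),
                 c(priors$sigma_scale, 0))
    y <- if (fam == "lognormal") log(bd$y) else bd$y
    X <- bd$X
    blocks[[i]] <- list(
      name = spec$name, family = .family_code(fam), X = X, y = y,
      prior_mean = pr$mean, prior_sd = pr$sd, scale_prior = scale_prior,
      scale_par1 = sp[1L], scale_par2 = sp[2L], init_coef = init$coef,
      init_scale = init$scale,
      init_prop_sd = .init_prop_sd(bd, init, pr))
    scale_nm <- if (fam == "mortality-logit") character() else {
      if (fam == "beta-logit") "phi" else "sigma"
    }
    param_index[[i]] <- data.frame(
      block = spec$name, term = c(spec$covariates, scale_nm),
      stringsAsFactors = FALSE)
  }
  param_index <- do.call(rbind, param_index)
  param_index$parameter <- paste(param_index$block, param_index$term,
                                 sep = ".")

  # imputation bookkeeping: one entry per dam with a missing 10-day mass
  flagged <- lapply(designs, function(bd) bd$rows[bd$missing_maternal])
  dam_ids <- unique(cohort$mother_id[unlist(flagged)])
  entries <- list()
  imp_init <- numeric(0)
  prior_block <- -1L
  if (length(dam_ids)) {
    mass_idx <- match("g1_mass_day10", names(specs))
    if (is.na(mass_idx)) {
      stop("missing maternal-mass covariates require the 'g1_mass_day10' ",
           "submodel for imputation", call. = FALSE)
    }
    prior_block <- mass_idx - 1L
    mass_spec <- specs[[mass_idx]]
    dam_rows <- match(dam_ids, cohort$id)
    if (anyNA(dam_rows)) {
      stop("dam(s) ", paste(dam_ids[is.na(dam_rows)], collapse = ", "),
           " not present in the cohort; cannot impute their mass",
           call. = FALSE)
    }
    imp_init <- rep(imp_start, length(dam_ids))
    for (j in seq_along(dam_ids)) {
      dam <- cohort[dam_rows[j], , drop = FALSE]
      prior_x <- vapply(mass_spec$covariates, function(tm) {
        .term_value(tm, dam)
      }, numeric(1))
      # latent row of the dam in the mass model (updated by the sampler)
      blocks[[mass_idx]]$X <- rbind(blocks[[mass_idx]]$X,
                                    matrix(prior_x, nrow = 1))
      blocks[[mass_idx]]$y <- c(blocks[[mass_idx]]$y, imp_init[j])
      pseudo_row <- length(blocks[[mass_idx]]$y) - 1L
      targets <- list()
      for (i in seq_along(specs)) {
        spec <- specs[[i]]
        if (!"maternal_mass" %in% spec$covariates) next
        local_rows <- which(cohort$mother_id[designs[[i]]$rows] == dam_ids[j] &
                              designs[[i]]$missing_maternal)
        if (!length(local_rows)) next
        col <- match("maternal_mass", spec$covariates) - 1L
        blocks[[i]]$X[local_rows, col + 1L] <- imp_init[j]
        targets <- c(targets, list(list(block = i - 1L, col = col,
                                        rows = local_rows - 1L)))
      }
      entries[[j]] <- list(prior_x = prior_x, pseudo_row = pseudo_row,
                           targets = targets)
    }
  }

  structure(list(blocks = blocks, param_index = param_index,
                 impute = list(init = imp_init, entries = entries),
                 imputed_dams = dam_ids, prior_block = prior_block,
                 specs = specs, priors = priors, designs = designs),
            class = "mcmc_model")
}

#' Prepare a joint model for sampling
#'
#' Builds every submodel's design, resolves priors and starting values, and
#' enumerates the missing maternal-mass entries to impute. Mostly useful
#' directly for [impute_missing()]; [sample_posterior()] calls it
#' internally.
#'
#' @param cohort a cohort data frame.
#' @param specs named list of [submodel_spec()]s (default: full model).
#' @param priors a [prior_spec()].
#' @param init `"auto"` or `"prior"` starting values.
#' @return An object of class `mcmc_model`.
#' @export
mcmc_model <- function(cohort, specs = default_submodels(),
                       priors = prior_spec(), init = "auto") {
  validate_cohort(cohort)
  .prepare_model(cohort, specs, priors, init_mode = init)
}

# Pre-flight: every submodel must have a finite log posterior at the
# starting state; report the offending submodel and cohort row otherwise.
.check_finite_init <- function(model, cohort) {
  for (i in seq_along(model$blocks)) {
    bl <- model$blocks[[i]]
    spec <- model$specs[[i]]
    eta <- drop(bl$X %*% bl$init_coef)
    rl <- switch(spec$family,
      "mortality-logit" = bl$y * plogis(eta, log.p = TRUE) +
        (1 - bl$y) * plogis(-eta, log.p = TRUE),
      "beta-logit" = {
        mu <- plogis(eta)
        dbeta(bl$y, mu * bl$init_scale, (1 - mu) * bl$init_scale, log = TRUE)
      },
      dnorm(bl$y, eta, bl$init_scale, log = TRUE))
    if (length(rl) && any(!is.finite(rl))) {
      bad <- which(!is.finite(rl))[1L]
      row <- if (bad <= length(model$designs[[i]]$rows)) {
        model$designs[[i]]$rows[bad]
      } else {
        NA_integer_
      }
      stop("non-finite log posterior at initialization in submodel '",
           spec$name, "' (cohort row ", row, ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Sample the joint posterior
#'
#' Runs the blockwise adaptive random-walk Metropolis sampler over all
#' submodels, imputing missing maternal 10-day masses within the chain:
#' each missing mass is redrawn every sweep from an independence proposal
#' given the current gen-1 mass-model parameters, accepted against the
#' likelihood of the offspring rows it enters. Proposals adapt only during
#' burn-in. A fixed seed, configuration and data set give bit-identical
#' draws.
#'
#' @param cohort a cohort data frame (validated against the schema first).
#' @param specs named list of [submodel_spec()]s; defaults to the full
#'   joint model.
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @return An object of class `posterior_draws`: list with `draws` (matrix
#'   of retained samples, one named column per parameter, scale parameters
#'   on their natural scale), `imputed` (retained draws of each imputed
#'   maternal mass, columns named by dam id), `chain`, `accept` (per-block
#'   sampling-phase acceptance rates), `impute_accept`, `param_index`,
#'   `config`, `specs` and `priors`.
#' @examples
#' \donttest{
#' design <- cohort_design(n_gen1_larvae = 80, n_sires = 2,
#'                         n_gen2_larvae = 120, seed = 3)
#' cohort <- simulate_cohort(design, default_params())
#' fit <- sample_posterior(cohort,
#'                         config = mcmc_config(burn_in = 2000, keep = 500,
#'                                              thin = 2, seed = 1))
#' head(summarize_draws(fit))
#' }
#' @export
sample_posterior <- function(cohort, specs = default_submodels(),
                             priors = prior_spec(),
                             config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"))
  validate_cohort(cohort)
  model <- .prepare_model(cohort, specs, priors, init_mode = config$init)
  .check_finite_init(model, cohort)

  run_cfg <- list(burn_in = config$burn_in, keep = config$keep,
                  thin = config$thin, adapt = config$adapt,
                  update_blocks = TRUE, update_impute = TRUE,
                  target_accept = config$target_accept,
                  prior_block = model$prior_block)
  draws <- NULL
  imputed <- NULL
  chain <- integer(0)
  accept <- list()
  impute_accept <- numeric(0)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    res <- .mcmc_run(model$blocks, model$impute, run_cfg)
    colnames(res$draws) <- model$param_index$parameter
    if (length(model$imputed_dams)) {
      colnames(res$imputed) <- model$imputed_dams
    }
    draws <- rbind(draws, res$draws)
    imputed <- rbind(imputed, res$imputed)
    chain <- c(chain, rep(ch, nrow(res$draws)))
    accept[[ch]] <- res$accept
    impute_accept <- c(impute_accept, res$impute_accept)
  }
  if (any(!is.finite(draws))) {
    stop("sampler produced non-finite draws", call. = FALSE)
  }
  structure(list(draws = draws, imputed = imputed, chain = chain,
                 accept = accept, impute_accept = impute_accept,
                 param_index = model$param_index,
                 imputed_dams = model$imputed_dams, config = config,
                 specs = model$specs, priors = priors),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("<posterior_draws>", nrow(x$draws), "draws x", ncol(x$draws),
      "parameters,", length(unique(x$chain)), "chain(s)\n")
  acc <- unlist(x$accept[[1L]])
  cat("  block acceptance:", sprintf("%.2f-%.2f", min(acc), max(acc)), "\n")
  if (length(x$imputed_dams)) {
    cat("  imputed maternal masses:", length(x$imputed_dams),
        sprintf("(acceptance %.2f)", x$impute_accept[1L]), "\n")
  }
  invisible(x)
}

#' Redraw imputed maternal masses given fixed parameters
#'
#' Runs only the imputation step of the sampler: every missing maternal
#' 10-day mass is redrawn from an independence proposal given the (fixed)
#' gen-1 mass-model parameters, accepted against the offspring likelihood
#' terms it enters. With the offspring likelihood uninformative (all
#' maternal-mass coefficients zero) the draws are exactly the gen-1
#' predictive for the dam's covariates. Observed masses are never altered.
#'
#' @param model an [mcmc_model()].
#' @param state optional named list overriding block states: `coef` (named
#'   list of coefficient vectors per block) and `scale` (named numeric).
#' @param sweeps number of imputation sweeps to run.
#' @return List with `imputed` (values after the final sweep, named by dam
#'   id), `draws` (sweeps x dams matrix) and `accept` (acceptance rate).
#' @export
impute_missing <- function(model, state = NULL, sweeps = 1L) {
  stopifnot(inherits(model, "mcmc_model"))
  blocks <- model$blocks
  if (!is.null(state)) {
    for (bn in names(state$coef)) {
      i <- match(bn, vapply(blocks, `[[`, "", "name"))
      if (is.na(i)) stop("unknown block '", bn, "' in state", call. = FALSE)
      stopifnot(length(state$coef[[bn]]) == length(blocks[[i]]$init_coef))
      blocks[[i]]$init_coef <- as.numeric(state$coef[[bn]])
    }
    for (bn in names(state$scale)) {
      i <- match(bn, vapply(blocks, `[[`, "", "name"))
      if (is.na(i)) stop("unknown block '", bn, "' in state", call. = FALSE)
      blocks[[i]]$init_scale <- state$scale[[bn]]
    }
  }
  run_cfg <- list(burn_in = 0L, keep = as.integer(sweeps), thin = 1L,
                  adapt = FALSE, update_blocks = FALSE,
                  update_impute = TRUE, target_accept = 0.3,
                  prior_block = model$prior_block)
  res <- .mcmc_run(blocks, model$impute, run_cfg)
  draws <- res$imputed
  if (length(model$imputed_dams)) colnames(draws) <- model$imputed_dams
  list(imputed = setNames(as.numeric(res$final_imputed),
                          model$imputed_dams),
       draws = draws, accept = res$impute_accept)
}

#' Convergence diagnostics for posterior draws
#'
#' Per-parameter autocorrelations (up to lag 50), effective sample size
#' (initial positive-sequence estimator) and a low-ESS flag. Constant
#' (degenerate) columns are flagged rather than failing.
#'
#' @param draws a `posterior_draws` object or a draws matrix.
#' @param ess_floor flag parameters whose ESS falls below this.
#' @param max_lag largest autocorrelation lag reported.
#' @return List with `summary` (data frame: parameter, ess, lag1, flag) and
#'   `acf` (lag x parameter matrix).
#' @export
diagnostics <- function(draws, ess_floor = 100, max_lag = 50L) {
  m <- if (inherits(draws, "posterior_draws")) draws$draws else as.matrix(draws)
  n <- nrow(m)
  if (n < 100L) stop("diagnostics require at least 100 draws", call. = FALSE)
  max_lag <- min(max_lag, n - 1L)
  if (is.null(colnames(m))) {
    colnames(m) <- paste0("par", seq_len(ncol(m)))
  }
  acfs <- matrix(NA_real_, nrow = max_lag, ncol = ncol(m),
                 dimnames = list(paste0("lag", seq_len(max_lag)),
                                 colnames(m)))
  out <- data.frame(parameter = colnames(m), ess = NA_real_,
                    lag1 = NA_real_, flag = "", stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (sd(x) == 0 || !is.finite(sd(x))) {
      out$flag[j] <- "degenerate"
      next
    }
    rho <- drop(acf(x, lag.max = max_lag, plot = FALSE)$acf)[-1L]
    acfs[, j] <- rho
    pos <- which(rho < 0)
    cut <- if (length(pos)) pos[1L] - 1L else length(rho)
    ess <- n / (1 + 2 * sum(rho[seq_len(cut)]))
    out$ess[j] <- min(max(ess, 1), n)
    out$lag1[j] <- rho[1L]
    if (out$ess[j] < ess_floor) out$flag[j] <- "low_ess"
  }
  list(summary = out, acf = acfs)
}
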