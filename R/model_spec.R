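# Joint model specification: per-submodel design construction with
# stage-conditional inclusion, likelihood components, priors, and the
# interaction-dropping model-reduction rule.

#' Specify one submodel
#'
#' A submodel couples one outcome with a likelihood family, an ordered
#' covariate list and a stage-conditional inclusion rule (the stages an
#' individual must have survived to contribute). The default joint model is
#' returned by [default_submodels()].
#'
#' @param name block name (used to key parameters, e.g. `"g2_surv_larval"`).
#' @param outcome cohort column holding the response.
#' @param family one of `"mortality-logit"` (death = 1 Bernoulli on the
#'   logit scale), `"normal"`, `"lognormal"` (normal on the natural log of
#'   the outcome) or `"beta-logit"` (Beta likelihood, logit link on the
#'   mean).
#' @param covariates ordered character vector of term names; `"intercept"`
#'   must come first; interaction terms (`"within:trans"`, `"male:trans"`)
#'   require both main effects.
#' @param generation which generation contributes rows (1 or 2).
#' @param survived character vector among `"24h"`, `"larval"`, `"pupal"`,
#'   `"adult"`: stages an individual must have survived to be included.
#' @return An object of class `submodel_spec`.
#' @export
submodel_spec <- function(name, outcome, family, covariates, generation,
                          survived = character()) {
  family <- match.arg(family, c("mortality-logit", "normal", "lognormal",
                                "beta-logit"))
  if (length(covariates) == 0L || covariates[1L] != "intercept") {
    stop("covariates must start with 'intercept'", call. = FALSE)
  }
  bad <- setdiff(covariates, .term_vocabulary)
  if (length(bad)) {
    stop("unknown covariate term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (ia in intersect(covariates, c("within:trans", "male:trans"))) {
    mains <- strsplit(ia, ":", fixed = TRUE)[[1L]]
    if (!all(mains %in% covariates)) {
      stop("interaction '", ia, "' requires both main effects", call. = FALSE)
    }
  }
  stages <- c("24h", "larval", "pupal", "adult")
  if (!all(survived %in% stages)) {
    stop("survived must be a subset of: ", paste(stages, collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, outcome = outcome, family = family,
                 covariates = covariates, generation = as.integer(generation),
                 survived = survived),
            class = "submodel_spec")
}

#' The default joint model: all submodels of the two-generation analysis
#'
#' Eighteen submodels: four stage-conditional mortality logits per
#' generation (gen-2 adult survival carries no within-by-maternal
#' interaction: too few deaths in some treatment combinations to estimate
#' it), lognormal development time, normal body masses, and the three beta
#' composition submodels, with covariate orders matching the published
#' coefficient table. The gen-1 24 h submodel is the only survival submodel
#' with the pre-treatment larval-mass covariate.
#'
#' @param blocks optional subset of block names.
#' @return Named list of [submodel_spec()] objects.
#' @export
default_submodels <- function(blocks = NULL) {
  specs <- lapply(names(.block_info), function(bn) {
    info <- .block_info[[bn]]
    fam <- info$family
    submodel_spec(name = bn, outcome = info$outcome, family = fam,
                  covariates = info$terms, generation = info$generation,
                  survived = info$survived)
  })
  names(specs) <- names(.block_info)
  if (!is.null(blocks)) {
    bad <- setdiff(blocks, names(specs))
    if (length(bad)) {
      stop("unknown block(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    specs <- specs[blocks]
  }
  specs
}

# Rows passing a spec's stage-conditional inclusion rule.
.included_rows <- function(cohort, spec) {
  keep <- cohort$generation == spec$generation
  stage_col <- c("24h" = "died_24h", larval = "died_larval",
                 pupal = "died_pupal", adult = "died_adult")
  for (st in spec$survived) {
    keep <- keep & (cohort[[stage_col[[st]]]] %in% FALSE)
  }
  which(keep)
}

#' Build the response vector and covariate matrix of one submodel
#'
#' Rows are exactly the individuals passing the spec's inclusion rule (the
#' generation's members that survived all stages the rule names). Columns
#' follow the spec's covariate order; interaction columns are elementwise
#' products. Rows with a missing maternal-mass covariate are retained and
#' flagged for within-sampler imputation rather than dropped; rows with a
#' missing response are dropped (responses are never imputed). For
#' `"beta-logit"` outcomes containing boundary values, the standard
#' `(y * (n - 1) + 0.5) / n` shrinkage ([smooth_fractions()]) is applied.
#'
#' @param cohort a cohort data frame.
#' @param spec a [submodel_spec()].
#' @return List with `y` (response), `X` (covariate matrix, columns named by
#'   term), `rows` (cohort row indices), `missing_maternal` (logical flag
#'   per row) and `spec`.
#' @export
build_design <- function(cohort, spec) {
  stopifnot(inherits(spec, "submodel_spec"))
  if (!spec$outcome %in% names(cohort)) {
    stop(errorCondition(
      paste0("outcome column '", spec$outcome, "' absent from the cohort"),
      class = c("sublethal_schema_error", "error", "condition")))
  }
  rows <- .included_rows(cohort, spec)
  y <- cohort[[spec$outcome]][rows]
  keep <- !is.na(y)
  rows <- rows[keep]
  y <- y[keep]
  sub <- cohort[rows, , drop = FALSE]
  X <- matrix(0, nrow = length(rows), ncol = length(spec$covariates),
              dimnames = list(NULL, spec$covariates))
  for (tm in spec$covariates) X[, tm] <- .term_value(tm, sub)
  missing_maternal <- if ("maternal_mass" %in% spec$covariates) {
    is.na(X[, "maternal_mass"])
  } else {
    rep(FALSE, length(rows))
  }
  # any other missing covariate is a schema error, not an imputation target
  other <- setdiff(spec$covariates, "maternal_mass")
  if (length(rows) && anyNA(X[, other, drop = FALSE])) {
    bad <- other[colSums(is.na(X[, other, drop = FALSE])) > 0]
    stop(errorCondition(
      paste0("missing covariate value(s) for term(s): ",
             paste(bad, collapse = ", "), " in submodel '", spec$name, "'"),
      class = c("sublethal_schema_error", "error", "condition")))
  }
  if (spec$family == "mortality-logit") {
    y <- as.numeric(y)
  } else if (spec$family == "beta-logit") {
    if (any(y <= 0 | y >= 1)) y <- smooth_fractions(y)
  }
  list(y = y, X = X, rows = rows, missing_maternal = missing_maternal,
       spec = spec)
}

#' Boundary shrinkage for proportion outcomes
#'
#' Maps `y` to `(y * (n - 1) + 0.5) / n`, the usual transformation pulling
#' proportions off the 0/1 boundaries so that a Beta likelihood is finite.
#'
#' @param y proportions in `[0, 1]`.
#' @param n sample size used for the shrinkage (defaults to `length(y)`).
#' @return Transformed proportions strictly inside (0, 1) for `n > 1`.
#' @export
smooth_fractions <- function(y, n = length(y)) {
  (y * (n - 1) + 0.5) / n
}

#' Log-likelihood of a stage-conditional mortality submodel
#'
#' Bernoulli log-likelihood with death coded 1 and a logit link:
#' `sum(death * log(p) + (1 - death) * log(1 - p))` with
#' `p = plogis(X %*% coef)`.
#'
#' @param coef coefficient vector (covariate order of `X`).
#' @param X covariate matrix.
#' @param death 0/1 death indicators.
#' @return Log-likelihood (scalar).
#' @export
loglik_mortality <- function(coef, X, death) {
  stopifnot(all(death %in% c(0, 1)))
  eta <- drop(X %*% coef)
  sum(death * plogis(eta, log.p = TRUE) +
        (1 - death) * plogis(-eta, log.p = TRUE))
}

#' Log-likelihood of a normal or lognormal submodel
#'
#' Normal log-density of `y` (or `log(y)` when `log_transform`) around the
#' linear predictor, with the Jacobian `-sum(log(y))` included under the log
#' transform so that densities are comparable across transforms.
#'
#' @param coef coefficient vector.
#' @param sigma residual SD (> 0).
#' @param X covariate matrix.
#' @param y response (> 0 when `log_transform`).
#' @param log_transform model `log(y)` instead of `y`.
#' @return Log-likelihood (scalar).
#' @export
loglik_gaussian <- function(coef, sigma, X, y, log_transform = FALSE) {
  stopifnot(sigma > 0)
  eta <- drop(X %*% coef)
  if (log_transform) {
    stopifnot(all(y > 0))
    z <- log(y)
    jac <- -sum(z)
  } else {
    z <- y
    jac <- 0
  }
  n <- length(y)
  -n * 0.5 * log(2 * pi) - n * log(sigma) -
    sum((z - eta)^2) / (2 * sigma^2) + jac
}

#' Log-likelihood of a logit-link beta submodel
#'
#' Sum of `Beta(mu * phi, (1 - mu) * phi)` log-densities with
#' `mu = plogis(X %*% coef)`.
#'
#' @param coef coefficient vector.
#' @param phi precision (> 0).
#' @param X covariate matrix.
#' @param y responses strictly inside (0, 1).
#' @return Log-likelihood (scalar).
#' @export
loglik_beta <- function(coef, phi, X, y) {
  stopifnot(phi > 0, all(y > 0 & y < 1))
  mu <- plogis(drop(X %*% coef))
  a <- mu * phi
  b <- (1 - mu) * phi
  sum(lgamma(phi) - lgamma(a) - lgamma(b) +
        (a - 1) * log(y) + (b - 1) * log1p(-y))
}

#' Prior specification
#'
#' Independent normal priors on regression coefficients, half-normal priors
#' on residual SDs and a gamma prior on beta precisions. Defaults follow
#' standard weakly-informative practice for logit-scale models:
#' N(0, 2.5^2) on mortality-logit and beta-logit effects with a wider
#' N(0, 10^2) on their intercepts (the scale-2.5 effect prior is what keeps
#' rare-event stages with quasi-separated likelihoods regularized), and
#' N(0, 100^2) on normal/lognormal-family coefficients (whose outcomes are
#' body masses of order 100 mg). Scales get Half-Normal(0, 10) on sigma and
#' Gamma(0.01, 0.01) on phi. Individual parameters can be overridden by
#' name — which is also how a gen-1 posterior summary is plugged in as the
#' gen-2 prior (see [priors_from_summary()]).
#'
#' @param coef_location,coef_scale normal prior location/scale for
#'   logit-scale effect coefficients.
#' @param intercept_scale prior scale for logit-scale intercepts.
#' @param coef_scale_normal prior scale for normal/lognormal-family
#'   coefficients.
#' @param sigma_scale half-normal scale for residual SDs.
#' @param phi_shape,phi_rate gamma prior for beta precisions.
#' @param overrides named list `"<block>.<term>" = c(location, scale)`.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(coef_location = 0, coef_scale = 2.5,
                       intercept_scale = 10, coef_scale_normal = 100,
                       sigma_scale = 10, phi_shape = 0.01, phi_rate = 0.01,
                       overrides = list()) {
  stopifnot(coef_scale > 0, intercept_scale > 0, coef_scale_normal > 0,
            sigma_scale > 0, phi_shape > 0, phi_rate > 0)
  for (ov in overrides) {
    if (length(ov) != 2L || ov[2L] <= 0) {
      stop("each prior override must be c(location, scale > 0)",
           call. = FALSE)
    }
  }
  structure(list(coef_location = coef_location, coef_scale = coef_scale,
                 intercept_scale = intercept_scale,
                 coef_scale_normal = coef_scale_normal,
                 sigma_scale = sigma_scale, phi_shape = phi_shape,
                 phi_rate = phi_rate, overrides = overrides),
            class = "prior_spec")
}

#' Turn a posterior summary into prior overrides
#'
#' Maps each summarized parameter to a normal prior with the posterior mean
#' and SD — the mechanism for letting the first generation's posterior act
#' as the prior of shared second-generation coefficients.
#'
#' @param summaries a data frame with columns `parameter`, `mean`, `sd`
#'   (e.g. from [summarize_draws()]).
#' @return Named list usable as `overrides` in [prior_spec()].
#' @export
priors_from_summary <- function(summaries) {
  stopifnot(all(c("parameter", "mean", "sd") %in% names(summaries)))
  out <- lapply(seq_len(nrow(summaries)), function(i) {
    c(summaries$mean[i], summaries$sd[i])
  })
  names(out) <- summaries$parameter
  out
}

# Resolve the prior location/scale of one block's coefficients.
.coef_priors <- function(spec, priors) {
  k <- length(spec$covariates)
  if (spec$family %in% c("normal", "lognormal")) {
    ps <- rep(priors$coef_scale_normal, k)
  } else {
    ps <- rep(priors$coef_scale, k)
    ps[spec$covariates == "intercept"] <- priors$intercept_scale
  }
  pm <- rep(priors$coef_location, k)
  keys <- paste(spec$name, spec$covariates, sep = ".")
  for (i in seq_len(k)) {
    ov <- priors$overrides[[keys[i]]]
    if (!is.null(ov)) {
      pm[i] <- ov[1L]
      ps[i] <- ov[2L]
    }
  }
  list(mean = pm, sd = ps)
}

#' Joint log-prior of a parameter set
#'
#' Sum of the independent prior log-densities of every coefficient and
#' scale parameter in `params` under `priors`.
#'
#' @param params a [param_set()] or named list of named coefficient vectors
#'   (subsets are allowed; only supplied parameters contribute).
#' @param priors a [prior_spec()].
#' @param specs submodel specs naming the blocks (defaults to the full
#'   model); used to resolve the per-family coefficient scale.
#' @return Log-prior density (scalar).
#' @export
log_prior <- function(params, priors = prior_spec(),
                      specs = default_submodels()) {
  stopifnot(inherits(priors, "prior_spec"))
  total <- 0
  for (bn in names(params)) {
    spec <- specs[[bn]]
    if (is.null(spec)) stop("no submodel spec for block '", bn, "'",
                            call. = FALSE)
    b <- params[[bn]]
    pr <- .coef_priors(spec, priors)
    for (i in seq_along(spec$covariates)) {
      tm <- spec$covariates[i]
      if (tm %in% names(b)) {
        total <- total + dnorm(b[[tm]], pr$mean[i], pr$sd[i], log = TRUE)
      }
    }
    if ("sigma" %in% names(b)) {
      total <- total + dnorm(b[["sigma"]], 0, priors$sigma_scale,
                             log = TRUE) + log(2)
    }
    if ("phi" %in% names(b)) {
      total <- total + dgamma(b[["phi"]], shape = priors$phi_shape,
                              rate = priors$phi_rate, log = TRUE)
    }
  }
  unname(total)
}

#' Drop unsupported non-treatment interactions from the model
#'
#' Implements the model-reduction rule of the analysis: every non-treatment
#' interaction (i.e. `male:trans`) whose 95% posterior interval contains 0
#' is removed from its submodel; main effects are never removed, and the
#' within-by-maternal treatment interaction (`within:trans`) is always kept
#' because it is a primary quantity of interest, whatever its interval.
#'
#' @param summaries data frame with columns `parameter`, `lo`, `hi` covering
#'   every interaction term of `full_specs` (e.g. [summarize_draws()] output
#'   or [reference_estimates()]).
#' @param full_specs named list of [submodel_spec()]s.
#' @return The reduced list of specs.
#' @export
reduce_model <- function(summaries, full_specs) {
  stopifnot(all(c("parameter", "lo", "hi") %in% names(summaries)))
  lapply(full_specs, function(spec) {
    drop <- character()
    for (ia in intersect(spec$covariates, "male:trans")) {
      key <- paste(spec$name, ia, sep = ".")
      row <- match(key, summaries$parameter)
      if (is.na(row)) {
        stop("no posterior summary for interaction term '", key, "'",
             call. = FALSE)
      }
      if (summaries$lo[row] <= 0 && summaries$hi[row] >= 0) {
        drop <- c(drop, ia)
      }
    }
    if (length(drop)) {
      spec$covariates <- setdiff(spec$covariates, drop)
    }
    spec
  })
}
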