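# Parameter sets: every coefficient of every submodel plus the residual
# scales (sigma) of the normal submodels and precisions (phi) of the beta
# submodels. Blocks and term orders mirror the layout of the published
# coefficient table.

.block_info <- local({
  surv1 <- c("intercept", "within")
  cont1 <- c("intercept", "within", "male")
  surv2 <- c("intercept", "within", "trans", "maternal_mass", "within:trans")
  cont2 <- c("intercept", "within", "male", "male:trans", "trans",
             "within:trans", "maternal_mass")
  beta2 <- c("intercept", "within", "male", "trans", "within:trans",
             "maternal_mass")
  list(
    g1_surv_24h      = list(family = "mortality-logit", generation = 1L,
                            terms = c("intercept", "within", "larval_mass"),
                            outcome = "died_24h",  survived = character()),
    g1_surv_larval   = list(family = "mortality-logit", generation = 1L,
                            terms = surv1, outcome = "died_larval",
                            survived = "24h"),
    g1_surv_pupal    = list(family = "mortality-logit", generation = 1L,
                            terms = surv1, outcome = "died_pupal",
                            survived = c("24h", "larval")),
    g1_surv_adult    = list(family = "mortality-logit", generation = 1L,
                            terms = surv1, outcome = "died_adult",
                            survived = c("24h", "larval", "pupal")),
    g1_devtime       = list(family = "lognormal", generation = 1L,
                            terms = cont1, outcome = "dev_time_days",
                            survived = c("24h", "larval", "pupal")),
    g1_mass_emergence = list(family = "normal", generation = 1L,
                            terms = cont1, outcome = "mass_emergence_mg",
                            survived = c("24h", "larval", "pupal")),
    g1_mass_day10    = list(family = "normal", generation = 1L,
                            terms = cont1, outcome = "mass_day10_mg",
                            survived = c("24h", "larval", "pupal", "adult")),
    g2_surv_24h      = list(family = "mortality-logit", generation = 2L,
                            terms = surv2, outcome = "died_24h",
                            survived = character()),
    g2_surv_larval   = list(family = "mortality-logit", generation = 2L,
                            terms = surv2, outcome = "died_larval",
                            survived = "24h"),
    g2_surv_pupal    = list(family = "mortality-logit", generation = 2L,
                            terms = surv2, outcome = "died_pupal",
                            survived = c("24h", "larval")),
    g2_surv_adult    = list(family = "mortality-logit", generation = 2L,
                            terms = surv2[-5L], outcome = "died_adult",
                            survived = c("24h", "larval", "pupal")),
    g2_devtime       = list(family = "lognormal", generation = 2L,
                            terms = cont2, outcome = "dev_time_days",
                            survived = c("24h", "larval", "pupal")),
    g2_mass_emergence = list(family = "normal", generation = 2L,
                            terms = cont2, outcome = "mass_emergence_mg",
                            survived = c("24h", "larval", "pupal")),
    g2_mass_day7     = list(family = "normal", generation = 2L,
                            terms = cont2, outcome = "mass_day7_mg",
                            survived = c("24h", "larval", "pupal", "adult")),
    g2_mass_day14    = list(family = "normal", generation = 2L,
                            terms = cont2, outcome = "mass_day14_mg",
                            survived = c("24h", "larval", "pupal", "adult")),
    g2_lipid         = list(family = "beta-logit", generation = 2L,
                            terms = beta2, outcome = "lipid_frac",
                            survived = c("24h", "larval", "pupal", "adult")),
    g2_water         = list(family = "beta-logit", generation = 2L,
                            terms = beta2, outcome = "water_frac",
                            survived = c("24h", "larval", "pupal", "adult")),
    g2_drymass       = list(family = "beta-logit", generation = 2L,
                            terms = beta2, outcome = "drymass_frac",
                            survived = c("24h", "larval", "pupal", "adult"))
  )
})

.block_names <- names(.block_info)
.term_vocabulary <- c("intercept", "within", "trans", "male", "maternal_mass",
                      "larval_mass", "within:trans", "male:trans")

.block_scale_name <- function(block) {
  fam <- .block_info[[block]]$family
  switch(fam, normal = "sigma", lognormal = "sigma", `beta-logit` = "phi",
         `mortality-logit` = NULL)
}

#' Construct and validate a full parameter set
#'
#' A parameter set holds one named coefficient vector per submodel block,
#' plus a `sigma` entry (residual SD) for every normal/lognormal block and a
#' `phi` entry (beta precision) for every beta block. It is the input of the
#' synthetic-cohort generator and the truth of recovery experiments.
#'
#' @param blocks named list; each element is a named numeric vector of
#'   coefficients for one block (names from the term vocabulary), including
#'   `sigma`/`phi` where the family requires it.
#' @return An object of class `param_set` (a validated named list).
#' @seealso [default_params()], [reference_estimates()]
#' @export
param_set <- function(blocks) {
  if (!is.list(blocks) || is.null(names(blocks))) {
    stop("`blocks` must be a named list of coefficient vectors", call. = FALSE)
  }
  missing_blocks <- setdiff(.block_names, names(blocks))
  if (length(missing_blocks)) {
    stop("parameter set is missing block(s): ",
         paste(missing_blocks, collapse = ", "), call. = FALSE)
  }
  for (bn in .block_names) {
    b <- blocks[[bn]]
    if (!is.numeric(b) || is.null(names(b))) {
      stop("block '", bn, "' must be a named numeric vector", call. = FALSE)
    }
    scale_name <- .block_scale_name(bn)
    coef_names <- setdiff(names(b), c("sigma", "phi"))
    bad <- setdiff(coef_names, .term_vocabulary)
    if (length(bad)) {
      stop("block '", bn, "' has unknown term(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!is.null(scale_name)) {
      if (!scale_name %in% names(b)) {
        stop("block '", bn, "' is missing its scale parameter '",
             scale_name, "'", call. = FALSE)
      }
      if (b[[scale_name]] <= 0) {
        stop("block '", bn, "': '", scale_name, "' must be > 0",
             call. = FALSE)
      }
    }
    if (anyNA(b)) stop("block '", bn, "' contains NA", call. = FALSE)
  }
  structure(blocks[.block_names], class = "param_set")
}

#' Default generator parameters
#'
#' Coefficients are the published posterior means ([reference_estimates()]).
#' Residual scales and beta precisions were not reported; the defaults below
#' are fixed, field-realistic choices (see the methods vignette): residual SD
#' 0.05 on log development time, 15-25 mg on body masses depending on age,
#' and beta precisions 150-300 giving composition-fraction SDs of ~2-3
#' percentage points.
#'
#' @param scales optional named numeric vector overriding individual scale
#'   entries, named `"<block>.sigma"` or `"<block>.phi"`.
#' @return A [param_set()].
#' @export
default_params <- function(scales = NULL) {
  ref <- reference_estimates()
  default_scales <- c(
    g1_devtime.sigma = 0.05, g1_mass_emergence.sigma = 15,
    g1_mass_day10.sigma = 20, g2_devtime.sigma = 0.05,
    g2_mass_emergence.sigma = 15, g2_mass_day7.sigma = 25,
    g2_mass_day14.sigma = 22, g2_lipid.phi = 150, g2_water.phi = 200,
    g2_drymass.phi = 300)
  if (!is.null(scales)) {
    bad <- setdiff(names(scales), names(default_scales))
    if (length(bad)) {
      stop("unknown scale override(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    default_scales[names(scales)] <- scales
  }
  blocks <- lapply(.block_names, function(bn) {
    rows <- ref[ref$block == bn, , drop = FALSE]
    b <- setNames(rows$mean, rows$term)
    sn <- .block_scale_name(bn)
    if (!is.null(sn)) b[sn] <- default_scales[[paste(bn, sn, sep = ".")]]
    b
  })
  names(blocks) <- .block_names
  param_set(blocks)
}

#' Flatten a parameter set to a named vector
#'
#' Names are `"<block>.<term>"`, matching the column names of posterior draw
#' matrices, so that generator truth and posterior estimates align.
#'
#' @param params a [param_set()].
#' @return Named numeric vector.
#' @export
flatten_params <- function(params) {
  stopifnot(inherits(params, "param_set"))
  out <- unlist(lapply(names(params), function(bn) {
    b <- params[[bn]]
    setNames(as.numeric(b), paste(bn, names(b), sep = "."))
  }))
  out
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set>", length(x), "blocks,",
      length(flatten_params(x)), "parameters\n")
  for (bn in names(x)) {
    cat(sprintf("  %-18s %s\n", bn,
                paste(sprintf("%s=%.4g", names(x[[bn]]), x[[bn]]),
                      collapse = ", ")))
  }
  invisible(x)
}

# Internal: check a parameter set covers the blocks needed for simulation of
# one generation; error names the missing block (configuration error).
.check_params_for <- function(params, blocks) {
  missing_blocks <- setdiff(blocks, names(params))
  if (length(missing_blocks)) {
    stop("incomplete parameter set: missing block(s) ",
         paste(missing_blocks, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
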