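# Published posterior summaries for the two-generation experiment.
# These are the fitted coefficient summaries of the original study, entered
# once and used as (i) defaults for the synthetic-cohort generator, (ii) the
# "truth" in parameter-recovery experiments, and (iii) the input for the
# odds-ratio and model-reduction reproductions.

.ref_row <- function(block, term, mean, sd, lo, hi, flag = "") {
  data.frame(block = block, term = term, mean = mean, sd = sd,
             lo = lo, hi = hi, flag = flag, stringsAsFactors = FALSE)
}

.reference_table <- local({
  r <- .ref_row
  out <- rbind(
    ## (a) survival, first generation (mortality-logit scale, death = 1)
    r("g1_surv_24h", "intercept",   -1.06, 1.972, -4.689,  2.979),
    r("g1_surv_24h", "within",       0.42, 0.696, -0.896,  1.807),
    r("g1_surv_24h", "larval_mass", -0.73, 0.584, -1.980,  0.278),
    r("g1_surv_larval", "intercept", -0.96, 0.211, -1.382, -0.555, "star"),
    r("g1_surv_larval", "within",     0.07, 0.292, -0.502,  0.641),
    r("g1_surv_pupal", "intercept",  -1.62, 0.298, -2.231, -1.057, "star"),
    r("g1_surv_pupal", "within",     -0.03, 0.419, -0.861,  0.791),
    r("g1_surv_adult", "intercept",  -1.95, 0.371, -2.722, -1.271, "star"),
    r("g1_surv_adult", "within",     -1.35, 0.741, -2.890,  0.024, "dagger"),
    ## (b) development time and body mass, first generation
    r("g1_devtime", "intercept",  3.380, 0.006,  3.369,  3.393, "star"),
    r("g1_devtime", "within",    -0.002, 0.007, -0.015,  0.012),
    r("g1_devtime", "male",      -0.020, 0.007, -0.032, -0.005, "star"),
    r("g1_mass_emergence", "intercept", 122.77, 1.906, 119.075, 126.568, "star"),
    r("g1_mass_emergence", "within",     -0.39, 2.205,  -4.660,   3.953),
    r("g1_mass_emergence", "male",      -18.38, 2.258, -22.888, -13.963, "star"),
    r("g1_mass_day10", "intercept", 164.93, 2.900, 159.289, 170.493, "star"),
    r("g1_mass_day10", "within",      7.00, 3.388,   0.364,  13.690, "star"),
    r("g1_mass_day10", "male",      -31.83, 3.401, -38.483, -25.129, "star"),
    ## (c) survival, second generation
    r("g2_surv_24h", "intercept",     -6.66, 1.762, -10.203, -3.222, "star"),
    r("g2_surv_24h", "within",         2.06, 0.874,   0.582,  4.011, "star"),
    r("g2_surv_24h", "trans",          1.02, 0.947,  -0.680,  3.057),
    r("g2_surv_24h", "maternal_mass",  0.01, 0.009,  -0.007,  0.027),
    r("g2_surv_24h", "within:trans",  -1.70, 1.073,  -3.954,  0.291),
    r("g2_surv_larval", "intercept",      0.51, 0.596, -0.670,  1.689),
    r("g2_surv_larval", "within",         0.29, 0.199, -0.096,  0.682),
    r("g2_surv_larval", "trans",         -0.56, 0.210, -0.975, -0.152, "star"),
    r("g2_surv_larval", "maternal_mass", -0.004, 0.003, -0.010, 0.003),
    r("g2_surv_larval", "within:trans",  -0.32, 0.293, -0.898,  0.259),
    r("g2_surv_pupal", "intercept",      0.52, 0.589, -0.641,  1.668),
    r("g2_surv_pupal", "within",         0.18, 0.196, -0.201,  0.565),
    r("g2_surv_pupal", "trans",         -0.58, 0.207, -0.986, -0.175, "star"),
    r("g2_surv_pupal", "maternal_mass", -0.004, 0.003, -0.010, 0.003),
    r("g2_surv_pupal", "within:trans",  -0.22, 0.290, -0.799,  0.336),
    r("g2_surv_adult", "intercept",     -7.26, 4.126, -15.692, 0.522),
    r("g2_surv_adult", "within",         1.00, 0.971,  -0.774, 3.083),
    r("g2_surv_adult", "trans",         -1.48, 1.043,  -3.792, 0.398, "dagger"),
    r("g2_surv_adult", "maternal_mass",  0.02, 0.023,  -0.027, 0.061),
    ## (d) development time and body mass, second generation
    r("g2_devtime", "intercept",   3.370, 0.025,  3.317,  3.413, "star"),
    r("g2_devtime", "within",      0.000, 0.009, -0.019,  0.018),
    r("g2_devtime", "male",       -0.030, 0.009, -0.045, -0.008, "star"),
    r("g2_devtime", "male:trans",  0.040, 0.013,  0.012,  0.061, "star"),
    r("g2_devtime", "trans",      -0.020, 0.011, -0.042,  0.000),
    r("g2_devtime", "within:trans", -0.005, 0.013, -0.030, 0.019),
    r("g2_devtime", "maternal_mass", 0.000, 0.0005, 0.000, 0.001),
    r("g2_mass_emergence", "intercept",  107.83, 4.973,  98.018, 117.455, "star"),
    r("g2_mass_emergence", "within",       1.35, 1.922,  -2.373,   5.135),
    r("g2_mass_emergence", "male",       -12.16, 1.907, -15.885,  -8.429, "star"),
    r("g2_mass_emergence", "male:trans",  -2.76, 2.512,  -7.738,   2.145),
    r("g2_mass_emergence", "trans",        4.85, 2.167,   0.625,   9.109, "star"),
    r("g2_mass_emergence", "within:trans", -1.99, 2.525, -6.845,   2.983),
    r("g2_mass_emergence", "maternal_mass", 0.03, 0.027, -0.021,   0.084),
    r("g2_mass_day7", "intercept",  176.37, 8.760, 159.017, 193.616, "star"),
    r("g2_mass_day7", "within",       3.02, 3.355,  -3.543,   9.624),
    r("g2_mass_day7", "male",       -28.31, 3.351, -34.988, -21.657, "star"),
    r("g2_mass_day7", "male:trans",  -7.98, 4.448, -16.644,   0.829, "dagger"),
    r("g2_mass_day7", "trans",        7.36, 3.763,  -0.002,  14.525, "dagger"),
    r("g2_mass_day7", "within:trans", -1.10, 4.434, -9.815,   7.519),
    r("g2_mass_day7", "maternal_mass", 0.01, 0.047, -0.083,   0.102),
    r("g2_mass_day14", "intercept",  142.12, 6.435, 129.316, 154.637, "star"),
    r("g2_mass_day14", "within",      -0.37, 2.471,  -5.260,   4.602),
    r("g2_mass_day14", "male",       -15.55, 2.478, -20.440, -10.663, "star"),
    r("g2_mass_day14", "male:trans",  -3.21, 3.301,  -9.737,   3.357),
    r("g2_mass_day14", "trans",        4.06, 2.806,  -1.499,   9.458),
    r("g2_mass_day14", "within:trans", 0.91, 3.258,  -5.293,   7.389),
    r("g2_mass_day14", "maternal_mass", 0.03, 0.035, -0.042,   0.094),
    ## (e) composition fractions, second generation (logit-mean scale)
    r("g2_lipid", "intercept",    -1.42, 0.119, -1.650, -1.187, "star"),
    r("g2_lipid", "within",       -0.03, 0.046, -0.118,  0.062),
    r("g2_lipid", "male",          0.06, 0.030,  0.004,  0.122, "star"),
    r("g2_lipid", "trans",        -0.04, 0.042, -0.118,  0.047),
    r("g2_lipid", "within:trans",  0.06, 0.060, -0.054,  0.181),
    r("g2_lipid", "maternal_mass", 0.00, 0.001, -0.001,  0.002),
    r("g2_water", "intercept",     0.07, 0.073, -0.070,  0.213),
    r("g2_water", "within",       0.006, 0.028, -0.050,  0.062),
    r("g2_water", "male",         -0.02, 0.019, -0.057,  0.016),
    r("g2_water", "trans",        0.003, 0.026, -0.049,  0.054),
    r("g2_water", "within:trans", -0.02, 0.038, -0.090,  0.058),
    r("g2_water", "maternal_mass", 0.00, 0.0005, -0.001, 0.001),
    r("g2_drymass", "intercept",    -0.89, 0.038, -0.963, -0.815, "star"),
    r("g2_drymass", "within",        0.01, 0.014, -0.017,  0.040),
    r("g2_drymass", "male",         -0.02, 0.009, -0.041, -0.004, "star"),
    r("g2_drymass", "trans",        0.005, 0.013, -0.021,  0.030),
    r("g2_drymass", "within:trans", -0.01, 0.019, -0.047,  0.028),
    r("g2_drymass", "maternal_mass", 0.00, 0.0005, 0.000, 0.001)
  )
  out$parameter <- paste(out$block, out$term, sep = ".")
  rownames(out) <- NULL
  out
})

#' Published posterior summaries of the two-generation experiment
#'
#' Posterior means, standard deviations and 95% credible intervals of every
#' regression coefficient of the original two-generation Colorado potato
#' beetle analysis, on the scale each submodel uses: mortality logits code
#' death as 1 (so survival odds ratios are `exp(-coefficient)`), development
#' time is in natural-log days, body masses in mg, and composition fractions
#' on the logit-mean scale. Reference levels are control = 0 / insecticide = 1
#' and female = 0 / male = 1; the maternal-mass covariate is the dam's 10-day
#' body mass in mg, uncentred.
#'
#' The `flag` column marks coefficients whose 95% interval excludes zero
#' (`"star"`) or that were reported as moderate effects (`"dagger"`).
#'
#' @param block optional character vector of submodel block names to subset.
#' @return A data frame with columns `block`, `term`, `mean`, `sd`, `lo`,
#'   `hi`, `flag` and `parameter` (`"block.term"`).
#' @examples
#' head(reference_estimates("g2_surv_larval"))
#' @export
reference_estimates <- function(block = NULL) {
  out <- .reference_table
  if (!is.null(block)) {
    bad <- setdiff(block, unique(out$block))
    if (length(bad)) {
      stop("unknown block(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    out <- out[out$block %in% block, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
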