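#' Design of a two-generation split-brood cohort
#'
#' Describes the experimental layout the synthetic generator emulates: a
#' first generation of larvae randomized to control/insecticide, a mating
#' design in which each control sire is paired with `dams_per_sire` dams
#' split equally between maternal-treatment groups, and a second generation
#' of larvae re-randomized to within-generation treatments. Defaults are the
#' study's own sizes: 245 first-generation larvae, 14 sires with 4 dams each
#' (56 families) and 842 second-generation larvae.
#'
#' @param n_gen1_larvae number of first-generation larvae.
#' @param n_sires number of (control) sires in the mating design.
#' @param dams_per_sire dams mated to each sire; must be even so that broods
#'   split equally between control and insecticide dams.
#' @param n_gen2_larvae number of second-generation larvae (0 gives a valid
#'   one-generation design).
#' @param treatment_allocation fraction of larvae assigned to the
#'   insecticide arm within each generation, strictly inside (0, 1).
#' @param seed integer seed recorded with the design and used by
#'   [simulate_cohort()].
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_gen1_larvae = 245L, n_sires = 14L,
                          dams_per_sire = 4L, n_gen2_larvae = 842L,
                          treatment_allocation = 0.5, seed = 1L) {
  n_gen1_larvae <- as.integer(n_gen1_larvae)
  n_sires <- as.integer(n_sires)
  dams_per_sire <- as.integer(dams_per_sire)
  n_gen2_larvae <- as.integer(n_gen2_larvae)
  if (n_gen1_larvae < 1L) stop("n_gen1_larvae must be positive", call. = FALSE)
  if (n_sires < 1L) stop("n_sires must be positive", call. = FALSE)
  if (dams_per_sire < 2L || dams_per_sire %% 2L != 0L) {
    stop("dams_per_sire must be a positive even number", call. = FALSE)
  }
  if (n_gen2_larvae < 0L) stop("n_gen2_larvae must be >= 0", call. = FALSE)
  if (!is.numeric(treatment_allocation) || treatment_allocation <= 0 ||
      treatment_allocation >= 1) {
    stop("treatment_allocation must be strictly inside (0, 1)", call. = FALSE)
  }
  structure(list(n_gen1_larvae = n_gen1_larvae, n_sires = n_sires,
                 dams_per_sire = dams_per_sire, n_gen2_larvae = n_gen2_larvae,
                 treatment_allocation = treatment_allocation,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design>\n")
  cat("  gen-1 larvae:        ", x$n_gen1_larvae, "\n")
  cat("  mating:              ", x$n_sires, "sires x", x$dams_per_sire,
      "dams =", x$n_sires * x$dams_per_sire, "families\n")
  cat("  gen-2 larvae:        ", x$n_gen2_larvae, "\n")
  cat("  insecticide fraction:", x$treatment_allocation, "\n")
  cat("  seed:                ", x$seed, "\n")
  invisible(x)
}
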