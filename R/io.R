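# Cohort CSV interface. One row per individual, column names exactly the
# cohort schema; missing values are empty cells and stage fates are 0/1.
# Numeric values are written with 17 significant digits so that a
# write -> read round trip is lossless.

.cohort_numeric_cols <- c(
  "larval_mass_mg", "maternal_mass10_mg", "dev_time_days",
  "mass_emergence_mg", "mass_day7_mg", "mass_day10_mg", "mass_day14_mg",
  "fresh_mg", "dry_mg", "lean_mg", "lipid_frac", "water_frac",
  "drymass_frac")
.cohort_logical_cols <- c("died_24h", "died_larval", "died_pupal",
                          "died_adult")
.cohort_character_cols <- c("id", "family_id", "mother_id",
                            "within_treatment", "maternal_treatment", "sex")

#' Write a cohort to CSV
#'
#' @param cohort a cohort data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort[, cohort_columns(), drop = FALSE]
  fmt <- function(x, f) ifelse(is.na(x), "", f(x))
  for (col in .cohort_numeric_cols) {
    out[[col]] <- fmt(out[[col]], function(x) sprintf("%.17g", x))
  }
  for (col in .cohort_logical_cols) {
    out[[col]] <- fmt(out[[col]], function(x) as.character(as.integer(x)))
  }
  out$generation <- as.character(out$generation)
  for (col in .cohort_character_cols) out[[col]] <- fmt(out[[col]], identity)
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' @param path file written by [write_cohort()] (or following the same
#'   schema).
#' @param validate validate the result against the cohort invariants.
#' @return A cohort data frame.
#' @export
read_cohort <- function(path, validate = TRUE) {
  raw <- read.csv(path, colClasses = "character", na.strings = "",
                  stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols)) {
    stop(errorCondition(
      paste0("cohort file is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = c("sublethal_schema_error", "error", "condition")))
  }
  df <- raw[, cohort_columns(), drop = FALSE]
  df$generation <- as.integer(df$generation)
  for (col in .cohort_numeric_cols) df[[col]] <- as.numeric(df[[col]])
  for (col in .cohort_logical_cols) {
    df[[col]] <- as.logical(as.integer(df[[col]]))
  }
  if (validate) validate_cohort(df)
  df
}

#' Validate a cohort against the data-model invariants
#'
#' Checks the column schema, the stage-conditional definedness of fates
#' (a later-stage fate is defined only when all earlier stages were
#' survived), the measurement-age availability of traits, the weight
#' ordering `lean <= dry <= fresh`, and that composition fractions lie
#' strictly inside (0, 1). Raises a condition of class
#' `"sublethal_schema_error"` on the first violation.
#'
#' @param cohort a cohort data frame.
#' @return `TRUE`, invisibly.
#' @export
validate_cohort <- function(cohort) {
  fail <- function(...) {
    stop(errorCondition(paste0(...), class = c("sublethal_schema_error",
                                               "error", "condition")))
  }
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    fail("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- cohort
  if (nrow(df) == 0L) return(invisible(TRUE))
  if (!all(df$generation %in% c(1L, 2L))) fail("generation must be 1 or 2")
  lev <- c("control", "insecticide")
  if (!all(df$within_treatment %in% lev)) {
    fail("within_treatment must be control/insecticide")
  }
  if (!all(df$maternal_treatment %in% c(lev, NA))) {
    fail("maternal_treatment must be control/insecticide or missing")
  }
  if (!all(df$sex %in% c("female", "male", NA))) {
    fail("sex must be female/male or missing")
  }
  if (any(df$generation == 1L & !is.na(df$maternal_treatment))) {
    fail("gen-1 rows cannot carry a maternal treatment")
  }
  if (anyNA(df$died_24h)) fail("died_24h must be defined for every row")
  dead24 <- df$died_24h
  if (any(dead24 & !is.na(df$died_larval))) {
    fail("died_larval defined for an individual that died in the first 24 h")
  }
  deadlarv <- df$died_larval %in% TRUE
  if (any((dead24 | deadlarv) & !is.na(df$died_pupal))) {
    fail("died_pupal defined for an individual that died earlier")
  }
  not_emerged <- dead24 | deadlarv | df$died_pupal %in% TRUE
  if (any(not_emerged & !is.na(df$died_adult))) {
    fail("died_adult defined for an individual that died earlier")
  }
  alive_mid <- !dead24 & !deadlarv
  if (any(alive_mid & is.na(df$died_larval))) {
    fail("died_larval missing for a 24 h survivor")
  }
  for (col in c("sex", "dev_time_days", "mass_emergence_mg")) {
    if (any(not_emerged & !is.na(df[[col]]))) {
      fail(col, " present for an individual that never emerged")
    }
  }
  gone <- not_emerged | df$died_adult %in% TRUE
  for (col in c("mass_day7_mg", "mass_day10_mg", "mass_day14_mg", "fresh_mg",
                "dry_mg", "lean_mg", "lipid_frac", "water_frac",
                "drymass_frac")) {
    if (any(gone & !is.na(df[[col]]))) {
      fail(col, " present for an individual dead before its measurement age")
    }
  }
  w <- !is.na(df$fresh_mg) & !is.na(df$dry_mg) & !is.na(df$lean_mg)
  if (any(w)) {
    tol <- 1e-8
    if (any(df$lean_mg[w] > df$dry_mg[w] + tol) ||
        any(df$dry_mg[w] > df$fresh_mg[w] + tol) ||
        any(df$lean_mg[w] < -tol)) {
      fail("weight ordering violated: need 0 <= lean <= dry <= fresh")
    }
  }
  for (col in c("lipid_frac", "water_frac", "drymass_frac")) {
    v <- df[[col]][!is.na(df[[col]])]
    if (length(v) && (any(v <= 0) || any(v >= 1))) {
      fail(col, " must lie strictly inside (0, 1)")
    }
  }
  if (any(!is.na(df$dev_time_days) & df$dev_time_days <= 0)) {
    fail("dev_time_days must be positive")
  }
  invisible(TRUE)
}

#' Write / read the design sidecar of a simulated cohort
#'
#' The sidecar (JSON) records the cohort design, the seed, and the true
#' generator parameters, which is what parameter-recovery tests need to
#' re-fit and score a simulated data set.
#'
#' @param design a [cohort_design()].
#' @param params the true [param_set()] used to simulate.
#' @param path sidecar file path.
#' @return `path` invisibly (`write_design_sidecar`); a list with elements
#'   `design` and `params` (`read_design_sidecar`).
#' @export
write_design_sidecar <- function(design, params, path) {
  stopifnot(inherits(design, "cohort_design"))
  payload <- list(
    design = unclass(design),
    true_params = lapply(unclass(param_set(params)), as.list))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_design_sidecar
#' @export
read_design_sidecar <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  d <- payload$design
  design <- cohort_design(
    n_gen1_larvae = d$n_gen1_larvae, n_sires = d$n_sires,
    dams_per_sire = d$dams_per_sire, n_gen2_larvae = d$n_gen2_larvae,
    treatment_allocation = d$treatment_allocation, seed = d$seed)
  blocks <- lapply(payload$true_params, function(b) unlist(b))
  list(design = design, params = param_set(blocks))
}
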