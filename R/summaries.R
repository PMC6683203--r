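# Posterior summaries: equal-tail and highest-posterior-density intervals,
# sign probabilities and significance flags, odds-ratio transforms of
# mortality-logit coefficients, and the coefficient-table renderer.

#' Highest posterior density interval
#'
#' The narrowest contiguous interval containing `ceiling(level * n)` order
#' statistics of the sample — the "shortest interval" definition of a
#' credible interval. For a degenerate (constant) sample the interval is
#' the single point, flagged through the `"degenerate"` attribute.
#'
#' @param x numeric sample of at least 50 draws.
#' @param level probability mass in (0, 1).
#' @return `c(lo, hi)` with attribute `"degenerate"`.
#' @export
hpd_interval <- function(x, level = 0.95) {
  n <- length(x)
  if (n < 50L) stop("hpd_interval requires at least 50 draws", call. = FALSE)
  stopifnot(level > 0, level < 1)
  s <- sort(x)
  m <- ceiling(level * n)
  if (m >= n) {
    out <- c(s[1L], s[n])
  } else {
    lo_idx <- seq_len(n - m + 1L)
    widths <- s[lo_idx + m - 1L] - s[lo_idx]
    i <- which.min(widths)
    out <- c(s[i], s[i + m - 1L])
  }
  names(out) <- c("lo", "hi")
  attr(out, "degenerate") <- unname(out[1L] == out[2L])
  out
}

.equal_tail <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  unname(quantile(x, c(a, 1 - a), names = FALSE))
}

#' Summarize posterior draws, coefficient-table style
#'
#' Per parameter: posterior mean, SD, 95% interval (equal-tail by default,
#' HPD on request), the probability of a positive value, and a flag:
#' `"star"` when the 95% interval excludes 0, `"dagger"` when the interval
#' contains 0 but `max(p_sign, 1 - p_sign)` falls in `dagger_band`
#' (the operationalization of a "moderate effect").
#'
#' @param draws a `posterior_draws` object or a draws matrix with named
#'   columns.
#' @param interval_kind `"equal_tail"` or `"hpd"`.
#' @param level interval probability mass.
#' @param dagger_band two probabilities delimiting the moderate-effect band
#'   `[lo, hi)`.
#' @return Data frame with columns `parameter`, `block`, `term`, `mean`,
#'   `sd`, `lo`, `hi`, `interval_kind`, `p_sign`, `flag`.
#' @export
summarize_draws <- function(draws, interval_kind = c("equal_tail", "hpd"),
                            level = 0.95, dagger_band = c(0.90, 0.975)) {
  interval_kind <- match.arg(interval_kind)
  m <- if (inherits(draws, "posterior_draws")) draws$draws else as.matrix(draws)
  if (is.null(colnames(m))) {
    stop("draws must have named columns", call. = FALSE)
  }
  param <- colnames(m)
  block <- sub("^([^.]+)\\..*$", "\\1", param)
  term <- sub("^[^.]+\\.", "", param)
  has_block <- grepl(".", param, fixed = TRUE)
  block[!has_block] <- NA_character_
  term[!has_block] <- param[!has_block]
  out <- data.frame(parameter = param, block = block, term = term,
                    mean = colMeans(m), sd = apply(m, 2, sd),
                    lo = NA_real_, hi = NA_real_,
                    interval_kind = interval_kind,
                    p_sign = colMeans(m > 0), flag = "",
                    stringsAsFactors = FALSE, row.names = NULL)
  for (j in seq_along(param)) {
    ci <- if (interval_kind == "hpd") {
      hpd_interval(m[, j], level)
    } else {
      .equal_tail(m[, j], level)
    }
    out$lo[j] <- ci[1L]
    out$hi[j] <- ci[2L]
  }
  excl0 <- out$lo > 0 | out$hi < 0
  psign_max <- pmax(out$p_sign, 1 - out$p_sign)
  out$flag[excl0] <- "star"
  moderate <- !excl0 & psign_max >= dagger_band[1L] &
    psign_max < dagger_band[2L]
  out$flag[moderate] <- "dagger"
  out
}

#' Odds-ratio summary of a mortality-logit coefficient
#'
#' Mortality submodels code death as 1, so a coefficient `x` multiplies the
#' odds of death by `exp(x)` and the odds of survival by `exp(-x)`. The
#' caller states the direction explicitly; on the survival direction the
#' interval endpoints are negated and swapped so `lo < hi` is preserved.
#'
#' @param coef posterior draws of the coefficient, or a single point value.
#' @param direction `"survival"` or `"death"`.
#' @param interval optional `c(lo, hi)` interval on the coefficient scale
#'   (required to get an OR interval when `coef` is a point value).
#' @param level interval mass used when `coef` is a vector of draws.
#' @return List of class `or_summary`: `point`, `lo`, `hi`, `p_gt1` (the
#'   posterior probability OR > 1; `NA` without draws) and `direction`.
#' @examples
#' odds_ratio_summary(-0.56, direction = "survival")$point  # 1.75
#' @export
odds_ratio_summary <- function(coef, direction = c("survival", "death"),
                               interval = NULL, level = 0.95) {
  direction <- match.arg(direction)
  s <- if (direction == "survival") -1 else 1
  if (length(coef) > 1L) {
    point <- exp(s * mean(coef))
    ci <- .equal_tail(coef, level)
    p_gt1 <- mean(s * coef > 0)
  } else {
    point <- exp(s * coef)
    ci <- interval
    p_gt1 <- NA_real_
  }
  lo <- hi <- NA_real_
  if (!is.null(ci)) {
    ends <- sort(exp(s * ci))
    lo <- ends[1L]
    hi <- ends[2L]
  }
  structure(list(point = unname(point), lo = lo, hi = hi, p_gt1 = p_gt1,
                 direction = direction),
            class = "or_summary")
}

#' @export
print.or_summary <- function(x, ...) {
  cat(sprintf("odds ratio (%s direction): %.2f", x$direction, x$point))
  if (!is.na(x$lo)) cat(sprintf(" [%.2f, %.2f]", x$lo, x$hi))
  if (!is.na(x$p_gt1)) cat(sprintf(", P(OR > 1) = %.3f", x$p_gt1))
  cat("\n")
  invisible(x)
}

# Canonical table layout: section letters and block order of the published
# coefficient table.
.table_sections <- list(
  a = c("g1_surv_24h", "g1_surv_larval", "g1_surv_pupal", "g1_surv_adult"),
  b = c("g1_devtime", "g1_mass_emergence", "g1_mass_day10"),
  c = c("g2_surv_24h", "g2_surv_larval", "g2_surv_pupal", "g2_surv_adult"),
  d = c("g2_devtime", "g2_mass_emergence", "g2_mass_day7", "g2_mass_day14"),
  e = c("g2_lipid", "g2_water", "g2_drymass"))

#' Render posterior summaries as the canonical coefficient table
#'
#' Emits per-block rows (mean, SD, 2.5%, 97.5%, flag) in the canonical
#' block and covariate order, sectioned (a)-(e) the way the published table
#' is: gen-1 survival, gen-1 development/mass, gen-2 survival, gen-2
#' development/mass, gen-2 composition.
#'
#' @param summaries output of [summarize_draws()] (scale parameters are
#'   dropped from the table).
#' @param blocks blocks to render (default: all present in `summaries`).
#' @return Data frame with columns `section`, `block`, `term`, `parameter`,
#'   `mean`, `sd`, `lo`, `hi`, `flag`, ordered canonically.
#' @export
render_table1 <- function(summaries, blocks = NULL) {
  stopifnot(all(c("parameter", "block", "term", "mean", "sd", "lo", "hi",
                  "flag") %in% names(summaries)))
  canonical <- unlist(.table_sections, use.names = FALSE)
  if (is.null(blocks)) blocks <- intersect(canonical, summaries$block)
  bad <- setdiff(blocks, canonical)
  if (length(bad)) {
    stop("unknown block(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(blocks, summaries$block)
  if (length(absent)) {
    stop("no summaries for block(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (!length(blocks)) stop("no blocks to render", call. = FALSE)
  section_of <- function(b) {
    names(.table_sections)[vapply(.table_sections, function(s) b %in% s,
                                  logical(1))]
  }
  rows <- list()
  for (b in intersect(canonical, blocks)) {
    terms <- .block_info[[b]]$terms
    sub <- summaries[summaries$block == b & summaries$term %in% terms, ,
                     drop = FALSE]
    sub <- sub[match(intersect(terms, sub$term), sub$term), , drop = FALSE]
    sub <- data.frame(section = section_of(b), sub[, c(
      "block", "term", "parameter", "mean", "sd", "lo", "hi", "flag")],
      stringsAsFactors = FALSE)
    rows[[b]] <- sub
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a summary table as CSV
#'
#' Machine-readable variant of [render_table1()]; numbers are written at
#' full precision so a round trip reproduces the summary set exactly.
#'
#' @param table data frame from [render_table1()] or [summarize_draws()].
#' @param path file path.
#' @return `path` invisibly; `read_summary_csv()` returns the data frame.
#' @export
write_summary_csv <- function(table, path) {
  out <- table
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
read_summary_csv <- function(path) {
  df <- read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  for (col in intersect(c("mean", "sd", "lo", "hi", "p_sign"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if ("flag" %in% names(df)) df$flag[is.na(df$flag)] <- ""
  df
}
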