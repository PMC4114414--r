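#' Median and IQR by group
#'
#' Small cohorts call for nonparametric summaries: per-group median and
#' interquartile range (25th-75th percentile, linear-interpolation quantile
#' convention, `stats::quantile` type 7). Missing metric values are excluded
#' and counted.
#'
#' @param values Numeric metric values (may contain `NA`).
#' @param groups Group label per value.
#' @return A tibble with one row per group: `group`, `n`, `n_excluded`,
#'   `median`, `q25`, `q75`. Errors if a group has no non-missing value.
#' @export
summarize_group <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  df <- tibble::tibble(value = as.numeric(values),
                       group = as.character(groups))
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$group),
    n = sum(!is.na(.data$value)),
    n_excluded = sum(is.na(.data$value)),
    median = stats::median(.data$value, na.rm = TRUE),
    q25 = unname(stats::quantile(.data$value, 0.25, na.rm = TRUE, type = 7)),
    q75 = unname(stats::quantile(.data$value, 0.75, na.rm = TRUE, type = 7)),
    .groups = "drop")
  bad <- out$group[out$n == 0L]
  if (length(bad) > 0L) {
    rlang::abort(sprintf("Group '%s' has no non-missing values.", bad[1L]))
  }
  out
}

#' Mann-Whitney U test (normal approximation, tie-corrected)
#'
#' Rank-sum comparison of two independent samples. Conventions, stamped into
#' the result so reported z values are unambiguous: U counts wins of the
#' first sample (`U = R1 - n1(n1+1)/2` from midranks), the variance carries
#' the tie correction, and no continuity correction is applied. The
#' two-sided p comes from the normal approximation
#' `z = (U - n1 n2 / 2) / sigma_U`.
#'
#' @param x,y Numeric samples (missing values dropped).
#' @return A list of class `mann_whitney`: `U`, `z`, `p_two_sided`, `n1`,
#'   `n2`, `tie_correction_applied`, `orientation`, `continuity_correction`.
#'   Errors when every observation is identical (`sigma_U = 0`).
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1L || n2 < 1L) {
    rlang::abort("Both samples must contain at least one non-missing value.")
  }
  pooled <- c(x, y)
  r <- rank(pooled)                       # midranks
  N <- n1 + n2
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    rlang::abort("Degenerate test: all observations identical (sigma_U = 0).")
  }
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  structure(list(
    U = U, z = z, p_two_sided = 2 * stats::pnorm(-abs(z)),
    n1 = n1, n2 = n2,
    tie_correction_applied = tie_term > 0,
    orientation = "U counts wins of x (sample 1)",
    continuity_correction = FALSE
  ), class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), z = %.3f, two-sided P = %.3g\n",
              x$U, x$n1, x$n2, x$z, x$p_two_sided))
  if (x$tie_correction_applied) cat("  (tie-corrected variance)\n")
  invisible(x)
}

#' Order PD participants by symptom severity
#'
#' Joins metadata and metrics for the PD group and sorts ascending by
#' baseline severity, taken as the sum of the motor and nonmotor partial
#' UPDRS self-report subscales (per-subscale columns are retained so either
#' ordering can be inspected). Ties break by `participant_id`; participants
#' missing a baseline score are listed last and flagged, never dropped
#' silently.
#'
#' @param meta Metadata tibble (see [read_participant_meta()]).
#' @param metrics Metric table from [compute_study()] /
#'   [lifespace_metrics()].
#' @return A tibble of PD participants with `severity_score`,
#'   `severity_missing`, the subscale columns and the four metrics, sorted
#'   by severity.
#' @export
severity_order <- function(meta, metrics) {
  pd <- meta[meta$group == "PD", , drop = FALSE]
  if (nrow(pd) == 0L) rlang::abort("No PD participants in metadata.")
  pd$severity_score <- pd$updrs_motor_baseline + pd$updrs_nonmotor_baseline
  pd$severity_missing <- is.na(pd$severity_score)
  out <- dplyr::left_join(
    pd[, c("participant_id", "updrs_motor_baseline",
           "updrs_nonmotor_baseline", "severity_score", "severity_missing")],
    metrics, by = "participant_id")
  out[order(out$severity_missing, out$severity_score, out$participant_id), ,
      drop = FALSE]
}

#' Compare Lifespace metrics between groups
#'
#' Produces the group-comparison table: per metric, each group's median and
#' IQR plus the Mann-Whitney z and two-sided P (PD as sample 1). No
#' multiple-testing correction is applied across the four metrics; the
#' result notes this.
#'
#' @param metrics Metric table, one row per participant.
#' @param meta Metadata with `participant_id` and `group`.
#' @param metric_cols Metric columns to compare.
#' @return A list of class `group_comparison`: `summary` (long tibble:
#'   metric, group, n, median, q25, q75), `tests` (metric, U, z,
#'   p_two_sided), and `notes`.
#' @export
compare_groups <- function(metrics, meta,
                           metric_cols = c("max_distance_km",
                                           "mean_daily_distance_km",
                                           "pct_time_at_home",
                                           "trips_per_week")) {
  df <- dplyr::left_join(metrics, meta[, c("participant_id", "group")],
                         by = "participant_id")
  if (any(is.na(df$group))) {
    rlang::abort("Some participants in `metrics` have no group label.")
  }
  if (length(unique(df$group)) < 2L) {
    rlang::abort("Both groups must be present for a comparison.")
  }
  summaries <- lapply(metric_cols, function(col) {
    s <- summarize_group(df[[col]], df$group)
    s$metric <- col
    s
  })
  tests <- lapply(metric_cols, function(col) {
    x <- df[[col]][df$group == "PD"]
    y <- df[[col]][df$group == "control"]
    mw <- mann_whitney(x[!is.na(x)], y[!is.na(y)])
    tibble::tibble(metric = col, U = mw$U, z = mw$z,
                   p_two_sided = mw$p_two_sided)
  })
  structure(list(
    summary = dplyr::bind_rows(summaries)[, c("metric", "group", "n",
                                              "n_excluded", "median",
                                              "q25", "q75")],
    tests = dplyr::bind_rows(tests),
    notes = paste("PD is sample 1 (U counts its wins); normal approximation,",
                  "tie-corrected variance, no continuity correction;",
                  "no multiple-testing correction across metrics.")
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (median [IQR] per group; Mann-Whitney z, P):\n")
  print(x$summary)
  print(x$tests)
  cat(x$notes, "\n")
  invisible(x)
}
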