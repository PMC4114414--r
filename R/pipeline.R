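#' Study-level analysis configuration
#'
#' Aggregates every tunable of the pipeline with its study default: the
#' 500 m home radius, the 15 min trip filter, the ~11 m home-inference grid,
#' the 5 min session gap, and the daily-distance definition. Sensitivity
#' runs change one field here.
#'
#' @param timezone Timezone for calendar dates (set explicitly for real
#'   deployments).
#' @param cell_size_deg Home-inference grid pitch, degrees.
#' @param radius_km Home radius, kilometers.
#' @param min_trip_duration_min Trip-qualification threshold, minutes.
#' @param session_gap_s Session-splitting gap, seconds.
#' @param daily_distance_mode `"path_length"` or `"max_home_distance"` (see
#'   [mean_daily_distance()]).
#' @param count_open_trips Count qualifying open trips (see
#'   [detect_trips()]).
#' @param heat_bins Heatmap bins per axis.
#' @return A list of class `study_config` with a stable content hash in
#'   `$hash`.
#' @export
study_config <- function(timezone = "UTC", cell_size_deg = 1e-4,
                         radius_km = 0.5, min_trip_duration_min = 15,
                         session_gap_s = 300,
                         daily_distance_mode = c("path_length",
                                                 "max_home_distance"),
                         count_open_trips = FALSE, heat_bins = 100) {
  daily_distance_mode <- match.arg(daily_distance_mode)
  stopifnot(cell_size_deg > 0, radius_km > 0, min_trip_duration_min >= 0,
            session_gap_s > 0, heat_bins >= 1)
  cfg <- list(timezone = timezone, cell_size_deg = cell_size_deg,
              radius_km = radius_km,
              min_trip_duration_min = min_trip_duration_min,
              session_gap_s = session_gap_s,
              daily_distance_mode = daily_distance_mode,
              count_open_trips = count_open_trips, heat_bins = heat_bins)
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "study_config")
}

#' Run the full per-participant pipeline for a study
#'
#' For each trace: recording sessions, home inference, trip detection, and
#' the four Lifespace metrics. A participant whose trace is empty or fails
#' yields a row of `NA` metrics plus a recorded warning; the run continues.
#'
#' @param traces A list of [ls_trace()] objects (names ignored; ids come
#'   from the traces).
#' @param config A [study_config()].
#' @return A tibble of class `study_metrics`, one row per participant, with
#'   the [lifespace_metrics()] columns. The configuration hash and any
#'   per-participant warnings are attached as attributes `config_hash` and
#'   `issues`.
#' @export
compute_study <- function(traces, config = study_config()) {
  issues <- list()
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    fallback_id <- if (nrow(tr) > 0L) tr$participant_id[1L] else
      names(traces)[i] %||% sprintf("trace%d", i)
    res <- tryCatch(
      lifespace_metrics(tr, config = config),
      error = function(e) {
        issues[[fallback_id]] <<- conditionMessage(e)
        tibble::tibble(
          participant_id = fallback_id, max_distance_km = NA_real_,
          mean_daily_distance_km = NA_real_, pct_time_at_home = NA_real_,
          trips_per_week = NA_real_, n_recorded_days = 0L,
          n_qualifying_trips = NA_integer_,
          daily_distance_mode = config$daily_distance_mode)
      })
    if (is.na(res$participant_id)) res$participant_id <- fallback_id
    if (nrow(tr) == 0L) issues[[fallback_id]] <<- "empty trace"
    res
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("study_metrics", class(out))
  attr(out, "config_hash") <- config$hash
  attr(out, "issues") <- issues
  if (length(issues) > 0L) {
    rlang::warn(sprintf("%d participant(s) produced no metrics: %s.",
                        length(issues), paste(names(issues), collapse = ", ")))
  }
  out
}

#' Compare groups and order by severity for a computed study
#'
#' The group-comparison stage: group medians and IQRs with Mann-Whitney
#' tests for each metric, plus the severity-ordered PD table.
#'
#' @param metrics A table from [compute_study()].
#' @param meta Participant metadata (see [read_participant_meta()]).
#' @param config A [study_config()].
#' @return A list: `comparison` (a [compare_groups()] result) and
#'   `severity` (a [severity_order()] table).
#' @export
compare_study <- function(metrics, meta, config = study_config()) {
  list(comparison = compare_groups(metrics, meta),
       severity = severity_order(meta, metrics),
       config_hash = config$hash)
}

#' Write a study metrics table to CSV
#'
#' Byte-deterministic formatting (6 decimal places for kilometers and
#' percentages), so identical inputs and configuration produce identical
#' files.
#'
#' @param metrics A table from [compute_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  num <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
  lines <- c(
    paste0("participant_id,max_distance_km,mean_daily_distance_km,",
           "pct_time_at_home,trips_per_week,n_recorded_days,",
           "n_qualifying_trips,daily_distance_mode"),
    sprintf("%s,%s,%s,%s,%s,%d,%s,%s",
            metrics$participant_id,
            num(metrics$max_distance_km),
            num(metrics$mean_daily_distance_km),
            num(metrics$pct_time_at_home),
            num(metrics$trips_per_week),
            metrics$n_recorded_days,
            ifelse(is.na(metrics$n_qualifying_trips), "",
                   as.character(metrics$n_qualifying_trips)),
            metrics$daily_distance_mode))
  writeLines(lines, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration (and its hash), package version, and any
#' per-participant issues next to a set of outputs, so every result file is
#' traceable to the configuration that produced it.
#'
#' @param config A [study_config()].
#' @param path Output JSON path.
#' @param extra Optional named list merged into the manifest (e.g. load
#'   reports).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(config, path, extra = list()) {
  manifest <- c(list(
    package = "lifespace",
    version = as.character(utils::packageVersion("lifespace")),
    config = unclass(config)),
    extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
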