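#' Furthest distance travelled from home
#'
#' @param trace An [ls_trace()].
#' @param home A [geo_point()] or `c(lat, lon)`.
#' @return Maximum over all fixes of the great-circle distance from home,
#'   in kilometers; `NA` (an undefined metric, not zero) for an empty trace.
#' @export
max_distance <- function(trace, home) {
  if (nrow(trace) == 0L) return(NA_real_)
  home <- as_geo_point(home)
  max(haversine_km(trace$lat, trace$lon, home[["lat"]], home[["lon"]]))
}

#' Per-day Lifespace summaries
#'
#' Aggregates a trace into one row per recorded calendar date. Distances and
#' durations come from consecutive-fix intervals within recording sessions
#' (gaps between sessions contribute nothing); each interval's duration is
#' attributed to the earlier fix's at-home status (left-constant
#' interpolation, the natural convention for a dense fix stream). Intervals
#' spanning midnight are split at the boundary, so both dates receive their
#' share of time and path length.
#'
#' @param trace An [ls_trace()].
#' @param home A [geo_point()] or `c(lat, lon)`.
#' @param radius_km Home radius in kilometers.
#' @param session_gap_s Session-splitting gap, seconds (see
#'   [segment_sessions()]).
#' @param tz Timezone for calendar dates.
#' @return A tibble with columns `date`, `path_length_km`,
#'   `max_home_distance_km`, `recorded_seconds`, `seconds_at_home`.
#' @export
daily_summaries <- function(trace, home, radius_km = 0.5,
                            session_gap_s = 300, tz = "UTC") {
  home <- as_geo_point(home)
  if (nrow(trace) == 0L) {
    return(tibble::tibble(date = as.Date(character()),
                          path_length_km = numeric(),
                          max_home_distance_km = numeric(),
                          recorded_seconds = numeric(),
                          seconds_at_home = numeric()))
  }
  dist_home <- haversine_km(trace$lat, trace$lon,
                            home[["lat"]], home[["lon"]])
  at_home <- dist_home <= radius_km
  pt_date <- as.Date(trace$time, tz = tz)

  iv <- trace_intervals(trace, session_gap_s)
  parts <- if (nrow(iv) > 0L) {
    split_at_midnight(
      t0 = as.numeric(trace$time)[iv$i], dt = iv$dt,
      dist = haversine_km(trace$lat[iv$i], trace$lon[iv$i],
                          trace$lat[iv$i + 1L], trace$lon[iv$i + 1L]),
      at_home = at_home[iv$i], tz = tz)
  } else {
    tibble::tibble(date = as.Date(character()), seconds = numeric(),
                   distance_km = numeric(), at_home = logical())
  }

  by_pt <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(date = pt_date, d = dist_home), date),
    max_home_distance_km = max(.data$d), .groups = "drop")
  by_iv <- dplyr::summarise(
    dplyr::group_by(parts, .data$date),
    path_length_km = sum(.data$distance_km),
    recorded_seconds = sum(.data$seconds),
    seconds_at_home = sum(.data$seconds[.data$at_home]),
    .groups = "drop")
  out <- dplyr::full_join(by_pt, by_iv, by = "date")
  out <- dplyr::arrange(out, .data$date)
  for (col in c("path_length_km", "recorded_seconds", "seconds_at_home")) {
    out[[col]][is.na(out[[col]])] <- 0
  }
  out[, c("date", "path_length_km", "max_home_distance_km",
          "recorded_seconds", "seconds_at_home")]
}

# consecutive-fix intervals within sessions: earlier index i and length dt (s)
trace_intervals <- function(trace, session_gap_s) {
  n <- nrow(trace)
  if (n < 2L) return(tibble::tibble(i = integer(), dt = numeric()))
  t_num <- as.numeric(trace$time)
  dt <- diff(t_num)
  same_session <- dt <= session_gap_s
  tibble::tibble(i = which(same_session), dt = dt[same_session])
}

# split intervals (t0, dt) at local-midnight boundaries; distance and time
# are apportioned linearly; at_home follows the earlier fix for all parts
split_at_midnight <- function(t0, dt, dist, at_home, tz) {
  d1 <- as.Date(as.POSIXct(t0, origin = "1970-01-01", tz = "UTC"), tz = tz)
  d2 <- as.Date(as.POSIXct(t0 + dt, origin = "1970-01-01", tz = "UTC"), tz = tz)
  same <- d1 == d2
  out <- tibble::tibble(date = d1[same], seconds = dt[same],
                        distance_km = dist[same], at_home = at_home[same])
  cross <- which(!same)
  if (length(cross) > 0L) {
    extra <- lapply(cross, function(k) {
      dates <- seq(d1[k], d2[k], by = "day")
      bounds <- c(t0[k],
                  as.numeric(as.POSIXct(paste(dates[-1L], "00:00:00"), tz = tz)),
                  t0[k] + dt[k])
      secs <- diff(bounds)
      keep <- secs > 0
      tibble::tibble(date = dates[keep], seconds = secs[keep],
                     distance_km = dist[k] * secs[keep] / dt[k],
                     at_home = at_home[k])
    })
    out <- dplyr::bind_rows(out, dplyr::bind_rows(extra))
  }
  out
}

#' Mean daily distance
#'
#' The field's "mean daily distance" admits two readings, both provided:
#' `path_length` (total distance travelled per day, summed over consecutive
#' fixes) and `max_home_distance` (each day's furthest excursion from home).
#' The mode used is stamped into every downstream output.
#'
#' @param summaries A table from [daily_summaries()].
#' @param mode Which per-day distance to average.
#' @return Arithmetic mean over recorded days, kilometers; `NA` if there are
#'   no recorded days.
#' @export
mean_daily_distance <- function(summaries,
                                mode = c("path_length", "max_home_distance")) {
  mode <- match.arg(mode)
  if (nrow(summaries) == 0L) return(NA_real_)
  col <- switch(mode, path_length = "path_length_km",
                max_home_distance = "max_home_distance_km")
  mean(summaries[[col]])
}

#' Percentage of recorded time at home
#'
#' A percentage of *recorded* time: gaps between recording sessions enter
#' neither numerator nor denominator.
#'
#' @param summaries A table from [daily_summaries()].
#' @return `100 * sum(seconds_at_home) / sum(recorded_seconds)`; `NA` when
#'   no time was recorded.
#' @export
pct_time_at_home <- function(summaries) {
  tot <- sum(summaries$recorded_seconds)
  if (nrow(summaries) == 0L || tot <= 0) return(NA_real_)
  100 * sum(summaries$seconds_at_home) / tot
}

#' Trips per week
#'
#' Normalizes a trip count by the number of recorded days (recording was
#' intermittent, so calendar weeks would understate the rate).
#'
#' @param n_trips Qualifying-trip count.
#' @param n_recorded_days Distinct recorded days ( >= 1 ).
#' @return `n_trips * 7 / n_recorded_days`; `NA` if no recorded days.
#' @export
trips_per_week <- function(n_trips, n_recorded_days) {
  if (is.na(n_recorded_days) || n_recorded_days < 1) return(NA_real_)
  n_trips * 7 / n_recorded_days
}

#' Compute the four Lifespace metrics for one participant
#'
#' Runs home inference (unless a home is supplied), trip detection, and the
#' daily summaries, and returns the per-participant metric row: furthest
#' distance from home, mean daily distance, percentage of recorded time at
#' home, and qualifying trips per recorded week.
#'
#' @param trace An [ls_trace()].
#' @param home Optional precomputed home; inferred from the trace when
#'   `NULL`.
#' @param config A [study_config()].
#' @return A one-row tibble: `participant_id`, `max_distance_km`,
#'   `mean_daily_distance_km`, `pct_time_at_home`, `trips_per_week`,
#'   `n_recorded_days`, `n_qualifying_trips`, `daily_distance_mode`.
#'   An empty trace yields a row of `NA` metrics.
#' @export
lifespace_metrics <- function(trace, home = NULL, config = study_config()) {
  id <- if (nrow(trace) > 0L) trace$participant_id[1L] else NA_character_
  if (nrow(trace) == 0L) {
    return(tibble::tibble(
      participant_id = id, max_distance_km = NA_real_,
      mean_daily_distance_km = NA_real_, pct_time_at_home = NA_real_,
      trips_per_week = NA_real_, n_recorded_days = 0L,
      n_qualifying_trips = NA_integer_,
      daily_distance_mode = config$daily_distance_mode))
  }
  if (is.null(home)) {
    home <- infer_home(trace, cell_size_deg = config$cell_size_deg)$home
  }
  home <- as_geo_point(home)
  trips <- detect_trips(trace, home,
                        fsm_config(radius_km = config$radius_km,
                                   min_trip_duration_min = config$min_trip_duration_min,
                                   count_open_trips = config$count_open_trips))
  sm <- daily_summaries(trace, home, radius_km = config$radius_km,
                        session_gap_s = config$session_gap_s,
                        tz = config$timezone)
  n_days <- recorded_days(trace, tz = config$timezone)
  n_trips <- count_qualifying_trips(trips, config$count_open_trips)
  tibble::tibble(
    participant_id = id,
    max_distance_km = max_distance(trace, home),
    mean_daily_distance_km = mean_daily_distance(sm, config$daily_distance_mode),
    pct_time_at_home = pct_time_at_home(sm),
    trips_per_week = trips_per_week(n_trips, n_days),
    n_recorded_days = n_days,
    n_qualifying_trips = as.integer(n_trips),
    daily_distance_mode = config$daily_distance_mode)
}
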