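#' Trip-detector configuration
#'
#' Constants of the two-state trip finite-state machine: the 500 m home
#' radius and the 15 min minimum trip duration that screens out false trips
#' arising from GPS inaccuracy.
#'
#' @param radius_km Home radius in kilometers (> 0).
#' @param min_trip_duration_min Minimum duration, in minutes, for a trip to
#'   qualify; shorter excursions are retained but flagged non-qualifying.
#' @param count_open_trips Whether trips without an observed departure from
#'   home or return to home (trace starting or ending away) enter counts.
#' @return A list of class `fsm_config`.
#' @export
fsm_config <- function(radius_km = 0.5, min_trip_duration_min = 15,
                       count_open_trips = FALSE) {
  stopifnot(radius_km > 0, min_trip_duration_min >= 0,
            is.logical(count_open_trips))
  structure(list(radius_km = radius_km,
                 min_trip_duration_min = min_trip_duration_min,
                 count_open_trips = count_open_trips),
            class = "fsm_config")
}

#' Detect trips to and from home
#'
#' Steps a two-state machine through the fixes in time order. The states are
#' SH (subject at home: within the radius) and SNH (subject not at home).
#' SH -> SNH fires at the first fix beyond the radius and records that fix's
#' timestamp as the departure; SNH -> SH fires at the first fix back within
#' the radius and records the return. Each closed SH -> SNH -> SH cycle is
#' one trip. Trips shorter than the minimum duration are emitted with
#' `qualifying = FALSE` rather than dropped, so time accounting and audits
#' stay consistent; counts use qualifying closed trips only.
#'
#' If the first fix is already beyond the radius the machine starts in SNH
#' with the first fix's timestamp as the departure, and that open-start trip
#' (like an open-end trip when the trace ends in SNH) is flagged
#' `closed = FALSE`. Recording gaps are passed through untouched: the
#' machine sees only fixes.
#'
#' @param trace An [ls_trace()].
#' @param home A [geo_point()] or `c(lat, lon)`.
#' @param config An [fsm_config()].
#' @return A tibble with one row per trip: `trip`, `depart_time`,
#'   `return_time` (`NA` for open-end trips), `duration_min`,
#'   `max_distance_km`, `qualifying`, `closed`. Empty trace -> zero rows.
#' @export
detect_trips <- function(trace, home, config = fsm_config()) {
  home <- as_geo_point(home)
  empty <- tibble::tibble(
    trip = integer(), depart_time = as.POSIXct(character(), tz = "UTC"),
    return_time = as.POSIXct(character(), tz = "UTC"),
    duration_min = numeric(), max_distance_km = numeric(),
    qualifying = logical(), closed = logical())
  n <- nrow(trace)
  if (n == 0L) return(empty)
  dist <- haversine_km(trace$lat, trace$lon, home[["lat"]], home[["lon"]])
  away <- dist > config$radius_km
  r <- rle(away)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_away_run <- which(r$values)
  if (length(is_away_run) == 0L) return(empty)

  t_num <- as.numeric(trace$time)
  depart <- t_num[starts[is_away_run]]
  ret_idx <- ends[is_away_run] + 1L            # first fix back within radius
  open_end <- ret_idx > n
  ret <- ifelse(open_end, NA_real_, t_num[pmin(ret_idx, n)])
  # open-end trips run to the last observed fix for duration purposes
  dur_min <- (ifelse(open_end, t_num[n], ret) - depart) / 60
  maxd <- vapply(is_away_run, function(k) max(dist[starts[k]:ends[k]]),
                 numeric(1))
  open_start <- starts[is_away_run] == 1L     # trace began beyond the radius
  tz <- attr(trace$time, "tzone") %||% "UTC"
  tibble::tibble(
    trip = seq_along(is_away_run),
    depart_time = as.POSIXct(depart, origin = "1970-01-01", tz = tz),
    return_time = as.POSIXct(ret, origin = "1970-01-01", tz = tz),
    duration_min = dur_min,
    max_distance_km = maxd,
    qualifying = dur_min >= config$min_trip_duration_min,
    closed = !open_start & !open_end
  )
}

#' Count qualifying trips
#'
#' @param trips A trip table from [detect_trips()].
#' @param count_open_trips Include open (unclosed) qualifying trips.
#' @return Integer count of qualifying trips.
#' @export
count_qualifying_trips <- function(trips, count_open_trips = FALSE) {
  if (nrow(trips) == 0L) return(0L)
  keep <- trips$qualifying & (trips$closed | count_open_trips)
  sum(keep)
}

#' Write a trip table to CSV
#'
#' @param trips A trip table from [detect_trips()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trips_csv <- function(trips, path) {
  fmt_t <- function(t) ifelse(is.na(t), "",
                              format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  lines <- c(
    "depart_time,return_time,duration_min,max_distance_km,qualifying,closed",
    sprintf("%s,%s,%.4f,%.6f,%s,%s",
            fmt_t(trips$depart_time), fmt_t(trips$return_time),
            trips$duration_min, trips$max_distance_km,
            tolower(trips$qualifying), tolower(trips$closed))
  )
  writeLines(lines, path)
  invisible(path)
}
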