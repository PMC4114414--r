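#' Construct a GPS trace
#'
#' A trace is one participant's time series of GPS fixes, stored as a tibble
#' with columns `participant_id`, `time` (POSIXct), `lat`, `lon`. On
#' construction the fixes are sorted by timestamp and duplicate timestamps
#' are collapsed to the last occurrence (devices occasionally re-emit a fix).
#'
#' @param participant_id Participant identifier (recycled if length one).
#' @param time POSIXct timestamps (any timezone; stored as given).
#' @param lat,lon Coordinates in decimal degrees WGS84.
#' @return A tibble of class `ls_trace`.
#' @export
ls_trace <- function(participant_id, time, lat, lon) {
  if (!inherits(time, "POSIXct")) {
    rlang::abort("`time` must be POSIXct.")
  }
  n <- length(time)
  if (n > 0L) validate_coords(lat, lon)
  tr <- tibble::tibble(
    participant_id = as.character(rep_len(participant_id, n)),
    time = time,
    lat = as.numeric(lat),
    lon = as.numeric(lon)
  )
  tr <- tr[order(tr$time), , drop = FALSE]
  if (n > 1L) {
    dup <- duplicated(tr$time, fromLast = TRUE)  # keep last record per stamp
    tr <- tr[!dup, , drop = FALSE]
  }
  class(tr) <- c("ls_trace", class(tr))
  tr
}

#' @export
print.ls_trace <- function(x, ...) {
  cat(sprintf("<ls_trace> %s: %d fixes", x$participant_id[1] %||% "?", nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf(" [%s .. %s]", format(min(x$time)), format(max(x$time))))
  }
  cat("\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Describe the layout of a trace CSV
#'
#' The column names and timestamp convention of trace CSV files are study
#' configuration, not something this package guesses. The default matches
#' the layout this package writes: `participant_id,timestamp,latitude,
#' longitude` with ISO-8601 UTC timestamps.
#'
#' @param col_id,col_time,col_lat,col_lon Column names.
#' @param tz Timezone the timestamps are interpreted in.
#' @param time_format Optional `strptime` format; when `NULL`, ISO-8601
#'   (`2011-12-01T09:30:00Z` or with a space) is parsed.
#' @return A list of class `trace_dialect`.
#' @export
trace_dialect <- function(col_id = "participant_id", col_time = "timestamp",
                          col_lat = "latitude", col_lon = "longitude",
                          tz = "UTC", time_format = NULL) {
  structure(list(col_id = col_id, col_time = col_time, col_lat = col_lat,
                 col_lon = col_lon, tz = tz, time_format = time_format),
            class = "trace_dialect")
}

parse_times <- function(x, dialect) {
  x <- trimws(as.character(x))
  if (!is.null(dialect$time_format)) {
    return(as.POSIXct(x, format = dialect$time_format, tz = dialect$tz))
  }
  x <- sub("Z$", "", x)
  x <- sub("T", " ", x, fixed = TRUE)
  as.POSIXct(x, format = "%Y-%m-%d %H:%M:%OS", tz = dialect$tz)
}

#' Read a GPS trace from CSV
#'
#' Rows with unparseable timestamps or out-of-range coordinates are dropped,
#' not fatal; the counts are attached as a load report
#' (`attr(trace, "load_report")`, also serializable via [jsonlite::toJSON]).
#'
#' @param path Path to a CSV file.
#' @param dialect A [trace_dialect()].
#' @param participant_id Overrides the id column (required if the file has
#'   no id column).
#' @return An [ls_trace()] with a `load_report` attribute listing
#'   `n_rows`, `n_kept`, `n_bad_time`, `n_bad_coord`, `n_dup_time`.
#' @export
read_trace_csv <- function(path, dialect = trace_dialect(),
                           participant_id = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  for (col in c(dialect$col_time, dialect$col_lat, dialect$col_lon)) {
    if (!col %in% names(raw)) {
      rlang::abort(sprintf("Column '%s' not found in %s.", col, path))
    }
  }
  n_rows <- nrow(raw)
  time <- parse_times(raw[[dialect$col_time]], dialect)
  lat <- suppressWarnings(as.numeric(raw[[dialect$col_lat]]))
  lon <- suppressWarnings(as.numeric(raw[[dialect$col_lon]]))
  bad_time <- is.na(time)
  bad_coord <- !bad_time &
    (is.na(lat) | is.na(lon) | lat < -90 | lat > 90 | lon < -180 | lon > 180)
  keep <- !bad_time & !bad_coord
  if (!any(keep)) {
    rlang::abort(sprintf("No valid GPS rows in %s.", path))
  }
  id <- participant_id %||%
    (if (dialect$col_id %in% names(raw)) raw[[dialect$col_id]][keep][1] else NA)
  if (is.na(id)) {
    rlang::abort("No participant id column found; supply `participant_id`.")
  }
  tr <- ls_trace(id, time[keep], lat[keep], lon[keep])
  attr(tr, "load_report") <- list(
    path = path, n_rows = n_rows, n_kept = nrow(tr),
    n_bad_time = sum(bad_time), n_bad_coord = sum(bad_coord),
    n_dup_time = sum(keep) - nrow(tr)
  )
  tr
}

#' Write a GPS trace to CSV
#'
#' Output is byte-deterministic: timestamps are ISO-8601 UTC to 1 s and
#' coordinates are fixed at 6 decimal places (~0.1 m), so a written trace
#' re-read with the default dialect round-trips within those precisions.
#'
#' @param trace An [ls_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  lines <- c(
    "participant_id,timestamp,latitude,longitude",
    sprintf("%s,%s,%.6f,%.6f",
            trace$participant_id,
            format(trace$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
            trace$lat, trace$lon)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a GPS trace from a GPX 1.1 file
#'
#' Track points (`<trkpt>`) from all segments are flattened, sorted, and
#' deduplicated like the CSV path. Every point must carry a `<time>` element
#' because the entire analysis is time-based.
#'
#' @param path Path to a GPX file.
#' @param participant_id Identifier for the resulting trace; defaults to the
#'   file name without extension.
#' @return An [ls_trace()].
#' @export
read_trace_gpx <- function(path, participant_id = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (length(pts) == 0L) {
    rlang::abort(sprintf("No track points in %s.", path))
  }
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  tnode <- xml2::xml_find_first(pts, "./time")
  tstr <- xml2::xml_text(tnode)
  if (any(is.na(tstr)) || any(!nzchar(tstr))) {
    rlang::abort("GPX track points without <time> elements; timestamps are mandatory.")
  }
  time <- parse_times(tstr, trace_dialect())
  if (any(is.na(time))) {
    rlang::abort("Unparseable <time> element in GPX file.")
  }
  id <- participant_id %||% sub("\\.[^.]*$", "", basename(path))
  ls_trace(id, time, lat, lon)
}

#' Segment a trace into recording sessions
#'
#' The study protocol produced intermittent recording (one 4-6 h charge
#' cycle per day), so a trace is a union of sessions separated by off
#' periods. A new session starts whenever the gap between consecutive fixes
#' is strictly greater than `session_gap_s`; a gap exactly equal to the
#' threshold does not split.
#'
#' @param trace An [ls_trace()].
#' @param session_gap_s Gap threshold in seconds (default 300: the phones
#'   sampled at about 1 Hz, so any gap well above that means the device or
#'   app was off, while 5 min tolerates brief GPS dropouts).
#' @return A tibble with columns `session`, `start`, `end`, `n_points`.
#' @export
segment_sessions <- function(trace, session_gap_s = 300) {
  stopifnot(session_gap_s > 0)
  n <- nrow(trace)
  if (n == 0L) {
    return(tibble::tibble(session = integer(), start = trace$time,
                          end = trace$time, n_points = integer()))
  }
  id <- session_index(trace$time, session_gap_s)
  starts <- tapply(as.numeric(trace$time), id, min)
  ends <- tapply(as.numeric(trace$time), id, max)
  tz <- attr(trace$time, "tzone") %||% "UTC"
  tibble::tibble(
    session = as.integer(names(starts)),
    start = as.POSIXct(as.numeric(starts), origin = "1970-01-01", tz = tz),
    end = as.POSIXct(as.numeric(ends), origin = "1970-01-01", tz = tz),
    n_points = as.integer(tabulate(id))
  )
}

# per-fix session index; split strictly-greater than the gap threshold
session_index <- function(time, session_gap_s) {
  if (length(time) == 0L) return(integer())
  gaps <- diff(as.numeric(time))
  cumsum(c(1L, as.integer(gaps > session_gap_s)))
}

#' Count distinct recorded calendar days
#'
#' @param trace An [ls_trace()].
#' @param tz Timezone in which calendar dates are taken (one per study; the
#'   default UTC must be overridden for real deployments).
#' @return Integer count of distinct local dates with at least one fix.
#' @export
recorded_days <- function(trace, tz = "UTC") {
  if (nrow(trace) == 0L) return(0L)
  length(unique(as.Date(trace$time, tz = tz)))
}

#' Read a participant metadata table
#'
#' Expected columns: `participant_id`, `group` (one of `PD`, `control`),
#' `age`, `gender`, `updrs_motor_baseline` (0-39), `updrs_nonmotor_baseline`
#' (0-12); optional end-of-study scores pass through untouched. Scores may
#' be missing (`NA`) for controls.
#'
#' @param path Path to a CSV file.
#' @return A tibble, one row per participant.
#' @export
read_participant_meta <- function(path) {
  meta <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  req <- c("participant_id", "group")
  miss <- setdiff(req, names(meta))
  if (length(miss) > 0L) {
    rlang::abort(sprintf("Metadata missing column(s): %s.",
                         paste(miss, collapse = ", ")))
  }
  if (!all(meta$group %in% c("PD", "control"))) {
    rlang::abort("`group` must be 'PD' or 'control'.")
  }
  check_score <- function(x, max, name) {
    if (!is.null(x) && any(!is.na(x) & (x < 0 | x > max))) {
      rlang::abort(sprintf("`%s` outside [0, %d].", name, max))
    }
  }
  check_score(meta$updrs_motor_baseline, 39L, "updrs_motor_baseline")
  check_score(meta$updrs_nonmotor_baseline, 12L, "updrs_nonmotor_baseline")
  meta$participant_id <- as.character(meta$participant_id)
  meta
}
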