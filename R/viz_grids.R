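#' Mean-subtracted scatter data
#'
#' The coordinate pairs behind a Lifespace scatterplot, in the
#' privacy-preserving mean-subtracted frame (see [mean_subtract()]). One
#' output row per fix; no absolute coordinates are emitted.
#'
#' @param trace An [ls_trace()].
#' @return A tibble with columns `dlat`, `dlon`.
#' @export
scatter_data <- function(trace) {
  mean_subtract(trace)
}

#' Dwell-time heatmap grid
#'
#' Bins a trace into a regular grid in the mean-subtracted frame and
#' accumulates dwell time: each within-session interval between consecutive
#' fixes is credited to the earlier fix's cell (the same left-constant
#' convention as the metrics), so irregular sampling does not distort the
#' map. The grid mass therefore equals the recorded in-period seconds
#' exactly. A point-count weighting is available as an option.
#'
#' @param trace An [ls_trace()].
#' @param period Optional POSIXct length-2 window `c(start, end)`
#'   (inclusive); `NULL` uses the full trace.
#' @param n_bins Bins per axis (default 100).
#' @param weight `"dwell"` (seconds, default) or `"count"` (fixes).
#' @param session_gap_s Session-splitting gap, seconds.
#' @param pad Fractional padding of the data bounding box (default 0.05).
#' @return A list of class `heat_grid`: `lat_edges`, `lon_edges` (length
#'   `n_bins + 1`, mean-subtracted degrees), `values` (n_bins x n_bins
#'   matrix, rows = latitude bins), `total`, `weight`, `n_points`, `empty`.
#'   An empty period yields an all-zero grid with `empty = TRUE` and a
#'   warning.
#' @export
heat_grid <- function(trace, period = NULL, n_bins = 100,
                      weight = c("dwell", "count"), session_gap_s = 300,
                      pad = 0.05) {
  weight <- match.arg(weight)
  stopifnot(n_bins >= 1)
  ms <- mean_subtract(trace)
  in_period <- if (is.null(period)) {
    rep_len(TRUE, nrow(trace))
  } else {
    stopifnot(inherits(period, "POSIXct"), length(period) == 2L)
    trace$time >= period[1L] & trace$time <= period[2L]
  }
  idx <- which(in_period)
  if (length(idx) == 0L) {
    rlang::warn("No fixes in the requested period; returning an empty grid.")
    edges <- seq(0, 1, length.out = n_bins + 1L)
    return(structure(list(lat_edges = edges, lon_edges = edges,
                          values = matrix(0, n_bins, n_bins), total = 0,
                          weight = weight, n_points = 0L, empty = TRUE),
                     class = "heat_grid"))
  }
  lat_edges <- padded_edges(ms$dlat[idx], n_bins, pad)
  lon_edges <- padded_edges(ms$dlon[idx], n_bins, pad)
  values <- matrix(0, n_bins, n_bins)
  if (weight == "dwell") {
    iv <- trace_intervals(trace, session_gap_s)
    keep <- in_period[iv$i]
    at <- iv$i[keep]
    w <- iv$dt[keep]
  } else {
    at <- idx
    w <- rep_len(1, length(idx))
  }
  if (length(at) > 0L) {
    bi <- bin_index(ms$dlat[at], lat_edges)
    bj <- bin_index(ms$dlon[at], lon_edges)
    for (k in seq_along(at)) {
      values[bi[k], bj[k]] <- values[bi[k], bj[k]] + w[k]
    }
  }
  structure(list(lat_edges = lat_edges, lon_edges = lon_edges,
                 values = values, total = sum(values), weight = weight,
                 n_points = length(idx), empty = FALSE),
            class = "heat_grid")
}

padded_edges <- function(x, n_bins, pad) {
  lo <- min(x)
  hi <- max(x)
  span <- hi - lo
  if (span == 0) span <- 1e-6           # degenerate extent: ~0.1 m box
  lo <- lo - pad * span
  hi <- hi + pad * span
  seq(lo, hi, length.out = n_bins + 1L)
}

bin_index <- function(x, edges) {
  n_bins <- length(edges) - 1L
  pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), n_bins)
}

#' @export
print.heat_grid <- function(x, ...) {
  cat(sprintf("<heat_grid> %dx%d bins, %s total %.0f, %d fixes%s\n",
              nrow(x$values), ncol(x$values), x$weight, x$total,
              x$n_points, if (x$empty) " (empty)" else ""))
  invisible(x)
}

#' Write a heatmap grid as flat JSON
#'
#' @param grid A [heat_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heat_grid_json <- function(grid, path) {
  jsonlite::write_json(
    list(lat_edges = grid$lat_edges, lon_edges = grid$lon_edges,
         values = grid$values, weight = grid$weight, total = grid$total),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Per-day recording timeline
#'
#' Splits recording sessions at local midnight and groups the resulting
#' intervals by calendar date, the data behind a recording-periods figure.
#'
#' @param sessions A session table from [segment_sessions()].
#' @param tz Timezone for calendar dates.
#' @return A tibble with columns `date`, `start`, `end`; intervals never
#'   cross midnight and do not overlap within a day.
#' @export
recording_timeline <- function(sessions, tz = "UTC") {
  if (nrow(sessions) == 0L) {
    return(tibble::tibble(date = as.Date(character()),
                          start = as.POSIXct(character(), tz = tz),
                          end = as.POSIXct(character(), tz = tz)))
  }
  rows <- lapply(seq_len(nrow(sessions)), function(k) {
    s <- as.numeric(sessions$start[k])
    e <- as.numeric(sessions$end[k])
    d1 <- as.Date(sessions$start[k], tz = tz)
    d2 <- as.Date(sessions$end[k], tz = tz)
    dates <- seq(d1, d2, by = "day")
    mids <- if (length(dates) > 1L) {
      as.numeric(as.POSIXct(paste(dates[-1L], "00:00:00"), tz = tz))
    } else {
      numeric()
    }
    bounds <- c(s, mids, e)
    lo <- bounds[-length(bounds)]
    hi <- bounds[-1L]
    keep <- hi >= lo
    tibble::tibble(
      date = dates[keep],
      start = as.POSIXct(lo[keep], origin = "1970-01-01", tz = tz),
      end = as.POSIXct(hi[keep], origin = "1970-01-01", tz = tz))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$date, .data$start)
}

#' Plot a dwell-time heatmap
#'
#' Thin ggplot2 rendering of a [heat_grid()]; the tested surface is the grid
#' itself. Axes are mean-subtracted degrees, so no absolute location is
#' shown.
#'
#' @param grid A [heat_grid()].
#' @param trans Scale transform for the fill (default `"sqrt"`).
#' @return A ggplot object.
#' @export
plot_heat_grid <- function(grid, trans = "sqrt") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    rlang::abort("Package 'ggplot2' is required for plotting.")
  }
  centers <- function(e) (e[-1L] + e[-length(e)]) / 2
  df <- expand.grid(dlat = centers(grid$lat_edges),
                    dlon = centers(grid$lon_edges))
  df$value <- as.vector(grid$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dlon, y = .data$dlat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans,
                                  name = if (grid$weight == "dwell")
                                    "dwell (s)" else "fixes") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude - mean (deg)", y = "latitude - mean (deg)")
}
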