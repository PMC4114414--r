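# Shared fixtures and independent oracles, built in code at test time.

KM_PER_DEG <- lifespace::EARTH_RADIUS_KM * pi / 180

HOME <- geo_point(40.0, -70.0)

# A trace whose fixes sit at prescribed distances (km) due north of `home`,
# at prescribed minute offsets from a fixed origin. Tangent-plane placement:
# along a meridian the haversine distance is exactly R * dphi, so the
# requested distances are realized to floating-point precision.
trace_at_distances <- function(minutes, dist_km, home = HOME, id = "t1") {
  t0 <- as.POSIXct("2012-01-10 09:00:00", tz = "UTC")
  ls_trace(id, t0 + minutes * 60,
           home[["lat"]] + dist_km / KM_PER_DEG,
           rep(home[["lon"]], length(minutes)))
}

# Random trace for FSM stress tests: a lazy random walk in distance-from-home
# with jumps, so at-home/away runs of many lengths occur, including traces
# that start and/or end away from home.
random_walk_trace <- function(n, home = HOME) {
  d <- numeric(n)
  d[1] <- stats::runif(1, 0, 3)
  for (i in seq_len(n)[-1]) {
    step <- stats::rnorm(1, 0, 0.15)
    if (stats::runif(1) < 0.02) step <- step + sample(c(-2, 2), 1)
    d[i] <- max(0, d[i - 1] + step)
  }
  gaps <- sample(c(10, 30, 60, 600), n, replace = TRUE)
  t0 <- as.POSIXct("2012-02-01 08:00:00", tz = "UTC")
  bearing <- stats::runif(n, 0, 2 * pi)
  ls_trace("rw", t0 + cumsum(gaps),
           home[["lat"]] + d * cos(bearing) / KM_PER_DEG,
           home[["lon"]] + d * sin(bearing) /
             (KM_PER_DEG * cos(home[["lat"]] * pi / 180)))
}

# Independent brute-force trip detector: explicitly materializes the SH/SNH
# state at every fix, one fix at a time. Deliberately naive; mirrors the
# stepping description, not the vectorized implementation.
fsm_oracle <- function(trace, home, config = fsm_config()) {
  n <- nrow(trace)
  out <- list()
  if (n == 0L) return(out)
  home <- c(lat = home[["lat"]], lon = home[["lon"]])
  d <- haversine_km(trace$lat, trace$lon, home[["lat"]], home[["lon"]])
  state <- if (d[1] > config$radius_km) "SNH" else "SH"
  open_start <- state == "SNH"
  depart <- if (state == "SNH") trace$time[1] else NULL
  maxd <- if (state == "SNH") d[1] else NULL
  i <- 2L
  while (i <= n) {
    if (state == "SH") {
      if (d[i] > config$radius_km) {
        state <- "SNH"
        depart <- trace$time[i]
        maxd <- d[i]
        open_start <- FALSE
      }
    } else {
      if (d[i] <= config$radius_km) {
        dur <- as.numeric(difftime(trace$time[i], depart, units = "mins"))
        out[[length(out) + 1L]] <- list(
          depart_time = depart, return_time = trace$time[i],
          duration_min = dur, max_distance_km = maxd,
          qualifying = dur >= config$min_trip_duration_min,
          closed = !open_start)
        state <- "SH"
      } else {
        maxd <- max(maxd, d[i])
      }
    }
    i <- i + 1L
  }
  if (state == "SNH") {
    dur <- as.numeric(difftime(trace$time[n], depart, units = "mins"))
    out[[length(out) + 1L]] <- list(
      depart_time = depart, return_time = as.POSIXct(NA),
      duration_min = dur, max_distance_km = maxd,
      qualifying = dur >= config$min_trip_duration_min, closed = FALSE)
  }
  out
}

expect_trips_match_oracle <- function(trace, home, config = fsm_config()) {
  got <- detect_trips(trace, home, config)
  want <- fsm_oracle(trace, home, config)
  expect_equal(nrow(got), length(want))
  for (k in seq_along(want)) {
    expect_equal(as.numeric(got$depart_time[k]),
                 as.numeric(want[[k]]$depart_time))
    expect_equal(as.numeric(got$return_time[k]),
                 as.numeric(want[[k]]$return_time))
    expect_equal(got$duration_min[k], want[[k]]$duration_min)
    expect_equal(got$max_distance_km[k], want[[k]]$max_distance_km)
    expect_identical(got$qualifying[k], want[[k]]$qualifying)
    expect_identical(got$closed[k], want[[k]]$closed)
  }
  invisible(got)
}

# Null distribution of U for group sizes (n1, n2), no ties, by full
# enumeration of group assignments.
mw_null_u <- function(n1, n2) {
  N <- n1 + n2
  apply(utils::combn(N, n1), 2, function(i) sum(i) - n1 * (n1 + 1) / 2)
}

# Exact permutation mid-p (two-sided: twice the smaller mid tail, capped at
# 1) at an observed U -- the quantity the uncorrected normal z estimates.
mw_exact_midp <- function(u_obs, u_all) {
  lo <- mean(u_all < u_obs - 1e-12) + mean(abs(u_all - u_obs) < 1e-12) / 2
  hi <- mean(u_all > u_obs + 1e-12) + mean(abs(u_all - u_obs) < 1e-12) / 2
  min(1, 2 * min(lo, hi))
}

# Small fast simulator settings for tests that need many replicates.
fast_sim <- function(...) {
  args <- list(n_days = 6, p_day_skipped = 0, sample_interval_s = 60,
               window_start_h = c(8, 10))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
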