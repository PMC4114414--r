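#' Simulation configuration for synthetic GPS traces
#'
#' Defaults emulate the study protocol the analysis assumes: one recording
#' window of 4-6 h per day (a phone charge cycle) over roughly eight weeks,
#' with some days recording nothing, out-and-back community trips from a
#' fixed home, and isotropic Gaussian GPS noise of about 10 m.
#'
#' @param n_days Length of the observation period in days.
#' @param start_date First calendar day of the period.
#' @param home True home location ([geo_point()]).
#' @param window_start_h Daily recording-window start, hours after local
#'   midnight, drawn uniformly from this range.
#' @param window_duration_h Window duration range in hours (default 4-6, a
#'   charge cycle).
#' @param sample_interval_s Seconds between fixes (default 10 to keep
#'   simulated traces light; 1 reproduces a 1 Hz study stream).
#' @param trips_per_day Mean trips per recorded day.
#' @param trip_count_mode `"poisson"` draws the daily count from a Poisson
#'   with that mean; `"fixed"` uses `round(trips_per_day)` every day.
#' @param trip_distance_meanlog,trip_distance_sdlog Log-normal parameters of
#'   the one-way trip distance (km).
#' @param trip_distance_range_km Hard clamp on trip distance; the lower
#'   bound (default 1.2 km) keeps destinations well clear of the 500 m home
#'   radius so that detected and true trips are comparable.
#' @param trip_dwell_min Range of dwell time at the destination, minutes.
#' @param travel_speed_kmh Range of (constant, straight-line) travel speed.
#' @param gps_noise_m Gaussian positional noise sigma in meters.
#' @param p_day_skipped Probability a day records nothing.
#' @param min_home_gap_min Minimum at-home time, minutes, between the window
#'   edges and a trip and between consecutive trips.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_days = 56,
                       start_date = as.Date("2011-12-01"),
                       home = geo_point(44.31, -69.78),
                       window_start_h = c(8, 14),
                       window_duration_h = c(4, 6),
                       sample_interval_s = 10,
                       trips_per_day = 1.0,
                       trip_count_mode = c("poisson", "fixed"),
                       trip_distance_meanlog = log(5),
                       trip_distance_sdlog = 0.6,
                       trip_distance_range_km = c(1.2, 60),
                       trip_dwell_min = c(20, 90),
                       travel_speed_kmh = c(20, 50),
                       gps_noise_m = 10,
                       p_day_skipped = 0.25,
                       min_home_gap_min = 20) {
  trip_count_mode <- match.arg(trip_count_mode)
  stopifnot(n_days >= 1, sample_interval_s >= 1, gps_noise_m >= 0,
            p_day_skipped >= 0, p_day_skipped < 1,
            trip_distance_range_km[1] > 0, min_home_gap_min > 0,
            diff(window_duration_h) >= 0, diff(travel_speed_kmh) >= 0)
  structure(as.list(environment()), class = "sim_config")
}

KM_PER_DEG_LAT <- EARTH_RADIUS_KM * pi / 180

#' Simulate one participant's GPS trace with ground truth
#'
#' For each non-skipped day a single recording window is drawn; within it
#' the participant dwells at the true home except during sampled
#' out-and-back trips (straight-line travel at constant speed to a
#' destination at a sampled bearing and distance, a dwell there, then the
#' return). Fixes are emitted at the configured interval with isotropic
#' Gaussian noise converted from meters to degrees in the local tangent
#' plane at the home latitude. Trips that cannot fit the remaining window
#' are re-sampled a bounded number of times, then dropped (counted in the
#' truth log). A given `(config, seed)` pair reproduces the output exactly.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this participant.
#' @param participant_id Identifier stamped into the trace.
#' @return A list with `trace` (an [ls_trace()]) and `truth`, a list of
#'   class `sim_truth`: `true_home`, `trips` (tibble: `date`, `depart`,
#'   `return`, `distance_km`, `speed_kmh`, `dwell_min`,
#'   `seconds_beyond_radius` for a 0.5 km radius), `windows` (tibble:
#'   `date`, `start`, `end`), totals `recorded_seconds` and
#'   `seconds_at_home`, `pct_time_at_home`, and `n_dropped_trips`.
#' @export
simulate_participant <- function(config = sim_config(), seed = 1L,
                                 participant_id = "sim01") {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  home_lat <- config$home[["lat"]]
  home_lon <- config$home[["lon"]]
  km_per_deg_lon <- KM_PER_DEG_LAT * cos(deg2rad(home_lat))

  times <- list(); lats <- list(); lons <- list()
  trips <- list(); windows <- list()
  n_dropped <- 0L
  total_window_s <- 0
  total_home_s <- 0

  for (day in seq_len(config$n_days) - 1L) {
    if (stats::runif(1) < config$p_day_skipped) next
    date <- config$start_date + day
    day0 <- as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = "UTC"))
    ws <- day0 + stats::runif(1, config$window_start_h[1],
                              config$window_start_h[2]) * 3600
    we <- ws + stats::runif(1, config$window_duration_h[1],
                            config$window_duration_h[2]) * 3600
    gap_s <- config$min_home_gap_min * 60

    n_trips <- switch(config$trip_count_mode,
                      poisson = stats::rpois(1, config$trips_per_day),
                      fixed = round(config$trips_per_day))
    cursor <- ws + gap_s
    day_trips <- list()
    for (k in seq_len(n_trips)) {
      placed <- FALSE
      for (attempt in 1:5) {
        d_km <- min(max(stats::rlnorm(1, config$trip_distance_meanlog,
                                      config$trip_distance_sdlog),
                        config$trip_distance_range_km[1]),
                    config$trip_distance_range_km[2])
        speed <- stats::runif(1, config$travel_speed_kmh[1],
                              config$travel_speed_kmh[2])
        dwell_s <- stats::runif(1, config$trip_dwell_min[1],
                                config$trip_dwell_min[2]) * 60
        travel_s <- d_km / speed * 3600
        trip_s <- 2 * travel_s + dwell_s
        latest <- we - gap_s - trip_s
        if (cursor <= latest) {
          t0 <- cursor + stats::runif(1, 0, min(3600, latest - cursor))
          bearing <- stats::runif(1, 0, 2 * pi)
          day_trips[[length(day_trips) + 1L]] <- list(
            t0 = t0, trip_s = trip_s, travel_s = travel_s,
            distance_km = d_km, speed_kmh = speed, dwell_s = dwell_s,
            bearing = bearing)
          cursor <- t0 + trip_s + gap_s
          placed <- TRUE
          break
        }
      }
      if (!placed) n_dropped <- n_dropped + 1L
    }

    fix_t <- seq(ws, we, by = config$sample_interval_s)
    lat <- rep(home_lat, length(fix_t))
    lon <- rep(home_lon, length(fix_t))
    for (tr in day_trips) {
      dest_dlat <- tr$distance_km * cos(tr$bearing) / KM_PER_DEG_LAT
      dest_dlon <- tr$distance_km * sin(tr$bearing) / km_per_deg_lon
      off <- fix_t - tr$t0
      on_trip <- off >= 0 & off < tr$trip_s
      frac <- numeric(sum(on_trip))
      o <- off[on_trip]
      frac <- ifelse(o < tr$travel_s, o / tr$travel_s,
                     ifelse(o < tr$travel_s + tr$dwell_s, 1,
                            (tr$trip_s - o) / tr$travel_s))
      lat[on_trip] <- home_lat + frac * dest_dlat
      lon[on_trip] <- home_lon + frac * dest_dlon
      # truth time beyond the 0.5 km radius: the out and back legs each
      # spend 0.5/speed hours inside it
      t500 <- 0.5 / tr$speed_kmh * 3600
      trips[[length(trips) + 1L]] <- tibble::tibble(
        date = date,
        depart = as.POSIXct(tr$t0, origin = "1970-01-01", tz = "UTC"),
        return = as.POSIXct(tr$t0 + tr$trip_s, origin = "1970-01-01",
                            tz = "UTC"),
        distance_km = tr$distance_km, speed_kmh = tr$speed_kmh,
        dwell_min = tr$dwell_s / 60,
        seconds_beyond_radius = tr$trip_s - 2 * t500)
    }
    if (config$gps_noise_m > 0) {
      lat <- lat + stats::rnorm(length(lat), 0,
                                config$gps_noise_m / 1000 / KM_PER_DEG_LAT)
      lon <- lon + stats::rnorm(length(lon), 0,
                                config$gps_noise_m / 1000 / km_per_deg_lon)
    }
    times[[length(times) + 1L]] <- fix_t
    lats[[length(lats) + 1L]] <- lat
    lons[[length(lons) + 1L]] <- lon
    windows[[length(windows) + 1L]] <- tibble::tibble(
      date = date,
      start = as.POSIXct(ws, origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(we, origin = "1970-01-01", tz = "UTC"))
    day_beyond <- sum(vapply(day_trips, function(tr)
      tr$trip_s - 2 * 0.5 / tr$speed_kmh * 3600, numeric(1)))
    total_window_s <- total_window_s + (we - ws)
    total_home_s <- total_home_s + (we - ws) - day_beyond
  }

  all_t <- as.POSIXct(unlist(times) %||% numeric(),
                      origin = "1970-01-01", tz = "UTC")
  trace <- ls_trace(participant_id, all_t,
                    unlist(lats) %||% numeric(), unlist(lons) %||% numeric())
  truth <- structure(list(
    true_home = config$home,
    trips = if (length(trips)) dplyr::bind_rows(trips) else tibble::tibble(
      date = as.Date(character()),
      depart = as.POSIXct(character(), tz = "UTC"),
      return = as.POSIXct(character(), tz = "UTC"),
      distance_km = numeric(), speed_kmh = numeric(), dwell_min = numeric(),
      seconds_beyond_radius = numeric()),
    windows = if (length(windows)) dplyr::bind_rows(windows) else
      tibble::tibble(date = as.Date(character()),
                     start = as.POSIXct(character(), tz = "UTC"),
                     end = as.POSIXct(character(), tz = "UTC")),
    recorded_seconds = total_window_s,
    seconds_at_home = total_home_s,
    pct_time_at_home = if (total_window_s > 0)
      100 * total_home_s / total_window_s else NA_real_,
    n_dropped_trips = n_dropped
  ), class = "sim_truth")
  list(trace = trace, truth = truth)
}

#' Simulate a two-group cohort with planted structure
#'
#' Draws per-participant child seeds deterministically from the master seed
#' and simulates a PD-like and a control-like group. Within the PD group the
#' trip rate is scaled by a descending sequence of multipliers and, when
#' `plant_severity` is `TRUE`, baseline UPDRS-style severity scores are
#' assigned so that severity increases as the planted trip rate decreases —
#' a planted monotone Lifespace-severity trend for downstream analyses to
#' recover.
#'
#' @param n_pd,n_control Group sizes (default 9 and 7).
#' @param cfg_pd,cfg_control Group-level [sim_config()]s.
#' @param seed Master seed.
#' @param pd_rate_multipliers Descending multipliers applied to
#'   `cfg_pd$trips_per_day` across PD participants.
#' @param plant_severity Assign severity scores anti-monotone to trip rate.
#' @return A list: `traces` (named list of [ls_trace()]), `truths` (named
#'   list of `sim_truth`), `meta` (tibble with `participant_id`, `group`,
#'   `age`, `gender`, `updrs_motor_baseline`, `updrs_nonmotor_baseline`,
#'   `planted_trips_per_day`).
#' @export
simulate_cohort <- function(n_pd = 9, n_control = 7,
                            cfg_pd = sim_config(),
                            cfg_control = sim_config(),
                            seed = 1L,
                            pd_rate_multipliers = seq(1.4, 0.6,
                                                      length.out = n_pd),
                            plant_severity = TRUE) {
  if (n_pd < 1 || n_control < 1) {
    rlang::abort("Both group sizes must be positive.")
  }
  stopifnot(length(pd_rate_multipliers) == n_pd)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- n_pd + n_control
  child_seeds <- sample.int(.Machine$integer.max, n)
  ages <- pmax(40L, pmin(85L, round(stats::rnorm(n, 58, 8))))
  genders <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.7, 0.3))

  ids <- c(sprintf("pd%02d", seq_len(n_pd)),
           sprintf("ct%02d", seq_len(n_control)))
  groups <- c(rep("PD", n_pd), rep("control", n_control))
  rates <- c(cfg_pd$trips_per_day * pd_rate_multipliers,
             rep(cfg_control$trips_per_day, n_control))

  motor <- rep(NA_real_, n)
  nonmotor <- rep(NA_real_, n)
  if (plant_severity) {
    # least-mobile PD participant gets the highest score (study range 5-23
    # motor, 0-6 nonmotor); strictly anti-monotone in the planted trip rate
    sev_rank <- rank(-pd_rate_multipliers, ties.method = "first")
    motor[seq_len(n_pd)] <- round(seq(5, 23, length.out = n_pd))[sev_rank]
    nonmotor[seq_len(n_pd)] <- round(seq(0, 6, length.out = n_pd))[sev_rank]
  }

  traces <- list(); truths <- list()
  for (i in seq_len(n)) {
    cfg <- if (groups[i] == "PD") cfg_pd else cfg_control
    cfg$trips_per_day <- rates[i]
    sim <- simulate_participant(cfg, seed = child_seeds[i],
                                participant_id = ids[i])
    traces[[ids[i]]] <- sim$trace
    truths[[ids[i]]] <- sim$truth
  }
  list(
    traces = traces,
    truths = truths,
    meta = tibble::tibble(
      participant_id = ids, group = groups, age = ages, gender = genders,
      updrs_motor_baseline = motor, updrs_nonmotor_baseline = nonmotor,
      planted_trips_per_day = rates)
  )
}
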