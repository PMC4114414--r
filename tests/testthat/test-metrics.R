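test_that("max distance from home is a simple maximum with NA when empty", {
  tr <- trace_at_distances(0:10, c(rep(0, 10), 67))
  expect_equal(max_distance(tr, HOME), 67, tolerance = 1e-9)
  empty <- ls_trace("p", as.POSIXct(character(), tz = "UTC"),
                    numeric(), numeric())
  expect_true(is.na(max_distance(empty, HOME)))
  # adding a fix never decreases the result
  tr2 <- trace_at_distances(0:11, c(rep(0, 10), 67, 12))
  expect_gte(max_distance(tr2, HOME), max_distance(tr, HOME))
})

test_that("daily summaries account distance and time per calendar date", {
  # stationary 1 h session at home
  tr <- trace_at_distances(0:60, rep(0, 61))
  sm <- daily_summaries(tr, HOME)
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$path_length_km, 0)
  expect_equal(sm$recorded_seconds, 3600)
  expect_equal(sm$seconds_at_home, 3600)

  # straight out-and-back, 5 km each way in one day: fixes every minute,
  # 1 km/min travel
  d <- c(0:5, 4:0)
  tr2 <- trace_at_distances(seq_along(d) - 1, d)
  sm2 <- daily_summaries(tr2, HOME)
  expect_equal(sm2$path_length_km, 10, tolerance = 1e-9)
  expect_equal(sm2$max_home_distance_km, 5, tolerance = 1e-9)

  # two days of data -> two summaries
  t0 <- as.POSIXct("2011-12-01 09:00:00", tz = "UTC")
  tr3 <- ls_trace("p", c(t0 + 0:10, t0 + 86400 + 0:10),
                  rep(40, 22), rep(-70, 22))
  expect_equal(nrow(daily_summaries(tr3, HOME)), 2L)
})

test_that("intervals spanning midnight are split between dates", {
  t0 <- as.POSIXct("2011-12-01 23:58:00", tz = "UTC")
  # fixes every 60 s for 4 min crossing midnight, all at home
  tr <- ls_trace("p", t0 + seq(0, 240, 60), rep(40, 5), rep(-70, 5))
  sm <- daily_summaries(tr, geo_point(40, -70))
  expect_equal(nrow(sm), 2L)
  expect_equal(sm$recorded_seconds, c(120, 120))
  expect_equal(sum(sm$seconds_at_home), 240)
})

test_that("percent time at home is interval-weighted over recorded time", {
  # 61 fixes a minute apart; first 30 intervals at home (left-constant)
  tr <- trace_at_distances(0:60, c(rep(0, 30), rep(2, 31)))
  sm <- daily_summaries(tr, HOME)
  expect_equal(pct_time_at_home(sm), 50)

  trh <- trace_at_distances(0:30, rep(0.2, 31))
  expect_equal(pct_time_at_home(daily_summaries(trh, HOME)), 100)

  # unaffected by a session split at an interior timestamp: additivity over
  # recorded time (the off-gap joins neither side)
  gap_mins <- c(0:30, 200 + 0:29)
  trg <- trace_at_distances(gap_mins, c(rep(0, 31), rep(2, 30)))
  smg <- daily_summaries(trg, HOME)
  expect_equal(sum(smg$recorded_seconds), (30 + 29) * 60)
  expect_equal(pct_time_at_home(smg), 100 * 30 / 59)

  expect_true(is.na(pct_time_at_home(daily_summaries(
    ls_trace("p", as.POSIXct(character(), tz = "UTC"), numeric(), numeric()),
    HOME))))
})

test_that("mean daily distance averages the chosen per-day field", {
  sm <- tibble::tibble(date = as.Date("2011-12-01") + 0:1,
                       path_length_km = c(4, 6),
                       max_home_distance_km = c(2, 3),
                       recorded_seconds = c(3600, 3600),
                       seconds_at_home = c(0, 0))
  expect_equal(mean_daily_distance(sm), 5)
  expect_equal(mean_daily_distance(sm, "max_home_distance"), 2.5)
  expect_equal(mean_daily_distance(sm[1, ]), 4)
  # duplicating every day leaves the mean unchanged
  expect_equal(mean_daily_distance(rbind(sm, sm)), 5)
  expect_true(is.na(mean_daily_distance(sm[0, ])))
})

test_that("per-day path length dominates the furthest home distance when the day starts at home", {
  set.seed(77)
  for (rep in 1:10) {
    d <- c(0, abs(cumsum(rnorm(99, 0, 0.5))))  # starts at home
    tr <- trace_at_distances(seq_along(d) - 1, d)
    sm <- daily_summaries(tr, HOME)
    expect_gte(sm$path_length_km + 1e-9, sm$max_home_distance_km)
  }
})

test_that("trips per week normalizes by recorded days", {
  expect_equal(trips_per_week(12, 14), 6)
  expect_equal(trips_per_week(0, 10), 0)
  expect_equal(trips_per_week(1, 7), 1)
  expect_true(is.na(trips_per_week(3, 0)))
})

test_that("metrics are invariant to fix order and undefined when empty", {
  set.seed(10)
  mins <- 0:199
  d <- abs(cumsum(rnorm(200, 0, 0.3)))
  p <- sample(200)
  m1 <- lifespace_metrics(trace_at_distances(mins, d))
  m2 <- lifespace_metrics(trace_at_distances(mins[p], d[p]))
  expect_equal(m1, m2)

  empty <- ls_trace("p", as.POSIXct(character(), tz = "UTC"),
                    numeric(), numeric())
  me <- lifespace_metrics(empty)
  expect_true(is.na(me$max_distance_km))
  expect_true(is.na(me$pct_time_at_home))
  expect_equal(me$n_recorded_days, 0L)
})
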