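test_that("home is the modal grid cell's point mean", {
  t0 <- as.POSIXct("2011-12-01 09:00:00", tz = "UTC")
  # 100 fixes at exactly (40, -70), 5 fixes ~1 km north
  tr <- ls_trace("p", t0 + 0:104,
                 c(rep(40, 100), rep(40 + 1 / KM_PER_DEG, 5)),
                 rep(-70, 105))
  h <- infer_home(tr)
  expect_equal(unname(h$home[["lat"]]), 40)
  expect_equal(unname(h$home[["lon"]]), -70)
  expect_equal(h$support, 100L)
  expect_equal(h$support_fraction, 100 / 105)

  # single fix
  tr1 <- ls_trace("p", t0, 40.123456, -70.654321)
  h1 <- infer_home(tr1)
  expect_equal(unname(h1$home[["lat"]]), 40.123456)
  expect_equal(h1$support_fraction, 1)

  empty <- ls_trace("p", as.POSIXct(character(), tz = "UTC"),
                    numeric(), numeric())
  expect_error(infer_home(empty), "empty")
})

test_that("cell ties break to the lexicographically smallest index pair", {
  t0 <- as.POSIXct("2011-12-01 09:00:00", tz = "UTC")
  cell <- 1e-4
  # two cells, 50 fixes each, centers well inside each cell; cell A has the
  # smaller latitude index
  lat_a <- 40 + 0.5 * cell; lat_b <- 40 + 5.5 * cell
  build <- function(first_b) {
    lats <- if (first_b) c(rep(lat_b, 50), rep(lat_a, 50))
            else c(rep(lat_a, 50), rep(lat_b, 50))
    ls_trace("p", t0 + 0:99, lats, rep(-70 + 0.5 * cell, 100))
  }
  h1 <- infer_home(build(FALSE))
  h2 <- infer_home(build(TRUE))
  expect_equal(unname(h1$home[["lat"]]), lat_a)
  # arrival order of the fixes must not matter
  expect_equal(unname(h2$home[["lat"]]), lat_a)
  expect_equal(h1$modal_cell, h2$modal_cell)

  # same tie on the longitude index
  lon_a <- -70 + 0.5 * cell; lon_b <- -70 + 3.5 * cell
  tr <- ls_trace("p", t0 + 0:99, rep(lat_a, 100),
                 c(rep(lon_b, 50), rep(lon_a, 50)))
  expect_equal(unname(infer_home(tr)$home[["lon"]]), lon_a)
})

test_that("home recovery on noisy synthetic dwell is within 50 m", {
  for (seed in 1:5) {
    sim <- simulate_participant(fast_sim(trips_per_day = 1.2), seed = seed)
    h <- infer_home(sim$trace)
    err_m <- 1000 * haversine_km(h$home[["lat"]], h$home[["lon"]],
                                 sim$truth$true_home[["lat"]],
                                 sim$truth$true_home[["lon"]])
    expect_lt(err_m, 50)
    # most of the window is home dwell in these configs
    expect_gt(sim$truth$seconds_at_home / sim$truth$recorded_seconds, 0.3)
  }
})

test_that("at-home mask follows the radius with an inclusive boundary", {
  tr <- trace_at_distances(c(0, 1, 2), c(0, 0.4, 0.6))
  m <- at_home_mask(tr, HOME)
  expect_identical(m, c(TRUE, TRUE, FALSE))

  # a fix at exactly the radius counts as at home: set the radius to the
  # bit-exact computed distance of a fix
  tr1 <- trace_at_distances(0, 0.5)
  d <- distance_from_home(tr1, HOME)$distance_km
  expect_true(at_home_mask(tr1, HOME, radius_km = d))

  # monotone in radius: enlarging never turns TRUE -> FALSE
  set.seed(21)
  trw <- random_walk_trace(300)
  m1 <- at_home_mask(trw, HOME, radius_km = 0.5)
  m2 <- at_home_mask(trw, HOME, radius_km = 0.8)
  expect_true(all(m2 | !m1))
})

test_that("mean subtraction centers the trace and keeps its shape", {
  t0 <- as.POSIXct("2011-12-01 09:00:00", tz = "UTC")
  tr <- ls_trace("p", t0 + 0:1, c(40.01, 39.99), c(-69.99, -70.01))
  ms <- mean_subtract(tr)
  expect_equal(ms$dlat, c(0.01, -0.01))
  expect_equal(ms$dlon, c(0.01, -0.01))

  trc <- ls_trace("p", t0 + 0:9, rep(40, 10), rep(-70, 10))
  expect_true(all(mean_subtract(trc)$dlat == 0))

  set.seed(4)
  trr <- random_walk_trace(500)
  msr <- mean_subtract(trr)
  expect_lt(abs(mean(msr$dlat)), 1e-9)
  expect_lt(abs(mean(msr$dlon)), 1e-9)
  expect_equal(nrow(msr), nrow(trr))

  empty <- ls_trace("p", as.POSIXct(character(), tz = "UTC"),
                    numeric(), numeric())
  expect_equal(nrow(mean_subtract(empty)), 0L)
})
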