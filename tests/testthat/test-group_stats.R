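test_that("group summaries use the linear-interpolation quantile convention", {
  s <- summarize_group(c(1, 2, 3, 4, 5), rep("PD", 5))
  expect_equal(s$median, 3)
  expect_equal(s$q25, 2)
  expect_equal(s$q75, 4)

  s1 <- summarize_group(7, "control")
  expect_equal(c(s1$median, s1$q25, s1$q75), c(7, 7, 7))

  s2 <- summarize_group(c(1, NA, 3), rep("PD", 3))
  expect_equal(s2$median, 2)
  expect_equal(s2$n_excluded, 1L)

  # order invariance
  set.seed(2)
  v <- rnorm(9)
  expect_equal(summarize_group(v, rep("PD", 9)),
               summarize_group(sample(v), rep("PD", 9)))

  expect_error(summarize_group(c(NA, 1), c("PD", "control")), "PD")
})

test_that("Mann-Whitney U follows the stamped conventions", {
  mw <- mann_whitney(1:3, 4:6)
  expect_equal(mw$U, 0)             # sample 1 wins nothing
  expect_lt(mw$z, 0)
  expect_false(mw$tie_correction_applied)

  # identical multisets: z = 0 after midranks
  mw0 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw0$z, 0)
  expect_equal(mw0$p_two_sided, 1)
  expect_true(mw0$tie_correction_applied)

  # swapping samples maps U -> n1 n2 - U and z -> -z
  set.seed(6)
  x <- rnorm(8); y <- rnorm(6, 0.5)
  a <- mann_whitney(x, y); b <- mann_whitney(y, x)
  expect_equal(b$U, a$n1 * a$n2 - a$U)
  expect_equal(b$z, -a$z)
  expect_equal(b$p_two_sided, a$p_two_sided)

  expect_error(mann_whitney(rep(2, 4), rep(2, 5)), "Degenerate")
})

test_that("Mann-Whitney agrees with the reference implementation", {
  set.seed(19)
  for (rep in 1:20) {
    x <- round(rnorm(sample(3:10, 1)), 1)  # rounding induces ties
    y <- round(rnorm(sample(3:10, 1), 0.4), 1)
    if (length(unique(c(x, y))) < 2) next
    mw <- mann_whitney(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(mw$U, unname(ref$statistic))
    expect_equal(mw$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal-approximation p tracks the exact permutation mid-p", {
  # spot checks on random no-tie samples; the exhaustive all-U sweep over
  # small group sizes runs in the acceptance suite
  set.seed(30)
  for (rep in 1:10) {
    x <- rnorm(sample(3:7, 1)); y <- rnorm(sample(3:7, 1))
    mw <- mann_whitney(x, y)
    u_all <- mw_null_u(length(x), length(y))
    expect_lt(abs(mw$p_two_sided - mw_exact_midp(mw$U, u_all)), 0.05)
  }
  # the 3-vs-3 full-separation case has exact one-sided p 1/20
  u_all <- mw_null_u(3, 3)
  expect_equal(mean(u_all <= 0), 1 / 20)
  expect_equal(mann_whitney(1:3, 4:6)$U, 0)
})

test_that("severity ordering sorts by summed baseline subscales", {
  meta <- tibble::tibble(
    participant_id = c("pd1", "pd2", "pd3", "ct1"),
    group = c("PD", "PD", "PD", "control"),
    updrs_motor_baseline = c(9, 5, 23, NA),
    updrs_nonmotor_baseline = c(0, 0, 0, NA))
  metrics <- tibble::tibble(
    participant_id = c("pd1", "pd2", "pd3", "ct1"),
    max_distance_km = 1:4)
  so <- severity_order(meta, metrics)
  expect_equal(so$participant_id, c("pd2", "pd1", "pd3"))

  # tie on the score: participant_id order
  meta$updrs_motor_baseline <- c(9, 9, 23, NA)
  so2 <- severity_order(meta, metrics)
  expect_equal(so2$participant_id[1:2], c("pd1", "pd2"))

  # missing score: listed last with a flag, not dropped
  meta$updrs_motor_baseline <- c(9, NA, 23, NA)
  so3 <- severity_order(meta, metrics)
  expect_equal(nrow(so3), 3L)
  expect_equal(so3$participant_id[3], "pd2")
  expect_true(so3$severity_missing[3])

  # singleton
  so4 <- severity_order(meta[meta$participant_id == "pd1", ], metrics)
  expect_equal(nrow(so4), 1L)
})

test_that("group comparison produces one test row per metric", {
  set.seed(55)
  metrics <- tibble::tibble(
    participant_id = c(sprintf("pd%d", 1:5), sprintf("ct%d", 1:4)),
    max_distance_km = c(rnorm(5, 50, 10), rnorm(4, 80, 10)),
    mean_daily_distance_km = rnorm(9, 10),
    pct_time_at_home = runif(9, 30, 70),
    trips_per_week = rpois(9, 5) + runif(9, 0, 0.1))
  meta <- tibble::tibble(participant_id = metrics$participant_id,
                         group = rep(c("PD", "control"), c(5, 4)))
  cmp <- compare_groups(metrics, meta)
  expect_equal(nrow(cmp$tests), 4L)
  expect_equal(nrow(cmp$summary), 8L)
  expect_true(all(cmp$summary$q25 <= cmp$summary$median &
                    cmp$summary$median <= cmp$summary$q75))

  # identical groups -> z exactly 0 for every metric
  metrics2 <- metrics[c(1:4, 6:9), ]
  metrics2[5:8, -1] <- metrics2[1:4, -1]
  cmp2 <- compare_groups(metrics2, meta[c(1:4, 6:9), ])
  expect_true(all(cmp2$tests$z == 0))

  expect_error(compare_groups(metrics, meta[meta$group == "PD", ]), "group")
})
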