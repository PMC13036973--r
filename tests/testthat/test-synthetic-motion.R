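test_that("generated sessions have the right shape and are seed-deterministic", {
  s <- generate_session(60, scenario_mix = c(steady_running = 1),
                        injury_rate = 0, seed = 7)
  expect_equal(nrow(s$data), 60 * 200)
  expect_equal(nrow(s$events), 0L)
  expect_identical(s$data, generate_session(
    60, scenario_mix = c(steady_running = 1), injury_rate = 0, seed = 7)$data)

  s2 <- generate_session(30, seed = 12)
  expect_identical(s2$data, generate_session(30, seed = 12)$data)
})

test_that("segments are ordered, non-overlapping, and NA appears only in dropout", {
  s <- generate_session(40, seed = 5)
  segs <- s$segments
  expect_true(all(segs$end_s > segs$start_s))
  if (nrow(segs) > 1L) {
    expect_true(all(segs$start_s[-1] >= segs$end_s[-nrow(segs)] - 1e-9))
  }
  # NA only inside recorded dropout intervals
  t <- s$data$time_s
  for (ch in s$channels) {
    na_idx <- which(is.na(s$data[[ch]]))
    if (!length(na_idx)) next
    dr <- s$dropout[s$dropout$channel == ch, ]
    covered <- rep(FALSE, length(na_idx))
    for (i in seq_len(nrow(dr))) {
      covered <- covered | (t[na_idx] >= dr$start_s[i] &
                              t[na_idx] < dr$end_s[i])
    }
    expect_true(all(covered))
  }
})

test_that("injury-type draws follow the configured proportions", {
  withr::with_seed(1, {
    draws <- sample_injury_types(10000)
  })
  frac <- mean(draws == "inversion")
  expect_lt(abs(frac - 0.625), 0.015)
  # chi-squared goodness of fit, alpha = 0.01
  props <- injury_type_proportions() / sum(injury_type_proportions())
  tab <- table(factor(draws, levels = names(props)))
  p <- suppressWarnings(stats::chisq.test(tab, p = props)$p.value)
  expect_gt(p, 0.01)
})

test_that("generator rejects invalid inputs", {
  expect_error(generate_session(0, seed = 1), "positive")
  expect_error(generate_session(-5, seed = 1), "positive")
  expect_error(generate_session(10, scenario_mix = c(steady_running = 0.9),
                                seed = 1), "sum to 1")
  expect_error(generate_session(10, scenario_mix = c(bad_name = 1), seed = 1),
               "unknown scenario")
})

test_that("injected injuries ramp the targeted axis and are additive", {
  base <- generate_session(10, scenario_mix = c(steady_running = 1),
                           injury_rate = 0, seed = 3)
  s <- inject_injury_event(base, time_s = 5.0, itype = "inversion",
                           drift_window_s = 0.5)
  t <- s$data$time_s
  rms <- function(x, lo, hi) sqrt(mean(x[t >= lo & t < hi]^2))
  expect_gt(rms(s$data$gyro_x, 4.5, 5.0), rms(s$data$gyro_x, 4.0, 4.5))
  expect_equal(nrow(s$events), 1L)

  # degenerate drift window: only the event sample changes
  s0 <- inject_injury_event(base, time_s = 5.0, itype = "rotational",
                            drift_window_s = 0)
  changed <- which(s0$data$gyro_z != base$data$gyro_z)
  expect_length(changed, 1L)

  # additivity/locality: two disjoint injections equal the sum of singles
  sA <- inject_injury_event(base, 3.0, "impact", drift_window_s = 0.4)
  sB <- inject_injury_event(base, 7.0, "rotational", drift_window_s = 0.4)
  sAB <- inject_injury_event(sA, 7.0, "rotational", drift_window_s = 0.4)
  expect_equal(nrow(sAB$events), 2L)
  for (ch in base$channels) {
    expect_equal(sAB$data[[ch]],
                 sA$data[[ch]] + sB$data[[ch]] - base$data[[ch]],
                 tolerance = 1e-12)
  }
})

test_that("injury injection validates its preconditions", {
  base <- generate_session(5, injury_rate = 0, seed = 2)
  expect_error(inject_injury_event(base, 9.0, "inversion"), "outside")
  expect_error(inject_injury_event(base, 0.1, "inversion",
                                   drift_window_s = 0.5), "before the start")
  expect_error(inject_injury_event(base, 2, "sprain"), "unknown injury type")
})

test_that("sensor dropout flags exactly the requested samples, unions overlap", {
  s <- generate_session(10, scenario_mix = c(steady_running = 1),
                        injury_rate = 0, seed = 4)
  d <- inject_sensor_dropout(s, "gyro_x", 2, 3)
  expect_equal(sum(is.na(d$data$gyro_x)), 200L)
  expect_equal(nrow(d$dropout), 1L)

  d0 <- inject_sensor_dropout(s, "gyro_x", 2, 2)
  expect_equal(sum(is.na(d0$data$gyro_x)), 0L)

  # overlapping dropouts flag the union of intervals
  d2 <- inject_sensor_dropout(d, "gyro_x", 2.5, 3.5)
  t <- d2$data$time_s
  in_union <- t >= 2 & t < 3.5  # interval-union oracle
  expect_equal(which(is.na(d2$data$gyro_x)), which(in_union))

  expect_error(inject_sensor_dropout(s, "nope", 1, 2), "unknown channel")
  expect_error(inject_sensor_dropout(s, "gyro_x", -1, 2), "inside the session")
})

test_that("steady running and jump landing windows are separable by variance features", {
  mk <- function(scn, seed) {
    s <- generate_session(30, scenario_mix = stats::setNames(1, scn),
                          injury_rate = 0, seed = seed)
    segment_windows(s)
  }
  run <- mk("steady_running", 21)
  jump <- mk("jump_landing", 22)
  # variance of first differences isolates the broadband landing content
  # from the smooth low-frequency gait carrier
  feat <- function(w) t(vapply(w$x, function(m) {
    c(var(diff(m[, 3])), mean(abs(diff(m[, 1]))))
  }, numeric(2)))
  X <- rbind(feat(run), feat(jump))
  y <- rep(c(0, 1), c(nrow(run), nrow(jump)))
  # variance-threshold classifier on the better single feature
  acc <- max(vapply(1:2, function(j) {
    th <- median(X[, j])
    max(mean((X[, j] > th) == y), mean((X[, j] <= th) == y))
  }, numeric(1)))
  expect_gt(acc, 0.9)
})

test_that("bilateral and magnetometer configurations extend the channel set", {
  s <- generate_session(5, seed = 9, bilateral = TRUE, magnetometer = TRUE,
                        injury_rate = 0)
  expect_length(s$channels, 18L)
  expect_true(all(c("left_acc_x", "right_mag_z") %in% s$channels))
})
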