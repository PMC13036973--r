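# Minimal session_run constructor for enumerated metric tests. Alerts are
# given as alert *times* (window start + window length = time the alert is
# available); rows are placed exactly at those times.
toy_run <- function(event_times, alert_times, duration_s = 30,
                    itype = "inversion") {
  filler <- seq(0, duration_s - 0.2, by = 1)          # non-alert rows
  starts <- sort(c(filler, alert_times - 0.2))
  alert <- starts %in% (alert_times - 0.2)
  logs <- tibble::tibble(
    window = seq_along(starts), start_s = starts, alpha = 0.5, beta = 0.4,
    p_risk = 0.1, decision = "no_risk", risk_forecast = 0.1, alert = alert,
    cpu = 0.5, energy = 1, latency = 10,
    inference_macs = 1000, adaptation_macs = 100,
    action = NA_integer_, degraded = FALSE)
  structure(list(
    logs = logs,
    events = tibble::tibble(time_s = event_times,
                            itype = rep_len(itype, length(event_times)),
                            side = "left"),
    mode = "full", tau = 0.6), class = "session_run")
}

test_that("IDA counts events with alerts inside the match window", {
  # alerts at offsets -200 ms and -50 ms match; +400 ms is outside the
  # [-1000, +100] ms window; the fourth event has no alert at all
  run <- toy_run(event_times = c(5, 10, 15, 20),
                 alert_times = c(5 - 0.2, 10 - 0.05, 15 + 0.4))
  det <- detection_records(run)
  expect_equal(compute_ida(det), 50)
  expect_equal(det$records$detected, c(TRUE, TRUE, FALSE, FALSE))

  all_hit <- toy_run(c(5, 10), c(4.8, 9.8))
  expect_equal(compute_ida(detection_records(all_hit)), 100)
  none <- toy_run(numeric(0), c(3.2))
  expect_error(compute_ida(detection_records(none)), "no injury events")
})

test_that("FAR uses merged alert episodes over a per-alert denominator", {
  # two alert windows 100 ms apart on one event collapse to one episode
  run <- toy_run(event_times = 5, alert_times = c(4.7, 4.8, 12.2, 20.2))
  det <- detection_records(run)
  expect_equal(nrow(det$alerts), 3L)          # merge-then-match oracle
  expect_equal(compute_far(det), 100 * 2 / 3)

  clean <- toy_run(5, c(4.7))
  expect_equal(compute_far(detection_records(clean)), 0)
  expect_warning(far0 <- compute_far(detection_records(toy_run(5, numeric(0)))),
                 "no alerts")
  expect_equal(far0, 0)
})

test_that("APA counts leads of at least 150 ms inclusively", {
  # leads 200, 160, 100 ms and one miss -> 50 %
  run <- toy_run(event_times = c(5, 10, 15, 20),
                 alert_times = c(5 - 0.2, 10 - 0.16, 15 - 0.1))
  det <- detection_records(run)
  expect_equal(sort(det$records$lead_ms[1:3]), c(100, 160, 200),
               tolerance = 1e-9)
  expect_equal(compute_apa(det), 50)
  # inclusive boundary: all leads exactly 150 ms
  b <- toy_run(c(5, 10), c(5 - 0.15, 10 - 0.15))
  expect_equal(compute_apa(detection_records(b)), 100)
  # threshold 0 restricts IDA to pre-event alerts
  expect_equal(compute_apa(det, lead_threshold_ms = 0), 75)
  expect_lte(compute_apa(det), compute_ida(det))
})

test_that("adaptation overhead is the adaptation share of total MACs", {
  logs <- tibble::tibble(inference_macs = c(500, 418),
                         adaptation_macs = c(50, 32))
  expect_equal(compute_adaptation_overhead(logs), 8.2)
  z <- tibble::tibble(inference_macs = c(100), adaptation_macs = c(0))
  expect_equal(compute_adaptation_overhead(z), 0)
  # ratio is stationary in session length for a stationary workload
  rep_logs <- logs[rep(1:2, 50), ]
  expect_lt(abs(compute_adaptation_overhead(rep_logs) -
                  compute_adaptation_overhead(logs)), 0.1)
})

test_that("paired comparisons detect a known shift and respect pairing", {
  ident <- paired_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_true(ident$tie)
  expect_false(ident$significant)

  withr::with_seed(2, {
    base <- rnorm(30)
    shifted <- base + 1 + rnorm(30, sd = 0.1)  # shift 1, difference sd 0.1
    res <- paired_comparison(shifted, base, alpha = 0.01, corrections = 4L)
    expect_true(res$significant)
    expect_equal(res$alpha_adjusted, 0.01 / 4)
    perm <- sample(30)
    res2 <- paired_comparison(shifted[perm], base[perm], corrections = 4L)
    expect_equal(res2$t, res$t, tolerance = 1e-12)
  })
  expect_error(paired_comparison(1, 1), ">= 2 pairs")
})

test_that("risk-outcome correlation behaves at the limits", {
  r <- correlation_risk_vs_outcome(c(0.1, 0.5, 0.9, 0.3), c(0.1, 0.5, 0.9, 0.3))
  expect_equal(r$r, 1)
  withr::with_seed(9, {
    a <- rnorm(1000); b <- rnorm(1000)
    expect_lt(abs(correlation_risk_vs_outcome(a, b)$r), 0.1)
  })
  x <- c(0.2, 0.4, 0.9, 0.1); y <- c(0, 1, 1, 0)
  expect_equal(correlation_risk_vs_outcome(-x, y)$r,
               -correlation_risk_vs_outcome(x, y)$r, tolerance = 1e-12)
  expect_error(correlation_risk_vs_outcome(c(1, 1, 1), c(0, 1, 0)),
               "zero variance")
  expect_error(correlation_risk_vs_outcome(c(1, 2), c(0, 1)), "at least 3")
})

test_that("metrics recomputed from logs are consistent and bounded", {
  models <- fixture_models()
  prep <- fixture_prep()
  sets <- if (length(prep$test_sets)) prep$test_sets else prep$train_sets
  runs <- purrr::map(sets, run_session, models = models, mode = "full")
  rep <- evaluate_sessions(runs)
  expect_true(rep$far_pct >= 0 && rep$far_pct <= 100)
  if (!is.na(rep$ida_pct)) {
    expect_true(rep$ida_pct >= 0 && rep$ida_pct <= 100)
    expect_lte(rep$apa150_pct, rep$ida_pct)
  }
  expect_s3_class(rep$by_injury_type, "tbl_df")
  expect_s3_class(rep$by_scenario, "tbl_df")
  # replaying the same logs reproduces the metrics
  rep2 <- evaluate_sessions(runs)
  expect_equal(tidy(rep2), tidy(rep))
  td <- tidy(rep)
  expect_named(td, c("metric", "value"))
})

test_that("the trade-off sweep produces a full, reproducible, non-empty grid", {
  models <- fixture_models()
  prep <- fixture_prep()
  tr <- prep$train_sets[1]
  ev <- prep$train_sets[length(prep$train_sets)]
  sw <- tradeoff_sweep(tr, ev, models, eps_values = c(0.05, 0.2),
                       hidden_widths = c(8L, 16L), episodes = 2L, seed = 5L)
  expect_equal(nrow(sw), 4L)
  sw2 <- tradeoff_sweep(tr, ev, models, eps_values = c(0.05, 0.2),
                        hidden_widths = c(8L, 16L), episodes = 2L, seed = 5L)
  expect_equal(sw, sw2)
  expect_true(any(sw$nondominated))
  # non-dominated rows are genuinely non-dominated
  for (i in which(sw$nondominated)) {
    expect_false(any(sw$accuracy > sw$accuracy[i] &
                       sw$latency_proxy < sw$latency_proxy[i]))
  }
})
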