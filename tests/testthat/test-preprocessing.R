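test_that("bias/scale correction applies (x - bias) * scale and round-trips", {
  s <- generate_session(5, injury_rate = 0, seed = 1)
  calib <- calibration_params(s$channels, bias = 0, scale = 1)
  expect_equal(correct_bias_scale(s, calib)$data, s$data)

  one <- s
  one$data$acc_x[] <- 2.0
  c2 <- calibration_params(s$channels, bias = 0.5, scale = 2)
  expect_equal(correct_bias_scale(one, c2)$data$acc_x[1], 3.0)

  # algebraic inverse round trip: y = (x - b) s  =>  x = (y - (-b s)) (1/s)
  set.seed(2)
  b <- runif(6, -1, 1); sc <- runif(6, 0.5, 2)
  fwd <- calibration_params(s$channels, b, sc)
  inv <- calibration_params(s$channels, bias = -b * sc, scale = 1 / sc)
  rt <- correct_bias_scale(correct_bias_scale(s, fwd), inv)
  for (ch in s$channels) expect_equal(rt$data[[ch]], s$data[[ch]],
                                      tolerance = 1e-12)
  expect_error(correct_bias_scale(s, calibration_params("acc_x")), "missing")
  expect_error(calibration_params("acc_x", scale = 0), "scale")
})

test_that("zero-phase Butterworth has unit DC gain, kills 80 Hz, keeps 2 Hz", {
  fs <- 200
  t <- seq(0, 5, by = 1 / fs)
  expect_equal(lowpass_series(rep(1.5, length(t)), fs), rep(1.5, length(t)),
               tolerance = 1e-9)
  hi <- sin(2 * pi * 80 * t)
  out_hi <- lowpass_series(hi, fs)
  mid <- seq(100, length(t) - 100)
  expect_lt(max(abs(out_hi[mid])), 1e-3)
  lo <- sin(2 * pi * 2 * t)
  out_lo <- lowpass_series(lo, fs)
  expect_lt(max(abs(out_lo[mid] - lo[mid])), 0.01)
  expect_error(lowpass_series(rnorm(5), fs), "warm-up")
})

test_that("stream filtering touches acc/gyro only and skips dropout runs", {
  s <- generate_session(5, injury_rate = 0, seed = 6, magnetometer = TRUE)
  s <- inject_sensor_dropout(s, "acc_x", 1, 2)
  f <- lowpass_filter(s)
  expect_identical(f$data$mag_x, s$data$mag_x)
  expect_identical(is.na(f$data$acc_x), is.na(s$data$acc_x))
  expect_false(identical(f$data$acc_y, s$data$acc_y))
})

test_that("complementary filter removes gravity", {
  # stationary sensor: acc = (0, 0, 9.81), zero rates
  n <- 400
  data <- tibble::tibble(time_s = (0:(n - 1)) / 200,
                         acc_x = 0, acc_y = 0, acc_z = 9.81,
                         gyro_x = 0, gyro_y = 0, gyro_z = 0)
  st <- ankleguard:::new_imu_stream(data, 200,
                                    tibble::tibble(scenario = character(),
                                                   start_s = double(),
                                                   end_s = double()),
                                    tibble::tibble(time_s = double(),
                                                   itype = character(),
                                                   side = character()),
                                    tibble::tibble(channel = character(),
                                                   start_s = double(),
                                                   end_s = double()))
  out <- remove_gravity(st)
  lin <- as.matrix(out$data[, c("acc_x", "acc_y", "acc_z")])
  expect_lt(max(sqrt(rowSums(lin^2))), 0.05)

  # accel-only limit on noiseless static input: exact after one step
  out1 <- remove_gravity(st, blend = 1e-9)
  expect_lt(max(abs(out1$data$acc_z)), 1e-6)

  # slow constant rotation about x: gravity tracks the rotating frame
  fs <- 200; dur <- 10; tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  omega <- 0.5  # rad/s
  phi <- omega * tt
  rot <- tibble::tibble(time_s = tt,
                        acc_x = 0,
                        acc_y = 9.81 * sin(phi),
                        acc_z = 9.81 * cos(phi),
                        gyro_x = omega, gyro_y = 0, gyro_z = 0)
  st2 <- st; st2$data <- rot
  out2 <- remove_gravity(st2)
  lin2 <- as.matrix(out2$data[, c("acc_x", "acc_y", "acc_z")])
  tail_idx <- tt > 3
  expect_lt(max(sqrt(rowSums(lin2[tail_idx, ]^2))), 0.2)
})

test_that("resampling is identity on uniform input and exact on ramps", {
  s <- generate_session(2, injury_rate = 0, seed = 3)
  r <- resample_align(s, 200)
  for (ch in s$channels) expect_equal(r$data[[ch]], s$data[[ch]],
                                      tolerance = 1e-9)

  ramp <- tibble::tibble(time_s = seq(0, 1, by = 0.01), v = seq(0, 1, by = 0.01))
  up <- resample_align(ramp, 200)
  expect_equal(up$data$v, up$data$time_s, tolerance = 1e-12)
  expect_equal(range(up$data$v), c(0, 1))

  # jittered timestamps of a 1 Hz sine interpolate within 0.01
  set.seed(4)
  tj <- sort(seq(0, 5, by = 1 / 200) + runif(1001, -1e-3, 1e-3))
  sig <- tibble::tibble(time_s = tj, v = sin(2 * pi * tj))
  rs <- resample_align(sig, 200)
  truth <- sin(2 * pi * (rs$data$time_s + tj[1]))
  expect_lt(max(abs(rs$data$v - truth), na.rm = TRUE), 0.01)

  bad <- tibble::tibble(time_s = c(0, 0.1, 0.1), v = 1:3)
  expect_error(resample_align(bad), "strictly increasing")
})

test_that("windowing yields floor((n - 40)/20) + 1 windows with stride 20", {
  s <- generate_session(1, injury_rate = 0, seed = 5)     # 200 samples
  w <- segment_windows(s)
  expect_equal(nrow(w), 9L)
  expect_equal(w$start_s, seq(0, 160) [seq(1, 161, by = 20)] / 200)
  expect_true(all(vapply(w$x, nrow, integer(1)) == 40L))

  s2 <- generate_session(0.2, injury_rate = 0, seed = 5)  # exactly one window
  expect_equal(nrow(segment_windows(s2)), 1L)
  s3 <- generate_session(0.19, injury_rate = 0, seed = 5)
  expect_equal(nrow(segment_windows(s3)), 0L)

  # property: window count formula over a sweep of lengths
  for (n_samp in c(40L, 47L, 60L, 123L, 400L)) {
    sx <- generate_session(n_samp / 200, injury_rate = 0, seed = 6)
    expect_equal(nrow(segment_windows(sx)), floor((n_samp - 40) / 20) + 1L)
  }
})

test_that("risk labeling marks windows overlapping the pre-event span by >= 50 %", {
  s <- generate_session(4, injury_rate = 0, seed = 7)
  s <- inject_injury_event(s, 2.0, "inversion", drift_window_s = 0.3)
  w <- label_risk_windows(segment_windows(s), s$events)
  risk_starts <- w$start_s[w$label == "risk"]
  expect_true(all(c(1.8, 1.9) %in% risk_starts))
  expect_false(2.0 %in% risk_starts)

  w0 <- label_risk_windows(segment_windows(s), s$events[0, ])
  expect_true(all(w0$label == "no_risk"))

  expect_warning(
    label_risk_windows(segment_windows(s),
                       tibble::tibble(time_s = 0.1)),
    "partial history")
})

test_that("z-normalization standardizes train windows and never leaks", {
  w <- fixture_windows()
  st <- compute_norm_stats(w)
  wn <- z_normalize(w, st)
  stacked <- do.call(rbind, wn$x)
  expect_lt(max(abs(colMeans(stacked))), 1e-9)
  expect_lt(max(abs(apply(stacked, 2, sd) - 1)), 1e-9)
  expect_identical(st$split, "train")

  ident <- structure(list(mean = rep(0, 6), sd = rep(1, 6), split = "train"),
                     class = "norm_stats")
  expect_equal(z_normalize(w, ident)$x, w$x)

  # test windows normalized by train stats generally keep nonzero mean
  s_test <- generate_session(10, seed = 55)
  w_test <- z_normalize(preprocess_stream(s_test), st)
  expect_gt(max(abs(colMeans(do.call(rbind, w_test$x)))), 1e-4)

  degen <- st; degen$sd[1] <- 0
  expect_error(z_normalize(w, degen), "degenerate")
})

test_that("SMOTE oversamples to parity with convex-combination synthetics", {
  w <- fixture_windows()
  n_min <- sum(w$label == "risk")
  skip_if(n_min < 2, "fixture lacks minority windows")
  reb <- rebalance_training(w)
  tab <- table(reb$windows$label)
  expect_equal(unname(tab["risk"]), unname(tab["no_risk"]))
  expect_equal(unname(reb$class_weights["risk"]),
               unname(reb$class_weights["no_risk"]))

  # every synthetic vector lies on a segment between two minority vectors
  real <- do.call(rbind, purrr::map(w$x[w$label == "risk"], as.vector))
  synth <- reb$windows[reb$windows$synthetic, ]
  for (i in seq_len(min(nrow(synth), 20L))) {
    v <- as.vector(synth$x[[i]])
    on_segment <- FALSE
    for (a in seq_len(nrow(real))) {
      dir <- v - real[a, ]
      for (b in seq_len(nrow(real))) {
        if (a == b) next
        seg <- real[b, ] - real[a, ]
        u <- sum(dir * seg) / sum(seg^2)
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            max(abs(dir - u * seg)) < 1e-8) {
          on_segment <- TRUE
          break
        }
      }
      if (on_segment) break
    }
    expect_true(on_segment)
  }

  # balanced input passes through with unit weights
  bal <- w[rep(which(w$label == "risk"), length.out = 10), ]
  bal$label <- factor(rep(c("no_risk", "risk"), 5),
                      levels = c("no_risk", "risk"))
  reb2 <- rebalance_training(bal)
  expect_equal(nrow(reb2$windows), 10L)
  expect_equal(unname(reb2$class_weights), c(1, 1))

  # single minority sample: weights-only fallback with warning
  one <- w
  one$label[w$label == "risk"][-1] <- "no_risk"
  expect_warning(rebalance_training(one), "weights-only")
})

test_that("subject-level splits partition subjects at the configured shares", {
  subs <- sprintf("A%02d", 1:87)
  sp <- split_subjects(subs, seed = 3)
  expect_setequal(names(sp), subs)
  expect_equal(sum(sp == "train"), 61)
  expect_equal(sum(sp == "validation"), 10)
  expect_equal(sum(sp == "test"), 16)
  expect_identical(sp, split_subjects(subs, seed = 3))
})

test_that("the conditioning chain is bit-stable on identical input", {
  s <- generate_session(5, seed = 31)
  w1 <- preprocess_stream(s)
  w2 <- preprocess_stream(s)
  expect_identical(w1$x, w2$x)
  expect_identical(w1$label, w2$label)
})
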