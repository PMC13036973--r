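#' Calibration parameters
#'
#' Per-channel additive bias and multiplicative scale corrections, as provided
#' by a sensor manufacturer's calibration sheet.
#'
#' @param channel Character vector of channel names.
#' @param bias Additive bias per channel (signal units).
#' @param scale Positive multiplicative scale per channel.
#' @return A `calibration_params` tibble.
#' @export
calibration_params <- function(channel, bias = 0, scale = 1) {
  out <- tibble::tibble(channel = channel,
                        bias = rep_len(bias, length(channel)),
                        scale = rep_len(scale, length(channel)))
  if (any(out$scale <= 0)) abort("calibration scale must be > 0")
  structure(out, class = c("calibration_params", class(out)))
}

#' Correct sensor bias and scale errors
#'
#' Applies `out = (in - bias) * scale` per channel.
#'
#' @param stream An `imu_stream`.
#' @param calib A [calibration_params()] table covering every channel.
#' @return The corrected `imu_stream`.
#' @export
correct_bias_scale <- function(stream, calib) {
  missing <- setdiff(stream$channels, calib$channel)
  if (length(missing)) {
    abort(paste0("calibration missing channel(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (i in seq_len(nrow(calib))) {
    ch <- calib$channel[i]
    if (!ch %in% stream$channels) next
    stream$data[[ch]] <- (stream$data[[ch]] - calib$bias[i]) * calib$scale[i]
  }
  stream
}

butter_warmup <- function(order) 3L * (order + 1L)

#' Zero-phase Butterworth low-pass filter
#'
#' Designs an `order`-th Butterworth low-pass filter at `cutoff_hz` and applies
#' it forward and backward ([signal::filtfilt()]), giving zero net group delay
#' and a squared magnitude response. Applied to acceleration and gyroscope
#' channels only; magnetometer channels pass through untouched. Missing-data
#' (dropout) runs are left unfiltered; each contiguous valid run is filtered
#' independently when long enough.
#'
#' @param stream An `imu_stream` (or a bare numeric series via
#'   [lowpass_series()]).
#' @param order Filter order (default 4).
#' @param cutoff_hz Cutoff frequency in Hz (default 20); the sample rate must
#'   exceed twice the cutoff.
#' @return Filtered `imu_stream`.
#' @export
lowpass_filter <- function(stream, order = 4, cutoff_hz = 20) {
  fs <- stream$sample_rate
  if (fs <= 2 * cutoff_hz) abort("sample rate must exceed twice the cutoff")
  targets <- grep("acc_|gyro_", stream$channels, value = TRUE)
  for (ch in targets) {
    x <- stream$data[[ch]]
    runs <- valid_runs(x)
    for (r in runs) {
      if (length(r) >= butter_warmup(order)) {
        stream$data[[ch]][r] <- lowpass_series(x[r], fs, order, cutoff_hz)
      }
    }
  }
  stream
}

#' @rdname lowpass_filter
#' @param x Numeric series without missing values.
#' @param fs Sampling rate in Hz.
#' @export
lowpass_series <- function(x, fs, order = 4, cutoff_hz = 20) {
  if (fs <= 2 * cutoff_hz) abort("sample rate must exceed twice the cutoff")
  if (length(x) < butter_warmup(order)) {
    abort(sprintf(
      "series of length %d is shorter than the filter warm-up length (%d samples)",
      length(x), butter_warmup(order)))
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass
  n <- length(x)
  np <- min(n - 1L, 150L)
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  as.numeric(y[(np + 1):(np + n)])
}

# Indices of maximal contiguous non-NA runs.
valid_runs <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  purrr::map2(starts[r$values], ends[r$values], seq.int)
}

#' Remove gravity via complementary-filter orientation tracking
#'
#' Estimates the gravity direction in the sensor frame with a complementary
#' filter — the gyroscope-propagated estimate (rotated by the small-angle
#' cross product each step) blended with the instantaneous accelerometer
#' direction — then subtracts the rotated gravity vector from the
#' accelerometer channels, leaving linear acceleration.
#'
#' @param stream An `imu_stream` whose acc channels still include gravity.
#' @param blend Gyro weight per step in (0, 1); the accelerometer contributes
#'   `1 - blend`. Default 0.98.
#' @param g Gravity magnitude (m/s^2).
#' @return `imu_stream` with acc channels replaced by linear acceleration.
#' @export
remove_gravity <- function(stream, blend = 0.98, g = 9.81) {
  assert_scalar_prob(blend, "blend", open = TRUE)
  sides <- unique(sub("(left_|right_)?(acc|gyro|mag)_[xyz]", "\\1",
                      stream$channels))
  dt <- 1 / stream$sample_rate
  for (pref in sides) {
    acc_ch <- paste0(pref, c("acc_x", "acc_y", "acc_z"))
    gyr_ch <- paste0(pref, c("gyro_x", "gyro_y", "gyro_z"))
    if (!all(c(acc_ch, gyr_ch) %in% stream$channels)) next
    acc <- as.matrix(stream$data[acc_ch])
    gyr <- as.matrix(stream$data[gyr_ch])
    lin <- complementary_gravity_removal(acc, gyr, dt, blend, g)
    for (j in 1:3) stream$data[[acc_ch[j]]] <- lin[, j]
  }
  stream
}

# Core loop: acc, gyr are n x 3; returns linear acceleration n x 3.
complementary_gravity_removal <- function(acc, gyr, dt, blend, g) {
  n <- nrow(acc)
  lin <- matrix(NA_real_, n, 3L)
  # initialise from the first valid accelerometer sample
  gvec <- NULL
  for (i in seq_len(n)) {
    a <- acc[i, ]
    w <- gyr[i, ]
    if (is.null(gvec)) {
      if (!anyNA(a) && sqrt(sum(a^2)) > 1e-9) {
        gvec <- a / sqrt(sum(a^2)) * g
        lin[i, ] <- a - gvec
      }
      next
    }
    # propagate gravity estimate through the body rotation (small angle):
    # in the sensor frame a fixed world vector evolves as v' = v - dt (w x v)
    if (!anyNA(w)) {
      gpred <- gvec - dt * cross3(w, gvec)
    } else {
      gpred <- gvec
    }
    if (!anyNA(a) && sqrt(sum(a^2)) > 1e-9) {
      gmeas <- a / sqrt(sum(a^2)) * g
      gvec <- blend * gpred + (1 - blend) * gmeas
    } else {
      gvec <- gpred  # gyro-only fallback for degenerate accelerometer samples
    }
    gvec <- gvec / sqrt(sum(gvec^2)) * g
    if (!anyNA(a)) lin[i, ] <- a - gvec
  }
  lin
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Resample onto a uniform time grid
#'
#' Linearly interpolates every channel onto a uniform `target_hz` grid spanning
#' the input's time range, so all channels share one time base. Gaps between
#' consecutive input timestamps longer than `max_gap_s` are flagged as dropout
#' (left `NA` and recorded), not interpolated across.
#'
#' @param df Tibble with strictly increasing `time_s` plus channel columns,
#'   or an `imu_stream`.
#' @param target_hz Target sampling rate (default 200).
#' @param max_gap_s Maximum gap to interpolate across (default 0.1 s).
#' @return An `imu_stream` at `target_hz`.
#' @export
resample_align <- function(df, target_hz = 200, max_gap_s = 0.1) {
  if (inherits(df, "imu_stream")) {
    meta <- df
    df <- df$data
  } else {
    meta <- NULL
  }
  t <- df$time_s
  if (any(diff(t) <= 0)) abort("input timestamps must be strictly increasing")
  grid <- seq(t[1], t[length(t)], by = 1 / target_hz)
  chans <- setdiff(names(df), "time_s")
  out <- tibble::tibble(time_s = grid - grid[1])
  gap_starts <- which(diff(t) > max_gap_s)
  drops <- empty_dropout()
  for (ch in chans) {
    y <- df[[ch]]
    ok <- !is.na(y)
    yi <- if (sum(ok) >= 2L) {
      stats::approx(t[ok], y[ok], xout = grid, rule = 1)$y
    } else {
      rep(NA_real_, length(grid))
    }
    # blank out long source gaps instead of interpolating across them
    for (gs in gap_starts) {
      bad <- grid > t[gs] & grid < t[gs + 1L]
      yi[bad] <- NA_real_
    }
    if (length(gap_starts)) {
      drops <- dplyr::bind_rows(drops, tibble::tibble(
        channel = ch, start_s = t[gap_starts] - grid[1],
        end_s = t[gap_starts + 1L] - grid[1]))
    }
    out[[ch]] <- yi
  }
  if (is.null(meta)) {
    new_imu_stream(out, target_hz, tibble::tibble(
      scenario = character(), start_s = double(), end_s = double()),
      empty_events(), drops)
  } else {
    meta$data <- out
    meta$sample_rate <- target_hz
    meta$dropout <- dplyr::bind_rows(meta$dropout, drops)
    meta
  }
}

#' Segment a uniform stream into overlapping windows
#'
#' Cuts the stream into fixed windows of `window_s` seconds advancing by
#' `window_s * (1 - overlap)` (default 200 ms with 50 % overlap: 40 samples,
#' stride 20 at 200 Hz). The trailing partial window is discarded. Missing
#' (dropout) samples are zero-imputed in the window tensor and recorded in a
#' per-window validity fraction.
#'
#' @param stream An `imu_stream` at a uniform rate.
#' @param window_s Window length in seconds (default 0.2).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @return A `motion_windows` tibble: `window_id`, `start_s`, `x` (list of
#'   samples x channels matrices), `valid_frac`, `scenario`, `subject`.
#' @export
segment_windows <- function(stream, window_s = 0.2, overlap = 0.5) {
  fs <- stream$sample_rate
  wlen <- round(window_s * fs)
  stride <- round(wlen * (1 - overlap))
  if (stride < 1L) abort("`overlap` must be in [0, 1)")
  mat <- as.matrix(stream$data[stream$channels])
  n <- nrow(mat)
  if (n < wlen) {
    return(empty_motion_windows(stream))
  }
  starts <- seq(1L, n - wlen + 1L, by = stride)
  segs <- stream$segments
  rows <- purrr::map(starts, function(s) {
    xw <- mat[s:(s + wlen - 1L), , drop = FALSE]
    valid <- 1 - sum(is.na(xw)) / length(xw)
    xw[is.na(xw)] <- 0
    start_s <- stream$data$time_s[s]
    mid <- start_s + window_s / 2
    scn <- NA_character_
    if (nrow(segs)) {
      hit <- which(segs$start_s <= mid & segs$end_s > mid)
      if (length(hit)) scn <- segs$scenario[hit[1L]]
    }
    tibble::tibble(start_s = start_s, x = list(xw), valid_frac = valid,
                   scenario = scn)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out, window_id = dplyr::row_number(),
                       subject = stream$subject, .before = 1L)
  class(out) <- c("motion_windows", class(out))
  attr(out, "sample_rate") <- fs
  attr(out, "window_s") <- window_s
  attr(out, "overlap") <- overlap
  attr(out, "channels") <- stream$channels
  out
}

empty_motion_windows <- function(stream) {
  out <- tibble::tibble(window_id = integer(), subject = character(),
                        start_s = double(), x = list(),
                        valid_frac = double(), scenario = character())
  class(out) <- c("motion_windows", class(out))
  attr(out, "channels") <- stream$channels
  out
}

#' Label pre-injury risk windows
#'
#' The 200 ms segment immediately prior to each injury event is the risk
#' span; every window overlapping that span by at least half the window
#' length is labeled `risk`, all others `no_risk`. Events earlier than one
#' window into the stream label whatever partial history exists, with a
#' warning.
#'
#' @param windows A `motion_windows` tibble.
#' @param events Tibble with `time_s` (e.g. `stream$events`).
#' @param window_s Window length in seconds.
#' @return `windows` with a `label` factor column (`no_risk`, `risk`).
#' @export
label_risk_windows <- function(windows, events, window_s = 0.2) {
  lab <- rep("no_risk", nrow(windows))
  if (nrow(windows) && !is.null(events) && nrow(events)) {
    for (ev in events$time_s) {
      if (ev < window_s) {
        warn(sprintf(
          "event at %.3f s precedes one full window; labeling partial history",
          ev))
      }
      span <- c(max(ev - window_s, 0), ev)
      ov <- pmin(windows$start_s + window_s, span[2]) -
        pmax(windows$start_s, span[1])
      lab[ov >= window_s / 2 - 1e-9] <- "risk"
    }
  }
  windows$label <- factor(lab, levels = c("no_risk", "risk"))
  windows
}

#' Channel normalization statistics
#'
#' Per-channel mean and standard deviation computed over a set of windows,
#' tagged with the split they came from so leakage is assertable.
#'
#' @param windows A `motion_windows` tibble (training split only).
#' @param split Split tag (default `"train"`).
#' @return A `norm_stats` object.
#' @export
compute_norm_stats <- function(windows, split = "train") {
  stacked <- do.call(rbind, windows$x)
  mu <- colMeans(stacked)
  sdv <- apply(stacked, 2L, sd)
  if (any(sdv <= 0 | !is.finite(sdv))) {
    abort("degenerate channel: zero standard deviation")
  }
  structure(list(mean = mu, sd = sdv, split = split), class = "norm_stats")
}

#' Z-normalize windows by training-split statistics
#'
#' @param windows A `motion_windows` tibble.
#' @param stats A [compute_norm_stats()] object (training split).
#' @return `windows` with each matrix standardized per channel.
#' @export
z_normalize <- function(windows, stats) {
  if (!inherits(stats, "norm_stats")) abort("`stats` must be norm_stats")
  if (any(stats$sd <= 0)) abort("degenerate channel: zero standard deviation")
  windows$x <- purrr::map(windows$x, function(m) {
    sweep(sweep(m, 2L, stats$mean, "-"), 2L, stats$sd, "/")
  })
  windows
}

#' Rebalance a training set with SMOTE and class weights
#'
#' Synthetic minority oversampling on flattened window vectors (k nearest
#' neighbours, default 5): each synthetic sample is a convex combination of a
#' real minority window and one of its nearest minority neighbours. Class
#' weights are inversely proportional to post-SMOTE class frequencies. With a
#' single minority sample SMOTE is skipped and weights alone carry the
#' rebalancing (warning issued).
#'
#' @param windows A labeled `motion_windows` tibble (training split only).
#' @param target_ratio Desired minority:majority ratio after oversampling
#'   (default 1, i.e. parity).
#' @param k Number of nearest neighbours (default 5).
#' @return List with `windows` (augmented tibble), `class_weights` (named
#'   vector over labels).
#' @export
rebalance_training <- function(windows, target_ratio = 1, k = 5L) {
  if (is.null(windows$label)) abort("windows must be labeled")
  tab <- table(windows$label)
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  out <- windows
  if (n_min >= 2L && n_min < round(target_ratio * n_maj)) {
    need <- round(target_ratio * n_maj) - n_min
    min_rows <- windows[windows$label == minority, ]
    flat <- do.call(rbind, purrr::map(min_rows$x, as.vector))
    d <- as.matrix(dist(flat))
    diag(d) <- Inf
    kk <- min(k, n_min - 1L)
    synth <- vector("list", need)
    base_idx <- sample.int(n_min, need, replace = TRUE)
    dims <- dim(min_rows$x[[1L]])
    for (i in seq_len(need)) {
      b <- base_idx[i]
      nb <- order(d[b, ])[seq_len(kk)]
      j <- nb[sample.int(kk, 1L)]
      u <- runif(1)
      v <- flat[b, ] + u * (flat[j, ] - flat[b, ])
      synth[[i]] <- matrix(v, dims[1L], dims[2L])
    }
    add <- min_rows[rep(1L, need), ]
    add$x <- synth
    add$window_id <- max(windows$window_id) + seq_len(need)
    add$synthetic <- TRUE
    out$synthetic <- FALSE
    out <- dplyr::bind_rows(out, add)
  } else {
    if (n_min < 2L) {
      warn("single minority sample: SMOTE skipped, weights-only fallback")
    }
    out$synthetic <- FALSE
  }
  tab2 <- table(out$label)
  w <- as.numeric(sum(tab2) / (length(tab2) * tab2))
  names(w) <- names(tab2)
  list(windows = out, class_weights = w)
}

#' Subject-level train/validation/test split
#'
#' Assigns whole subjects to splits at the configured proportions
#' (default 70 / 11.5 / 18.5 %), so no subject contributes windows to more
#' than one split.
#'
#' @param subjects Character vector of unique subject ids.
#' @param props Proportions for train, validation, test.
#' @param seed Seed for the assignment.
#' @return Named character vector mapping subject to split.
#' @export
split_subjects <- function(subjects, props = c(train = 0.70, validation = 0.115,
                                               test = 0.185), seed = 1L) {
  with_seed(seed, {
    n <- length(subjects)
    shuffled <- sample(subjects)
    n_tr <- max(1L, round(props[["train"]] * n))
    n_va <- max(1L, round(props[["validation"]] * n))
    if (n_tr + n_va >= n) n_tr <- max(1L, n - n_va - 1L)
    split <- rep("test", n)
    split[seq_len(n_tr)] <- "train"
    split[n_tr + seq_len(n_va)] <- "validation"
    stats::setNames(split, shuffled)
  })
}

#' Run the fixed-order conditioning chain on one stream
#'
#' Calibration correction, zero-phase low-pass filtering, complementary-filter
#' gravity removal, resampling to the common rate, then 200 ms / 50 %
#' windowing and risk labeling. Normalization is applied afterwards with
#' training-split statistics (see [compute_norm_stats()]), never here, so the
#' chain cannot leak test information.
#'
#' @param stream An `imu_stream`.
#' @param calib Optional [calibration_params()].
#' @param target_hz Common sampling rate (default 200).
#' @param window_s,overlap Windowing parameters.
#' @param cutoff_hz Low-pass cutoff (default 20 Hz).
#' @return Labeled, unnormalized `motion_windows`.
#' @export
preprocess_stream <- function(stream, calib = NULL, target_hz = 200,
                              window_s = 0.2, overlap = 0.5, cutoff_hz = 20) {
  if (!is.null(calib)) stream <- correct_bias_scale(stream, calib)
  stream <- lowpass_filter(stream, cutoff_hz = cutoff_hz)
  stream <- remove_gravity(stream)
  if (stream$sample_rate != target_hz) {
    stream <- resample_align(stream, target_hz)
  }
  w <- segment_windows(stream, window_s, overlap)
  label_risk_windows(w, stream$events, window_s)
}
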