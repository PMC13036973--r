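#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained branch
#'
#' @param x A `branch_fit`.
#' @param ... Unused.
#' @return Per-epoch loss history.
#' @export
tidy.branch_fit <- function(x, ...) x$history

#' @rdname tidy.branch_fit
#' @export
glance.branch_fit <- function(x, ...) {
  tibble::tibble(branch = x$branch, epochs = nrow(x$history),
                 best_val_loss = min(x$history$val_loss),
                 prune_ratio = x$prune_ratio,
                 sparsity = if (x$branch == "lstm") lstm_sparsity(x$params)
                 else NA_real_)
}

#' Tidy an RL agent's learning curve
#'
#' @param x An `rl_agent`.
#' @param ... Unused.
#' @return Reward-curve tibble.
#' @export
tidy.rl_agent <- function(x, ...) x$reward_curve

#' @rdname tidy.rl_agent
#' @export
glance.rl_agent <- function(x, ...) {
  n <- nrow(x$reward_curve)
  k <- max(1L, floor(n / 10))
  tibble::tibble(
    episodes = n, steps = x$steps,
    mean_reward_first10pct = mean(x$reward_curve$reward[seq_len(k)]),
    mean_reward_last10pct = mean(x$reward_curve$reward[(n - k + 1L):n]))
}

#' Tidy a metric report
#'
#' @param x A `metric_report`.
#' @param ... Unused.
#' @return Long tibble of metric names and values.
#' @export
tidy.metric_report <- function(x, ...) {
  tibble::tibble(
    metric = c("ida_pct", "far_pct", "apa150_pct",
               "adaptation_overhead_pct", "latency_proxy_mean"),
    value = c(x$ida_pct, x$far_pct, x$apa150_pct,
              x$adaptation_overhead_pct, x$latency_proxy_stats[["mean"]]))
}

#' @rdname tidy.metric_report
#' @export
glance.metric_report <- function(x, ...) {
  tibble::tibble(mode = paste(x$mode, collapse = "+"),
                 n_events = x$n_events, n_alerts = x$n_alerts,
                 ida_pct = x$ida_pct, far_pct = x$far_pct,
                 apa150_pct = x$apa150_pct,
                 adaptation_overhead_pct = x$adaptation_overhead_pct)
}

#' Tidy detection records
#'
#' @param x A `detection_records`.
#' @param ... Unused.
#' @return Per-event records tibble.
#' @export
tidy.detection_records <- function(x, ...) x$records

#' Plot an IMU stream
#'
#' Faceted channel traces with injury events marked.
#'
#' @param object An `imu_stream`.
#' @param channels Channels to show (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.imu_stream <- function(object, channels = object$channels, ...) {
  long <- tidyr::pivot_longer(object$data[, c("time_s", channels)],
                              -"time_s", names_to = "channel")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 3L) +
    ggplot2::labs(x = "time (s)", y = NULL)
  if (nrow(object$events)) {
    p <- p + ggplot2::geom_vline(data = object$events,
                                 ggplot2::aes(xintercept = .data$time_s),
                                 colour = "red", linetype = 2)
  }
  p
}

#' Plot an agent's reward curve
#'
#' @param object An `rl_agent`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rl_agent <- function(object, ...) {
  ggplot2::ggplot(object$reward_curve,
                  ggplot2::aes(.data$episode, .data$reward)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$reward_smooth),
                       colour = "steelblue", na.rm = TRUE) +
    ggplot2::labs(x = "episode", y = "episode reward")
}

#' Plot a session run
#'
#' Fused risk probability, GP risk forecast, the adaptation trajectory of
#' the mixing coefficient, and alert/event marks.
#'
#' @param object A `session_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.session_run <- function(object, ...) {
  logs <- object$logs
  long <- tidyr::pivot_longer(
    logs[, c("start_s", "p_risk", "risk_forecast", "alpha")],
    -"start_s", names_to = "series")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$start_s, .data$value,
                                          colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL)
  if (nrow(object$events)) {
    p <- p + ggplot2::geom_vline(data = object$events,
                                 ggplot2::aes(xintercept = .data$time_s),
                                 colour = "red", linetype = 2)
  }
  p
}

#' Plot the accuracy-latency trade-off grid
#'
#' @param sweep Output of [tradeoff_sweep()].
#' @return A ggplot heatmap-style scatter.
#' @export
plot_tradeoff <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$latency_proxy, .data$accuracy)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$nondominated,
                                     colour = factor(.data$hidden)),
                        size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("eps=%.2f", .data$eps)),
                       vjust = -1, size = 2.8) +
    ggplot2::labs(x = "latency proxy (ms-equivalent)", y = "accuracy",
                  colour = "Q width", shape = "non-dominated")
}

#' @importFrom rlang .data
NULL
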