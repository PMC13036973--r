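#' Match alert episodes to injury events
#'
#' Collapses consecutive alert windows separated by at most `merge_gap_s`
#' into alert episodes, then matches each episode to an injury event when
#' the episode starts inside `[event + match_window[1], event +
#' match_window[2]]` seconds (default `[-1.0, +0.1]`). Lead time of a
#' detected event is measured from its earliest matched alert.
#'
#' @param run A `session_run` (or list of them).
#' @param match_window Two-sided match window in seconds relative to the
#'   event.
#' @param merge_gap_s Alerts closer than this collapse into one episode.
#' @param window_s Window length (alert time = window start + length).
#' @return A `detection_records` list: `records` (per event: `event_time`,
#'   `itype`, `detected`, `lead_ms`), `alerts` (per episode: `time_s`,
#'   `matched`).
#' @export
detection_records <- function(run, match_window = c(-1.0, 0.1),
                              merge_gap_s = 0.2, window_s = 0.2) {
  runs <- if (inherits(run, "session_run")) list(run) else run
  rec_list <- list()
  alert_list <- list()
  for (si in seq_along(runs)) {
    r <- runs[[si]]
    a_times <- r$logs$start_s[r$logs$alert] + window_s
    episodes <- merge_alert_times(a_times, merge_gap_s)
    ev <- r$events
    matched <- rep(FALSE, length(episodes))
    recs <- NULL
    if (!is.null(ev) && nrow(ev)) {
      recs <- purrr::map(seq_len(nrow(ev)), function(i) {
        e <- ev$time_s[i]
        hit <- which(episodes >= e + match_window[1] &
                       episodes <= e + match_window[2])
        if (length(hit)) matched[hit] <<- TRUE
        detected <- length(hit) > 0L
        tibble::tibble(
          session = si, event_time = e,
          itype = if (!is.null(ev$itype)) ev$itype[i] else NA_character_,
          detected = detected,
          alert_time = if (detected) min(episodes[hit]) else NA_real_,
          lead_ms = if (detected) (e - min(episodes[hit])) * 1000 else
            NA_real_)
      })
    }
    rec_list[[si]] <- dplyr::bind_rows(recs)
    alert_list[[si]] <- tibble::tibble(session = si, time_s = episodes,
                                       matched = matched)
  }
  structure(list(records = dplyr::bind_rows(rec_list),
                 alerts = dplyr::bind_rows(alert_list)),
            class = "detection_records")
}

merge_alert_times <- function(times, merge_gap_s) {
  if (!length(times)) return(numeric(0))
  times <- sort(times)
  keep <- c(TRUE, diff(times) > merge_gap_s)
  times[keep]
}

#' Injury detection accuracy (IDA)
#'
#' Percentage of injury events with at least one matched alert.
#'
#' @param det A [detection_records()] object.
#' @return Percentage in `[0, 100]`.
#' @export
compute_ida <- function(det) {
  recs <- det$records
  if (is.null(recs) || nrow(recs) == 0L) {
    abort("IDA undefined: no injury events")
  }
  100 * mean(recs$detected)
}

#' False alarm rate (FAR)
#'
#' Percentage of alert episodes not matched to any injury event (per-alert
#' denominator; set `per_window_total` to use a per-window denominator
#' instead).
#'
#' @param det A [detection_records()] object.
#' @param per_window_total Optional total window count for the per-window
#'   variant.
#' @return Percentage in `[0, 100]`.
#' @export
compute_far <- function(det, per_window_total = NULL) {
  al <- det$alerts
  if (is.null(al) || nrow(al) == 0L) {
    warn("no alerts raised: FAR reported as 0 %")
    return(0)
  }
  unmatched <- sum(!al$matched)
  denom <- per_window_total %||% nrow(al)
  100 * unmatched / denom
}

#' Advance prediction accuracy (APA)
#'
#' Percentage of injury events alerted at least `lead_threshold_ms` before
#' occurrence (inclusive). `rule = "within"` gives the alternative reading —
#' detection within `lead_threshold_ms` of the event in either direction.
#'
#' @param det A [detection_records()] object.
#' @param lead_threshold_ms Lead threshold in milliseconds (default 150).
#' @param rule `"lead_at_least"` (default) or `"within"`.
#' @return Percentage in `[0, 100]`.
#' @export
compute_apa <- function(det, lead_threshold_ms = 150,
                        rule = c("lead_at_least", "within")) {
  rule <- match.arg(rule)
  recs <- det$records
  if (is.null(recs) || nrow(recs) == 0L) {
    abort("APA undefined: no injury events")
  }
  ok <- if (rule == "lead_at_least") {
    recs$detected & !is.na(recs$lead_ms) & recs$lead_ms >= lead_threshold_ms
  } else {
    recs$detected & !is.na(recs$lead_ms) & abs(recs$lead_ms) <= lead_threshold_ms
  }
  100 * mean(ok)
}

#' Adaptation overhead
#'
#' Percentage of total proxy MACs spent on the adaptation machinery (GP
#' forecaster, agent evaluation, re-pruning) rather than inference.
#'
#' @param logs Per-window session logs with `inference_macs` and
#'   `adaptation_macs` columns (or a `session_run`).
#' @return Percentage in `[0, 100]`.
#' @export
compute_adaptation_overhead <- function(logs) {
  if (inherits(logs, "session_run")) logs <- logs$logs
  ad <- sum(logs$adaptation_macs)
  total <- ad + sum(logs$inference_macs)
  if (total == 0) return(0)
  100 * ad / total
}

#' Paired comparison with Bonferroni correction
#'
#' Paired t-test of two metrics over the same items, with the significance
#' level adjusted to `alpha / corrections`. Zero-variance differences yield
#' an exact-tie report without a t statistic.
#'
#' @param metric_a,metric_b Paired numeric vectors.
#' @param alpha Family significance level (default 0.01).
#' @param corrections Number of comparisons in the family.
#' @return One-row tibble: `t`, `df`, `p`, `alpha_adjusted`, `significant`,
#'   `tie`.
#' @export
paired_comparison <- function(metric_a, metric_b, alpha = 0.01,
                              corrections = 1L) {
  if (length(metric_a) != length(metric_b) || length(metric_a) < 2L) {
    abort("need >= 2 pairs of equal length")
  }
  d <- metric_a - metric_b
  if (sd(d) <= 1e-10 * max(abs(d), 1)) {
    return(tibble::tibble(t = NA_real_, df = length(d) - 1L,
                          p = NA_real_, alpha_adjusted = alpha / corrections,
                          significant = FALSE, tie = all(d == 0)))
  }
  tt <- t.test(metric_a, metric_b, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, alpha_adjusted = alpha / corrections,
                 significant = tt$p.value < alpha / corrections, tie = FALSE)
}

#' Pearson correlation of risk scores and outcomes
#'
#' @param risk Numeric risk scores.
#' @param outcomes Numeric (or 0/1) outcomes.
#' @return One-row tibble with `r` and `p`.
#' @export
correlation_risk_vs_outcome <- function(risk, outcomes) {
  outcomes <- as.numeric(outcomes)
  if (length(risk) < 3L) abort("need at least 3 observations")
  if (sd(risk) == 0 || sd(outcomes) == 0) {
    abort("zero variance: correlation undefined")
  }
  ct <- cor.test(risk, outcomes, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value)
}

#' Metric report over a set of session runs
#'
#' IDA, FAR, APA at 150 ms, adaptation overhead and latency-proxy summary,
#' plus per-injury-type breakdowns.
#'
#' @param runs A `session_run` or list of them.
#' @param ... Passed to [detection_records()].
#' @return A `metric_report`.
#' @export
evaluate_sessions <- function(runs, ...) {
  runs_list <- if (inherits(runs, "session_run")) list(runs) else runs
  det <- detection_records(runs_list, ...)
  logs <- dplyr::bind_rows(purrr::map(runs_list, "logs"))
  has_events <- !is.null(det$records) && nrow(det$records) > 0L
  by_type <- if (has_events) {
    dplyr::summarise(dplyr::group_by(det$records, .data$itype),
                     n = dplyr::n(),
                     ida_pct = 100 * mean(.data$detected),
                     .groups = "drop")
  } else {
    tibble::tibble(itype = character(), n = integer(), ida_pct = double())
  }
  # per-scenario breakdown: each event attributed to its segment's scenario
  recs <- det$records
  if (has_events) {
    recs$scenario <- NA_character_
    for (i in seq_len(nrow(recs))) {
      seg <- runs_list[[recs$session[i]]]$segments
      if (is.null(seg) || !nrow(seg)) next
      hit <- which(seg$start_s <= recs$event_time[i] &
                     seg$end_s > recs$event_time[i])
      if (length(hit)) recs$scenario[i] <- seg$scenario[hit[1L]]
    }
  }
  by_scenario <- if (has_events && any(!is.na(recs$scenario))) {
    dplyr::summarise(dplyr::group_by(recs, .data$scenario),
                     n = dplyr::n(),
                     ida_pct = 100 * mean(.data$detected),
                     .groups = "drop")
  } else {
    tibble::tibble(scenario = character(), n = integer(), ida_pct = double())
  }
  structure(list(
    ida_pct = if (has_events) compute_ida(det) else NA_real_,
    far_pct = compute_far(det),
    apa150_pct = if (has_events) compute_apa(det) else NA_real_,
    adaptation_overhead_pct = compute_adaptation_overhead(logs),
    latency_proxy_stats = c(mean = mean(logs$latency),
                            sd = sd(logs$latency),
                            max = max(logs$latency)),
    by_injury_type = by_type,
    by_scenario = by_scenario,
    n_events = if (has_events) nrow(det$records) else 0L,
    n_alerts = nrow(det$alerts),
    detections = det,
    mode = unique(vapply(runs_list, function(r) r$mode, character(1)))
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report:%s> IDA %.1f%% | FAR %.1f%% | APA@150ms %.1f%% | overhead %.2f%% | latency-proxy mean %.1f\n",
    paste(x$mode, collapse = "+"), x$ida_pct, x$far_pct, x$apa150_pct,
    x$adaptation_overhead_pct, x$latency_proxy_stats[["mean"]]))
  invisible(x)
}

#' Accuracy-latency trade-off sweep
#'
#' Re-trains the agent under each combination of exploration rate and
#' Q-network width, then evaluates greedy-policy classification accuracy and
#' mean latency proxy on the given window sets.
#'
#' @param window_sets Labeled, normalized training `motion_windows` list.
#' @param eval_sets Held-out window sets for evaluation.
#' @param models An [ensemble_models()] with trained branches.
#' @param eps_values Exploration endpoints to sweep.
#' @param hidden_widths Q-network widths to sweep.
#' @param episodes Training episodes per configuration.
#' @param seed Seed.
#' @return Tibble with one row per configuration: `eps`, `hidden`,
#'   `accuracy`, `latency_proxy`, `nondominated`.
#' @export
tradeoff_sweep <- function(window_sets, eval_sets, models,
                           eps_values = c(0.05, 0.1, 0.2),
                           hidden_widths = c(16L, 32L, 64L),
                           episodes = 20L, seed = 1L) {
  combos <- tidyr::expand_grid(eps = eps_values, hidden = hidden_widths)
  env <- make_adaptation_env(window_sets, models, seed = seed)
  rows <- purrr::pmap(combos, function(eps, hidden) {
    sched <- exploration_schedule(eps_start = eps, eps_end = 0.01)
    net <- q_network(2L + 3L, env$n_actions, hidden = hidden,
                     seed = child_seed(seed, paste0("sweep", eps, hidden)))
    ag <- run_training(env, episodes = episodes, net = net, schedule = sched,
                       seed = child_seed(seed, paste0("train", eps, hidden)))
    m <- models
    m$agent <- ag
    evals <- purrr::map(eval_sets, function(w) {
      r <- run_session(w, m, mode = "full")
      acc <- mean((r$logs$p_risk > 0.5) == (r$logs$label == "risk"))
      tibble::tibble(accuracy = acc, latency = mean(r$logs$latency))
    })
    ev <- dplyr::bind_rows(evals)
    tibble::tibble(eps = eps, hidden = hidden,
                   accuracy = mean(ev$accuracy),
                   latency_proxy = mean(ev$latency))
  })
  out <- dplyr::bind_rows(rows)
  out$nondominated <- pareto_nondominated(out$accuracy, -out$latency_proxy)
  out
}

# TRUE for rows not strictly dominated on both (maximized) objectives.
pareto_nondominated <- function(obj1, obj2) {
  n <- length(obj1)
  vapply(seq_len(n), function(i) {
    !any(obj1 > obj1[i] & obj2 > obj2[i])
  }, logical(1))
}
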