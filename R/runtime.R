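#' Fuse branch predictions with the mixing coefficient
#'
#' `y_hat = alpha * softmax(cnn_logits) + (1 - alpha) * softmax(lstm_logits)`.
#' The fused vector is a probability vector for any `alpha` in `[0, 1]`.
#'
#' @param alpha Mixing coefficient in `[0, 1]` (weight on the CNN branch).
#' @param cnn_logits,lstm_logits Length-2 logit vectors (or probability
#'   vectors with `already_probs = TRUE`).
#' @param risk Optional GP risk forecast used for the alert flag.
#' @param tau Risk threshold (default 0.6).
#' @param already_probs Inputs are probabilities, skip the softmax.
#' @return An `ensemble_output`: `p_cnn`, `p_lstm`, `y_hat`, `decision`
#'   (`"no_risk"`/`"risk"`), `alert`.
#' @export
fuse_predictions <- function(alpha, cnn_logits, lstm_logits, risk = NA_real_,
                             tau = 0.6, already_probs = FALSE) {
  assert_scalar_prob(alpha, "alpha")
  p_cnn <- if (already_probs) cnn_logits else softmax(cnn_logits)
  p_lstm <- if (already_probs) lstm_logits else softmax(lstm_logits)
  y_hat <- alpha * p_cnn + (1 - alpha) * p_lstm
  decision <- c("no_risk", "risk")[which.max(y_hat)]
  alert <- identical(decision, "risk") ||
    (!is.na(risk) && risk > tau)
  structure(list(p_cnn = p_cnn, p_lstm = p_lstm, y_hat = y_hat,
                 decision = decision, alert = alert),
            class = "ensemble_output")
}

#' Analytic multiply-accumulate counts
#'
#' Exact MAC count of the CNN branch (per window of length `len`) and of the
#' LSTM branch at pruning ratio `beta` (prunable input/recurrent MACs scale
#' by `1 - beta`).
#'
#' @param params Branch parameters.
#' @param len Window length in samples (default 40).
#' @return MAC count.
#' @export
cnn_mac_count <- function(params, len = 40L) {
  total <- 0
  L <- len
  for (bl in params$blocks) {
    L_out <- conv_out_length(L, bl$stride)
    if (params$conv_order == "as_printed") {
      total <- total + L * bl$c_in * bl$c_out         # pointwise at input length
      total <- total + L_out * bl$c_out * bl$kernel   # strided depthwise
    } else {
      total <- total + L_out * bl$c_in * bl$kernel
      total <- total + L_out * bl$c_in * bl$c_out
    }
    L <- L_out
  }
  total + nrow(params$W_c) * ncol(params$W_c)
}

#' @rdname cnn_mac_count
#' @param beta Pruning ratio applied to input/recurrent matrices.
#' @export
lstm_mac_count <- function(params, len = 40L, beta = 0) {
  per_step <- sum(vapply(params$layers, function(ly) {
    length(ly$W) + length(ly$U)
  }, numeric(1)))
  len * per_step * (1 - beta) + nrow(params$W_l) * ncol(params$W_l)
}

#' Resource proxy configuration
#'
#' Maps analytic MAC counts onto latency-, energy- and CPU-usage proxies:
#' `latency = mu * macs` (ms-equivalent), `energy = kappa * macs`
#' (mJ-equivalent), `cpu = macs / budget` clamped to `[0, 1]`. The default
#' constants are calibrated so the full ensemble at `(alpha = 0.5, beta = 0)`
#' maps to 26.4 ms-equivalent and 4.8 mJ-equivalent per window; proxies are
#' reward inputs only, never hardware measurements.
#'
#' @param cnn_params,lstm_params Branch parameters defining the topology.
#' @param latency_full,energy_full Proxy values assigned to the full
#'   configuration.
#' @param len Window length.
#' @return A `proxy_config` list with `mu`, `kappa`, `budget`.
#' @export
proxy_config <- function(cnn_params, lstm_params, latency_full = 26.4,
                         energy_full = 4.8, len = 40L) {
  mac_full <- cnn_mac_count(cnn_params, len) + lstm_mac_count(lstm_params, len, 0)
  structure(list(mu = latency_full / mac_full,
                 kappa = energy_full / mac_full,
                 budget = mac_full, len = len),
            class = "proxy_config")
}

#' Per-window resource proxies for a fusion configuration
#'
#' `alpha = 1` removes the LSTM MACs entirely (branch skipped); `alpha = 0`
#' removes the CNN MACs; interior `alpha` runs both branches. The proxy is
#' strictly decreasing in `beta` whenever the LSTM branch runs.
#'
#' @param cnn_params,lstm_params Branch parameters.
#' @param alpha,beta Current fusion configuration.
#' @param proxy A [proxy_config()].
#' @return A `resource_proxy`: `mac_count`, `cpu_usage`, `energy_proxy`,
#'   `latency_proxy`.
#' @export
estimate_resources <- function(cnn_params, lstm_params, alpha, beta,
                               proxy) {
  macs <- 0
  if (alpha > 0) macs <- macs + cnn_mac_count(cnn_params, proxy$len)
  if (alpha < 1) macs <- macs + lstm_mac_count(lstm_params, proxy$len, beta)
  structure(list(mac_count = macs,
                 cpu_usage = min(macs / proxy$budget, 1),
                 energy_proxy = proxy$kappa * macs,
                 latency_proxy = proxy$mu * macs),
            class = "resource_proxy")
}

# MAC proxies of the adaptation machinery itself (GP + agent + re-prune).
adaptation_macs <- function(n_buffer, n_features, net, repruned,
                            prunable_count) {
  gp <- n_features * (n_buffer^3 / 3 + 2 * n_buffer^2 + n_buffer)
  agent <- net$hidden * net$state_dim + net$n_actions * net$hidden
  reprune <- if (repruned) prunable_count else 0
  gp + agent + reprune
}

#' Apply an agent action to the fusion state
#'
#' Sets the mixing coefficient, and recomputes the LSTM prune mask from the
#' dense checkpoint at the new ratio (so ratio changes are reversible).
#' `alpha = 1` short-circuits the LSTM branch entirely (CNN-only fallback).
#'
#' @param fusion_state List with `alpha`, `beta`.
#' @param action_row One row of an [action_grid()].
#' @param lstm_dense Dense LSTM checkpoint (`branch_fit$dense`).
#' @return List with updated `fusion_state`, `lstm_params`, and `repruned`
#'   flag.
#' @export
apply_action <- function(fusion_state, action_row, lstm_dense) {
  if (is.null(lstm_dense)) abort("missing dense LSTM checkpoint")
  repruned <- !isTRUE(all.equal(fusion_state$beta, action_row$beta))
  fusion_state$alpha <- action_row$alpha
  fusion_state$beta <- action_row$beta
  lstm_params <- if (repruned) {
    if (action_row$beta > 0) magnitude_prune(lstm_dense, action_row$beta)
    else lstm_dense
  } else {
    NULL
  }
  list(fusion_state = fusion_state, lstm_params = lstm_params,
       repruned = repruned)
}

#' Bundle trained components into a runnable model set
#'
#' @param cnn_fit,lstm_fit `branch_fit` objects.
#' @param norm_stats Training-split [compute_norm_stats()].
#' @param theta GP kernel hyperparameters.
#' @param head Risk head from [fit_risk_head()].
#' @param agent Optional trained `rl_agent`.
#' @param grid Action grid.
#' @param reward_cfg Reward configuration.
#' @param gp_capacity GP buffer capacity (default 50).
#' @param quantized_cnn Use the int8 CNN path at inference.
#' @return An `ensemble_models` list.
#' @export
ensemble_models <- function(cnn_fit, lstm_fit, norm_stats,
                            theta = gp_kernel_params(), head = NULL,
                            agent = NULL, grid = action_grid(),
                            reward_cfg = reward_config(),
                            gp_capacity = 50L, quantized_cnn = TRUE) {
  proxy <- proxy_config(cnn_fit$params, lstm_fit$params)
  structure(list(cnn_fit = cnn_fit, lstm_fit = lstm_fit,
                 norm_stats = norm_stats, theta = theta, head = head,
                 agent = agent, grid = grid, reward_cfg = reward_cfg,
                 gp_capacity = gp_capacity, proxy = proxy,
                 quantized_cnn = quantized_cnn),
            class = "ensemble_models")
}

default_action_for <- function(grid, alpha, beta) {
  i <- which(abs(grid$alpha - alpha) < 1e-9 & abs(grid$beta - beta) < 1e-9)
  if (!length(i)) i <- which.min((grid$alpha - alpha)^2 + (grid$beta - beta)^2)
  i[1L]
}

# Build the mutable runtime state for a session.
init_runtime_state <- function(models, mode) {
  defaults <- list(alpha = 0.5, beta = 0.4)
  lstm_params <- if (defaults$beta > 0 && !is.null(models$lstm_fit$dense)) {
    magnitude_prune(models$lstm_fit$dense, defaults$beta)
  } else {
    models$lstm_fit$params
  }
  list(fusion = list(alpha = defaults$alpha, beta = defaults$beta),
       lstm_params = lstm_params,
       buffer = gp_buffer(models$gp_capacity),
       mode = mode, step_idx = 0L,
       last_proxy = estimate_resources(models$cnn_fit$params, lstm_params,
                                       defaults$alpha, defaults$beta,
                                       models$proxy))
}

#' One window of the five-step runtime loop
#'
#' Executes, in order: (1) ensemble inference through the current
#' configuration, (2) GP buffer update with the observed motion features,
#' (3) risk forecast for the next time window, (4) agent action selection,
#' (5) architecture adjustment — the chosen action reconfigures inference
#' for the *next* window. A window with every channel missing forces the
#' CNN-only fallback (`alpha = 1`) for that window and logs the event.
#'
#' @param window One row of a normalized `motion_windows` tibble (list with
#'   `x`, `start_s`, `valid_frac`, `label` if known).
#' @param rt Runtime state from the session loop.
#' @param models An [ensemble_models()].
#' @return List with `output` (`ensemble_output`), `forecast`, `log` (one-row
#'   tibble) and the updated `rt`.
#' @export
runtime_step <- function(window, rt, models) {
  mode <- rt$mode
  tau <- models$reward_cfg$tau
  degraded <- isTRUE(window$valid_frac <= 0)
  alpha <- if (degraded) 1 else rt$fusion$alpha
  beta <- rt$fusion$beta

  # (1) ensemble inference under the current configuration
  cnn_logits <- cnn_forward(window$x, models$cnn_fit$params,
                            quantized = models$quantized_cnn &&
                              !is.null(models$cnn_fit$params$quant))
  lstm_logits <- if (alpha < 1) {
    lstm_forward(window$x, rt$lstm_params)$logits
  } else {
    matrix(0, 1L, 2L)  # branch skipped
  }

  # (2) GP update with the observed motion pattern
  feats <- window_features(window$x, attr(window, "channels"))
  rt$buffer <- update_buffer(rt$buffer, window$start_s, feats)

  # (3) risk prediction for the next time window
  if (mode == "no_gp" || is.null(models$head)) {
    risk <- 0.5
    forecast <- NULL
  } else {
    forecast <- predict_ahead(rt$buffer, models$theta)
    risk <- risk_score(forecast, models$head)
    forecast$risk <- risk
  }

  out <- fuse_predictions(alpha, as.numeric(cnn_logits),
                          as.numeric(lstm_logits), risk = if (mode == "no_gp")
                            NA_real_ else risk, tau = tau)

  # (4) agent action selection / (5) architecture adjustment for next window
  repruned <- FALSE
  action <- NA_integer_
  adapts <- mode %in% c("full", "no_gp", "no_dyn_prune") &&
    !is.null(models$agent)
  if (adapts) {
    state <- build_state(out$y_hat, min(max(risk, 1e-6), 1 - 1e-6),
                         rt$last_proxy$cpu_usage,
                         rt$last_proxy$energy_proxy)
    q <- q_forward(state, models$agent$net)
    cand <- seq_len(nrow(models$grid))
    if (mode == "no_dyn_prune") {
      cand <- which(abs(models$grid$beta - 0.4) < 1e-9)
    }
    action <- cand[which.max(q[cand])]
    row <- models$grid[action, ]
    ap <- apply_action(rt$fusion, row, models$lstm_fit$dense)
    rt$fusion <- ap$fusion_state
    if (!is.null(ap$lstm_params)) rt$lstm_params <- ap$lstm_params
    repruned <- ap$repruned
  }

  proxy <- estimate_resources(models$cnn_fit$params, rt$lstm_params,
                              alpha, beta, models$proxy)
  ad_macs <- adaptation_macs(
    length(rt$buffer$t), length(feats), models$agent$net %||%
      q_network(5L, nrow(models$grid), seed = 0L),
    repruned, lstm_prunable_count(models$lstm_fit$params))
  if (mode %in% c("no_rl", "fixed_ensemble")) {
    ad_macs <- ad_macs - (if (is.null(models$agent)) 0 else
      models$agent$net$hidden * models$agent$net$state_dim +
      models$agent$net$n_actions * models$agent$net$hidden)
  }
  if (mode == "no_gp") {
    ad_macs <- ad_macs - length(feats) *
      (length(rt$buffer$t)^3 / 3 + 2 * length(rt$buffer$t)^2 +
         length(rt$buffer$t))
  }
  rt$last_proxy <- proxy
  rt$step_idx <- rt$step_idx + 1L

  win_start <- window$start_s
  log <- tibble::tibble(
    window = rt$step_idx, start_s = win_start,
    alpha = alpha, beta = beta,
    p_risk = out$y_hat[2L], decision = out$decision,
    risk_forecast = risk, alert = out$alert,
    cpu = proxy$cpu_usage, energy = proxy$energy_proxy,
    latency = proxy$latency_proxy,
    inference_macs = proxy$mac_count, adaptation_macs = max(ad_macs, 0),
    action = action, degraded = degraded
  )
  list(output = out, forecast = forecast, log = log, rt = rt)
}

#' Run a full session through the adaptive runtime
#'
#' Preprocesses and normalizes the stream, then executes the five-step loop
#' over every window. Ablation modes: `no_rl` fixes `(alpha, beta)` at the
#' defaults (0.5, 0.4); `no_gp` feeds a constant risk of 0.5 and disables the
#' risk-indicator reward term; `no_dyn_prune` lets the agent set `alpha` but
#' holds `beta` at the training-time 0.4; `fixed_ensemble` fixes
#' `alpha = 0.5, beta = 0.4` with the agent off.
#'
#' @param stream An `imu_stream` (raw; preprocessing is applied here), or a
#'   pre-labeled, pre-normalized `motion_windows` tibble.
#' @param models An [ensemble_models()].
#' @param mode One of `"full"`, `"no_rl"`, `"no_gp"`, `"no_dyn_prune"`,
#'   `"fixed_ensemble"`.
#' @param calib Optional calibration passed to [preprocess_stream()].
#' @return A `session_run`: `logs` (per-window tibble), `events`, `mode`.
#' @export
run_session <- function(stream, models,
                        mode = c("full", "no_rl", "no_gp", "no_dyn_prune",
                                 "fixed_ensemble"),
                        calib = NULL) {
  mode <- match.arg(mode)
  if (inherits(stream, "imu_stream")) {
    windows <- preprocess_stream(stream, calib)
    windows <- z_normalize(windows, models$norm_stats)
    events <- stream$events
    segments <- stream$segments
  } else {
    windows <- stream
    events <- attr(stream, "events") %||% empty_events()
    segments <- attr(stream, "segments") %||% NULL
  }
  rt <- init_runtime_state(models, mode)
  chans <- attr(windows, "channels")
  logs <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- list(x = windows$x[[i]], start_s = windows$start_s[i],
              valid_frac = windows$valid_frac[i])
    attr(w, "channels") <- chans
    res <- runtime_step(w, rt, models)
    rt <- res$rt
    logs[[i]] <- res$log
  }
  logs <- dplyr::bind_rows(logs)
  if (!is.null(windows$label)) logs$label <- windows$label
  structure(list(logs = logs, events = events, segments = segments,
                 mode = mode, tau = models$reward_cfg$tau),
            class = "session_run")
}

#' @export
print.session_run <- function(x, ...) {
  cat(sprintf("<session_run:%s> %d windows, %d events, %d alert windows\n",
              x$mode, nrow(x$logs), nrow(x$events), sum(x$logs$alert)))
  invisible(x)
}

#' Build a replay environment over preprocessed sessions
#'
#' Wraps a list of labeled, normalized window sets as an episodic environment
#' for [run_training()]: one session per episode, one window per step. Branch
#' probabilities for every pruning ratio in the grid and the GP risk trace
#' are precomputed so agent training touches only the fusion arithmetic and
#' reward.
#'
#' @param window_sets List of labeled, normalized `motion_windows`.
#' @param models An [ensemble_models()] (agent slot unused).
#' @param seed Seed for episode ordering.
#' @return Environment list with `reset`, `step`, `n_actions`.
#' @export
make_adaptation_env <- function(window_sets, models, seed = 1L) {
  grid <- models$grid
  cfg <- models$reward_cfg
  betas <- sort(unique(grid$beta))
  # class weights for the accuracy term (mean 1 over the window
  # distribution), mirroring the weighted loss used for branch training
  all_labels <- unlist(purrr::map(window_sets, function(w)
    as.character(w$label)))
  cw <- c(no_risk = 1, risk = 1)
  if (isTRUE(attr(cfg, "class_weighted_accuracy"))) {
    tab <- table(factor(all_labels, levels = c("no_risk", "risk")))
    if (all(tab > 0)) cw <- as.numeric(sum(tab) / (2 * tab))
  }
  prep <- purrr::map(window_sets, function(w) {
    x <- as_window_array(w$x, models$cnn_fit$params$n_channels)
    p_cnn <- softmax_rows(cnn_forward(x, models$cnn_fit$params,
                                      quantized = models$quantized_cnn &&
                                        !is.null(models$cnn_fit$params$quant)))
    p_lstm <- purrr::map(betas, function(b) {
      pars <- if (b > 0) magnitude_prune(models$lstm_fit$dense, b) else
        models$lstm_fit$dense
      softmax_rows(lstm_forward(x, pars)$logits)
    })
    names(p_lstm) <- as.character(betas)
    # GP risk trace (action-independent)
    risk <- rep(0.5, nrow(w))
    if (!is.null(models$head)) {
      buf <- gp_buffer(models$gp_capacity)
      for (i in seq_len(nrow(w))) {
        buf <- update_buffer(buf, w$start_s[i],
                             window_features(w$x[[i]], attr(w, "channels")))
        fc <- predict_ahead(buf, models$theta)
        risk[i] <- risk_score(fc, models$head)
      }
    }
    list(y = as.integer(w$label), p_cnn = p_cnn, p_lstm = p_lstm, risk = risk)
  })
  env <- new.env()
  env$i_sess <- 0L
  env$i_win <- 0L
  state_at <- function(sess, i, alpha, beta, proxy_last) {
    pl <- sess$p_lstm[[as.character(beta)]][i, ]
    y_hat <- alpha * sess$p_cnn[i, ] + (1 - alpha) * pl
    c(y_hat, min(max(sess$risk[i], 1e-6), 1 - 1e-6),
      proxy_last$cpu_usage, proxy_last$energy_proxy)
  }
  list(
    n_actions = nrow(grid),
    reset = function() {
      env$i_sess <- (env$i_sess %% length(prep)) + 1L
      env$i_win <- 1L
      env$fusion <- list(alpha = 0.5, beta = 0.4)
      env$proxy <- estimate_resources(models$cnn_fit$params,
                                      models$lstm_fit$params, 0.5, 0.4,
                                      models$proxy)
      state_at(prep[[env$i_sess]], 1L, 0.5, 0.4, env$proxy)
    },
    step = function(action) {
      sess <- prep[[env$i_sess]]
      row <- grid[action, ]
      i <- env$i_win
      pl <- sess$p_lstm[[as.character(row$beta)]][i, ]
      y_hat <- row$alpha * sess$p_cnn[i, ] + (1 - row$alpha) * pl
      proxy <- estimate_resources(models$cnn_fit$params,
                                  models$lstm_fit$params,
                                  row$alpha, row$beta, models$proxy)
      lambda4 <- if (is.null(models$head)) 0 else cfg$lambda4
      reward <- cfg$lambda1 * cw[sess$y[i]] *
        as.numeric(which.max(y_hat) == sess$y[i]) -
        cfg$lambda2 * proxy$latency_proxy / cfg$latency_scale -
        cfg$lambda3 * proxy$energy_proxy / cfg$energy_scale +
        lambda4 * as.numeric(sess$risk[i] > cfg$tau)
      env$proxy <- proxy
      env$fusion <- list(alpha = row$alpha, beta = row$beta)
      done <- i >= length(sess$y)
      j <- min(i + 1L, length(sess$y))
      env$i_win <- j
      list(state = state_at(sess, j, row$alpha, row$beta, proxy),
           reward = reward, done = done)
    }
  )
}
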