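#' Simulate a cohort of subjects
#'
#' One session per synthetic subject, each with its own substream of the
#' global seed, plus a subject-level train/validation/test split.
#'
#' @param cfg A validated `run_config` (or `NULL` for defaults).
#' @param seed Overrides `cfg$seed`.
#' @return List with `streams` (named by subject) and `split`.
#' @export
simulate_cohort <- function(cfg = NULL, seed = NULL) {
  cfg <- validate_config(cfg)
  seed <- seed %||% cfg$seed
  sim <- cfg$simulation
  subjects <- sprintf("S%02d", seq_len(sim$n_subjects))
  streams <- purrr::map(seq_along(subjects), function(i) {
    generate_session(
      duration_s = sim$duration_s, injury_rate = sim$injury_rate,
      seed = child_seed(seed, paste0("sim", i)),
      sample_rate = sim$sample_rate, bilateral = sim$bilateral,
      magnetometer = sim$magnetometer, drift_window_s = sim$drift_window_s,
      subject = subjects[i])
  })
  names(streams) <- subjects
  split <- split_subjects(subjects, seed = child_seed(seed, "split"))
  list(streams = streams, split = split)
}

#' Preprocess a cohort into labeled, normalized window sets
#'
#' Runs the conditioning chain on every stream, computes normalization
#' statistics on the training split only, and rebalances the pooled training
#' windows with SMOTE plus class weights.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param cfg A validated `run_config`.
#' @return List with `train` (rebalanced windows), `class_weights`,
#'   `train_sets`, `val_sets`, `test_sets` (per-session normalized windows),
#'   `norm_stats`.
#' @export
preprocess_cohort <- function(cohort, cfg = NULL) {
  cfg <- validate_config(cfg)
  pp <- cfg$preprocessing
  winsets <- purrr::map(cohort$streams, function(s) {
    w <- preprocess_stream(s, target_hz = pp$target_hz,
                           window_s = pp$window_s, overlap = pp$overlap,
                           cutoff_hz = pp$cutoff_hz)
    attr(w, "events") <- s$events
    w
  })
  split <- cohort$split
  by_split <- function(tag) winsets[names(winsets)[split[names(winsets)] == tag]]
  train_sets <- by_split("train")
  stats <- compute_norm_stats(dplyr::bind_rows(train_sets), split = "train")
  normalize_all <- function(sets) purrr::map(sets, z_normalize, stats = stats)
  train_sets <- normalize_all(train_sets)
  val_sets <- normalize_all(by_split("validation"))
  test_sets <- normalize_all(by_split("test"))
  pooled_train <- dplyr::bind_rows(train_sets)
  reb <- with_seed(child_seed(cfg$seed, "smote"), {
    rebalance_training(pooled_train, target_ratio = pp$smote_ratio,
                       k = pp$smote_k)
  })
  list(train = reb$windows, class_weights = reb$class_weights,
       train_sets = train_sets, val_sets = val_sets, test_sets = test_sets,
       norm_stats = stats)
}

#' GP forecast features aligned with next-window labels
#'
#' Streams the training windows through the sliding-buffer GP and pairs each
#' forecast with the label of the window containing the forecast time.
#'
#' @param windows Labeled, normalized `motion_windows`.
#' @param theta Kernel hyperparameters.
#' @param capacity Buffer capacity.
#' @param horizon_s Forecast horizon.
#' @return List with `X` (forecast features) and `y` (aligned labels, 0/1).
#' @export
forecast_features_over <- function(windows, theta = gp_kernel_params(),
                                   capacity = 50L, horizon_s = 0.150) {
  n <- nrow(windows)
  buf <- gp_buffer(capacity)
  stride_s <- if (n >= 2L) windows$start_s[2L] - windows$start_s[1L] else 0.1
  lead <- max(1L, floor(horizon_s / stride_s))  # window containing t + horizon
  X <- NULL
  y <- integer(0)
  chans <- attr(windows, "channels")
  for (i in seq_len(n)) {
    buf <- update_buffer(buf, windows$start_s[i],
                         window_features(windows$x[[i]], chans))
    j <- i + lead
    if (j > n) break
    fc <- predict_ahead(buf, theta, horizon_s)
    X <- rbind(X, fc$x_hat)
    y <- c(y, as.integer(windows$label[j] == "risk"))
  }
  list(X = X, y = y)
}

#' Train all model components on a preprocessed cohort
#'
#' Trains both ensemble branches, calibrates CNN quantization, optionally
#' refits the GP hyperparameters, fits the risk head on forecast features,
#' and trains the Q-learning agent on the training sessions.
#'
#' @param prep Output of [preprocess_cohort()].
#' @param cfg A validated `run_config`.
#' @param train_agent Set `FALSE` to skip agent training.
#' @return An [ensemble_models()] bundle.
#' @export
train_models <- function(prep, cfg = NULL, train_agent = TRUE) {
  cfg <- validate_config(cfg)
  mc <- cfg$models
  tc <- train_config(learning_rate = mc$learning_rate,
                     batch_size = mc$batch_size,
                     max_epochs = mc$max_epochs, patience = mc$patience,
                     seed = child_seed(cfg$seed, "branches"))
  val <- if (length(prep$val_sets)) dplyr::bind_rows(prep$val_sets) else NULL
  cnn_fit <- train_branch(prep$train, val, "cnn", tc, prep$class_weights)
  lstm_fit <- train_branch(prep$train, val, "lstm", tc, prep$class_weights,
                           prune_ratio = mc$prune_ratio)
  # quantization calibration on a held-out batch (validation if present)
  calib_w <- val %||% prep$train
  n_cal <- min(nrow(calib_w), 256L)
  x_cal <- as_window_array(calib_w$x[seq_len(n_cal)],
                           cnn_fit$params$n_channels)
  cnn_fit$params <- cnn_calibrate_quantization(cnn_fit$params, x_cal)

  gpcfg <- cfg$gp
  theta <- gp_kernel_params(gpcfg$sigma_f_sq, gpcfg$sigma_p_sq,
                            gpcfg$matern_length, gpcfg$periodic_length,
                            gpcfg$periodic_period, gpcfg$noise_var)
  pooled_train <- dplyr::bind_rows(prep$train_sets)
  if (isTRUE(gpcfg$refit)) {
    feats <- t(vapply(pooled_train$x,
                      function(m) window_features(m, attr(pooled_train, "channels")),
                      numeric(length(window_features(pooled_train$x[[1L]])))))
    n_fit <- min(nrow(feats), 200L)
    theta <- fit_hyperparameters(pooled_train$start_s[seq_len(n_fit)],
                                 feats[seq_len(n_fit), , drop = FALSE],
                                 init = theta,
                                 seed = child_seed(cfg$seed, "gp"))
  }
  ffs <- purrr::map(prep$train_sets, forecast_features_over, theta = theta,
                    capacity = gpcfg$buffer, horizon_s = gpcfg$horizon_s)
  ff <- list(X = do.call(rbind, purrr::map(ffs, "X")),
             y = unlist(purrr::map(ffs, "y")))
  head <- if (length(unique(ff$y)) == 2L) {
    h <- fit_risk_head(ff$X, ff$y, balanced = TRUE)
    # calibrate the alert operating point on the validation sessions
    ffv <- if (length(prep$val_sets)) {
      vv <- purrr::map(prep$val_sets, forecast_features_over, theta = theta,
                       capacity = gpcfg$buffer, horizon_s = gpcfg$horizon_s)
      list(X = do.call(rbind, purrr::map(vv, "X")),
           y = unlist(purrr::map(vv, "y")))
    } else {
      ff
    }
    calibrate_risk_head(h, ffv$X, ffv$y, tau = cfg$runtime$tau)
  } else {
    NULL
  }

  rl <- cfg$rl
  # latency/energy proxies are normalized by their full-configuration values
  # so the lambda weights act on a comparable [0, 1] scale
  rcfg <- reward_config(rl$lambda1, rl$lambda2, rl$lambda3, rl$lambda4,
                        tau = cfg$runtime$tau,
                        latency_scale = cfg$runtime$latency_full,
                        energy_scale = cfg$runtime$energy_full)
  attr(rcfg, "class_weighted_accuracy") <- isTRUE(rl$class_weighted_accuracy)
  models <- ensemble_models(cnn_fit, lstm_fit, prep$norm_stats, theta, head,
                            agent = NULL, grid = action_grid(),
                            reward_cfg = rcfg,
                            gp_capacity = gpcfg$buffer,
                            quantized_cnn = mc$quantized_cnn)
  if (train_agent) {
    env <- make_adaptation_env(prep$train_sets, models,
                               seed = child_seed(cfg$seed, "env"))
    models$agent <- run_training(
      env, episodes = rl$episodes,
      schedule = exploration_schedule(rl$train_eps_start, rl$train_eps_end,
                                      rl$train_decay_steps),
      gamma = rl$gamma, learning_rate = rl$learning_rate,
      batch_size = rl$batch_size, buffer_capacity = rl$replay,
      sync_every = rl$sync_every, update_every = rl$update_every,
      seed = child_seed(cfg$seed, "agent"))
  }
  models
}

stage_file <- function(out_dir, name) file.path(out_dir, paste0(name, ".rds"))

run_stage <- function(name, out_dir, manifest, force, compute) {
  f <- stage_file(out_dir, name)
  if (!force && file.exists(f)) {
    return(list(value = readRDS(f), recomputed = FALSE))
  }
  value <- compute()
  saveRDS(value, f)
  list(value = value, recomputed = TRUE)
}

#' Run the full pipeline end to end
#'
#' simulate -> preprocess -> train -> run (all ablation modes on the test
#' sessions) -> evaluate, with each stage checkpointed under `out_dir`.
#' Deleting an intermediate checkpoint recomputes that stage and everything
#' downstream while reusing upstream results; a changed configuration hash
#' invalidates all checkpoints. Re-running with the same seed reproduces
#' identical metrics.
#'
#' @param cfg A `run_config` (or `NULL` for defaults).
#' @param out_dir Output directory (default from the config).
#' @param modes Runtime modes to evaluate.
#' @param force Recompute everything.
#' @return A `run_manifest`: config hash, seeds, stage status, per-mode
#'   `metric_report`s, and the trained models.
#' @export
run_end_to_end <- function(cfg = NULL, out_dir = NULL,
                           modes = c("full", "no_rl", "no_gp",
                                     "no_dyn_prune", "fixed_ensemble"),
                           force = FALSE) {
  cfg <- validate_config(cfg)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  hash_file <- file.path(out_dir, "config-hash.txt")
  if (file.exists(hash_file) && !identical(readLines(hash_file), hash)) {
    force <- TRUE
  }
  writeLines(hash, hash_file)
  write_run_config(cfg, file.path(out_dir, "config.yaml"))

  stages <- logical(0)
  sim <- run_stage("01-simulate", out_dir, NULL, force,
                   function() simulate_cohort(cfg))
  force <- force || sim$recomputed
  stages <- c(stages, simulate = sim$recomputed)
  prep <- run_stage("02-preprocess", out_dir, NULL, force,
                    function() preprocess_cohort(sim$value, cfg))
  force <- force || prep$recomputed
  stages <- c(stages, preprocess = prep$recomputed)
  models <- run_stage("03-train", out_dir, NULL, force,
                      function() train_models(prep$value, cfg))
  force <- force || models$recomputed
  stages <- c(stages, train = models$recomputed)
  runs <- run_stage("04-run", out_dir, NULL, force, function() {
    eval_sets <- if (length(prep$value$test_sets)) prep$value$test_sets else
      prep$value$train_sets
    purrr::map(stats::setNames(modes, modes), function(m) {
      purrr::map(eval_sets, function(w) run_session(w, models$value, mode = m))
    })
  })
  force <- force || runs$recomputed
  stages <- c(stages, run = runs$recomputed)
  reports <- run_stage("05-evaluate", out_dir, NULL, force, function() {
    ev <- cfg$evaluation
    purrr::map(runs$value, evaluate_sessions,
               match_window = c(-ev$match_before_s, ev$match_after_s),
               merge_gap_s = ev$merge_gap_s)
  })
  stages <- c(stages, evaluate = reports$recomputed)

  metrics <- purrr::imap(reports$value, function(rep, mode) {
    list(mode = mode, ida_pct = rep$ida_pct, far_pct = rep$far_pct,
         apa150_pct = rep$apa150_pct,
         adaptation_overhead_pct = rep$adaptation_overhead_pct)
  })
  jsonlite::write_json(list(config_hash = hash, seed = cfg$seed,
                            metrics = metrics),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(config_hash = hash, seed = cfg$seed, out_dir = out_dir,
                 stages = stages, reports = reports$value,
                 models = models$value),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %s (seed %d)\n", x$config_hash, x$seed))
  for (m in names(x$reports)) {
    r <- x$reports[[m]]
    cat(sprintf("  %-14s IDA %5.1f%%  FAR %5.1f%%  APA %5.1f%%\n",
                m, r$ida_pct, r$far_pct, r$apa150_pct))
  }
  invisible(x)
}
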