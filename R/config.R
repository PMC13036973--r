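#' Default run configuration
#'
#' Single-document configuration with one section per module. Defaults carry
#' the framework's operating constants: risk threshold 0.6, kernel variances
#' 1.24 / 0.58, 50-observation GP buffer, 10,000-transition replay buffer,
#' epsilon 0.1 -> 0.01 over 1,000 steps, 200 ms windows with 50 % overlap at
#' 200 Hz, 20 Hz low-pass cutoff, prune ratio 0.4.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "ankleguard-run",
    simulation = list(
      n_subjects = 5L, duration_s = 120, injury_rate = 12,
      sample_rate = 200, bilateral = FALSE, magnetometer = FALSE,
      drift_window_s = 0.5
    ),
    preprocessing = list(
      cutoff_hz = 20, filter_order = 4L, window_s = 0.2, overlap = 0.5,
      target_hz = 200, blend = 0.98, smote_ratio = 1, smote_k = 5L
    ),
    models = list(
      prune_ratio = 0.4, conv_order = "as_printed", quantized_cnn = TRUE,
      learning_rate = 1e-3, batch_size = 64L, max_epochs = 12L, patience = 3L
    ),
    gp = list(
      sigma_f_sq = 1.24, sigma_p_sq = 0.58, matern_length = 0.5,
      periodic_length = 0.3, periodic_period = 0.7, noise_var = 0.05,
      buffer = 50L, horizon_s = 0.150, refit = FALSE
    ),
    rl = list(
      # deployment exploration: the documented 0.1 -> 0.01 decay
      eps_start = 0.1, eps_end = 0.01, decay_steps = 1000L,
      # training exploration: broad early coverage of the action grid
      train_eps_start = 1.0, train_eps_end = 0.05,
      train_decay_steps = 2000L,
      replay = 10000L, gamma = 0.5, sync_every = 100L, update_every = 4L,
      learning_rate = 3e-3, batch_size = 64L, episodes = 30L,
      hidden = 32L, class_weighted_accuracy = TRUE,
      lambda1 = 1.0, lambda2 = 0.01, lambda3 = 0.01, lambda4 = 0.5
    ),
    runtime = list(
      tau = 0.6, alpha_default = 0.5, beta_default = 0.4,
      latency_full = 26.4, energy_full = 4.8
    ),
    evaluation = list(
      match_before_s = 1.0, match_after_s = 0.1, merge_gap_s = 0.2,
      lead_threshold_ms = 150
    )
  )
}

#' Validate and complete a configuration document
#'
#' Accepts a nested list or a YAML file path, fills missing keys from
#' [default_run_config()], rejects unknown keys and out-of-range values.
#' Serialization round-trips bit-identically through
#' [write_run_config()] / [read_run_config()].
#'
#' @param document Nested list, YAML path, or `NULL` for all defaults.
#' @return Validated `run_config` list.
#' @export
validate_config <- function(document = NULL) {
  if (is.character(document)) document <- yaml::read_yaml(document)
  document <- document %||% list()
  defaults <- default_run_config()
  merge_checked <- function(def, doc, path = "") {
    unknown <- setdiff(names(doc), names(def))
    if (length(unknown)) {
      abort(paste0("unknown config key(s): ",
                   paste0(path, unknown, collapse = ", ")))
    }
    for (k in names(doc)) {
      if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
        def[[k]] <- merge_checked(def[[k]], doc[[k]], paste0(path, k, "."))
      } else {
        def[[k]] <- doc[[k]]
      }
    }
    def
  }
  cfg <- merge_checked(defaults, document)
  with(cfg, {
    if (runtime$tau <= 0 || runtime$tau >= 1) abort("tau must be in (0, 1)")
    if (preprocessing$overlap < 0 || preprocessing$overlap >= 1) {
      abort("overlap must be in [0, 1)")
    }
    if (gp$sigma_f_sq <= 0 || gp$sigma_p_sq <= 0 || gp$noise_var <= 0) {
      abort("kernel variances must be positive")
    }
    if (models$prune_ratio < 0 || models$prune_ratio >= 1) {
      abort("prune_ratio must be in [0, 1)")
    }
    if (simulation$sample_rate <= 2 * preprocessing$cutoff_hz) {
      abort("sample rate must exceed twice the low-pass cutoff")
    }
  })
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname validate_config
#' @param cfg A `run_config`.
#' @param path YAML output path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname validate_config
#' @export
read_run_config <- function(path) validate_config(yaml::read_yaml(path))

#' Stable hash of a configuration
#' @param cfg A `run_config`.
#' @return Character hash.
#' @export
config_hash <- function(cfg) rlang::hash(unclass(cfg))
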