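# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture_config <- function() {
  validate_config(list(
    simulation = list(n_subjects = 5L, duration_s = 30),
    models = list(max_epochs = 4L, patience = 2L)
  ))
}

# A small trained pipeline: 5 subjects x 30 s, both branches, GP head, agent.
fixture_models <- function() {
  if (is.null(.fixture_env$models)) {
    cfg <- fixture_config()
    sim <- simulate_cohort(cfg)
    prep <- preprocess_cohort(sim, cfg)
    .fixture_env$cfg <- cfg
    .fixture_env$sim <- sim
    .fixture_env$prep <- prep
    .fixture_env$models <- train_models(prep, cfg)
  }
  .fixture_env$models
}

fixture_prep <- function() {
  fixture_models()
  .fixture_env$prep
}

# A small labeled, normalized window set (no training required).
fixture_windows <- function() {
  if (is.null(.fixture_env$windows)) {
    s <- generate_session(20, seed = 101)
    w <- preprocess_stream(s)
    st <- compute_norm_stats(w)
    .fixture_env$windows <- z_normalize(w, st)
    .fixture_env$window_stream <- s
  }
  .fixture_env$windows
}

# Shared end-to-end run, memoized across test files.
fixture_e2e <- function() {
  if (is.null(.fixture_env$e2e)) {
    dir <- file.path(tempdir(), "ankleguard-e2e")
    .fixture_env$e2e <- run_end_to_end(fixture_config(), out_dir = dir)
    .fixture_env$e2e_dir <- dir
  }
  .fixture_env$e2e
}

# Brute-force nested-loop depthwise-separable convolution oracle
# (pointwise then depthwise, "same" padding, ReLU), independent of the
# package's vectorized implementation.
oracle_separable_conv <- function(x, W_d, W_p, stride) {
  T_in <- nrow(x); C_out <- ncol(W_p); k <- nrow(W_d)
  pad <- (k - 1) %/% 2
  p <- matrix(0, T_in, C_out)
  for (tt in seq_len(T_in)) {
    for (co in seq_len(C_out)) {
      p[tt, co] <- sum(x[tt, ] * W_p[, co])
    }
  }
  T_out <- ceiling(T_in / stride)
  out <- matrix(0, T_out, C_out)
  for (to in seq_len(T_out)) {
    center <- (to - 1) * stride + 1
    for (co in seq_len(C_out)) {
      acc <- 0
      for (kk in seq_len(k)) {
        src <- center + kk - 1 - pad
        if (src >= 1 && src <= T_in) acc <- acc + W_d[kk, co] * p[src, co]
      }
      out[to, co] <- max(acc, 0)
    }
  }
  out
}

# Dense-matrix constant-mean GP posterior oracle (direct formulas, no shared
# code paths with predict_ahead beyond the exported kernel).
oracle_gp_posterior <- function(t_obs, y, t_star, theta) {
  n <- length(t_obs)
  K <- outer(t_obs, t_obs, function(a, b) kernel_eval(a, b, theta)) +
    diag(theta$noise_var, n)
  ks <- vapply(t_obs, function(ti) kernel_eval(ti, t_star, theta), numeric(1))
  Kinv <- solve(K)
  mu <- mean(y)
  list(mean = mu + as.numeric(ks %*% Kinv %*% (y - mu)),
       var = kernel_eval(t_star, t_star, theta) -
         as.numeric(ks %*% Kinv %*% ks))
}
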