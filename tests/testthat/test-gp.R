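test_that("kernel evaluates to sigma_f_sq + sigma_p_sq at zero distance", {
  expect_equal(kernel_eval(1.3, 1.3), 1.24 + 0.58, tolerance = 1e-12)
  th <- gp_kernel_params(sigma_f_sq = 2, sigma_p_sq = 1e-12)
  expect_lt(kernel_eval(0, 1e6, th), 1e-6)      # Matern decay limit
  set.seed(1)
  a <- runif(100, 0, 10); b <- runif(100, 0, 10)
  expect_equal(kernel_eval(a, b), kernel_eval(b, a))
  expect_error(gp_kernel_params(sigma_f_sq = -1), "positive")
})

test_that("the buffer is FIFO with a hard 50-observation cap", {
  b <- gp_buffer(50L)
  for (i in 1:50) b <- update_buffer(b, i, c(i, 0))
  expect_equal(length(b$t), 50L)
  b <- update_buffer(b, 51, c(51, 0))
  expect_equal(length(b$t), 50L)
  expect_equal(b$t[1], 2)            # oldest evicted
  expect_error(update_buffer(b, 10, c(0, 0)), "out-of-order")
  expect_error(predict_ahead(gp_buffer()), "empty buffer")
})

test_that("posterior matches a dense-matrix oracle and interpolates data", {
  th <- gp_kernel_params(noise_var = 1e-10)
  # single noise-free observation, horizon 0: posterior mean = observation
  b <- update_buffer(gp_buffer(), 1.0, c(2.5, -1))
  fc <- predict_ahead(b, th, horizon_s = 0)
  expect_equal(fc$x_hat, c(2.5, -1), tolerance = 1e-8)

  # oracle equivalence on all instances with n <= 10
  set.seed(3)
  th2 <- gp_kernel_params()
  for (n in c(2L, 3L, 5L, 10L)) {
    t_obs <- sort(runif(n, 0, 3))
    y <- cbind(sin(t_obs), rnorm(n))
    b <- gp_buffer()
    for (i in seq_len(n)) b <- update_buffer(b, t_obs[i], y[i, ])
    fc <- predict_ahead(b, th2, horizon_s = 0.15)
    t_star <- t_obs[n] + 0.15
    for (j in 1:2) {
      oracle <- oracle_gp_posterior(t_obs, y[, j], t_star, th2)
      expect_equal(fc$x_hat[j], oracle$mean, tolerance = 1e-8)
      expect_equal(fc$variance[j], oracle$var, tolerance = 1e-8)
    }
    expect_true(all(fc$variance >= 0))
  }
})

test_that("far-horizon forecasts revert to the prior for a Matern-only kernel", {
  th <- gp_kernel_params(sigma_f_sq = 1.5, sigma_p_sq = 1e-12,
                         noise_var = 0.01)
  b <- gp_buffer()
  for (i in 1:5) b <- update_buffer(b, i * 0.1, 3)
  fc <- predict_ahead(b, th, horizon_s = 100)
  # constant-mean GP: reverts to the buffer mean, with prior variance
  expect_equal(fc$x_hat[1], 3, tolerance = 1e-6)
  expect_equal(fc$variance[1], 1.5, tolerance = 1e-6)

  # posterior variance non-decreasing in horizon beyond the last datum
  vars <- vapply(c(0.1, 0.3, 0.6, 1, 2, 5),
                 function(h) predict_ahead(b, th, h)$variance[1], numeric(1))
  expect_true(all(diff(vars) >= -1e-9))
})

test_that("hyperparameter fitting recovers known variances within a factor of 2", {
  set.seed(3)
  th_true <- gp_kernel_params(sigma_f_sq = 1.0, sigma_p_sq = 0.5,
                              matern_length = 0.5, periodic_length = 0.4,
                              periodic_period = 0.7, noise_var = 0.05)
  t_obs <- sort(runif(200, 0, 10))
  K <- outer(t_obs, t_obs, function(a, b) kernel_eval(a, b, th_true)) +
    diag(th_true$noise_var, 200)
  y <- as.numeric(t(chol(K)) %*% rnorm(200))
  fit <- fit_hyperparameters(t_obs, y, restarts = 5L, seed = 3L)
  expect_lt(abs(log2(fit$sigma_f_sq / th_true$sigma_f_sq)), 1)
  expect_lt(abs(log2(fit$sigma_p_sq / th_true$sigma_p_sq)), 1)
  expect_error(fit_hyperparameters(1:5, rnorm(5)), "at least 10")
})

test_that("white noise drives signal variances to the floor; scaling is equivariant", {
  set.seed(4)
  t_obs <- sort(runif(120, 0, 10))
  y <- rnorm(120, sd = 2)
  fit <- fit_hyperparameters(t_obs, y, restarts = 3L, seed = 4L)
  expect_lt(fit$sigma_f_sq + fit$sigma_p_sq, 0.5)
  expect_lt(abs(fit$noise_var - var(y)) / var(y), 0.2)

  fit2 <- fit_hyperparameters(t_obs, 2 * y, restarts = 3L, seed = 4L)
  total1 <- fit$sigma_f_sq + fit$sigma_p_sq + fit$noise_var
  total2 <- fit2$sigma_f_sq + fit2$sigma_p_sq + fit2$noise_var
  expect_lt(abs(total2 / total1 - 4) / 4, 0.1)
})

test_that("the risk head is a calibrated, permutation-invariant logistic fit", {
  expect_equal(risk_score(c(0.5, 0.1),
                          structure(list(w = c(1, -1), b = 0.2),
                                    class = "risk_head")),
               1 / (1 + exp(-0.6)), tolerance = 1e-4)
  expect_equal(risk_score(c(0, 0), structure(list(w = c(0, 0), b = 0),
                                             class = "risk_head")), 0.5)
  big <- structure(list(w = c(100, 100), b = 0), class = "risk_head")
  expect_gt(risk_score(c(10, 10), big), 1 - 1e-12)

  # separable 1-D toy: near-zero training log-loss
  x <- matrix(c(seq(-2, -0.5, length.out = 20),
                seq(0.5, 2, length.out = 20)))
  y <- rep(c(0, 1), each = 20)
  head <- fit_risk_head(x, y)
  p <- vapply(seq_len(40), function(i) risk_score(x[i, ], head), numeric(1))
  logloss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_lt(logloss, 0.1)

  # null calibration: mean predicted risk tracks prevalence
  set.seed(5)
  Xn <- matrix(rnorm(2000), 1000, 2)
  yn <- rbinom(1000, 1, 0.3)
  hn <- fit_risk_head(Xn, yn)
  pn <- vapply(seq_len(1000), function(i) risk_score(Xn[i, ], hn), numeric(1))
  expect_lt(abs(mean(pn) - mean(yn)), 0.05)

  # joint permutation invariance
  perm <- sample(40)
  h2 <- fit_risk_head(x[perm, , drop = FALSE], y[perm])
  expect_equal(h2$w, head$w, tolerance = 1e-8)
  expect_equal(h2$b, head$b, tolerance = 1e-8)

  expect_error(fit_risk_head(x, rep(1, 40)), "both classes")
})
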