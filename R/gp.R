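#' Composite kernel hyperparameters
#'
#' Parameters of the Matern-3/2 plus exp-sine-squared periodic kernel:
#' `k(t, t') = sigma_f_sq * (1 + sqrt(3) d / l) exp(-sqrt(3) d / l) +
#' sigma_p_sq * exp(-2 sin^2(pi d / period) / l_p^2)` with observation noise
#' `noise_var`. Defaults: signal variance 1.24, periodic variance 0.58;
#' length scales 0.5 s (Matern) and 0.3 (periodic), period 0.7 s (one stride),
#' noise 0.05 — all refittable via [fit_hyperparameters()].
#'
#' @param sigma_f_sq,sigma_p_sq Signal and periodic variances (> 0).
#' @param matern_length,periodic_length Length scales (> 0).
#' @param periodic_period Period in seconds (> 0).
#' @param noise_var Observation noise variance (> 0).
#' @return A `gp_kernel_params` list.
#' @export
gp_kernel_params <- function(sigma_f_sq = 1.24, sigma_p_sq = 0.58,
                             matern_length = 0.5, periodic_length = 0.3,
                             periodic_period = 0.7, noise_var = 0.05) {
  vals <- c(sigma_f_sq, sigma_p_sq, matern_length, periodic_length,
            periodic_period, noise_var)
  if (any(!is.finite(vals) | vals <= 0)) {
    abort("all kernel hyperparameters must be strictly positive")
  }
  structure(list(sigma_f_sq = sigma_f_sq, sigma_p_sq = sigma_p_sq,
                 matern_length = matern_length,
                 periodic_length = periodic_length,
                 periodic_period = periodic_period,
                 noise_var = noise_var),
            class = "gp_kernel_params")
}

#' Evaluate the composite kernel
#'
#' @param x_i,x_j Time points (scalars or vectors; recycled pairwise).
#' @param theta A [gp_kernel_params()].
#' @return Covariance value(s).
#' @export
kernel_eval <- function(x_i, x_j, theta = gp_kernel_params()) {
  d <- abs(x_i - x_j)
  m <- sqrt(3) * d / theta$matern_length
  matern <- (1 + m) * exp(-m)
  periodic <- exp(-2 * sin(pi * d / theta$periodic_period)^2 /
                    theta$periodic_length^2)
  theta$sigma_f_sq * matern + theta$sigma_p_sq * periodic
}

kernel_matrix <- function(t1, t2, theta) {
  outer(t1, t2, function(a, b) kernel_eval(a, b, theta))
}

# Cholesky with escalating jitter 1e-8 -> 1e-4 (x10 per step).
chol_jitter <- function(K) {
  jit <- 0
  for (j in c(0, 1e-8 * 10^(0:4))) {
    L <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j))
  }
  abort("covariance not positive definite after jitter escalation to 1e-4")
}

#' Sliding observation buffer
#'
#' Fixed-capacity (default 50) FIFO of `(timestamp, feature vector)`
#' observations; the oldest entry is evicted first, bounding all covariance
#' work at `capacity x capacity`.
#'
#' @param capacity Maximum number of observations.
#' @return A `gp_buffer`.
#' @export
gp_buffer <- function(capacity = 50L) {
  structure(list(capacity = as.integer(capacity), t = numeric(0),
                 x = NULL), class = "gp_buffer")
}

#' @rdname gp_buffer
#' @param buffer A `gp_buffer`.
#' @param time_s Observation timestamp (must exceed the newest entry).
#' @param features Numeric feature vector.
#' @export
update_buffer <- function(buffer, time_s, features) {
  if (length(buffer$t) && time_s <= buffer$t[length(buffer$t)]) {
    abort("out-of-order timestamp: observations must arrive in time order")
  }
  features <- as.numeric(features)
  buffer$t <- c(buffer$t, time_s)
  buffer$x <- rbind(buffer$x, features)
  if (length(buffer$t) > buffer$capacity) {
    keep <- seq.int(length(buffer$t) - buffer$capacity + 1L, length(buffer$t))
    buffer$t <- buffer$t[keep]
    buffer$x <- buffer$x[keep, , drop = FALSE]
  }
  buffer
}

#' @export
print.gp_buffer <- function(x, ...) {
  cat(sprintf("<gp_buffer> %d/%d observations\n", length(x$t), x$capacity))
  invisible(x)
}

#' Exact GP forecast at a fixed horizon
#'
#' Computes the exact Gaussian-process posterior mean and variance for every
#' feature dimension (modeled independently over time) at
#' `t_last + horizon_s`, using the buffered observations. Factorization uses
#' jitter escalation from 1e-8 by factors of 10 up to 1e-4.
#'
#' @param buffer A non-empty [gp_buffer()].
#' @param theta A [gp_kernel_params()].
#' @param horizon_s Forecast horizon in seconds (default 0.150).
#' @return A `gp_forecast`: `x_hat`, `variance`, `horizon_s`, `at_time_s`,
#'   `risk` (unset, `NA`).
#' @export
predict_ahead <- function(buffer, theta = gp_kernel_params(),
                          horizon_s = 0.150) {
  n <- length(buffer$t)
  if (n == 0L) abort("cannot predict from an empty buffer")
  t_star <- buffer$t[n] + horizon_s
  K <- kernel_matrix(buffer$t, buffer$t, theta) + diag(theta$noise_var, n)
  cj <- chol_jitter(K)
  k_star <- kernel_matrix(buffer$t, t_star, theta)[, 1L]
  # constant-mean GP: center each feature on its buffer mean so forecasts
  # of positive-valued features do not shrink toward zero
  mu <- colMeans(buffer$x)
  yc <- sweep(buffer$x, 2L, mu, "-")
  alpha <- backsolve(cj$L, forwardsolve(t(cj$L), yc))
  x_hat <- mu + as.numeric(crossprod(k_star, alpha))
  v <- forwardsolve(t(cj$L), k_star)
  var_star <- kernel_eval(t_star, t_star, theta) - sum(v^2)
  var_star <- max(var_star, 0)
  structure(list(x_hat = x_hat,
                 variance = rep(var_star, length(x_hat)),
                 horizon_s = horizon_s, at_time_s = t_star, risk = NA_real_),
            class = "gp_forecast")
}

# Negative log marginal likelihood of the time-indexed GP, summed over
# independent feature dimensions. par is log(theta) in fixed order.
gp_nll <- function(log_par, t, Y) {
  th <- exp(log_par)
  theta <- gp_kernel_params(th[1], th[2], th[3], th[4], th[5], th[6])
  n <- length(t)
  K <- kernel_matrix(t, t, theta) + diag(theta$noise_var, n)
  cj <- tryCatch(chol_jitter(K), error = function(e) NULL)
  if (is.null(cj)) return(1e10)
  L <- cj$L
  logdet <- 2 * sum(log(diag(L)))
  nll <- 0
  for (j in seq_len(ncol(Y))) {
    a <- forwardsolve(t(L), Y[, j])
    nll <- nll + 0.5 * sum(a^2) + 0.5 * logdet + 0.5 * n * log(2 * pi)
  }
  nll
}

# Analytic gradient of gp_nll in log-parameter space.
gp_nll_grad <- function(log_par, t, Y) {
  th <- exp(log_par)
  theta <- gp_kernel_params(th[1], th[2], th[3], th[4], th[5], th[6])
  n <- length(t)
  D <- abs(outer(t, t, "-"))
  m <- sqrt(3) * D / theta$matern_length
  expm <- exp(-m)
  matern <- (1 + m) * expm
  s <- sin(pi * D / theta$periodic_period)
  cphi <- cos(pi * D / theta$periodic_period)
  per <- exp(-2 * s^2 / theta$periodic_length^2)
  K <- theta$sigma_f_sq * matern + theta$sigma_p_sq * per +
    diag(theta$noise_var, n)
  cj <- tryCatch(chol_jitter(K), error = function(e) NULL)
  if (is.null(cj)) return(rep(0, 6))
  L <- cj$L
  Kinv <- chol2inv(L)
  A <- backsolve(L, forwardsolve(t(L), Y))  # K^{-1} Y
  # d(nll)/dK contracted with dK/dlog(param)
  W <- ncol(Y) * Kinv - tcrossprod(A)  # tr and quadratic terms combined
  dks <- list(
    theta$sigma_f_sq * matern,
    theta$sigma_p_sq * per,
    theta$sigma_f_sq * m^2 * expm,
    theta$sigma_p_sq * per * 4 * s^2 / theta$periodic_length^2,
    theta$sigma_p_sq * per * 4 * pi * D * s * cphi /
      (theta$periodic_period * theta$periodic_length^2),
    diag(theta$noise_var, n)
  )
  vapply(dks, function(dK) 0.5 * sum(W * dK), numeric(1))
}

#' Fit kernel hyperparameters by marginal likelihood
#'
#' Bound-constrained quasi-Newton (`L-BFGS-B`) maximization of the exact GP
#' log marginal likelihood in log-parameter space, with seeded multi-start
#' (default 5 restarts).
#'
#' @param t Observation times (>= 10).
#' @param y Numeric vector or matrix (features in columns).
#' @param init Starting [gp_kernel_params()].
#' @param restarts Number of random restarts.
#' @param seed Seed for restart jitter.
#' @return Fitted `gp_kernel_params` with attribute `"nll"`.
#' @export
fit_hyperparameters <- function(t, y, init = gp_kernel_params(),
                                restarts = 5L, seed = 1L) {
  y <- as.matrix(y)
  if (length(t) < 10L) abort("need at least 10 observations")
  p0 <- log(unlist(init, use.names = FALSE))
  lower <- log(c(1e-4, 1e-4, 1e-3, 1e-2, 1e-2, 1e-6))
  upper <- log(c(1e3, 1e3, 1e2, 1e2, 1e2, 1e3))
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      start <- if (r == 1L) p0 else pmin(pmax(p0 + rnorm(6, sd = 1), lower), upper)
      fit <- tryCatch(
        optim(start, gp_nll, gp_nll_grad, t = t, Y = y, method = "L-BFGS-B",
              lower = lower, upper = upper,
              control = list(maxit = 500, factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) abort("hyperparameter optimization failed for all starts")
  th <- exp(best$par)
  out <- gp_kernel_params(th[1], th[2], th[3], th[4], th[5], th[6])
  attr(out, "nll") <- best$value
  out
}

#' Sigmoid risk head over forecast features
#'
#' @param forecast A `gp_forecast` (or bare feature vector).
#' @param head A `risk_head` from [fit_risk_head()].
#' @return Risk score in (0, 1).
#' @export
risk_score <- function(forecast, head) {
  x <- if (inherits(forecast, "gp_forecast")) forecast$x_hat else
    as.numeric(forecast)
  if (length(head$w) != length(x)) {
    abort("risk head dimension does not match forecast features")
  }
  as.numeric(sigmoid(sum(head$w * x) + head$b))
}

#' Fit the risk head by ridge-penalized logistic regression
#'
#' Deterministic BFGS fit of labels on predicted features (training split),
#' with a small L2 penalty on the weights for stability on separable data.
#'
#' @param X `n x p` matrix of forecast features.
#' @param y Binary labels (0/1, logical, or factor with 2 levels).
#' @param lambda Ridge penalty (default 1e-4).
#' @param balanced Weight observations inversely to class frequency, so the
#'   risk score of a rare pre-injury class is not squashed toward zero (the
#'   alert threshold sits at 0.6). Default `FALSE`.
#' @return A `risk_head`: list with `w` and `b`.
#' @export
fit_risk_head <- function(X, y, lambda = 1e-4, balanced = FALSE) {
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) abort("both classes must be present")
  p <- ncol(X)
  wobs <- rep(1, length(y))
  if (balanced) {
    n1 <- sum(y == 1)
    wobs <- ifelse(y == 1, length(y) / (2 * n1),
                   length(y) / (2 * (length(y) - n1)))
  }
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    eta <- X %*% w + b
    -sum(wobs * (y * eta - log1p(exp(eta)))) + lambda * sum(w^2)
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    mu <- sigmoid(X %*% w + b)
    r <- wobs * (mu - y)
    c(crossprod(X, r) + 2 * lambda * w, sum(r))
  }
  fit <- optim(rep(0, p + 1L), obj, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  structure(list(w = fit$par[seq_len(p)], b = fit$par[p + 1L]),
            class = "risk_head")
}

#' Calibrate the risk head to the alert threshold
#'
#' Shifts the head's intercept so that the F1-optimal score threshold on a
#' held-out split coincides with the operating threshold `tau` (0.6). This
#' mirrors selecting the alert threshold by validation F1 while keeping the
#' threshold constant.
#'
#' @param head A `risk_head`.
#' @param X,y Held-out forecast features and 0/1 labels.
#' @param tau Operating threshold (default 0.6).
#' @return The recalibrated `risk_head`.
#' @export
calibrate_risk_head <- function(head, X, y, tau = 0.6) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!any(y == 1) || !any(y == 0)) return(head)
  eta <- as.numeric(X %*% head$w + head$b)
  sc <- sigmoid(eta)
  cand <- sort(unique(sc))
  if (length(cand) > 512L) {
    cand <- stats::quantile(sc, seq(0.01, 0.99, length.out = 512L),
                            names = FALSE)
  }
  f1 <- vapply(cand, function(th) {
    tp <- sum(sc >= th & y == 1)
    fp <- sum(sc >= th & y == 0)
    fn <- sum(sc < th & y == 1)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  t_star <- cand[which.max(f1)]
  t_star <- min(max(t_star, 1e-6), 1 - 1e-6)
  head$b <- head$b + (log(tau / (1 - tau)) - log(t_star / (1 - t_star)))
  head
}

#' Per-window summary features for the motion forecaster
#'
#' A seven-dimensional motion summary the GP models over time: RMS of each
#' accelerometer axis, absolute mean of each gyroscope axis (gait
#' oscillations average to ~0, while pre-injury drift is a unidirectional
#' rate offset), and the peak gyroscope magnitude. Kept deliberately
#' low-dimensional so the 50-point exact GP stays trivial.
#'
#' @param xw A `samples x channels` window matrix.
#' @param channels Channel names (to locate acc/gyro axes).
#' @return Numeric feature vector (length 7 for a 6-channel stream).
#' @export
window_features <- function(xw, channels = colnames(xw)) {
  channels <- channels %||% paste0("ch", seq_len(ncol(xw)))
  aidx <- grep("acc_", channels)
  gidx <- grep("gyro_", channels)
  if (!length(aidx)) aidx <- seq_len(min(3L, ncol(xw)))
  if (!length(gidx)) gidx <- seq_len(ncol(xw))
  acc_rms <- sqrt(colMeans(xw[, aidx, drop = FALSE]^2))
  gyro_mean <- abs(colMeans(xw[, gidx, drop = FALSE]))
  gyro_peak <- max(sqrt(rowSums(xw[, gidx, drop = FALSE]^2)))
  unname(c(acc_rms, gyro_mean, gyro_peak))
}
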