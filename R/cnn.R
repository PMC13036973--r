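#' Initialize the depthwise-separable 1D-CNN branch
#'
#' Three convolutional blocks with kernel sizes 5, 3, 3 and channel widths
#' 32, 64, 128, each using stride-2 temporal downsampling, batch
#' normalization and ReLU, followed by global average pooling over the final
#' temporal axis and a linear projection to class logits. Each block factors
#' the convolution into a pointwise (1x1 channel-mixing) and a depthwise
#' (per-channel temporal) stage; by default the pointwise stage is applied
#' first, with `conv_order = "conventional"` available for the
#' depthwise-first factorization.
#'
#' @param n_channels Input channel count (default 6).
#' @param n_classes Output classes (default 2).
#' @param kernel_sizes,channels Per-block kernel sizes and output widths.
#' @param conv_order `"as_printed"` (pointwise then depthwise) or
#'   `"conventional"`.
#' @param seed Seed for weight initialization.
#' @return A `cnn_params` object.
#' @export
cnn_init <- function(n_channels = 6L, n_classes = 2L,
                     kernel_sizes = c(5L, 3L, 3L),
                     channels = c(32L, 64L, 128L),
                     conv_order = c("as_printed", "conventional"),
                     seed = 1L) {
  conv_order <- match.arg(conv_order)
  stopifnot(length(kernel_sizes) == length(channels))
  with_seed(seed, {
    blocks <- list()
    c_in <- n_channels
    for (l in seq_along(channels)) {
      c_out <- channels[l]
      k <- kernel_sizes[l]
      # He-style initialization
      dw_ch <- if (conv_order == "as_printed") c_out else c_in
      blocks[[l]] <- list(
        W_p = matrix(rnorm(c_in * c_out, sd = sqrt(2 / c_in)), c_in, c_out),
        W_d = matrix(rnorm(k * dw_ch, sd = sqrt(2 / k)), k, dw_ch),
        bn = list(gamma = rep(1, c_out), beta = rep(0, c_out),
                  mean = rep(0, c_out), var = rep(1, c_out)),
        kernel = k, c_in = c_in, c_out = c_out, stride = 2L
      )
      c_in <- c_out
    }
    structure(list(
      blocks = blocks,
      W_c = matrix(rnorm(c_in * n_classes, sd = sqrt(1 / c_in)), c_in, n_classes),
      b_c = rep(0, n_classes),
      conv_order = conv_order,
      n_channels = n_channels, n_classes = n_classes,
      quant = NULL
    ), class = "cnn_params")
  })
}

# ---- depthwise convolution primitives (batched over [n, T, C] arrays) ----

conv_out_length <- function(len, stride) as.integer(ceiling(len / stride))

# Depthwise 1D convolution with "same" padding and the given stride.
# x: [n, T, C]; W_d: k x C. Returns [n, ceil(T/stride), C].
dwconv_batch <- function(x, W_d, stride) {
  d <- dim(x)
  n <- d[1L]; len <- d[2L]; C <- d[3L]
  k <- nrow(W_d)
  pad <- (k - 1L) %/% 2L
  t_out <- conv_out_length(len, stride)
  centers <- (seq_len(t_out) - 1L) * stride + 1L
  out <- array(0, c(n, t_out, C))
  for (kk in seq_len(k)) {
    src <- centers + (kk - 1L) - pad
    ok <- src >= 1L & src <= len
    if (!any(ok)) next
    xs <- x[, src[ok], , drop = FALSE]
    wk <- W_d[kk, ]
    out[, ok, ] <- out[, ok, , drop = FALSE] +
      sweep(xs, 3L, wk, "*")
  }
  out
}

# Gradients of dwconv_batch: returns list(dx, dW_d).
dwconv_batch_backward <- function(x, W_d, stride, dout) {
  d <- dim(x)
  n <- d[1L]; len <- d[2L]; C <- d[3L]
  k <- nrow(W_d)
  pad <- (k - 1L) %/% 2L
  t_out <- dim(dout)[2L]
  centers <- (seq_len(t_out) - 1L) * stride + 1L
  dx <- array(0, dim(x))
  dW <- matrix(0, k, C)
  for (kk in seq_len(k)) {
    src <- centers + (kk - 1L) - pad
    ok <- src >= 1L & src <= len
    if (!any(ok)) next
    do_k <- dout[, ok, , drop = FALSE]
    xs <- x[, src[ok], , drop = FALSE]
    dW[kk, ] <- apply(do_k * xs, 3L, sum)
    dx[, src[ok], ] <- dx[, src[ok], , drop = FALSE] +
      sweep(do_k, 3L, W_d[kk, ], "*")
  }
  list(dx = dx, dW_d = dW)
}

# Pointwise (1x1) convolution: channel mixing at every time step.
pwconv_batch <- function(x, W_p) {
  d <- dim(x)
  y <- matrix(x, d[1L] * d[2L], d[3L]) %*% W_p
  array(y, c(d[1L], d[2L], ncol(W_p)))
}

pwconv_batch_backward <- function(x, W_p, dout) {
  d <- dim(x)
  xm <- matrix(x, d[1L] * d[2L], d[3L])
  dm <- matrix(dout, d[1L] * d[2L], ncol(W_p))
  list(dx = array(dm %*% t(W_p), d), dW_p = crossprod(xm, dm))
}

#' One depthwise-separable convolution stage
#'
#' Applies the factored convolution to a single `time x channels` input:
#' pointwise channel mixing and per-channel depthwise temporal convolution
#' (order set by `conv_order`), stride-`stride` downsampling with "same"
#' padding, then ReLU. No batch normalization — this is the bare stage the
#' network blocks are built from.
#'
#' @param h_prev `time x channels_in` numeric matrix.
#' @param W_d `kernel x channels` depthwise kernels.
#' @param W_p `channels_in x channels_out` pointwise kernels.
#' @param stride Temporal stride (default 2).
#' @param conv_order `"as_printed"` (pointwise first) or `"conventional"`.
#' @return `ceil(time/stride) x channels_out` matrix.
#' @export
depthwise_separable_conv <- function(h_prev, W_d, W_p, stride = 2L,
                                     conv_order = c("as_printed",
                                                    "conventional")) {
  conv_order <- match.arg(conv_order)
  if (nrow(h_prev) < nrow(W_d)) abort("input shorter than kernel")
  x <- array(h_prev, c(1L, nrow(h_prev), ncol(h_prev)))
  y <- if (conv_order == "as_printed") {
    dwconv_batch(pwconv_batch(x, W_p), W_d, stride)
  } else {
    pwconv_batch(dwconv_batch(x, W_d, stride), W_p)
  }
  matrix(relu(y), dim(y)[2L], dim(y)[3L])
}

bn_eps <- 1e-5

# Batch norm over [n, T, C]: normalize each channel over n*T elements.
bn_forward <- function(x, bn, training) {
  d <- dim(x)
  xm <- matrix(x, d[1L] * d[2L], d[3L])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2L, mu, "-")^2)
  } else {
    mu <- bn$mean
    v <- bn$var
  }
  xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, sqrt(v + bn_eps), "/")
  y <- sweep(sweep(xhat, 2L, bn$gamma, "*"), 2L, bn$beta, "+")
  list(y = array(y, d), cache = list(xhat = xhat, mu = mu, v = v, d = d))
}

bn_backward <- function(dout, bn, cache) {
  d <- cache$d
  m <- d[1L] * d[2L]
  dy <- matrix(dout, m, d[3L])
  xhat <- cache$xhat
  inv_sd <- 1 / sqrt(cache$v + bn_eps)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, bn$gamma, "*")
  # standard batch-norm backward, vectorized per channel
  term1 <- sweep(dxhat, 2L, colMeans(dxhat), "-")
  term2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
  dx <- sweep(term1 - term2, 2L, inv_sd, "*")
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# Forward through all blocks; returns logits and (optionally) caches.
cnn_forward_internal <- function(x, params, training = FALSE,
                                 keep_cache = FALSE, momentum = 0.1) {
  caches <- list()
  h <- x
  for (l in seq_along(params$blocks)) {
    bl <- params$blocks[[l]]
    if (params$conv_order == "as_printed") {
      p <- pwconv_batch(h, bl$W_p)
      z <- dwconv_batch(p, bl$W_d, bl$stride)
    } else {
      p <- dwconv_batch(h, bl$W_d, bl$stride)
      z <- pwconv_batch(p, bl$W_p)
    }
    bnf <- bn_forward(z, bl$bn, training)
    a <- relu(bnf$y)
    if (keep_cache) {
      caches[[l]] <- list(h_in = h, p = p, z = z, bn = bnf$cache, a = a)
    }
    if (training) {
      params$blocks[[l]]$bn$mean <-
        (1 - momentum) * bl$bn$mean + momentum * bnf$cache$mu
      params$blocks[[l]]$bn$var <-
        (1 - momentum) * bl$bn$var + momentum * bnf$cache$v
    }
    h <- a
  }
  # global average pooling over the temporal axis
  feat <- apply(h, c(1L, 3L), mean)
  logits <- sweep(feat %*% params$W_c, 2L, params$b_c, "+")
  list(logits = logits, feat = feat, h_final = h, caches = caches,
       params = params)
}

cnn_backward_internal <- function(fw, params, dlogits) {
  grads <- list(blocks = vector("list", length(params$blocks)))
  grads$W_c <- crossprod(fw$feat, dlogits)
  grads$b_c <- colSums(dlogits)
  dfeat <- dlogits %*% t(params$W_c)
  dh <- array(0, dim(fw$h_final))
  t_fin <- dim(fw$h_final)[2L]
  for (tt in seq_len(t_fin)) dh[, tt, ] <- dfeat / t_fin
  for (l in rev(seq_along(params$blocks))) {
    bl <- params$blocks[[l]]
    cc <- fw$caches[[l]]
    dh <- dh * (cc$a > 0)
    bnb <- bn_backward(dh, bl$bn, cc$bn)
    if (params$conv_order == "as_printed") {
      dw <- dwconv_batch_backward(cc$p, bl$W_d, bl$stride, bnb$dx)
      pw <- pwconv_batch_backward(cc$h_in, bl$W_p, dw$dx)
      dh <- pw$dx
    } else {
      pw <- pwconv_batch_backward(cc$p, bl$W_p, bnb$dx)
      dw <- dwconv_batch_backward(cc$h_in, bl$W_d, bl$stride, pw$dx)
      dh <- dw$dx
    }
    grads$blocks[[l]] <- list(W_p = pw$dW_p, W_d = dw$dW_d,
                              gamma = bnb$dgamma, beta = bnb$dbeta)
  }
  grads
}

#' Calibrate activation quantization scales
#'
#' Runs a held-out batch through the float network, folds batch-norm into the
#' depthwise stage, quantizes all weights symmetrically per tensor, and
#' records per-layer activation scales from the observed activation ranges.
#'
#' @param params A trained `cnn_params`.
#' @param x_calib `[n, 40, channels]` calibration batch.
#' @return `cnn_params` with a populated `quant` slot.
#' @export
cnn_calibrate_quantization <- function(params, x_calib) {
  fw <- cnn_forward_internal(x_calib, params, training = FALSE,
                             keep_cache = TRUE)
  quant <- list(blocks = list(), act_scales = numeric(0))
  h_scale <- max(abs(x_calib)) / 127
  for (l in seq_along(params$blocks)) {
    bl <- params$blocks[[l]]
    inv_sd <- 1 / sqrt(bl$bn$var + bn_eps)
    # fold BN into the (per-channel linear) depthwise stage output
    w_fold <- sweep(bl$W_d, 2L, bl$bn$gamma * inv_sd, "*")
    b_fold <- bl$bn$beta - bl$bn$gamma * bl$bn$mean * inv_sd
    quant$blocks[[l]] <- list(
      W_p = quantize_tensor(bl$W_p),
      W_d = quantize_tensor(w_fold),
      bias = b_fold,
      act_scale = max(abs(fw$caches[[l]]$a)) / 127
    )
  }
  quant$W_c <- quantize_tensor(params$W_c)
  quant$input_scale <- h_scale
  params$quant <- quant
  params
}

cnn_forward_quantized <- function(x, params) {
  if (is.null(params$quant)) abort("quantized path requires calibration")
  q <- params$quant
  h <- fake_quantize_scaled(x, q$input_scale)
  for (l in seq_along(q$blocks)) {
    qb <- q$blocks[[l]]
    bl <- params$blocks[[l]]
    W_p <- dequantize_tensor(qb$W_p)
    W_d <- dequantize_tensor(qb$W_d)
    if (params$conv_order == "as_printed") {
      z <- dwconv_batch(pwconv_batch(h, W_p), W_d, bl$stride)
    } else {
      z <- pwconv_batch(dwconv_batch(h, W_d, bl$stride), W_p)
    }
    z <- sweep(z, 3L, qb$bias, "+")
    h <- fake_quantize_scaled(relu(z), qb$act_scale)
  }
  feat <- apply(h, c(1L, 3L), mean)
  sweep(feat %*% dequantize_tensor(q$W_c), 2L, params$b_c, "+")
}

#' CNN branch forward pass
#'
#' Maps a batch of motion windows through the three convolutional blocks
#' (temporal trace 40 -> 20 -> 10 -> 5), global average pooling and the class
#' projection. With `quantized = TRUE` the int8 inference path is used
#' (requires [cnn_calibrate_quantization()]).
#'
#' @param x A `samples x channels` matrix (one window), a list of such
#'   matrices, or an `[n, samples, channels]` array.
#' @param params `cnn_params`.
#' @param quantized Run the 8-bit path.
#' @return `n x n_classes` logit matrix.
#' @export
cnn_forward <- function(x, params, quantized = FALSE) {
  x <- as_window_array(x, params$n_channels)
  if (quantized) {
    cnn_forward_quantized(x, params)
  } else {
    cnn_forward_internal(x, params)$logits
  }
}

# Coerce window input forms to [n, T, C].
as_window_array <- function(x, n_channels) {
  if (is.list(x) && !is.array(x)) {
    arr <- array(0, c(length(x), nrow(x[[1L]]), ncol(x[[1L]])))
    for (i in seq_along(x)) arr[i, , ] <- x[[i]]
    x <- arr
  } else if (is.matrix(x)) {
    x <- array(x, c(1L, nrow(x), ncol(x)))
  }
  if (dim(x)[3L] != n_channels) {
    abort(sprintf("expected %d channels, got %d", n_channels, dim(x)[3L]))
  }
  x
}

#' Temporal shape trace of the CNN
#'
#' @param params `cnn_params`.
#' @param len Input temporal length (default 40; must be >= the first kernel).
#' @return Tibble with per-block output length and channels.
#' @export
cnn_shape_trace <- function(params, len = 40L) {
  out <- list()
  for (l in seq_along(params$blocks)) {
    len <- conv_out_length(len, params$blocks[[l]]$stride)
    out[[l]] <- tibble::tibble(block = l, length = len,
                               channels = params$blocks[[l]]$c_out)
  }
  dplyr::bind_rows(out)
}
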