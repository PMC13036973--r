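#' Initialize the stacked LSTM branch
#'
#' Two stacked recurrent layers with 64 and 32 hidden units, inter-layer
#' dropout 0.2 (training only), and a linear readout from the last time
#' step's 32-dimensional hidden state to class logits. Input and recurrent
#' weight matrices are the prunable tensors targeted by
#' [magnitude_prune()]; biases and the readout are exempt.
#'
#' @param n_input Input channel count (default 6).
#' @param hidden Hidden sizes per layer (default `c(64, 32)`).
#' @param n_classes Output classes (default 2).
#' @param dropout Inter-layer dropout rate (default 0.2).
#' @param seed Seed for initialization.
#' @return An `lstm_params` object.
#' @export
lstm_init <- function(n_input = 6L, hidden = c(64L, 32L), n_classes = 2L,
                      dropout = 0.2, seed = 1L) {
  with_seed(seed, {
    layers <- list()
    d <- n_input
    for (l in seq_along(hidden)) {
      h <- hidden[l]
      layers[[l]] <- list(
        W = matrix(rnorm(d * 4L * h, sd = sqrt(1 / d)), d, 4L * h),
        U = matrix(rnorm(h * 4L * h, sd = sqrt(1 / h)), h, 4L * h),
        b = c(rep(0, h), rep(1, h), rep(0, 2L * h)),  # forget-gate bias 1
        mask_W = NULL, mask_U = NULL, hidden = h
      )
      d <- h
    }
    structure(list(
      layers = layers,
      W_l = matrix(rnorm(d * n_classes, sd = sqrt(1 / d)), d, n_classes),
      b_l = rep(0, n_classes),
      dropout = dropout, n_input = n_input, n_classes = n_classes
    ), class = "lstm_params")
  })
}

effective_weights <- function(layer) {
  W <- if (is.null(layer$mask_W)) layer$W else layer$W * layer$mask_W
  U <- if (is.null(layer$mask_U)) layer$U else layer$U * layer$mask_U
  list(W = W, U = U)
}

gate_slices <- function(h) {
  list(i = seq_len(h), f = h + seq_len(h), g = 2L * h + seq_len(h),
       o = 3L * h + seq_len(h))
}

#' LSTM branch forward pass
#'
#' Runs a batch of windows through both recurrent layers (masked weights if
#' pruned) and projects the final hidden state to class logits. Dropout
#' between the layers is active only with `training = TRUE`.
#'
#' @param x A window matrix, list of windows, or `[n, T, channels]` array.
#' @param params `lstm_params`.
#' @param state Optional initial state (list per layer of `h`, `c` matrices);
#'   defaults to zeros.
#' @param training Apply inter-layer dropout.
#' @param keep_cache Retain per-step activations (for backpropagation).
#' @return List with `logits` (`n x n_classes`), `h` (final hidden), `state`.
#' @export
lstm_forward <- function(x, params, state = NULL, training = FALSE,
                         keep_cache = FALSE) {
  x <- as_window_array(x, params$n_input)
  n <- dim(x)[1L]; T_len <- dim(x)[2L]
  if (!is.null(state)) {
    if (length(state) != length(params$layers) ||
        !all(vapply(seq_along(state), function(l) {
          ncol(state[[l]]$h) == params$layers[[l]]$hidden
        }, logical(1)))) {
      abort("state dimensions do not match layer hidden sizes")
    }
  }
  caches <- list()
  inp <- x
  drop_masks <- list()
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    h_sz <- ly$hidden
    ew <- effective_weights(ly)
    sl <- gate_slices(h_sz)
    h <- if (is.null(state)) matrix(0, n, h_sz) else state[[l]]$h
    cc <- if (is.null(state)) matrix(0, n, h_sz) else state[[l]]$c
    outs <- array(0, c(n, T_len, h_sz))
    layer_cache <- if (keep_cache) vector("list", T_len) else NULL
    for (tt in seq_len(T_len)) {
      xt <- matrix(inp[, tt, ], n, dim(inp)[3L])
      z <- xt %*% ew$W + h %*% ew$U + matrix(ly$b, n, 4L * h_sz, byrow = TRUE)
      gi <- sigmoid(z[, sl$i, drop = FALSE])
      gf <- sigmoid(z[, sl$f, drop = FALSE])
      gg <- tanh(z[, sl$g, drop = FALSE])
      go <- sigmoid(z[, sl$o, drop = FALSE])
      c_prev <- cc
      cc <- gf * c_prev + gi * gg
      tc <- tanh(cc)
      h_prev <- h
      h <- go * tc
      outs[, tt, ] <- h
      if (keep_cache) {
        layer_cache[[tt]] <- list(x = xt, h_prev = h_prev, c_prev = c_prev,
                                  i = gi, f = gf, g = gg, o = go, tc = tc)
      }
    }
    if (keep_cache) caches[[l]] <- layer_cache
    if (l < length(params$layers)) {
      if (training && params$dropout > 0) {
        dm <- array(rbinom(n * T_len * h_sz, 1L, 1 - params$dropout),
                    c(n, T_len, h_sz)) / (1 - params$dropout)
        outs <- outs * dm
        drop_masks[[l]] <- dm
      }
    }
    inp <- outs
    state_out <- if (l == 1L) list(list(h = h, c = cc)) else
      c(state_out, list(list(h = h, c = cc)))
  }
  logits <- sweep(h %*% params$W_l, 2L, params$b_l, "+")
  out <- list(logits = logits, h = h, state = state_out)
  if (keep_cache) {
    out$caches <- caches
    out$drop_masks <- drop_masks
    out$inputs <- x
    out$T_len <- T_len
  }
  out
}

# Backpropagation through time given dlogits; returns gradients mirroring
# the parameter structure (masked positions zeroed).
lstm_backward <- function(fw, params, dlogits) {
  n <- nrow(dlogits)
  L <- length(params$layers)
  T_len <- fw$T_len
  h_last <- fw$state[[L]]$h
  grads <- list(layers = vector("list", L))
  grads$W_l <- crossprod(h_last, dlogits)
  grads$b_l <- colSums(dlogits)

  # dh on the last layer's outputs: only the final step receives readout grad
  dout_next <- NULL  # [n, T, h] gradient w.r.t. this layer's output sequence
  for (l in rev(seq_len(L))) {
    ly <- params$layers[[l]]
    h_sz <- ly$hidden
    ew <- effective_weights(ly)
    sl <- gate_slices(h_sz)
    cache <- fw$caches[[l]]
    dW <- matrix(0, nrow(ly$W), ncol(ly$W))
    dU <- matrix(0, h_sz, 4L * h_sz)
    db <- numeric(4L * h_sz)
    d_in <- array(0, c(n, T_len, nrow(ly$W)))
    dh <- matrix(0, n, h_sz)
    dc <- matrix(0, n, h_sz)
    for (tt in rev(seq_len(T_len))) {
      ch <- cache[[tt]]
      dh_t <- dh
      if (l == L && tt == T_len) dh_t <- dh_t + dlogits %*% t(params$W_l)
      if (!is.null(dout_next)) dh_t <- dh_t + dout_next[, tt, ]
      do_ <- dh_t * ch$tc
      dc <- dc + dh_t * ch$o * (1 - ch$tc^2)
      di <- dc * ch$g
      df <- dc * ch$c_prev
      dg <- dc * ch$i
      dz <- cbind(di * ch$i * (1 - ch$i),
                  df * ch$f * (1 - ch$f),
                  dg * (1 - ch$g^2),
                  do_ * ch$o * (1 - ch$o))
      dW <- dW + crossprod(ch$x, dz)
      dU <- dU + crossprod(ch$h_prev, dz)
      db <- db + colSums(dz)
      d_in[, tt, ] <- dz %*% t(ew$W)
      dh <- dz %*% t(ew$U)
      dc <- dc * ch$f
    }
    if (!is.null(ly$mask_W)) dW <- dW * ly$mask_W
    if (!is.null(ly$mask_U)) dU <- dU * ly$mask_U
    grads$layers[[l]] <- list(W = dW, U = dU, b = db)
    if (l > 1L) {
      dm <- if (length(fw$drop_masks) >= l - 1L) fw$drop_masks[[l - 1L]] else NULL
      dout_next <- if (!is.null(dm)) d_in * dm else d_in
    }
  }
  grads
}

#' Magnitude-based unstructured pruning
#'
#' Zeros the `floor(ratio * n)` smallest-magnitude weights in each input
#' (`W`) and recurrent (`U`) matrix of every LSTM layer; biases and the
#' readout projection are exempt. Masks persist: masked weights stay zero
#' through subsequent gradient updates, and re-pruning from a dense
#' checkpoint at a different ratio is fully reversible.
#'
#' @param params `lstm_params`.
#' @param ratio Fraction of weights to remove, in `[0, 1)`.
#' @return `lstm_params` with masks applied.
#' @export
magnitude_prune <- function(params, ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio < 0 || ratio >= 1) {
    abort("`ratio` must be a single value in [0, 1)")
  }
  prune_mat <- function(M) {
    n <- length(M)
    k <- floor(ratio * n)
    mask <- matrix(1, nrow(M), ncol(M))
    if (k > 0L) {
      ord <- order(abs(M))[seq_len(k)]  # ties broken by index order
      mask[ord] <- 0
    }
    mask
  }
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    params$layers[[l]]$mask_W <- prune_mat(ly$W)
    params$layers[[l]]$mask_U <- prune_mat(ly$U)
    params$layers[[l]]$W <- ly$W * params$layers[[l]]$mask_W
    params$layers[[l]]$U <- ly$U * params$layers[[l]]$mask_U
  }
  attr(params, "prune_ratio") <- ratio
  params
}

#' Achieved sparsity of the prunable matrices
#'
#' @param params `lstm_params`.
#' @return Fraction of zero weights over all input and recurrent matrices.
#' @export
lstm_sparsity <- function(params) {
  zeros <- 0; total <- 0
  for (ly in params$layers) {
    ew <- effective_weights(ly)
    zeros <- zeros + sum(ew$W == 0) + sum(ew$U == 0)
    total <- total + length(ew$W) + length(ew$U)
  }
  zeros / total
}

#' Count of prunable weights
#' @param params `lstm_params`.
#' @return Total number of input and recurrent weights.
#' @export
lstm_prunable_count <- function(params) {
  sum(vapply(params$layers,
             function(ly) length(ly$W) + length(ly$U), numeric(1)))
}
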