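#' Training configuration for the ensemble branches
#'
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience on validation loss (>= 1).
#' @param seed Seed controlling shuffling, dropout and initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64L,
                         max_epochs = 30L, patience = 5L, seed = 1L) {
  if (patience < 1L) abort("`patience` must be >= 1")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience, seed = seed),
            class = "train_config")
}

# ---- Adam over arbitrary nested numeric structures -----------------------

adam_init <- function() list(m = NULL, v = NULL, t = 0L)

# Walk grads (a nested list of numeric leaves) and update matching leaves of
# params in place. `paths` addresses leaves shared between both structures.
adam_update <- function(params, grads, opt, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  upd <- function(p, g, m, v) {
    if (is.list(g)) {
      if (is.null(m)) m <- vector("list", length(g))
      if (is.null(v)) v <- vector("list", length(g))
      for (nm in seq_along(g)) {
        if (is.null(g[[nm]])) next
        key <- if (!is.null(names(g)) && nzchar(names(g)[nm])) names(g)[nm] else nm
        r <- upd(p[[key]], g[[nm]], m[[nm]], v[[nm]])
        p[[key]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^opt$t)
    vhat <- v / (1 - beta2^opt$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, opt$m, opt$v)
  opt$m <- r$m; opt$v <- r$v
  list(params = r$p, opt = opt)
}

# Weighted cross-entropy; returns loss and dlogits.
weighted_ce <- function(logits, y, sample_w) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  idx <- cbind(seq_len(n), y)
  wsum <- sum(sample_w)
  loss <- -sum(sample_w * log(pmax(p[idx], 1e-12))) / wsum
  d <- p
  d[idx] <- d[idx] - 1
  d <- d * (sample_w / wsum)
  list(loss = loss, dlogits = d)
}

windows_to_xy <- function(windows, n_channels) {
  x <- as_window_array(windows$x, n_channels)
  y <- as.integer(windows$label)  # 1 = no_risk, 2 = risk
  list(x = x, y = y)
}

#' Train one ensemble branch
#'
#' Minimizes weighted cross-entropy with Adam, stopping early when the
#' validation loss has not improved for `patience` epochs. For the LSTM
#' branch, pruning can be applied after training (the default: the dense
#' checkpoint is retained so runtime ratios re-prune reversibly) or at the
#' start of training with the mask held fixed through every update.
#'
#' @param train_windows Labeled (and rebalanced) `motion_windows`.
#' @param val_windows Labeled validation `motion_windows`.
#' @param branch `"cnn"` or `"lstm"`.
#' @param config A [train_config()].
#' @param class_weights Named weights per label level (from
#'   [rebalance_training()]).
#' @param prune_ratio LSTM prune ratio (default 0.4); ignored for the CNN.
#' @param prune_when `"after"` (default) or `"during"` training.
#' @param init Optional pre-initialized parameter object.
#' @return A `branch_fit`: `params`, `dense` checkpoint (LSTM), `history`
#'   tibble and metadata.
#' @export
train_branch <- function(train_windows, val_windows,
                         branch = c("cnn", "lstm"),
                         config = train_config(),
                         class_weights = NULL,
                         prune_ratio = 0.4,
                         prune_when = c("after", "during"),
                         init = NULL) {
  branch <- match.arg(branch)
  prune_when <- match.arg(prune_when)
  if (length(unique(train_windows$label)) < 2L) {
    abort("training data must contain both classes")
  }
  n_channels <- ncol(train_windows$x[[1L]])
  if (is.null(class_weights)) {
    class_weights <- c(no_risk = 1, risk = 1)
  }
  with_seed(config$seed, {
    params <- init %||% if (branch == "cnn") {
      cnn_init(n_channels = n_channels, seed = config$seed)
    } else {
      lstm_init(n_input = n_channels, seed = config$seed)
    }
    if (branch == "lstm" && prune_when == "during" && prune_ratio > 0) {
      params <- magnitude_prune(params, prune_ratio)
    }
    tr <- windows_to_xy(train_windows, n_channels)
    va <- if (!is.null(val_windows) && nrow(val_windows)) {
      windows_to_xy(val_windows, n_channels)
    } else {
      NULL
    }
    w_tr <- unname(class_weights[as.character(train_windows$label)])

    opt <- adam_init()
    best <- list(loss = Inf, params = params, epoch = 0L)
    history <- list()
    n <- dim(tr$x)[1L]
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (b in batches) {
        xb <- tr$x[b, , , drop = FALSE]
        yb <- tr$y[b]
        wb <- w_tr[b]
        if (branch == "cnn") {
          fw <- cnn_forward_internal(xb, params, training = TRUE,
                                     keep_cache = TRUE)
          params <- fw$params  # running batch-norm statistics
          ce <- weighted_ce(fw$logits, yb, wb)
          grads <- cnn_backward_internal(fw, params, ce$dlogits)
          grads <- list(W_c = grads$W_c, b_c = grads$b_c,
                        blocks = purrr::map(grads$blocks, function(g) {
                          list(W_p = g$W_p, W_d = g$W_d,
                               bn = list(gamma = g$gamma, beta = g$beta))
                        }))
        } else {
          fw <- lstm_forward(xb, params, training = TRUE, keep_cache = TRUE)
          ce <- weighted_ce(fw$logits, yb, wb)
          g <- lstm_backward(fw, params, ce$dlogits)
          grads <- list(W_l = g$W_l, b_l = g$b_l,
                        layers = purrr::map(g$layers, function(gl) {
                          list(W = gl$W, U = gl$U, b = gl$b)
                        }))
        }
        if (config$learning_rate > 0) {
          r <- adam_update(params, grads, opt, config$learning_rate)
          params <- r$params
          opt <- r$opt
          if (branch == "lstm" && prune_when == "during" && prune_ratio > 0) {
            for (l in seq_along(params$layers)) {
              ly <- params$layers[[l]]
              if (!is.null(ly$mask_W)) params$layers[[l]]$W <- ly$W * ly$mask_W
              if (!is.null(ly$mask_U)) params$layers[[l]]$U <- ly$U * ly$mask_U
            }
          }
        }
        ep_loss <- ep_loss + ce$loss * length(b)
      }
      ep_loss <- ep_loss / n
      val_loss <- if (!is.null(va)) {
        logits <- if (branch == "cnn") {
          cnn_forward_internal(va$x, params)$logits
        } else {
          lstm_forward(va$x, params)$logits
        }
        weighted_ce(logits, va$y, rep(1, length(va$y)))$loss
      } else {
        ep_loss
      }
      history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = ep_loss,
                                         val_loss = val_loss)
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) {
        break
      }
    }
    params <- best$params
    dense <- NULL
    if (branch == "lstm") {
      if (prune_when == "after") {
        dense <- params
        if (prune_ratio > 0) params <- magnitude_prune(params, prune_ratio)
      } else {
        dense <- params  # masked training: checkpoint carries the mask
      }
    }
    structure(list(branch = branch, params = params, dense = dense,
                   prune_ratio = if (branch == "lstm") prune_ratio else NA,
                   history = dplyr::bind_rows(history),
                   config = config, class_weights = class_weights),
              class = "branch_fit")
  })
}

#' Branch class probabilities
#'
#' @param fit A `branch_fit`.
#' @param x Window matrix, list or array.
#' @param quantized Use the int8 CNN path (requires calibration).
#' @return `n x 2` probability matrix.
#' @export
predict_branch <- function(fit, x, quantized = FALSE) {
  logits <- if (fit$branch == "cnn") {
    cnn_forward(x, fit$params, quantized = quantized)
  } else {
    lstm_forward(x, fit$params)$logits
  }
  softmax_rows(logits)
}

#' @export
print.branch_fit <- function(x, ...) {
  cat(sprintf("<branch_fit:%s> %d epochs, best val loss %.4f\n",
              x$branch, nrow(x$history), min(x$history$val_loss)))
  invisible(x)
}
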