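#' Discrete action grid over mixing coefficient and pruning ratio
#'
#' Cross product of admissible mixing coefficients `alpha` (CNN weight in the
#' fused prediction) and pruning ratios `beta`. The default grid (11 x 5 = 55
#' actions) contains the two reported operating anchors (0.3, 0.6) and
#' (0.8, 0.4).
#'
#' @param alphas Ordered values in `[0, 1]`.
#' @param betas Ordered values in `[0, 1)`.
#' @return An `action_grid` tibble with `action`, `alpha`, `beta`.
#' @export
action_grid <- function(alphas = seq(0, 1, by = 0.1),
                        betas = seq(0, 0.8, by = 0.2)) {
  if (any(alphas < 0 | alphas > 1)) abort("`alphas` must lie in [0, 1]")
  if (any(betas < 0 | betas >= 1)) abort("`betas` must lie in [0, 1)")
  g <- tidyr::expand_grid(alpha = alphas, beta = betas)
  g <- dplyr::mutate(g, action = dplyr::row_number(), .before = 1L)
  structure(g, class = c("action_grid", class(g)))
}

#' Assemble the agent state vector
#'
#' Fixed-order concatenation of the fused class probabilities, the GP risk
#' forecast, and the CPU-usage and energy proxies.
#'
#' @param y_hat Probability vector summing to 1 (tolerance 1e-6).
#' @param risk Risk forecast in (0, 1).
#' @param cpu CPU-usage proxy in `[0, 1]`.
#' @param energy Energy proxy (>= 0).
#' @return Numeric state vector of length `length(y_hat) + 3`.
#' @export
build_state <- function(y_hat, risk, cpu, energy) {
  if (abs(sum(y_hat) - 1) > 1e-6) {
    abort("`y_hat` must sum to 1 (tolerance 1e-6)")
  }
  if (risk <= 0 || risk >= 1) abort("`risk` must be in (0, 1)")
  assert_scalar_prob(cpu, "cpu")
  if (energy < 0) abort("`energy` must be non-negative")
  c(y_hat, risk, cpu, energy)
}

#' Reward configuration
#'
#' Weights of the four-term reward
#' `R = lambda1 * Accuracy - lambda2 * Latency - lambda3 * Energy +
#'  lambda4 * I(risk > tau)`, with normalization divisors for the latency and
#' energy proxies and the risk threshold `tau` (default 0.6).
#'
#' @param lambda1,lambda2,lambda3,lambda4 Non-negative trade-off weights.
#' @param tau Risk threshold in (0, 1).
#' @param latency_scale,energy_scale Normalization divisors.
#' @return A `reward_config` list.
#' @export
reward_config <- function(lambda1 = 1.0, lambda2 = 0.01, lambda3 = 0.01,
                          lambda4 = 0.5, tau = 0.6,
                          latency_scale = 1, energy_scale = 1) {
  if (any(c(lambda1, lambda2, lambda3, lambda4) < 0)) {
    abort("reward weights must be non-negative")
  }
  assert_scalar_prob(tau, "tau", open = TRUE)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 lambda4 = lambda4, tau = tau,
                 latency_scale = latency_scale, energy_scale = energy_scale),
            class = "reward_config")
}

#' Four-term reward
#'
#' Accuracy term is 1 when `argmax(y_hat)` equals the true class; latency and
#' energy proxies are normalized by their scales; the indicator term adds
#' `lambda4` when the forecast risk strictly exceeds `tau`.
#'
#' @param y_true True class index (1-based).
#' @param y_hat Predicted probability vector.
#' @param latency_proxy,energy_proxy Resource proxies.
#' @param risk GP risk forecast.
#' @param cfg A [reward_config()].
#' @return Scalar reward.
#' @export
compute_reward <- function(y_true, y_hat, latency_proxy, energy_proxy, risk,
                           cfg = reward_config()) {
  acc <- as.numeric(which.max(y_hat) == y_true)
  cfg$lambda1 * acc -
    cfg$lambda2 * latency_proxy / cfg$latency_scale -
    cfg$lambda3 * energy_proxy / cfg$energy_scale +
    cfg$lambda4 * as.numeric(risk > cfg$tau)
}

#' Initialize the two-layer swish Q-network
#'
#' `Q(s, a) = w2^T swish(W1 s + b1) + b2`, one output per action.
#'
#' @param state_dim State vector length.
#' @param n_actions Number of discrete actions.
#' @param hidden Hidden width (default 32).
#' @param seed Seed for initialization.
#' @return A `q_network`.
#' @export
q_network <- function(state_dim, n_actions, hidden = 32L, seed = 1L) {
  with_seed(seed, {
    structure(list(
      W1 = matrix(rnorm(hidden * state_dim, sd = sqrt(2 / state_dim)),
                  hidden, state_dim),
      b1 = rep(0, hidden),
      W2 = matrix(rnorm(n_actions * hidden, sd = sqrt(1 / hidden)),
                  n_actions, hidden),
      b2 = rep(0, n_actions),
      state_dim = state_dim, n_actions = n_actions, hidden = hidden
    ), class = "q_network")
  })
}

#' Q-network forward pass
#'
#' @param state State vector, or `n x state_dim` matrix of states.
#' @param net A [q_network()].
#' @return Named value per action (vector) or `n x n_actions` matrix.
#' @export
q_forward <- function(state, net) {
  single <- is.null(dim(state))
  S <- if (single) matrix(state, 1L) else state
  if (ncol(S) != net$state_dim) {
    abort(sprintf("state dimension %d does not match network input %d",
                  ncol(S), net$state_dim))
  }
  Z <- S %*% t(net$W1) + matrix(net$b1, nrow(S), net$hidden, byrow = TRUE)
  H <- swish(Z)
  Q <- H %*% t(net$W2) + matrix(net$b2, nrow(S), net$n_actions, byrow = TRUE)
  if (single) as.numeric(Q) else Q
}

#' Linearly decaying epsilon-greedy schedule
#'
#' Exploration probability decays linearly from `eps_start` (0.1) to
#' `eps_end` (0.01) over the first `decay_steps` (1,000) timesteps and stays
#' clamped at `eps_end` thereafter.
#'
#' @param eps_start,eps_end Endpoints of the schedule.
#' @param decay_steps Steps over which to decay.
#' @return An `exploration_schedule`.
#' @export
exploration_schedule <- function(eps_start = 0.1, eps_end = 0.01,
                                 decay_steps = 1000L) {
  structure(list(eps_start = eps_start, eps_end = eps_end,
                 decay_steps = decay_steps), class = "exploration_schedule")
}

#' @rdname exploration_schedule
#' @param schedule An `exploration_schedule`.
#' @param step Timestep (>= 0).
#' @export
epsilon_at <- function(schedule, step) {
  frac <- pmin(pmax(step, 0) / schedule$decay_steps, 1)
  schedule$eps_start + (schedule$eps_end - schedule$eps_start) * frac
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon_at(schedule, step)` a uniform random action;
#' otherwise the argmax of [q_forward()], ties broken by the lowest action
#' index.
#'
#' @param state State vector.
#' @param net A [q_network()].
#' @param schedule An [exploration_schedule()].
#' @param step Current timestep (>= 0).
#' @param eps Optional override of the schedule's epsilon.
#' @return Action index in `1..n_actions`.
#' @export
select_action <- function(state, net, schedule = exploration_schedule(),
                          step = 0L, eps = NULL) {
  if (step < 0) abort("`step` must be >= 0")
  e <- eps %||% epsilon_at(schedule, step)
  if (e > 0 && runif(1) < e) {
    sample.int(net$n_actions, 1L)
  } else {
    q <- q_forward(state, net)
    which.max(q)  # which.max takes the first (lowest-index) maximum
  }
}

#' Circular experience replay buffer
#'
#' Fixed-capacity (default 10,000) circular store of
#' `(state, action, reward, next_state)` transitions; once full, the oldest
#' entry is overwritten first.
#'
#' @param capacity Maximum number of transitions.
#' @return A `replay_buffer` environment.
#' @export
replay_buffer <- function(capacity = 10000L) {
  structure(list(capacity = as.integer(capacity),
                 entries = vector("list", capacity),
                 size = 0L, cursor = 0L),
            class = "replay_buffer")
}

#' @rdname replay_buffer
#' @param buffer A `replay_buffer`.
#' @param state,action,reward,next_state Transition components.
#' @export
push_transition <- function(buffer, state, action, reward, next_state) {
  buffer$cursor <- (buffer$cursor %% buffer$capacity) + 1L
  buffer$entries[[buffer$cursor]] <-
    list(s = state, a = action, r = reward, s2 = next_state)
  buffer$size <- min(buffer$size + 1L, buffer$capacity)
  buffer
}

#' @rdname replay_buffer
#' @param n Minibatch size (<= buffer size).
#' @export
sample_minibatch <- function(buffer, n) {
  if (buffer$size == 0L) abort("cannot sample from an empty buffer")
  if (n > buffer$size) abort("minibatch larger than buffer contents")
  idx <- sample.int(buffer$size, n)  # without replacement
  buffer$entries[idx]
}

#' One temporal-difference update
#'
#' Takes a single gradient step on the squared TD error
#' `(R + gamma * max_a' Q_target(s', a') - Q(s, a))^2` averaged over the
#' minibatch. The target network is held fixed here; sync it periodically via
#' the training loop.
#'
#' @param net Online [q_network()].
#' @param target_net Target network (defaults to `net`).
#' @param minibatch List of transitions from [sample_minibatch()].
#' @param gamma Discount in `[0, 1)`.
#' @param learning_rate SGD step size.
#' @param terminal_next Optional logical vector: transitions whose next state
#'   is terminal (bootstrap term dropped).
#' @return Updated `q_network`.
#' @export
td_update <- function(net, target_net = net, minibatch, gamma = 0.95,
                      learning_rate = 1e-3, terminal_next = NULL) {
  if (gamma < 0 || gamma >= 1) abort("`gamma` must be in [0, 1)")
  n <- length(minibatch)
  S <- do.call(rbind, purrr::map(minibatch, "s"))
  S2 <- do.call(rbind, purrr::map(minibatch, "s2"))
  a <- vapply(minibatch, function(tr) tr$a, numeric(1))
  r <- vapply(minibatch, function(tr) tr$r, numeric(1))
  if (any(!is.finite(r))) abort("non-finite reward in minibatch")
  q_next <- q_forward(S2, target_net)
  boot <- apply(q_next, 1L, max)
  if (!is.null(terminal_next)) boot[terminal_next] <- 0
  target <- r + gamma * boot

  # forward with cache
  Z <- S %*% t(net$W1) + matrix(net$b1, n, net$hidden, byrow = TRUE)
  sig <- sigmoid(Z)
  H <- Z * sig
  Q <- H %*% t(net$W2) + matrix(net$b2, n, net$n_actions, byrow = TRUE)
  idx <- cbind(seq_len(n), a)
  err <- Q[idx] - target
  # gradient of mean squared TD error w.r.t. selected outputs
  dQ <- matrix(0, n, net$n_actions)
  dQ[idx] <- 2 * err / n
  dW2 <- crossprod(dQ, H)
  db2 <- colSums(dQ)
  dH <- dQ %*% net$W2
  dZ <- dH * (sig + Z * sig * (1 - sig))  # swish'(z)
  dW1 <- crossprod(dZ, S)
  db1 <- colSums(dZ)
  net$W1 <- net$W1 - learning_rate * dW1
  net$b1 <- net$b1 - learning_rate * db1
  net$W2 <- net$W2 - learning_rate * dW2
  net$b2 <- net$b2 - learning_rate * db2
  net
}

#' Train the agent with Q-learning and experience replay
#'
#' Episodic loop coupling [select_action()], [push_transition()] and
#' [td_update()], with a target network synced every `sync_every` updates and
#' a smoothed per-episode reward curve. `env` must be a list with `reset()`
#' returning an initial state and `step(action)` returning
#' `list(state, reward, done)`.
#'
#' @param env Environment interface (see Details).
#' @param episodes Number of episodes (default 500, the scaled-down test
#'   setting; the full schedule is 10,000).
#' @param net Optional pre-built [q_network()].
#' @param schedule Exploration schedule.
#' @param gamma Discount factor.
#' @param learning_rate TD step size.
#' @param batch_size Replay minibatch size.
#' @param buffer_capacity Replay capacity (default 10,000).
#' @param sync_every Target-network sync period in updates (default 100).
#' @param update_every Environment steps between TD updates.
#' @param max_steps Per-episode step cap.
#' @param seed Seed for all randomness in the loop.
#' @return An `rl_agent`: `net`, `reward_curve` tibble, `schedule`, grid
#'   metadata if supplied by the environment.
#' @export
run_training <- function(env, episodes = 500L, net = NULL,
                         schedule = exploration_schedule(),
                         gamma = 0.95, learning_rate = 1e-3,
                         batch_size = 32L, buffer_capacity = 10000L,
                         sync_every = 100L, update_every = 1L,
                         max_steps = 1000L, seed = 1L) {
  with_seed(seed, {
    s0 <- env$reset()
    if (is.null(net)) {
      net <- q_network(length(s0), env$n_actions, seed = child_seed(seed, "q"))
    }
    target <- net
    buf <- replay_buffer(buffer_capacity)
    step_count <- 0L
    update_count <- 0L
    curve <- numeric(episodes)
    for (ep in seq_len(episodes)) {
      s <- env$reset()
      ep_reward <- 0
      for (k in seq_len(max_steps)) {
        a <- select_action(s, net, schedule, step_count)
        out <- env$step(a)
        if (!is.finite(out$reward)) {
          abort("environment returned a non-finite reward")
        }
        buf <- push_transition(buf, s, a, out$reward, out$state)
        ep_reward <- ep_reward + out$reward
        s <- out$state
        step_count <- step_count + 1L
        if (buf$size >= batch_size && step_count %% update_every == 0L) {
          mb <- sample_minibatch(buf, batch_size)
          net <- td_update(net, target, mb, gamma, learning_rate)
          update_count <- update_count + 1L
          if (update_count %% sync_every == 0L) target <- net
        }
        if (isTRUE(out$done)) break
      }
      curve[ep] <- ep_reward
    }
    k <- min(10L, length(curve))
    smooth <- stats::filter(curve, rep(1 / k, k), sides = 1)
    structure(list(
      net = net,
      reward_curve = tibble::tibble(episode = seq_len(episodes),
                                    reward = curve,
                                    reward_smooth = as.numeric(smooth)),
      schedule = schedule, gamma = gamma,
      steps = step_count
    ), class = "rl_agent")
  })
}

#' @export
print.rl_agent <- function(x, ...) {
  cat(sprintf("<rl_agent> %d episodes, %d steps, final smoothed reward %.3f\n",
              nrow(x$reward_curve), x$steps,
              utils::tail(stats::na.omit(x$reward_curve$reward_smooth), 1)))
  invisible(x)
}
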