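test_that("the state vector concatenates in fixed order and is validated", {
  s <- build_state(c(0.5, 0.5), 0.5, 0, 0)
  expect_equal(s, c(0.5, 0.5, 0.5, 0, 0))
  expect_length(s, 5L)
  expect_error(build_state(c(0.9, 0.2), 0.5, 0, 0), "sum to 1")
  expect_error(build_state(c(0.5, 0.5), 1.2, 0, 0), "risk")
  expect_error(build_state(c(0.5, 0.5), 0.5, 2, 0), "cpu")
})

test_that("the action grid contains the reported operating anchors", {
  g <- action_grid()
  expect_equal(nrow(g), 55L)
  expect_true(any(abs(g$alpha - 0.3) < 1e-9 & abs(g$beta - 0.6) < 1e-9))
  expect_true(any(abs(g$alpha - 0.8) < 1e-9 & abs(g$beta - 0.4) < 1e-9))
  expect_error(action_grid(alphas = c(-0.1)), "\\[0, 1\\]")
  expect_error(action_grid(betas = c(1)), "\\[0, 1\\)")
})

test_that("the four-term reward reproduces direct arithmetic", {
  cfg <- reward_config(1, 0, 0, 0)
  expect_equal(compute_reward(2, c(0.3, 0.7), 99, 99, 0.1, cfg), 1)
  cfg2 <- reward_config(1, 0.01, 0.01, 0.5)
  expect_equal(compute_reward(1, c(0.8, 0.2), 17.2, 3.1, 0.7, cfg2),
               1 - 0.172 - 0.031 + 0.5, tolerance = 1e-12)
  # strict inequality at the threshold
  expect_equal(compute_reward(1, c(0.8, 0.2), 0, 0, 0.6, cfg2), 1)
  # monotone: more latency never raises the reward
  r <- vapply(c(0, 1, 5, 20), function(l)
    compute_reward(1, c(0.8, 0.2), l, 0, 0.1, cfg2), numeric(1))
  expect_true(all(diff(r) <= 0))
})

test_that("the Q-network matches by-hand swish arithmetic", {
  net <- q_network(2L, 1L, hidden = 2L, seed = 1)
  net$W1 <- matrix(c(0.5, -0.2, 0.3, 0.8), 2, 2)
  net$b1 <- c(0.1, -0.1)
  net$W2 <- matrix(c(1.5, -0.7), 1, 2)
  net$b2 <- 0.25
  s <- c(0.4, -0.6)
  z <- as.numeric(net$W1 %*% s) + net$b1
  sw <- z / (1 + exp(-z))
  want <- sum(net$W2 * sw) + net$b2
  expect_equal(q_forward(s, net), want, tolerance = 1e-10)

  zero <- q_network(3L, 4L, seed = 2)
  zero$W1[] <- 0; zero$b1[] <- 0; zero$W2[] <- 0; zero$b2 <- rep(0.7, 4)
  expect_equal(q_forward(c(1, 2, 3), zero), rep(0.7, 4))
  expect_error(q_forward(c(1, 2), zero), "dimension")
})

test_that("the epsilon schedule is piecewise-linear with exact endpoints", {
  sch <- exploration_schedule()
  expect_equal(epsilon_at(sch, 0), 0.1)
  expect_equal(epsilon_at(sch, 500), 0.055)
  expect_equal(epsilon_at(sch, 1000), 0.01)
  expect_equal(epsilon_at(sch, 5000), 0.01)
  steps <- 0:2000
  eps <- epsilon_at(sch, steps)
  expect_true(all(diff(eps) <= 1e-15))
  expect_true(all(eps >= 0.01 - 1e-15))
})

test_that("greedy selection is deterministic; exploration rate concentrates", {
  net <- q_network(2L, 5L, seed = 3)
  s <- c(0.3, 0.9)
  a <- select_action(s, net, eps = 0)
  expect_equal(a, which.max(q_forward(s, net)))
  # argmax ties break to the lowest index
  tied <- net; tied$W1[] <- 0; tied$b1[] <- 0; tied$W2[] <- 0; tied$b2 <- rep(1, 5)
  expect_equal(select_action(s, tied, eps = 0), 1L)

  withr::with_seed(9, {
    n <- 100000L
    greedy <- which.max(q_forward(s, net))
    draws <- vapply(seq_len(n), function(i) select_action(s, net, eps = 0.1),
                    numeric(1))
    # random draws that happen to hit the greedy arm still count as random;
    # observed non-greedy fraction = eps * (1 - 1/|A|)
    frac <- mean(draws != greedy)
    expect_lt(abs(frac - 0.1 * (1 - 1 / 5)), 0.003)
  })
})

test_that("the replay buffer is circular at capacity with uniform sampling", {
  buf <- replay_buffer(10000L)
  for (i in 1:10001) {
    buf <- push_transition(buf, i, 1L, 0, i + 1)
  }
  expect_equal(buf$size, 10000L)
  stored_first <- buf$entries[[1L]]$s
  expect_equal(stored_first, 10001)  # oldest slot overwritten

  small <- replay_buffer(8L)
  for (i in 1:8) small <- push_transition(small, i, 1L, 0, i)
  perm <- vapply(sample_minibatch(small, 8L), function(tr) tr$s, numeric(1))
  expect_setequal(perm, 1:8)
  expect_error(sample_minibatch(replay_buffer(4L), 1L), "empty")
  expect_error(sample_minibatch(small, 9L), "larger")

  withr::with_seed(10, {
    counts <- numeric(8)
    for (i in 1:12500) {
      idx <- vapply(sample_minibatch(small, 4L), function(tr) tr$s, numeric(1))
      counts[idx] <- counts[idx] + 1
    }
    expect_true(all(abs(counts / sum(counts) - 1 / 8) < 0.1 / 8))
  })
})

test_that("TD updates converge to the value-iteration fixed point on a 2-state MDP", {
  gamma <- 0.9
  P <- matrix(c(1, 2, 1, 2), 2, 2)               # deterministic transitions
  R <- matrix(c(1, 0, 0, 0.5), 2, 2, byrow = TRUE)
  Q <- matrix(0, 2, 2)                            # value-iteration oracle
  for (i in 1:2000) {
    Qn <- R + gamma * matrix(apply(Q, 1, max)[P], 2, 2)
    if (max(abs(Qn - Q)) < 1e-12) break
    Q <- Qn
  }
  svec <- list(c(1, 0), c(0, 1))
  withr::with_seed(11, {
    net <- q_network(2L, 2L, hidden = 32L, seed = 11)
    target <- net
    buf <- replay_buffer(100L)
    for (s in 1:2) for (a in 1:2) {
      buf <- push_transition(buf, svec[[s]], a, R[s, a], svec[[P[s, a]]])
    }
    for (it in 1:6000) {
      net <- td_update(net, target, sample_minibatch(buf, 4L),
                       gamma = gamma, learning_rate = 0.02)
      if (it %% 100 == 0) target <- net
    }
  })
  Qhat <- rbind(q_forward(svec[[1]], net), q_forward(svec[[2]], net))
  expect_lt(max(abs(Qhat - Q)), 0.05)
  expect_equal(apply(Qhat, 1, which.max), apply(Q, 1, which.max))
})

test_that("gamma = 0 regresses Q toward immediate rewards on a frozen batch", {
  withr::with_seed(12, {
    net <- q_network(3L, 2L, seed = 12)
    mb <- purrr::map(1:8, function(i) {
      list(s = rnorm(3), a = sample(1:2, 1), r = rnorm(1), s2 = rnorm(3))
    })
    loss_of <- function(nn) {
      mean(vapply(mb, function(tr) {
        (q_forward(tr$s, nn)[tr$a] - tr$r)^2
      }, numeric(1)))
    }
    l0 <- loss_of(net)
    for (i in 1:100) net <- td_update(net, net, mb, gamma = 0,
                                      learning_rate = 0.05)
    expect_lt(loss_of(net), l0)
  })
  # zero learning rate leaves the network untouched
  net <- q_network(3L, 2L, seed = 13)
  mb <- list(list(s = c(1, 0, 0), a = 1L, r = 1, s2 = c(0, 1, 0)))
  net2 <- td_update(net, net, mb, gamma = 0.5, learning_rate = 0)
  expect_identical(net, net2)
  expect_error(td_update(net, net, mb, gamma = 1), "gamma")
})

test_that("training learns a known-optimum contextual bandit deterministically", {
  make_env <- function() {
    e <- new.env()
    e$s <- c(1, 0)
    list(
      n_actions = 3L,
      reset = function() { e$s <- c(runif(1), runif(1)); e$s },
      step = function(a) {
        r <- if (a == 2L) 1 else 0   # action 2 always best
        e$s <- c(runif(1), runif(1))
        list(state = e$s, reward = r, done = FALSE)
      })
  }
  ag1 <- run_training(make_env(), episodes = 20L, max_steps = 50L, seed = 21L)
  ag2 <- run_training(make_env(), episodes = 20L, max_steps = 50L, seed = 21L)
  expect_identical(ag1$reward_curve, ag2$reward_curve)   # seeded determinism

  withr::with_seed(22, {
    states <- matrix(runif(200), 100, 2)
    picks <- apply(q_forward(states, ag1$net), 1L, which.max)
    expect_gt(mean(picks == 2L), 0.95)
  })
  g <- glance(ag1)
  expect_gte(g$mean_reward_last10pct, g$mean_reward_first10pct)
})
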