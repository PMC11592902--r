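default_rc <- function(C = 2L, minority = 1L)
  reward_config(minority = minority, classes = 0:(C - 1L))

test_that("the reward table covers all four cases exhaustively", {
  rc <- default_rc()
  expect_identical(compute_reward(1L, 1L, rc), 1.0)    # minority correct
  expect_identical(compute_reward(0L, 1L, rc), -1.0)   # minority missed
  expect_identical(compute_reward(0L, 0L, rc), 0.1)    # majority correct
  expect_identical(compute_reward(1L, 0L, rc), 0.0)    # majority missed
  expect_error(compute_reward(5L, 0L, rc), "unknown class")
  expect_error(reward_config(minority = 0L, classes = 0:1,
                             majority_correct = 2), "minority_correct")
})

test_that("batch rewards average the per-sample table values", {
  rc <- default_rc()
  expect_identical(batch_reward(c(1L, 1L), c(1L, 1L), rc), 1.0)
  expect_identical(batch_reward(c(1L, 0L), c(1L, 1L), rc), 0.0)
  expect_identical(batch_reward(c(1L, 0L), c(1L, 0L), rc), 0.55)
  expect_error(batch_reward(integer(0), integer(0), rc), "empty")
})

test_that("weight actions follow the multiplicative rule with mean-1 projection", {
  w <- weight_vector(3)
  expect_identical(apply_action(w, 0L), w)   # no-op
  w2 <- apply_action(w, 3L, beta = 1.5)      # raise class 3
  expect_equal(w2, c(1, 1, 1.5) / mean(c(1, 1, 1.5)), tolerance = 1e-12)
  expect_equal(w2, c(0.857, 0.857, 1.286), tolerance = 1e-3)
  # repeated raising saturates at w_max
  w3 <- weight_vector(2)
  for (i in 1:40) w3 <- apply_action(w3, 1L, bounds = c(0.25, 4))
  expect_lte(max(w3), 4 + 1e-9)
  expect_error(apply_action(weight_vector(2), 7L), "out of range")
})

test_that("weight invariants survive arbitrary action streams", {
  set.seed(31)
  for (C in c(2L, 3L, 5L)) {
    w <- weight_vector(C)
    for (i in 1:300) {
      w <- apply_action(w, sample(0:(2 * C), 1L), beta = 1.3,
                        bounds = c(0.25, 4))
      expect_equal(mean(w), 1, tolerance = 1e-9)
      expect_true(all(w >= 0.25 - 1e-9 & w <= 4 + 1e-9))
    }
  }
})

test_that("epsilon-greedy selection is greedy, tie-stable and uniform at eps=1", {
  qn <- q_network(3L, 3L, hidden = 8L, seed = 5L)
  # force known Q rows through the final layer bias with zero weights
  qn$W1$val[] <- 0; qn$W2$val[] <- 0
  qn$b2$val[] <- c(0.1, 0.9, 0.2)
  expect_identical(select_action(qn, c(1, 0, 0), eps = 0), 1L)
  qn$b2$val[] <- c(0.5, 0.5, 0)
  expect_identical(select_action(qn, c(1, 0, 0), eps = 0), 0L)
  set.seed(17)
  draws <- replicate(10000, select_action(qn, c(1, 0, 0), eps = 1))
  freq <- tabulate(draws + 1L, 3L) / 10000
  sigma <- sqrt((1 / 3) * (2 / 3) / 10000)
  expect_true(all(abs(freq - 1 / 3) < 3 * sigma + 1e-9))
})

test_that("replay buffer evicts FIFO and samples only stored transitions", {
  buf <- replay_buffer(3L)
  for (i in 1:5)
    buffer_push(buf, list(state = i, action = 0L, reward = i,
                          next_state = i, terminal = FALSE))
  expect_identical(buf$size, 3L)
  stored <- vapply(buf$data, function(tr) tr$reward, 1)
  expect_setequal(stored, c(3, 4, 5))   # 1 and 2 evicted first
  set.seed(1)
  s <- buffer_sample(buf, 10L)
  expect_true(all(vapply(s, function(tr) tr$reward, 1) %in% 3:5))
  expect_error(buffer_push(buf, list(reward = NA_real_)), "finite")
})

test_that("Bellman targets follow r + gamma * max Q with terminal cutoff", {
  qn <- q_network(2L, 2L, hidden = 4L, seed = 2L)
  qn$W1$val[] <- 0; qn$W2$val[] <- 0; qn$b2$val[] <- c(2, 1)
  expect_identical(bellman_target(1, c(1, 0), qn, gamma = 0), 1)
  expect_identical(bellman_target(1, c(1, 0), qn, gamma = 0.9,
                                  terminal = TRUE), 1)
  expect_equal(bellman_target(1, c(1, 0), qn, gamma = 0.9), 2.8)
})

test_that("dqn_update has a zero-gradient fixed point and nonnegative loss", {
  qn <- q_network(2L, 2L, hidden = 4L, seed = 3L)
  tg <- q_network(2L, 2L, hidden = 4L, seed = 3L)
  target_sync(qn, tg)
  # gamma = 0: targets equal rewards; set rewards to the current Q values
  s1 <- c(1, 0); s2 <- c(0, 1)
  r1 <- q_values(qn, s1)[1, 1]; r2 <- q_values(qn, s2)[1, 2]
  batch <- list(list(state = s1, action = 0L, reward = r1, next_state = s1,
                     terminal = TRUE),
                list(state = s2, action = 1L, reward = r2, next_state = s2,
                     terminal = TRUE))
  before <- lapply(list(qn$W1, qn$b1, qn$W2, qn$b2), tn_val)
  loss <- dqn_update(qn, tg, batch, alpha = 0.1, gamma = 0)
  expect_lt(loss, 1e-20)
  after <- lapply(list(qn$W1, qn$b1, qn$W2, qn$b2), tn_val)
  expect_equal(before, after, tolerance = 1e-12)
  # and a generic batch yields nonnegative loss
  batch[[1]]$reward <- r1 + 1
  expect_gte(dqn_update(qn, tg, batch, alpha = 0.01, gamma = 0), 0)
})

test_that("target network changes only at sync points", {
  qn <- q_network(2L, 2L, hidden = 4L, seed = 6L)
  tg <- q_network(2L, 2L, hidden = 4L, seed = 7L)
  target_sync(qn, tg)
  snap <- tn_val(tg$W2)
  batch <- list(list(state = c(1, 0), action = 0L, reward = 1,
                     next_state = c(0, 1), terminal = FALSE))
  for (i in 1:5) dqn_update(qn, tg, batch, alpha = 0.05, gamma = 0.9)
  expect_identical(tn_val(tg$W2), snap)
  target_sync(qn, tg)
  expect_identical(tn_val(tg$W2), tn_val(qn$W2))
})

test_that("value iteration matches closed forms and has tiny Bellman residual", {
  # single state, gamma = 0: Q equals the immediate rewards
  m0 <- list(R = matrix(c(1, 0), 1, 2),
             next_state = matrix(c(1L, 1L), 1, 2))
  expect_equal(solve_mdp_exact(m0, 0), matrix(c(1, 0), 1, 2))
  # self-loop reward 1, gamma = 0.5 -> V = 1 / (1 - 0.5) = 2
  m1 <- list(R = matrix(1, 1, 1), next_state = matrix(1L, 1, 1))
  expect_equal(solve_mdp_exact(m1, 0.5)[1, 1], 2, tolerance = 1e-10)
  expect_error(solve_mdp_exact(m1, 1), "gamma")
  # random 3-state MDP: residual of the returned Q is ~0
  set.seed(41)
  P <- array(stats::runif(3 * 2 * 3), c(3, 2, 3))
  for (s in 1:3) for (a in 1:2) P[s, a, ] <- P[s, a, ] / sum(P[s, a, ])
  m2 <- list(R = matrix(stats::rnorm(6), 3, 2), P = P)
  Q <- solve_mdp_exact(m2, 0.8)
  V <- apply(Q, 1, max)
  resid <- abs(Q - (m2$R + 0.8 * apply(P, c(1, 2), function(p) sum(p * V))))
  expect_lt(max(resid), 1e-10)
})

test_that("trained DQN recovers the optimal greedy policy on a toy MDP", {
  mdp <- toy_mdps()[[1]]
  Qstar <- solve_mdp_exact(mdp, 0.9)
  fit <- dqn_train(mdp_env(mdp), steps = 800L, gamma = 0.9, alpha = 0.05,
                   seed = 11L)
  pol <- greedy_policy(fit$qnet, nrow(mdp$R))
  expect_identical(pol, apply(Qstar, 1L, which.max))
  # approximation error shrinks with more training
  qerr <- function(f) {
    qd <- t(vapply(seq_len(nrow(mdp$R)), function(s) {
      v <- numeric(nrow(mdp$R)); v[s] <- 1
      q_values(f$qnet, v)[1, ]
    }, numeric(ncol(mdp$R))))
    max(abs(qd - Qstar))
  }
  early <- dqn_train(mdp_env(mdp), steps = 120L, gamma = 0.9, alpha = 0.05,
                     seed = 11L)
  expect_lt(qerr(fit), qerr(early))
})
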