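# Deep-Q-learning machinery for class-imbalance reweighting: the four-case
# reward table, the discrete class-weight action space, epsilon-greedy action
# selection over a small Q-network, replay buffer with FIFO eviction, Bellman
# targets against a delayed target network, and the squared-error DQN update
# trained by plain stochastic gradient descent.  An exact value-iteration
# solver doubles as the test oracle on tabular problems.

#' Reward configuration
#'
#' Four cases: correct minority (+1), misclassified minority (-1), correct
#' majority (+delta = +0.1), misclassified majority (0).
#' @param minority integer vector of minority class ids
#' @param classes integer vector of all valid class ids
#' @param minority_correct,minority_wrong,majority_correct,majority_wrong
#'   the four reward values; must satisfy
#'   minority_correct > majority_correct > 0 > minority_wrong
#' @return a `reward_config`
#' @export
reward_config <- function(minority, classes,
                          minority_correct = 1.0, minority_wrong = -1.0,
                          majority_correct = 0.1, majority_wrong = 0.0) {
  if (!(minority_correct > majority_correct && majority_correct > 0 &&
        minority_wrong < 0))
    stop("need minority_correct > majority_correct > 0 > minority_wrong")
  if (!all(minority %in% classes))
    stop("minority ids must be a subset of classes")
  structure(list(minority = as.integer(minority),
                 classes = as.integer(classes),
                 minority_correct = minority_correct,
                 minority_wrong = minority_wrong,
                 majority_correct = majority_correct,
                 majority_wrong = majority_wrong),
            class = "reward_config")
}

#' Reward for one prediction
#'
#' @param predicted_class,true_class class ids (must be in `cfg$classes`)
#' @param cfg a [reward_config()]
#' @return scalar reward
#' @export
compute_reward <- function(predicted_class, true_class, cfg) {
  if (!(predicted_class %in% cfg$classes) || !(true_class %in% cfg$classes))
    stop("unknown class id")
  minority <- true_class %in% cfg$minority
  correct <- predicted_class == true_class
  if (minority) {
    if (correct) cfg$minority_correct else cfg$minority_wrong
  } else {
    if (correct) cfg$majority_correct else cfg$majority_wrong
  }
}

#' Mean reward over a mini-batch of predictions
#' @param predictions,labels equal-length class-id vectors
#' @param cfg a [reward_config()]
#' @return scalar mean reward
#' @export
batch_reward <- function(predictions, labels, cfg) {
  if (!length(predictions)) stop("empty batch")
  if (length(predictions) != length(labels))
    stop("predictions and labels must have equal length")
  mean(vapply(seq_along(labels), function(i)
    compute_reward(predictions[i], labels[i], cfg), 1))
}

#' Uniform class-weight vector
#' @param C number of classes
#' @return numeric vector of C ones
#' @export
weight_vector <- function(C) rep(1, C)

#' Apply one discrete weight action
#'
#' Action 0 is a no-op; actions 1..C multiply class i's weight by `beta`;
#' actions C+1..2C divide it by `beta`.  The weights are then projected onto
#' the feasible set {w in [w_min, w_max]^C, mean(w) = 1} by alternating
#' clipping and mean-1 renormalisation.
#' @param w positive weight vector, mean 1
#' @param action integer in 0..2C
#' @param beta multiplicative step (> 1)
#' @param bounds c(w_min, w_max)
#' @return updated weight vector (mean 1, within bounds)
#' @export
apply_action <- function(w, action, beta = 1.2, bounds = c(0.25, 4.0)) {
  C <- length(w)
  if (action < 0 || action > 2 * C) stop("action out of range 0..", 2 * C)
  if (action >= 1 && action <= C) w[action] <- w[action] * beta
  else if (action > C) w[action - C] <- w[action - C] / beta
  for (i in 1:100) {
    w2 <- pmin(pmax(w, bounds[1]), bounds[2])
    w2 <- w2 / mean(w2)
    if (max(abs(w2 - w)) < 1e-12) { w <- w2; break }
    w <- w2
  }
  w / mean(w)
}

# ---- Q-network --------------------------------------------------------------

#' Small MLP Q-network
#' @param state_dim input dimension
#' @param n_actions output dimension (one Q-value per action)
#' @param hidden hidden width
#' @param seed initialisation seed
#' @return a `q_network`
#' @export
q_network <- function(state_dim, n_actions, hidden = 24L, seed = 1L) {
  structure(list(
    W1 = tn_param(init_mat(state_dim, hidden, derive_seed(seed, 31))),
    b1 = tn_param(matrix(0, 1, hidden)),
    W2 = tn_param(init_mat(hidden, n_actions, derive_seed(seed, 32),
                           sd = 0.1)),
    b2 = tn_param(matrix(0, 1, n_actions)),
    state_dim = as.integer(state_dim), n_actions = as.integer(n_actions)),
    class = "q_network")
}

.q_forward <- function(qnet, states_node) {
  h <- tn_relu(tn_add(tn_matmul(states_node, qnet$W1), qnet$b1))
  tn_add(tn_matmul(h, qnet$W2), qnet$b2)
}

#' Q-values for a batch of states
#' @param qnet a [q_network()]
#' @param states numeric matrix (rows = states) or a single state vector
#' @return matrix of Q-values (rows = states, cols = actions)
#' @export
q_values <- function(qnet, states) {
  if (!is.matrix(states)) states <- matrix(states, 1L)
  tn_val(.q_forward(qnet, tn_const(states)))
}

#' Copy the online network's parameters into the target network
#' @param qnet,target two [q_network()]s of identical shape
#' @export
target_sync <- function(qnet, target) {
  for (nm in c("W1", "b1", "W2", "b2")) target[[nm]]$val <- qnet[[nm]]$val
  invisible(target)
}

#' Epsilon-greedy action selection
#'
#' With probability 1 - epsilon the greedy action argmax_a Q(s, a) is chosen
#' (lowest index on ties); otherwise an action is drawn uniformly.  Actions
#' are 0-based (0..n_actions-1).  Uses the current RNG stream.
#' @param qnet a [q_network()]
#' @param state numeric state vector
#' @param eps exploration probability in `[0, 1]`
#' @return 0-based integer action
#' @export
select_action <- function(qnet, state, eps) {
  if (eps < 0 || eps > 1) stop("eps must be in [0, 1]")
  if (eps > 0 && stats::runif(1) < eps)
    return(sample.int(qnet$n_actions, 1L) - 1L)
  q <- q_values(qnet, state)
  which.max(q) - 1L
}

# ---- replay buffer ----------------------------------------------------------

#' Create a FIFO replay buffer
#' @param capacity maximum number of stored transitions
#' @return a `replay_buffer`
#' @export
replay_buffer <- function(capacity) {
  e <- new.env(parent = emptyenv())
  e$data <- vector("list", capacity)
  e$capacity <- as.integer(capacity)
  e$size <- 0L
  e$head <- 0L   # next write slot (FIFO overwrite once full)
  class(e) <- "replay_buffer"
  e
}

#' Store a transition (FIFO eviction at capacity)
#' @param buf a [replay_buffer()]
#' @param transition list(state, action, reward, next_state, terminal)
#' @export
buffer_push <- function(buf, transition) {
  if (!is.finite(transition$reward)) stop("reward must be finite")
  buf$head <- buf$head %% buf$capacity + 1L
  buf$data[[buf$head]] <- transition
  buf$size <- min(buf$size + 1L, buf$capacity)
  invisible(buf)
}

#' Sample stored transitions uniformly (with replacement if n > size)
#' @param buf a [replay_buffer()]
#' @param n batch size
#' @return list of transitions
#' @export
buffer_sample <- function(buf, n) {
  if (buf$size == 0L) stop("empty replay buffer")
  idx <- sample.int(buf$size, n, replace = n > buf$size)
  buf$data[idx]
}

# ---- Bellman targets + update ----------------------------------------------

#' Bellman target for one transition
#'
#' r + gamma * max_a' Q(s', a'; theta^-), or r for terminal transitions.
#' @param r reward
#' @param next_state numeric state vector
#' @param target_net the delayed target [q_network()]
#' @param gamma discount in `[0, 1)`
#' @param terminal logical
#' @return scalar target
#' @export
bellman_target <- function(r, next_state, target_net, gamma, terminal = FALSE) {
  if (gamma < 0 || gamma >= 1) stop("gamma must be in [0, 1)")
  if (terminal || gamma == 0) return(r)
  r + gamma * max(q_values(target_net, next_state))
}

#' One DQN update step
#'
#' Loss = mean over the batch of (Y_t - Q(s_t, a_t; theta))^2 with Y_t the
#' Bellman targets from the frozen target network; theta takes one SGD step
#' of size `alpha`.  The target network is untouched.
#' @param qnet online [q_network()]
#' @param target_net frozen target network
#' @param batch list of transitions (state, action 0-based, reward,
#'   next_state, terminal)
#' @param alpha SGD learning rate
#' @param gamma discount
#' @return the scalar loss before the step
#' @export
dqn_update <- function(qnet, target_net, batch, alpha, gamma) {
  if (!length(batch)) stop("batch must be nonempty")
  B <- length(batch)
  A <- qnet$n_actions
  states <- do.call(rbind, lapply(batch, function(tr) tr$state))
  targets <- vapply(batch, function(tr)
    bellman_target(tr$reward, tr$next_state, target_net, gamma, tr$terminal),
    1)
  onehot <- matrix(0, B, A)
  onehot[cbind(seq_len(B),
               vapply(batch, function(tr) tr$action, 1L) + 1L)] <- 1
  params <- list(qnet$W1, qnet$b1, qnet$W2, qnet$b2)
  zero_grads(params)
  qs <- .q_forward(qnet, tn_const(states))
  qsa <- tn_matmul(tn_mul(qs, tn_const(onehot)), tn_const(matrix(1, A, 1)))
  diff <- tn_sub(qsa, tn_const(matrix(targets, ncol = 1)))
  loss <- tn_mean(tn_mul(diff, diff))
  tn_backward(loss)
  sgd_step(params, alpha)
  tn_val(loss)[1]
}

# ---- exact tabular solver (oracle) ------------------------------------------

#' Exact value iteration on a finite MDP
#'
#' `mdp` is a list with `R` (S x A reward matrix) and either `next_state`
#' (S x A deterministic transition matrix) or `P` (S x A x S probability
#' array); optional logical `terminal` of length S (absorbing, value 0).
#' Iterates the Bellman optimality operator to a fixed point.
#' @param mdp the MDP description
#' @param gamma discount in `[0, 1)`
#' @param tol sup-norm convergence tolerance
#' @return S x A matrix of optimal Q-values
#' @export
solve_mdp_exact <- function(mdp, gamma, tol = 1e-12) {
  if (gamma >= 1 || gamma < 0) stop("gamma must be in [0, 1)")
  S <- nrow(mdp$R); A <- ncol(mdp$R)
  term <- mdp$terminal %||% rep(FALSE, S)
  Q <- matrix(0, S, A)
  repeat {
    V <- apply(Q, 1L, max)
    V[term] <- 0
    Qn <- if (!is.null(mdp$next_state)) {
      mdp$R + gamma * matrix(V[mdp$next_state], S, A)
    } else {
      EV <- apply(mdp$P, c(1, 2), function(p) sum(p * V))
      mdp$R + gamma * EV
    }
    Qn[term, ] <- 0
    if (max(abs(Qn - Q)) < tol) return(Qn)
    Q <- Qn
  }
}

#' Wrap a tabular MDP as a generic RL environment
#'
#' States are encoded one-hot for the Q-network.  Episodes run for `horizon`
#' steps or until a terminal state is entered.
#' @param mdp as in [solve_mdp_exact()]
#' @param horizon episode length
#' @param start starting state (default 1)
#' @return environment interface: list(reset, step, state_dim, n_actions)
#' @export
mdp_env <- function(mdp, horizon = 30L, start = 1L) {
  S <- nrow(mdp$R); A <- ncol(mdp$R)
  term <- mdp$terminal %||% rep(FALSE, S)
  e <- new.env()
  e$s <- start; e$t <- 0L
  onehot <- function(s) { v <- numeric(S); v[s] <- 1; v }
  list(
    reset = function() { e$s <- start; e$t <- 0L; onehot(e$s) },
    step = function(action) {   # 0-based action
      a <- action + 1L
      r <- mdp$R[e$s, a]
      s2 <- if (!is.null(mdp$next_state)) mdp$next_state[e$s, a]
      else sample.int(S, 1L, prob = mdp$P[e$s, a, ])
      e$s <- s2; e$t <- e$t + 1L
      list(state = onehot(s2), reward = r,
           terminal = term[s2] || e$t >= horizon)
    },
    state_dim = S, n_actions = A)
}

#' Train a DQN agent on a generic environment
#'
#' Linear epsilon decay, FIFO replay, periodic target sync; deterministic
#' given `seed`.
#' @param env an environment as returned by [mdp_env()]
#' @param steps total environment steps
#' @param gamma discount
#' @param alpha SGD learning rate
#' @param seed RNG seed
#' @param hidden Q-network hidden width
#' @param batch_size replay sample size
#' @param sync_period target-network refresh interval (steps)
#' @param eps_start,eps_end linear exploration schedule over the first half
#'   of training
#' @return list(qnet, target, losses)
#' @export
dqn_train <- function(env, steps = 1500L, gamma = 0.9, alpha = 0.05,
                      seed = 1L, hidden = 24L, batch_size = 32L,
                      sync_period = 50L, eps_start = 1.0, eps_end = 0.05) {
  with_seed(seed, {
    qnet <- q_network(env$state_dim, env$n_actions, hidden,
                      derive_seed(seed, 41))
    target <- q_network(env$state_dim, env$n_actions, hidden,
                        derive_seed(seed, 41))
    target_sync(qnet, target)
    buf <- replay_buffer(4096L)
    s <- env$reset()
    losses <- numeric(0)
    half <- max(1L, steps %/% 2L)
    for (t in seq_len(steps)) {
      eps <- max(eps_end, eps_start - (eps_start - eps_end) * (t - 1) / half)
      a <- select_action(qnet, s, eps)
      out <- env$step(a)
      buffer_push(buf, list(state = s, action = a, reward = out$reward,
                            next_state = out$state, terminal = out$terminal))
      s <- if (out$terminal) env$reset() else out$state
      if (buf$size >= batch_size) {
        losses <- c(losses, dqn_update(qnet, target,
                                       buffer_sample(buf, batch_size),
                                       alpha, gamma))
      }
      if (t %% sync_period == 0L) target_sync(qnet, target)
    }
    list(qnet = qnet, target = target, losses = losses)
  })
}

#' Greedy policy of a Q-network over one-hot tabular states
#' @param qnet a [q_network()]
#' @param S number of states
#' @return integer vector of 1-based greedy actions per state
#' @export
greedy_policy <- function(qnet, S) {
  vapply(seq_len(S), function(s) {
    v <- numeric(S); v[s] <- 1
    which.max(q_values(qnet, v))
  }, 1L)
}

#' Three small deterministic MDP fixtures with well-separated optima
#'
#' Used to validate the DQN against exact value iteration.
#' @return list of three MDPs (see [solve_mdp_exact()] for the format)
#' @export
toy_mdps <- function() {
  list(
    # two-state switch: reach s2 and stay there collecting +1
    list(R = matrix(c(0, 0,      # s1: a1 -> s1 (0), a2 -> s2 (0)
                      1, 0), 2, 2, byrow = TRUE),
         next_state = matrix(c(1L, 2L,
                               2L, 1L), 2, 2, byrow = TRUE)),
    # three-state cycle: moving "forward" collects the big reward at s3
    list(R = matrix(c(0.0, 1.0,
                      0.0, 1.0,
                      3.0, 0.0), 3, 2, byrow = TRUE),
         next_state = matrix(c(1L, 2L,
                               2L, 3L,
                               1L, 3L), 3, 2, byrow = TRUE)),
    # gated goal: s3 is absorbing; the safe path s1->s2->goal beats the
    # immediate small reward
    list(R = matrix(c(0.4, 0.0,
                      0.0, 2.0,
                      0.0, 0.0), 3, 2, byrow = TRUE),
         next_state = matrix(c(1L, 2L,
                               1L, 3L,
                               3L, 3L), 3, 2, byrow = TRUE),
         terminal = c(FALSE, FALSE, TRUE)))
}
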