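# Deep Q-network value learner with linearly decaying epsilon-greedy
# exploration.
#
# The network scores candidate molecules directly (a merged state-action
# value, as in MolDQN): input is the candidate's circular fingerprint plus
# the normalized steps-remaining clock.  Reward is terminal-only; targets
# bootstrap through a periodically synced target network.

#' Agent configuration
#'
#' Defaults follow the study conditions: 6000 episodes with epsilon
#' decaying linearly from 1.0 by 1/6000 per episode.
#'
#' @param episodes total optimization episodes.
#' @param epsilon_init initial exploration probability.
#' @param epsilon_decrement linear decrement per episode (default
#'   `1/episodes`).
#' @param epsilon_floor lower bound of the schedule.
#' @param gamma discount factor for bootstrapped targets.
#' @param replay_capacity transition buffer size.
#' @param batch_size minibatch size per gradient step.
#' @param target_sync_every episodes between target-network syncs.
#' @param train_every environment steps between gradient steps.
#' @param fp_radius,fp_width circular fingerprint radius and folded width.
#' @param hidden integer vector of hidden-layer sizes.
#' @param learning_rate Adam step size.
#' @param seed master seed; fans out to initialization, action selection
#'   and replay sampling through one reproducible stream.
#' @return an object of class `agent_config`.
#' @export
agent_config <- function(episodes = 6000L, epsilon_init = 1.0,
                         epsilon_decrement = NULL,
                         epsilon_floor = 0.0, gamma = 0.9,
                         replay_capacity = 5000L, batch_size = 128L,
                         target_sync_every = 20L, train_every = 1L,
                         fp_radius = 2L, fp_width = 2048L,
                         hidden = c(1024L, 512L), learning_rate = 1e-4,
                         seed = 1L) {
  if (episodes < 1L) stop("episodes must be >= 1", call. = FALSE)
  if (epsilon_init < 0 || epsilon_init > 1)
    stop("epsilon_init must lie in [0,1]", call. = FALSE)
  # the default schedule 1/episodes is kept in rational form so that the
  # linear decay is exact at every episode (1 - 1500/6000 is exactly 0.75)
  epsilon_den <- NULL
  if (is.null(epsilon_decrement)) {
    epsilon_den <- as.numeric(episodes)
    epsilon_decrement <- 1 / epsilon_den
  } else if (epsilon_decrement > 0 &&
             abs(1 / epsilon_decrement - round(1 / epsilon_decrement)) <
               1e-9) {
    epsilon_den <- round(1 / epsilon_decrement)
  }
  if (epsilon_decrement < 0)
    stop("epsilon_decrement must be >= 0", call. = FALSE)
  structure(list(episodes = as.integer(episodes),
                 epsilon_init = epsilon_init,
                 epsilon_decrement = epsilon_decrement,
                 epsilon_den = epsilon_den,
                 epsilon_floor = epsilon_floor, gamma = gamma,
                 replay_capacity = as.integer(replay_capacity),
                 batch_size = as.integer(batch_size),
                 target_sync_every = as.integer(target_sync_every),
                 train_every = as.integer(train_every),
                 fp_radius = as.integer(fp_radius),
                 fp_width = as.integer(fp_width),
                 hidden = as.integer(hidden),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "agent_config")
}

#' Exploration probability at a given episode
#'
#' The linear schedule `max(floor, init - episode * decrement)`, evaluated
#' in exact double arithmetic; with the defaults, episode 0 gives 1.0 and
#' episode 6000 gives 0.0.
#'
#' @param episode 0-based episode index.
#' @param cfg an `agent_config`.
#' @return a probability.
#' @export
epsilon_at <- function(episode, cfg) {
  if (any(episode < 0)) stop("episode must be >= 0", call. = FALSE)
  dec <- if (!is.null(cfg$epsilon_den)) episode / cfg$epsilon_den
         else episode * cfg$epsilon_decrement
  pmax(cfg$epsilon_floor, cfg$epsilon_init - dec)
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniform-random candidate; otherwise the
#' argmax of the Q estimates, ties broken by lexicographic canonical
#' SMILES.
#'
#' @param candidates list of candidate molecules.
#' @param q_values numeric vector aligned with `candidates`.
#' @param epsilon exploration probability.
#' @return index of the selected candidate.
#' @export
select_action <- function(candidates, q_values, epsilon) {
  k <- length(candidates)
  if (k == 0L) stop("empty candidate set", call. = FALSE)
  if (length(q_values) != k)
    stop("q_values not aligned with candidates", call. = FALSE)
  if (stats::runif(1) < epsilon) return(sample.int(k, 1L))
  mx <- which(q_values == max(q_values))
  if (length(mx) == 1L) return(mx)
  smi <- canonical_smiles(candidates[mx])
  mx[order(smi)[1L]]
}

# --- multilayer perceptron with Adam ---------------------------------------

mlp_init <- function(n_in, hidden, seed) {
  set.seed(seed)
  sizes <- c(n_in, hidden, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(net, X) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% net$W[[l]]
    Z <- sweep(Z, 2L, net$b[[l]], `+`)
    acts[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
  }
  acts
}

mlp_predict <- function(net, X) {
  drop(mlp_forward(net, X)[[length(net$W) + 1L]])
}

# Gradient of mean squared error 0.5 * mean((q - y)^2).
mlp_gradients <- function(net, acts, y) {
  L <- length(net$W)
  nb <- nrow(acts[[1L]])
  delta <- (acts[[L + 1L]] - y) / nb
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1L) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% t(net$W[[l]])) * (acts[[l]] > 0)
  }
  list(W = gW, b = gb)
}

adam_init <- function(net) {
  list(mW = lapply(net$W, function(w) w * 0),
       vW = lapply(net$W, function(w) w * 0),
       mb = lapply(net$b, function(b) b * 0),
       vb = lapply(net$b, function(b) b * 0), t = 0L)
}

adam_step <- function(net, g, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (l in seq_along(net$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * g$W[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * g$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * g$b[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * g$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(net = net, st = st)
}

# --- replay buffer ----------------------------------------------------------

replay_new <- function(capacity) {
  env <- new.env(parent = emptyenv())
  env$buf <- vector("list", capacity)
  env$n <- 0L; env$pos <- 0L; env$capacity <- capacity
  env
}

replay_push <- function(rp, transition) {
  rp$pos <- rp$pos %% rp$capacity + 1L
  rp$buf[[rp$pos]] <- transition
  rp$n <- min(rp$n + 1L, rp$capacity)
  invisible(rp)
}

replay_sample <- function(rp, k) rp$buf[sample.int(rp$n, k, replace = FALSE)]

#' One temporal-difference gradient step
#'
#' Computes bootstrapped targets `r + gamma * max Q_target(next)` for a
#' replay sample, takes one Adam step on the squared TD error and returns
#' the batch loss.
#'
#' @param sample list of transitions (as stored by [run_optimization()]).
#' @param networks list with elements `net`, `target`, `adam`.
#' @param cfg an `agent_config`.
#' @return list with updated `networks` and the scalar `loss`.
#' @export
train_on_batch <- function(sample, networks, cfg) {
  nb <- length(sample)
  width <- cfg$fp_width
  X <- matrix(0, nb, width + 1L)
  y <- numeric(nb)
  nonterm <- which(!vapply(sample, `[[`, TRUE, "terminal"))
  for (i in seq_len(nb)) {
    tr <- sample[[i]]
    X[i, seq_len(width)] <- tabulate(tr$sa_bits, width)
    X[i, width + 1L] <- tr$sa_frac
    y[i] <- tr$reward
  }
  if (length(nonterm)) {
    counts <- vapply(sample[nonterm], function(tr) length(tr$next_bits), 0L)
    Xn <- matrix(0, sum(counts), width + 1L)
    row <- 0L
    for (i in nonterm) {
      tr <- sample[[i]]
      for (j in seq_along(tr$next_bits)) {
        row <- row + 1L
        Xn[row, seq_len(width)] <- tabulate(tr$next_bits[[j]], width)
        Xn[row, width + 1L] <- tr$next_frac
      }
    }
    qn <- mlp_predict(networks$target, Xn)
    grp <- rep.int(seq_along(nonterm), counts)
    qmax <- vapply(split(qn, grp), max, 0)
    y[nonterm] <- y[nonterm] + cfg$gamma * qmax
  }
  acts <- mlp_forward(networks$net, X)
  loss <- 0.5 * mean((drop(acts[[length(networks$net$W) + 1L]]) - y)^2)
  if (!is.finite(loss))
    stop("training diverged: non-finite TD loss (batch of ", nb, ")",
         call. = FALSE)
  g <- mlp_gradients(networks$net, acts, y)
  upd <- adam_step(networks$net, g, networks$adam, cfg$learning_rate)
  networks$net <- upd$net; networks$adam <- upd$st
  list(networks = networks, loss = loss)
}

# --- episode generation -----------------------------------------------------

#' Run the reinforcement-learning optimization
#'
#' Generates `cfg$episodes` episodes of at most `mdp_cfg$step_limit` edits
#' from the lead, learning a Q-network from terminal rewards.  The scalar
#' training reward is `w_aff * (-affinity/10) + w_qed * QED + w_sa * SA`;
#' the three components are logged separately per episode.  Fully
#' reproducible for a fixed seed when the affinity oracle is deterministic.
#'
#' @param lead a valid `molecule`.
#' @param mdp_cfg an `mdp_config`.
#' @param agent_cfg an `agent_config`.
#' @param reward_cfg a `reward_config` (see [reward_config()]).
#' @param agent `"dqn"` (learned) or `"random"` (epsilon fixed at 1, no
#'   training; the exploration-only baseline).
#' @param trajectory_file optional path: one JSON line per step with state
#'   SMILES, action SMILES and step index.
#' @param verbose print progress every 50 episodes.
#' @return data.frame of episode records: `episode`, `smiles`,
#'   `affinity_kcal_mol`, `qed`, `sa`, `epsilon`, `scalar_reward`,
#'   `failed`.
#' @export
run_optimization <- function(lead, mdp_cfg, agent_cfg, reward_cfg,
                             agent = c("dqn", "random"),
                             trajectory_file = NULL, verbose = FALSE) {
  agent <- match.arg(agent)
  set.seed(agent_cfg$seed)
  width <- agent_cfg$fp_width
  net <- mlp_init(width + 1L, agent_cfg$hidden, seed = agent_cfg$seed)
  target <- net
  adam <- adam_init(net)
  networks <- list(net = net, target = target, adam = adam)
  rp <- replay_new(agent_cfg$replay_capacity)
  lead_key <- mol_key(lead)
  traj_con <- if (!is.null(trajectory_file))
    file(trajectory_file, "w") else NULL
  on.exit(if (!is.null(traj_con)) close(traj_con))
  records <- vector("list", agent_cfg$episodes)
  n_failed <- 0L
  step_since_train <- 0L
  for (ep in seq_len(agent_cfg$episodes) - 1L) {
    eps <- if (agent == "random") 1.0 else epsilon_at(ep, agent_cfg)
    s <- initial_state(lead, mdp_cfg)
    pending <- NULL
    final <- lead
    rv <- NULL; failed <- FALSE
    while (!is_terminal(s)) {
      cands <- enumerate_actions(s, mdp_cfg)
      bits <- lapply(cands, featurize_bits, cfg = agent_cfg)
      # clock of a candidate: steps remaining after applying it
      cand_frac <- (s$step_limit - s$steps_taken - 1L) / s$step_limit
      # attach the candidate set of this state to the previous transition
      if (!is.null(pending)) {
        pending$next_bits <- bits
        pending$next_frac <- cand_frac
        replay_push(rp, pending)
        pending <- NULL
      }
      if (agent == "dqn" && stats::runif(1) >= eps) {
        X <- matrix(0, length(cands), width + 1L)
        for (i in seq_along(bits))
          X[i, seq_len(width)] <- tabulate(bits[[i]], width)
        X[, width + 1L] <- cand_frac
        qv <- mlp_predict(networks$net, X)
        mx <- which(qv == max(qv))
        sel <- if (length(mx) == 1L) mx
               else mx[order(canonical_smiles(cands[mx]))[1L]]
      } else {
        sel <- sample.int(length(cands), 1L)
      }
      chosen <- cands[[sel]]
      terminal_next <- s$steps_taken + 1L >= s$step_limit
      reward <- 0
      if (terminal_next) {
        rv <- tryCatch(reward_vector(chosen, reward_cfg),
                       error = function(e) e)
        if (inherits(rv, "error")) {
          failed <- TRUE
          rv <- list(affinity = NA_real_, qed = NA_real_, sa = NA_real_,
                     scalar = NA_real_)
        }
        reward <- if (failed) 0 else rv$scalar
      }
      tr <- list(sa_bits = bits[[sel]], sa_frac = cand_frac,
                 reward = reward, terminal = terminal_next,
                 next_bits = NULL, next_frac = NA_real_)
      if (terminal_next) replay_push(rp, tr) else pending <- tr
      if (!is.null(traj_con))
        writeLines(jsonlite::toJSON(list(
          episode = ep, step = s$steps_taken,
          state = to_canonical_smiles(s$mol),
          action = to_canonical_smiles(chosen)), auto_unbox = TRUE),
          traj_con)
      # successor built directly: `chosen` is cands[[sel]] by construction
      s <- structure(list(mol = chosen, steps_taken = s$steps_taken + 1L,
                          step_limit = s$step_limit),
                     class = "mdp_state")
      final <- chosen
      step_since_train <- step_since_train + 1L
      if (agent == "dqn" && rp$n >= agent_cfg$batch_size &&
          step_since_train >= agent_cfg$train_every) {
        res <- train_on_batch(replay_sample(rp, agent_cfg$batch_size),
                              networks, agent_cfg)
        networks <- res$networks
        step_since_train <- 0L
      }
    }
    if (failed) n_failed <- n_failed + 1L
    if (n_failed > 0.1 * agent_cfg$episodes)
      stop("more than 10% of episodes failed reward evaluation; aborting",
           call. = FALSE)
    records[[ep + 1L]] <- data.frame(
      episode = ep, smiles = to_canonical_smiles(final),
      affinity_kcal_mol = rv_or_na(rv, "affinity"),
      qed = rv_or_na(rv, "qed"), sa = rv_or_na(rv, "sa"),
      epsilon = eps, scalar_reward = rv_or_na(rv, "scalar"),
      failed = failed, stringsAsFactors = FALSE)
    if (agent == "dqn" && (ep + 1L) %% agent_cfg$target_sync_every == 0L)
      networks$target <- networks$net
    if (verbose && (ep + 1L) %% 50L == 0L)
      message(sprintf("episode %d/%d  eps=%.3f", ep + 1L,
                      agent_cfg$episodes, eps))
  }
  log <- do.call(rbind, records)
  attr(log, "networks") <- networks
  log
}

rv_or_na <- function(rv, field) {
  if (is.null(rv) || inherits(rv, "error")) return(NA_real_)
  as.numeric(rv[[field]])
}
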