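# Q-learning machinery: epsilon schedule, featurization, action
# selection, TD training, and reproducibility of episode generation.

test_that("the epsilon schedule is exactly linear", {
  cfg <- agent_config(episodes = 6000L)
  expect_identical(epsilon_at(0, cfg), 1.0)
  expect_identical(epsilon_at(3000, cfg), 0.5)
  expect_identical(epsilon_at(6000, cfg), 0.0)
  expect_identical(epsilon_at(9000, cfg), 0.0)  # floor
  expect_error(epsilon_at(-1, cfg), ">= 0")

  cfg2 <- agent_config(episodes = 100L, epsilon_floor = 0.1)
  expect_equal(epsilon_at(95, cfg2), 0.1)
})

test_that("featurization separates structures and carries the step clock", {
  cfg <- agent_config(fp_width = 512L)
  m1 <- parse_smiles("c1ccccc1")
  m2 <- parse_smiles("c1ccncc1")
  v1 <- featurize(m1, cfg); v2 <- featurize(m2, cfg)
  expect_length(v1, 513L)
  expect_false(identical(v1, v2))
  expect_identical(featurize(parse_smiles("C"), cfg),
                   featurize(parse_smiles("C"), cfg))
  v3 <- featurize(m1, cfg, steps_frac = 0.5)
  expect_equal(v3[513L], 0.5)
  expect_identical(v1[1:512], v3[1:512])
})

test_that("epsilon-greedy selection is uniform at epsilon 1 and greedy at 0", {
  cands <- lapply(c("C", "CC", "CCC", "CCO", "CCN", "CO", "CN", "C=O",
                    "C=C"), parse_smiles)
  q <- c(5, 1, 2, 3, 4, 0, -1, 2, 2.5)
  set.seed(99)
  picks <- tabulate(replicate(90000, select_action(cands, q, 1.0)),
                    nbins = 9L)
  expect_true(all(abs(picks - 10000) <= 400))   # binomial 99% interval

  expect_equal(select_action(cands, q, 0.0), 1L)

  # tie: the lexicographically smaller canonical SMILES wins
  qtie <- c(0, 7, 7, 0, 0, 0, 0, 0, 0)
  sel <- select_action(cands, qtie, 0.0)
  expect_equal(to_canonical_smiles(cands[[sel]]), "CC")
  expect_error(select_action(list(), numeric(0), 0.5), "empty")
  expect_error(select_action(cands, q[1:3], 0.5), "aligned")
})

test_that("TD training reaches its fixed points", {
  cfg <- agent_config(episodes = 10L, fp_width = 32L, hidden = c(16L),
                      gamma = 0, batch_size = 4L, learning_rate = 1e-2)
  net <- leadopt:::mlp_init(33L, cfg$hidden, seed = 4L)
  networks <- list(net = net, target = net,
                   adam = leadopt:::adam_init(net))

  # all-zero rewards: loss decays toward zero on repeated identical batches
  zero_batch <- lapply(1:4, function(i)
    list(sa_bits = c(i, i + 5L), sa_frac = 0.5, reward = 0,
         terminal = TRUE, next_bits = NULL, next_frac = NA_real_))
  losses <- numeric(300)
  for (k in seq_along(losses)) {
    res <- train_on_batch(zero_batch, networks, cfg)
    networks <- res$networks; losses[k] <- res$loss
  }
  expect_lt(losses[300], losses[1] / 100)
  expect_lt(losses[300], 1e-4)

  # a single repeated transition with reward r drives Q(s,a) to r
  r <- 0.73
  one <- list(list(sa_bits = c(2L, 9L), sa_frac = 0, reward = r,
                   terminal = TRUE, next_bits = NULL,
                   next_frac = NA_real_))
  net2 <- leadopt:::mlp_init(33L, cfg$hidden, seed = 5L)
  networks2 <- list(net = net2, target = net2,
                    adam = leadopt:::adam_init(net2))
  for (k in 1:800)
    networks2 <- train_on_batch(rep(one, 4L), networks2, cfg)$networks
  x <- matrix(0, 1, 33L); x[1, c(2L, 9L)] <- 1
  expect_equal(leadopt:::mlp_predict(networks2$net, x), r,
               tolerance = 0.02)
})

test_that("losses stay finite through a seeded smoke of training steps", {
  cfg <- agent_config(episodes = 10L, fp_width = 64L, hidden = c(32L, 16L),
                      gamma = 0.9, batch_size = 8L, learning_rate = 1e-3)
  net <- leadopt:::mlp_init(65L, cfg$hidden, seed = 21L)
  networks <- list(net = net, target = net,
                   adam = leadopt:::adam_init(net))
  set.seed(21)
  mk_tr <- function() {
    term <- runif(1) < 0.3
    list(sa_bits = sample.int(64L, 8L), sa_frac = runif(1),
         reward = if (term) rnorm(1) else 0, terminal = term,
         next_bits = if (term) NULL else
           lapply(1:5, function(i) sample.int(64L, 8L)),
         next_frac = runif(1))
  }
  ok <- TRUE
  for (k in 1:1000) {
    res <- train_on_batch(lapply(1:8, function(i) mk_tr()), networks, cfg)
    networks <- res$networks
    ok <- ok && is.finite(res$loss)
  }
  expect_true(ok)
})

test_that("short optimizations reproduce exactly under a fixed seed", {
  cfg <- seeded_smoke_config(seed = 11L)
  cfg$agent$episodes <- 12L
  cfg$agent$epsilon_den <- 12
  cfg$mdp <- mdp_config(step_limit = 4L)
  log1 <- run_optimization(cfg$lead, cfg$mdp, cfg$agent, cfg$reward)
  log2 <- run_optimization(cfg$lead, cfg$mdp, cfg$agent, cfg$reward)
  attr(log1, "networks") <- NULL; attr(log2, "networks") <- NULL
  expect_identical(log1, log2)
  expect_equal(nrow(log1), 12L)
  expect_equal(log1$epsilon, epsilon_at(log1$episode, cfg$agent))
  expect_true(all(!log1$failed))
  # every final structure is a valid molecule
  for (s in log1$smiles)
    expect_true(isTRUE(validate_molecule(parse_smiles(s))))
})

test_that("a fully random agent matches uniform action frequencies", {
  # one-step episodes from methane: 9 candidates, chi-square on picks
  cfg <- seeded_smoke_config(seed = 77L)
  cfg$agent$episodes <- 450L
  cfg$agent$epsilon_den <- NULL
  cfg$agent$epsilon_decrement <- 0    # epsilon fixed at 1
  cfg$mdp <- mdp_config(step_limit = 1L)
  log <- run_optimization(parse_smiles("C"), cfg$mdp, cfg$agent,
                          cfg$reward, agent = "random")
  counts <- table(log$smiles)
  expect_equal(length(counts), 9L)
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.001)
})
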