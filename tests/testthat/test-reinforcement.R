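test_that("actions are greedy with seeded random tie-breaking", {
  expect_identical(choose_action(c(0.2, 0.5)), 2L)
  expect_identical(choose_action(c(-0.3, -0.3, 0.1)), 3L)
  set.seed(91)
  draws <- replicate(2000, choose_action(c(0, 0)))
  expect_setequal(unique(draws), c(1L, 2L))
  expect_gt(mean(draws == 1L), 0.45)
  expect_lt(mean(draws == 1L), 0.55)
  set.seed(92)
  a <- choose_action(c(0.7, 0.7))
  set.seed(92)
  expect_identical(choose_action(c(0.7, 0.7)), a)
})

test_that("episode buffer keeps the last m steps in order", {
  buf <- episode_buffer(3)
  for (i in 1:5) buf <- buffer_push(buf, rep(i / 10, 2), (i %% 2) + 1L)
  expect_length(buf$actions, 3L)
  expect_identical(buf$inputs[[1]], rep(0.3, 2)) # oldest surviving step
  expect_identical(buf$inputs[[3]], rep(0.5, 2)) # newest
})

test_that("failure neurogenesis fades inhibition linearly over the window", {
  buf <- episode_buffer(10)
  for (i in 1:10) buf <- buffer_push(buf, runif(4), sample(1:2, 1))
  net <- failure_neurogenesis(edn_network(4, 2), buf)
  expect_identical(n_neurons(net), 10L)
  w <- vapply(net$neurons, function(nu) nu$eff_weight, numeric(1))
  # created newest first: -1, -0.9, ..., -0.1
  expect_equal(w, -(1 - (0:9) / 10))
  expect_true(all(w < 0)) # only inhibition is ever written
  # afferents store the full observation of their own step
  expect_identical(net$neurons[[1]]$aff_value, buf$inputs[[10]])
  expect_identical(net$neurons[[10]]$aff_value, buf$inputs[[1]])
  # window shorter than m: one neuron per buffered step
  short <- episode_buffer(10)
  for (i in 1:7) short <- buffer_push(short, runif(4), 1L)
  expect_identical(n_neurons(failure_neurogenesis(edn_network(4, 2), short)),
                   7L)
  # empty buffer is a no-op
  expect_identical(
    n_neurons(failure_neurogenesis(edn_network(4, 2), episode_buffer(10))),
    0L)
})

test_that("new neurons inherit the mean reward of the network", {
  net <- edn_network(4, 2)
  net <- edn:::add_neuron(net, 1:4, runif(4), 1, -0.5, reward = 0.2)
  net <- edn:::add_neuron(net, 1:4, runif(4), 2, -0.5, reward = 0.6)
  buf <- buffer_push(episode_buffer(5), runif(4), 1L)
  grown <- failure_neurogenesis(net, buf)
  expect_equal(grown$neurons[[3]]$reward, 0.4)
  # first neurons of an empty network start at zero
  first <- failure_neurogenesis(edn_network(4, 2), buf)
  expect_identical(first$neurons[[1]]$reward, 0)
})

test_that("reward low-pass credits activity and decays otherwise", {
  net <- edn_network(2, 2)
  net <- edn:::add_neuron(net, 1:2, c(0.5, 0.5), 1, -1, reward = 0)
  net <- edn:::add_neuron(net, 1:2, c(0.5, 0.5), 2, -1, reward = 0.3)
  up <- update_rewards(net, c(1, 0), r = 1, tau = 0.9999)
  expect_equal(up$neurons[[1]]$reward, 0.0001)
  expect_equal(up$neurons[[2]]$reward, 0.9999 * 0.3) # pure decay
  up0 <- update_rewards(net, c(1, 1), r = 0, tau = 0.9999)
  expect_equal(up0$neurons[[1]]$reward, 0)
  expect_equal(up0$neurons[[2]]$reward, 0.9999 * 0.3)
})

test_that("pruning removes lowest-reward neurons, oldest first on ties", {
  net <- edn_network(2, 2)
  for (rw in c(0.5, 0.1, 0.3)) {
    net <- edn:::add_neuron(net, 1:2, runif(2), 1, -1, reward = rw)
  }
  pruned <- prune(net, 2)
  expect_identical(vapply(pruned$neurons, function(nu) nu$reward, numeric(1)),
                   c(0.5, 0.3))
  expect_identical(serialize_edn(prune(net, 3)), serialize_edn(net))
  # tie at the minimum drops the oldest id
  tie <- edn_network(2, 2)
  for (i in 1:3) tie <- edn:::add_neuron(tie, 1:2, runif(2), 1, -1,
                                         reward = 0.1)
  kept <- prune(tie, 2)
  expect_identical(vapply(kept$neurons, function(nu) nu$id, integer(1)),
                   c(2L, 3L))
})

test_that("cart-pole dynamics match an independent Lagrangian solution", {
  set.seed(103)
  p <- cartpole_params()
  for (i in 1:50) {
    state <- c(runif(1, -2, 2), runif(1, -2, 2),
               runif(1, -0.2, 0.2), runif(1, -2, 2))
    action <- sample(1:2, 1)
    nxt <- cartpole_step(state, action, p)$state
    acc <- oracle_cartpole_acc(state, action, p)
    expect_equal(nxt[2], state[2] + p$dt * acc$x_acc, tolerance = 1e-10)
    expect_equal(nxt[4], state[4] + p$dt * acc$theta_acc, tolerance = 1e-10)
    expect_equal(nxt[1], state[1] + p$dt * state[2])
    expect_equal(nxt[3], state[3] + p$dt * state[4])
  }
})

test_that("cart-pole dynamics are mirror symmetric", {
  set.seed(104)
  for (i in 1:20) {
    state <- c(runif(1, -1, 1), runif(1, -1, 1),
               runif(1, -0.15, 0.15), runif(1, -1, 1))
    a <- cartpole_step(state, 2L)
    b <- cartpole_step(-state, 1L)
    expect_identical(a$state, -b$state)
    expect_identical(a$terminal, b$terminal)
  }
})

test_that("episodes terminate on position or angle bound violations", {
  p <- cartpole_params()
  out <- cartpole_step(c(0, 0, 0.209, 3), 2L, p) # angle tips past 12 deg
  expect_true(out$terminal)
  out2 <- cartpole_step(c(2.39, 3, 0, 0), 2L, p) # cart crosses 2.4 m
  expect_true(out2$terminal)
  out3 <- cartpole_step(c(0, 0, 0, 0), 2L, p)
  expect_false(out3$terminal)
  expect_error(cartpole_step(c(0, 0, 0, 0), 3L), "action")
})

test_that("observation normalization clamps then scales to the unit box", {
  b <- cartpole_obs_bounds()
  expect_equal(normalize_observation(c(0, 0, 0, 0), b), rep(0.5, 4))
  expect_equal(normalize_observation(c(-2.4, 3, 12 * pi / 180, -9), b),
               c(0, 1, 1, 0))
  expect_equal(normalize_observation(c(99, -99, 1, 9), b), c(1, 0, 1, 1))
})

test_that("compiled and reference trainers are bit-identical", {
  for (norm in c("running", "fixed")) {
    a <- run_cartpole_training(max_trials = 40, max_size = 25, seed = 17,
                               engine = "compiled", normalization = norm,
                               stop_when_solved = FALSE)
    b <- run_cartpole_training(max_trials = 40, max_size = 25, seed = 17,
                               engine = "reference", normalization = norm,
                               stop_when_solved = FALSE)
    expect_identical(a$balance, b$balance)
    expect_identical(a$neurons, b$neurons)
    expect_identical(serialize_edn(a$network), serialize_edn(b$network))
  }
})

test_that("training runs are reproducible and respect the size cap", {
  a <- run_cartpole_training(max_trials = 60, max_size = 40, seed = 19,
                             stop_when_solved = FALSE)
  b <- run_cartpole_training(max_trials = 60, max_size = 40, seed = 19,
                             stop_when_solved = FALSE)
  expect_identical(a$balance, b$balance)
  expect_identical(serialize_edn(a$network), serialize_edn(b$network))
  expect_true(all(a$neurons <= 40))
  # rewards accumulate within [0, r] and weights stay inhibitory
  rewards <- vapply(a$network$neurons, function(nu) nu$reward, numeric(1))
  expect_true(all(rewards >= 0 & rewards <= 1))
  weights <- vapply(a$network$neurons, function(nu) nu$eff_weight, numeric(1))
  expect_true(all(weights < 0))
})
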