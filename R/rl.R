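#' Greedy action selection with random tie-breaking
#'
#' The action is the argmax of the output activations. When every output is
#' equal -- including the all-zero outputs of an empty network -- a uniformly
#' random action is drawn from R's RNG stream.
#'
#' @param outputs Signed output activations (length >= 2).
#' @return Action index in `1..n_outputs`.
#' @export
choose_action <- function(outputs) {
  stopifnot(length(outputs) >= 2L)
  if (all(outputs == outputs[1])) {
    return(floor(stats::runif(1) * length(outputs)) + 1L)
  }
  which.max(outputs)
}

#' Episode buffer for failure credit assignment
#'
#' Rolling window of the last `m` (observation, action) pairs, oldest first.
#'
#' @param m Window capacity (the failure memory length).
#' @return An object of class `edn_buffer`.
#' @export
episode_buffer <- function(m) {
  stopifnot(m >= 1)
  structure(list(m = as.integer(m), inputs = list(), actions = integer(0)),
            class = "edn_buffer")
}

#' Push a step onto the episode buffer
#' @param buffer An [episode_buffer()].
#' @param inputs Normalized observation at this step.
#' @param action Action index taken at this step.
#' @return The updated buffer (length capped at `m`, oldest dropped).
#' @export
buffer_push <- function(buffer, inputs, action) {
  buffer$inputs[[length(buffer$inputs) + 1L]] <- inputs
  buffer$actions <- c(buffer$actions, as.integer(action))
  if (length(buffer$actions) > buffer$m) {
    buffer$inputs <- buffer$inputs[-1L]
    buffer$actions <- buffer$actions[-1L]
  }
  buffer
}

#' Failure-window neurogenesis
#'
#' On failure, the buffered steps are inhibited: for the step at age `t`
#' (t = 0 is the most recent), a neuron is created whose afferents store that
#' step's full observation and whose single efferent connects to the chosen
#' action's output with weight `-(1 - t/m)`. The most recent step gets the
#' full error of -1; the window fades linearly to zero. New neurons start
#' with reward equal to the current mean reward over existing neurons (0 for
#' an empty network), giving them time to be evaluated before pruning.
#'
#' Neurons are created newest step first, so within one failure the most
#' strongly inhibited step gets the lowest id.
#'
#' @param network An [edn_network()].
#' @param buffer An [episode_buffer()] holding the steps before the failure.
#' @return The network with up to `m` new neurons.
#' @export
failure_neurogenesis <- function(network, buffer) {
  len <- length(buffer$actions)
  if (len == 0L) {
    return(network)
  }
  m <- buffer$m
  rewards <- vapply(network$neurons, function(nu) nu$reward, numeric(1))
  r0 <- if (length(rewards) > 0L) mean(rewards) else 0
  for (t in 0:(len - 1L)) {
    pos <- len - t # newest last in the buffer
    w <- -(1 - t / m)
    if (w == 0) next # steps at the window edge carry no weight
    network <- add_neuron(network,
                          aff_index = seq_along(buffer$inputs[[pos]]),
                          aff_value = buffer$inputs[[pos]],
                          eff_index = buffer$actions[pos],
                          eff_weight = w,
                          reward = r0)
  }
  network
}

#' Low-pass reward accumulation per neuron
#'
#' At every environment timestep each neuron's accumulated reward is updated
#' as `R <- tau * R + (1 - tau) * r * a_n`, crediting active neurons in
#' proportion to their activity while slowly forgetting.
#'
#' @param network An [edn_network()].
#' @param activations Per-neuron activations from the current forward pass.
#' @param r Reward delivered this timestep (1 while the pole is balanced).
#' @param tau Low-pass time constant (default 0.9999).
#' @return The network with updated rewards.
#' @export
update_rewards <- function(network, activations, r = 1, tau = 0.9999) {
  stopifnot(length(activations) == n_neurons(network))
  for (i in seq_along(network$neurons)) {
    nu <- network$neurons[[i]]
    nu$reward <- tau * nu$reward + (1 - tau) * r * activations[i]
    network$neurons[[i]] <- nu
  }
  network
}

#' Prune the network to a size cap by accumulated reward
#'
#' While the neuron count exceeds the cap, the neuron with the lowest
#' accumulated reward is removed (ties drop the oldest id), keeping the
#' mappings that contribute most to rewarded behavior.
#'
#' @param network An [edn_network()].
#' @param max_size Size cap (>= 1).
#' @return The pruned network.
#' @export
prune <- function(network, max_size) {
  stopifnot(max_size >= 1)
  while (n_neurons(network) > max_size) {
    rewards <- vapply(network$neurons, function(nu) nu$reward, numeric(1))
    network$neurons[[which.min(rewards)]] <- NULL
  }
  network
}

solved_at <- function(balance, window = 100L, threshold = 475) {
  n <- length(balance)
  if (n < window) return(NA_integer_)
  cs <- cumsum(balance)
  means <- (cs[window:n] - c(0, cs[seq_len(n - window)])) / window
  hit <- which(means > threshold)
  if (length(hit) == 0L) NA_integer_ else hit[1L] + window - 1L
}

#' Train an error-driven-neurogenesis agent on cart-pole
#'
#' Per trial: the state is reset with a small uniform perturbation, then the
#' loop runs choose-action, environment step, reward update (r = 1 per
#' balanced timestep) with observations min-max normalized by the fixed
#' state bounds. On failure the last `memory` steps are inhibited via
#' [failure_neurogenesis()], the network is pruned to `max_size` (when set),
#' and the buffer is cleared. Training stops when the running mean balance
#' over the last 100 trials exceeds 475 of the 500-step maximum (the solved
#' criterion), or at the trial cap.
#'
#' The default engine is a compiled loop; `engine = "reference"` runs a pure
#' R implementation that consumes R's RNG stream in the identical order, so
#' the two produce identical learning curves for the same seed.
#'
#' @param spread Kernel spread (0.6 works well here).
#' @param memory Failure window length `m`.
#' @param max_size Optional neuron cap with reward pruning; `NULL` disables
#'   deletion.
#' @param tau Reward low-pass constant.
#' @param max_trials Trial cap.
#' @param max_steps Episode cap (500 by convention).
#' @param seed Integer seed; set before any randomness.
#' @param stop_when_solved Stop at the solved criterion (default) or always
#'   run `max_trials` trials.
#' @param engine `"compiled"` (default) or `"reference"`.
#' @param normalization `"running"` (default) scales each observation by the
#'   per-dimension min/max of all observations seen so far, the online
#'   analogue of min-max normalizing a dataset before training; `"fixed"`
#'   clamps to the static bounds of [cartpole_obs_bounds()]. Running
#'   normalization keeps the kernel distances discriminative around the
#'   states the agent actually visits.
#' @param params Environment constants from [cartpole_params()].
#' @return List with `balance` (steps per trial), `neurons` (count per
#'   trial), `trials_to_solve` (`NA` if unsolved), `solved`, and `network`
#'   (the final [edn_network()]).
#' @export
run_cartpole_training <- function(spread = 0.6, memory = 10, max_size = NULL,
                                  tau = 0.9999, max_trials = 2000,
                                  max_steps = 500, seed = 1,
                                  stop_when_solved = TRUE,
                                  engine = c("compiled", "reference"),
                                  normalization = c("running", "fixed"),
                                  params = cartpole_params()) {
  engine <- match.arg(engine)
  normalization <- match.arg(normalization)
  set.seed(seed)
  if (engine == "compiled") {
    bounds <- cartpole_obs_bounds()
    res <- cartpole_train_cpp(
      spread, as.integer(memory),
      if (is.null(max_size)) 0L else as.integer(max_size),
      tau, as.integer(max_trials), as.integer(max_steps),
      isTRUE(stop_when_solved),
      c(params$gravity, params$cart_mass, params$pole_mass,
        params$pole_half_length, params$force_mag, params$dt,
        params$x_threshold, params$theta_threshold),
      bounds["low", ], bounds["high", ],
      normalization == "running")
    net <- edn_network(4L, 2L, spread = spread, error_threshold = 0,
                       surprise_threshold = 0, max_size = max_size)
    ids <- res$ids
    for (i in seq_along(ids)) {
      net <- within_id_add(net, ids[i], res$centers[i, ], res$actions[i],
                           res$weights[i], res$rewards[i])
    }
    net$next_id <- as.integer(res$next_id)
    list(balance = as.integer(res$balance),
         neurons = as.integer(res$neuron_counts),
         trials_to_solve = if (res$trials_to_solve > 0)
           as.integer(res$trials_to_solve) else NA_integer_,
         solved = res$trials_to_solve > 0,
         network = net)
  } else {
    cartpole_train_reference(spread, memory, max_size, tau, max_trials,
                             max_steps, stop_when_solved, normalization,
                             params)
  }
}

# Append a neuron preserving an externally assigned id (compiled engine
# hands back ids so pruning history is reflected).
within_id_add <- function(network, id, centers, action, weight, reward) {
  nu <- edn_neuron(id, seq_along(centers), centers, action, weight, reward)
  network$neurons[[length(network$neurons) + 1L]] <- nu
  network
}

# Pure R mirror of the compiled cart-pole trainer. Draws from R's RNG in the
# same order as the C++ loop: 4 uniforms per reset, one uniform per tied
# action choice.
cartpole_train_reference <- function(spread, memory, max_size, tau,
                                     max_trials, max_steps, stop_when_solved,
                                     normalization, params) {
  net <- edn_network(4L, 2L, spread = spread, error_threshold = 0,
                     surprise_threshold = 0, max_size = max_size)
  bounds <- cartpole_obs_bounds()
  running <- normalization == "running"
  run_min <- NULL
  run_max <- NULL
  balance <- integer(0)
  neuron_counts <- integer(0)
  for (trial in seq_len(max_trials)) {
    state <- cartpole_reset()
    buffer <- episode_buffer(memory)
    steps <- 0L
    failed <- FALSE
    while (steps < max_steps) {
      if (running) {
        if (is.null(run_min)) {
          run_min <- state
          run_max <- state
        }
        run_min <- pmin(run_min, state)
        run_max <- pmax(run_max, state)
        rng <- run_max - run_min
        obs <- ifelse(rng > 0, (state - run_min) / rng, 0.5)
      } else {
        obs <- normalize_observation(state, bounds)
      }
      acts <- neuron_activations(net, obs)
      out <- numeric(2)
      for (i in seq_along(net$neurons)) {
        k <- kernel_activation(acts[i], 1, spread)
        if (k > 0) {
          nu <- net$neurons[[i]]
          out[nu$eff_index] <- out[nu$eff_index] + nu$eff_weight * k
        }
      }
      action <- choose_action(out)
      st <- cartpole_step(state, action, params)
      net <- update_rewards(net, acts, r = 1, tau = tau)
      buffer <- buffer_push(buffer, obs, action)
      state <- st$state
      steps <- steps + 1L
      if (st$terminal) {
        failed <- TRUE
        break
      }
    }
    if (failed) {
      net <- failure_neurogenesis(net, buffer)
      if (!is.null(max_size)) net <- prune(net, max_size)
    }
    balance <- c(balance, steps)
    neuron_counts <- c(neuron_counts, n_neurons(net))
    ts <- solved_at(balance)
    if (stop_when_solved && !is.na(ts)) break
  }
  ts <- solved_at(balance)
  list(balance = balance, neurons = neuron_counts,
       trials_to_solve = ts, solved = !is.na(ts), network = net)
}
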