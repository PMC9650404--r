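# Shared helpers: independent oracles and random-case generators.

# Straight-line, term-by-term evaluation of the forward pass (triangle
# kernels -> averaged neuron activation -> efferent kernel at v = 1 ->
# weighted sum), written independently of the package's vectorized path.
oracle_forward <- function(network, inputs) {
  out <- rep(0, network$n_outputs)
  s <- network$spread
  for (nu in network$neurons) {
    ks <- numeric(length(nu$aff_index))
    for (j in seq_along(nu$aff_index)) {
      d <- abs(nu$aff_value[j] - inputs[nu$aff_index[j]])
      ks[j] <- max(0, 1 - d / s)
    }
    a <- mean(ks)
    keff <- max(0, 1 - abs(1 - a) / s)
    for (j in seq_along(nu$eff_index)) {
      out[nu$eff_index[j]] <- out[nu$eff_index[j]] +
        nu$eff_weight[j] * keff
    }
  }
  out
}

# Random small network: up to max_neurons neurons over n_inputs inputs and
# n_outputs outputs, with random afferent subsets and signed weights.
random_network <- function(n_inputs = 4, n_outputs = 3, max_neurons = 5,
                           spread = NULL) {
  spread <- if (is.null(spread)) runif(1, 0.2, 1.2) else spread
  net <- edn_network(n_inputs, n_outputs, spread = spread)
  for (i in seq_len(sample.int(max_neurons, 1))) {
    n_aff <- sample.int(n_inputs, 1)
    aff <- sort(sample.int(n_inputs, n_aff))
    n_eff <- sample.int(n_outputs, 1)
    eff <- sort(sample.int(n_outputs, n_eff))
    w <- runif(n_eff, -1, 1)
    w[w == 0] <- 0.5
    net <- edn:::add_neuron(net, aff, runif(n_aff), eff, w)
  }
  net
}

# Independent cart-pole acceleration oracle: solves the coupled Lagrangian
# equations of motion as a 2x2 linear system instead of using the reduced
# closed form.
#   (M + m) xacc + m l cos(th) thacc = F + m l thdot^2 sin(th)
#   m l cos(th) xacc + (4/3) m l^2 thacc = m g l sin(th)
oracle_cartpole_acc <- function(state, action, p = cartpole_params()) {
  th <- state[3]
  thdot <- state[4]
  force <- if (action == 2L) p$force_mag else -p$force_mag
  m <- p$pole_mass
  M <- p$cart_mass
  l <- p$pole_half_length
  A <- rbind(c(M + m, m * l * cos(th)),
             c(m * l * cos(th), 4 / 3 * m * l^2))
  b <- c(force + m * l * thdot^2 * sin(th),
         m * p$gravity * l * sin(th))
  acc <- solve(A, b)
  list(x_acc = acc[1], theta_acc = acc[2])
}

# One-epoch classification fit on normalized data; returns the result of
# train_classification plus held-out accuracy (abstentions count as errors).
fit_and_score <- function(train_x, train_y, test_x, test_y, ...) {
  net <- edn_network(ncol(train_x), max(train_y), ...)
  fit <- train_classification(net, train_x, train_y)
  preds <- classify(fit$network, test_x)
  fit$accuracy <- mean(!is.na(preds) & preds == test_y)
  fit
}
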