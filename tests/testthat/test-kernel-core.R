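test_that("triangle kernel matches its closed form and is symmetric", {
  expect_identical(kernel_activation(0.5, 0.5, 0.4), 1.0)
  expect_identical(kernel_activation(0.9, 0.5, 0.4), 0.0)
  expect_equal(kernel_activation(0.3, 0.5, 0.4), 0.5)
  # vectorized over x
  expect_equal(kernel_activation(c(0.5, 0.9, 0.3), 0.5, 0.4),
               c(1, 0, 0.5))
  set.seed(101)
  for (i in 1:200) {
    x <- runif(1, -0.5, 1.5)
    v <- runif(1)
    s <- runif(1, 0.05, 2)
    expect_identical(kernel_activation(x, v, s), kernel_activation(v, x, s))
    k <- kernel_activation(x, v, s)
    expect_gte(k, 0)
    expect_lte(k, 1)
    expect_identical(k == 1, x == v)
  }
  expect_error(kernel_activation(0.5, 0.5, 0), "spread")
  expect_error(kernel_activation(0.5, 0.5, -1), "spread")
})

test_that("neuron activation averages over the neuron's own afferents", {
  nu <- edn_neuron(1, c(1, 2), c(0.2, 0.8), 1, 0.5)
  expect_identical(neuron_activation(c(0.2, 0.8), nu, 0.4), 1.0)
  expect_equal(neuron_activation(c(0.2, 0.4), nu, 0.4), 0.5)
  # subsampled afferent: only input 1 is watched, input 2 is ignored
  nu1 <- edn_neuron(1, 1, 0.2, 1, 0.5)
  expect_identical(neuron_activation(c(0.9, 0.123), nu1, 0.4), 0.0)
  expect_identical(neuron_activation(c(0.2, 0.999), nu1, 0.4), 1.0)
  expect_error(neuron_activation(c(0.2), nu, 0.4), "out of range")
})

test_that("output activation thresholds weak neurons and sums weights", {
  # a neuron exactly matching its stored pattern contributes its weight
  net <- edn_network(2, 2, spread = 0.4)
  net <- edn:::add_neuron(net, c(1, 2), c(0.3, 0.7), 1, 0.7)
  expect_equal(output_activations(net, c(0.3, 0.7)), c(0.7, 0))
  # boundary closed at zero: a_n == 1 - s contributes exactly 0
  # (dyadic values keep the arithmetic exact: s = 0.5, a_n = 0.5)
  net2 <- edn_network(1, 1, spread = 0.5)
  net2 <- edn:::add_neuron(net2, 1, 0.5, 1, 3)
  expect_identical(output_activations(net2, 0.75), 0)
  # partial activation scales a negative weight: a_n = 0.75, s = 0.5
  net3 <- edn_network(1, 1, spread = 0.5)
  net3 <- edn:::add_neuron(net3, 1, 0.5, 1, -0.4)
  expect_equal(output_activations(net3, 0.625), -0.2)
  # empty network is all zeros
  expect_identical(output_activations(edn_network(2, 3), c(0.1, 0.2)),
                   c(0, 0, 0))
  expect_error(output_activations(net, c(0.1, 0.2, 0.3)), "length")
})

test_that("forward pass matches the term-by-term oracle to 1e-12", {
  set.seed(202)
  for (case in 1:300) {
    net <- random_network()
    x <- runif(net$n_inputs)
    expect_equal(output_activations(net, x), oracle_forward(net, x),
                 tolerance = 1e-12)
  }
})

test_that("neurons at or below the efferent cutoff are removable without trace", {
  set.seed(303)
  for (case in 1:50) {
    net <- random_network(n_inputs = 3, max_neurons = 6)
    x <- runif(3)
    acts <- neuron_activations(net, x)
    keep <- acts > 1 - net$spread
    pruned <- net
    pruned$neurons <- net$neurons[keep]
    expect_identical(output_activations(net, x),
                     output_activations(pruned, x))
  }
})

test_that("forward pass does not mutate the network", {
  set.seed(404)
  net <- random_network()
  before <- serialize_edn(net)
  invisible(output_activations(net, runif(net$n_inputs)))
  invisible(neuron_activations(net, runif(net$n_inputs)))
  expect_identical(serialize_edn(net), before)
})

test_that("softmax normalizes, is shift invariant, and handles zeros", {
  expect_equal(softmax_outputs(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax_outputs(c(7.3, 7.3)), c(0.5, 0.5))
  expect_equal(softmax_outputs(c(1, 0)),
               c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)))
  set.seed(7)
  v <- rnorm(5)
  expect_equal(softmax_outputs(v), softmax_outputs(v + 100))
  expect_equal(sum(softmax_outputs(v * 50)), 1)
  expect_error(softmax_outputs(numeric(0)), "empty")
})

test_that("prediction abstains on all-zero outputs and breaks ties low", {
  expect_identical(predict_class(c(0, 0, 0)), NA_integer_)
  expect_identical(predict_class(c(0.1, 0.9, 0.2)), 2L)
  expect_identical(predict_class(c(0.5, 0.5, 0.0)), 1L)
  expect_identical(predict_class(c(-0.2, -0.1)), 2L)
})

test_that("model serialization round-trips losslessly at full precision", {
  set.seed(505)
  net <- random_network(n_inputs = 6, n_outputs = 4, max_neurons = 5)
  net$neurons[[1]]$reward <- pi / 7 # irrational-ish stored double
  json <- serialize_edn(net)
  back <- deserialize_edn(json)
  expect_identical(serialize_edn(back), json)
  # field-level identity, not just re-serialized identity
  expect_identical(back$spread, net$spread)
  for (i in seq_along(net$neurons)) {
    expect_identical(back$neurons[[i]]$aff_value, net$neurons[[i]]$aff_value)
    expect_identical(back$neurons[[i]]$eff_weight,
                     net$neurons[[i]]$eff_weight)
    expect_identical(back$neurons[[i]]$reward, net$neurons[[i]]$reward)
  }
  # file round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_edn(net, path)
  expect_identical(serialize_edn(read_edn(path)), json)
  expect_error(deserialize_edn('{"format": "other"}'), "format")
})
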