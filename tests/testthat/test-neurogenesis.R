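test_that("classification error is one-hot minus softmax and sums to zero", {
  # empty network: uniform softmax over 3 classes, true class 3
  e <- classification_error(c(0, 0, 0), 3)
  expect_equal(e, c(-1 / 3, -1 / 3, 2 / 3))
  # overconfident wrong output
  out <- c(log(9), 0) # softmax (0.9, 0.1)
  e2 <- classification_error(out, 2)
  expect_equal(e2, c(-0.9, 0.9))
  # near-one-hot correct softmax leaves errors below any practical threshold
  e3 <- classification_error(c(50, 0, 0), 1)
  expect_lt(max(abs(e3)), 1e-10)
  set.seed(11)
  for (i in 1:100) {
    v <- rnorm(sample(2:6, 1), sd = 2)
    lab <- sample.int(length(v), 1)
    err <- classification_error(v, lab)
    expect_lt(abs(sum(err)), 1e-12)
    expect_true(all(err > -1 & err < 1))
  }
  expect_error(classification_error(c(0, 0), 3), "label")
})

test_that("neurogenesis triggers on strict max-|error| threshold crossing", {
  expect_false(neurogenesis_triggered(c(0.05, -0.05, 0), 0.1))
  expect_true(neurogenesis_triggered(c(-1 / 3, -1 / 3, 2 / 3), 0.1))
  expect_false(neurogenesis_triggered(c(0.1, -0.1), 0.1)) # strict
  expect_true(neurogenesis_triggered(c(1e-300, 0), 0))
  expect_false(neurogenesis_triggered(c(0, 0), 0))
})

test_that("surprise selection defaults to everything and thresholds discrepancy", {
  ex <- class_expectation(3, 2)
  # no recorded events: all inputs selected by default
  expect_identical(
    select_inputs_surprise(c(0.1, 0.5, 0.9), ex, c(0.5, 0.5), 0.05),
    1:3)
  # one stored event for class 1 at inputs 1 and 2
  ex <- update_expectation(ex, 1, c(1, 2), c(0.5, 0.5, 0.7))
  # softmax fully on class 1: expectation is (0.5, 0.5, undefined)
  sel <- select_inputs_surprise(c(0.9, 0.52, 0.1), ex, c(1, 0), 0.05)
  expect_identical(sel, c(1L, 3L)) # |0.5-0.9| = 0.4 > s_th; input 3 default
  sel2 <- select_inputs_surprise(c(0.52, 0.52, 0.1), ex, c(1, 0), 0.05)
  expect_identical(sel2, 3L) # surprise 0.02 below threshold
  # surprise can select nothing once every input has an expectation
  ex <- update_expectation(ex, 1, 3L, c(0.5, 0.5, 0.1))
  expect_length(
    select_inputs_surprise(c(0.5, 0.5, 0.1), ex, c(1, 0), 0.05), 0)
})

test_that("expectation weighs class means by the class softmax", {
  ex <- class_expectation(1, 2)
  ex <- update_expectation(ex, 1, 1L, 0.2)
  ex <- update_expectation(ex, 2, 1L, 0.8)
  # combined expectation 0.6*0.2 + 0.4*0.8 = 0.44; input 0.5 surprise 0.06
  expect_identical(select_inputs_surprise(0.5, ex, c(0.6, 0.4), 0.05), 1L)
  expect_length(select_inputs_surprise(0.5, ex, c(0.6, 0.4), 0.07), 0)
})

test_that("random input selection is seeded, in-range, and near-uniform", {
  expect_identical(select_inputs_random(4, 4), 1:4)
  set.seed(21)
  a <- select_inputs_random(4, 1)
  set.seed(21)
  expect_identical(select_inputs_random(4, 1), a)
  expect_error(select_inputs_random(4, 0), "n_select")
  expect_error(select_inputs_random(4, 5), "n_select")
  set.seed(22)
  draws <- replicate(10000, select_inputs_random(4, 1))
  counts <- tabulate(draws, 4)
  expect_true(all(counts >= 2350 & counts <= 2650)) # binomial 99% interval
  # subsets are without replacement
  set.seed(23)
  for (i in 1:50) {
    sel <- select_inputs_random(8, sample.int(8, 1))
    expect_identical(anyDuplicated(sel), 0L)
  }
})

test_that("neuron creation copies selected inputs and gates outputs by error", {
  net <- edn_network(4, 3, error_threshold = 0.1)
  x <- c(0.1, 0.2, 0.3, 0.9)
  err <- c(-1 / 3, -1 / 3, 2 / 3)
  net2 <- create_neuron(net, x, c(1, 4), err, 0.1)
  nu <- net2$neurons[[1]]
  expect_identical(nu$aff_index, c(1L, 4L))
  expect_identical(nu$aff_value, c(0.1, 0.9))
  expect_identical(nu$eff_index, c(1L, 2L, 3L))
  expect_identical(nu$eff_weight, err)
  # per-output gating: only |E| > E_th outputs connect
  net3 <- create_neuron(edn_network(2, 2), c(0.5, 0.5), 1:2,
                        c(0.15, -0.05), 0.1)
  expect_identical(net3$neurons[[1]]$eff_index, 1L)
  expect_identical(net3$neurons[[1]]$eff_weight, 0.15)
  # empty selection is a soft no-op
  net4 <- create_neuron(net, x, integer(0), err, 0.1)
  expect_identical(n_neurons(net4), 0L)
  expect_identical(serialize_edn(net4), serialize_edn(net))
})

test_that("expectation accumulates per class and per input in isolation", {
  ex <- class_expectation(2, 2)
  ex <- update_expectation(ex, 1, 1L, c(0.2, 0.9))
  ex <- update_expectation(ex, 1, 1L, c(0.4, 0.9))
  img <- class_expectation_image(ex, 1)
  expect_equal(img$values[1], 0.3)
  expect_identical(img$coverage, c(2L, 0L))
  expect_true(is.na(img$values[2])) # never selected: undefined, not 0
  # class 2 untouched by class-1 events
  expect_true(all(ex$count[2, ] == 0L))
})

test_that("a single stored sample is recalled one-shot", {
  net <- edn_network(2, 3)
  ex <- class_expectation(2, 3)
  st <- train_classification_step(net, ex, c(0.2, 0.8), 2)
  expect_identical(st$prediction, NA_integer_) # evaluated before storing
  expect_identical(n_neurons(st$network), 1L)
  expect_identical(
    predict_class(output_activations(st$network, c(0.2, 0.8))), 2L)
  set.seed(31)
  for (i in 1:25) {
    n_in <- sample(2:8, 1)
    n_cls <- sample(2:5, 1)
    x <- runif(n_in)
    lab <- sample.int(n_cls, 1)
    fresh <- edn_network(n_in, n_cls)
    st <- train_classification_step(fresh, class_expectation(n_in, n_cls),
                                    x, lab)
    expect_identical(
      predict_class(output_activations(st$network, x)), lab)
  }
})

test_that("a well-classified sample leaves the network unchanged", {
  net <- edn_network(2, 2, error_threshold = 0.3)
  ex <- class_expectation(2, 2)
  st <- train_classification_step(net, ex, c(0.2, 0.8), 1)
  net <- st$network
  # pump the stored output high enough that softmax error drops below E_th
  net <- edn:::add_neuron(net, 1:2, c(0.2, 0.8), 1, 5)
  before <- serialize_edn(net)
  st2 <- train_classification_step(net, st$expectations, c(0.2, 0.8), 1)
  expect_identical(serialize_edn(st2$network), before)
  expect_identical(st2$prediction, 1L)
})

test_that("zero error threshold stores every distinct sample", {
  set.seed(41)
  x <- matrix(runif(40 * 3), ncol = 3)
  y <- sample.int(3, 40, replace = TRUE)
  net <- edn_network(3, 3, error_threshold = 0)
  fit <- train_classification(net, x, y)
  expect_identical(n_neurons(fit$network), 40L)
  expect_true(all(diff(fit$log$neurons) >= 0)) # monotone growth
})

test_that("training never alters previously stored neurons", {
  set.seed(51)
  x <- matrix(runif(60 * 2), ncol = 2)
  y <- sample.int(3, 60, replace = TRUE)
  net <- edn_network(2, 3)
  fit1 <- train_classification(net, x[1:30, ], y[1:30])
  frozen <- lapply(fit1$network$neurons, identity)
  fit2 <- train_classification(fit1$network, x[31:60, ], y[31:60],
                               expectations = fit1$expectations)
  for (i in seq_along(frozen)) {
    expect_identical(fit2$network$neurons[[i]], frozen[[i]])
  }
})
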