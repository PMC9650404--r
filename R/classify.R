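#' Per-class expectation accumulator
#'
#' Tracks, for each class, the running sum and count of input values stored
#' on afferent synapses whenever neurogenesis fires for that class. The
#' per-input mean is the class's "expected input" and drives surprise-based
#' input selection; inputs that were never stored have an undefined mean.
#'
#' @param n_inputs Number of inputs.
#' @param n_classes Number of classes.
#' @return An object of class `edn_expectation` holding an
#'   `n_classes x n_inputs` sum matrix and count matrix.
#' @export
class_expectation <- function(n_inputs, n_classes) {
  structure(
    list(
      sum = matrix(0, nrow = n_classes, ncol = n_inputs),
      count = matrix(0L, nrow = n_classes, ncol = n_inputs),
      n_inputs = as.integer(n_inputs),
      n_classes = as.integer(n_classes)
    ),
    class = "edn_expectation"
  )
}

#' Classification error vector
#'
#' The error is the one-hot encoding of the true label minus the softmax of
#' the current outputs: positive where an output was too low, negative where
#' it was too high. The components always sum to zero.
#'
#' @param outputs Signed output activations.
#' @param label True class index in `1..n_outputs`.
#' @return Signed error vector, one entry per output.
#' @export
classification_error <- function(outputs, label) {
  n <- length(outputs)
  if (!is.numeric(label) || length(label) != 1L || is.na(label) ||
      label < 1 || label > n) {
    stop(sprintf("label must be a class index in 1..%d", n), call. = FALSE)
  }
  one_hot <- numeric(n)
  one_hot[label] <- 1
  one_hot - softmax_outputs(outputs)
}

#' Does an error vector trigger neurogenesis?
#'
#' Neurogenesis fires when the largest error magnitude strictly exceeds the
#' error threshold. With `e_th = 0` any non-zero error triggers, so every
#' training example creates a neuron.
#'
#' @param errors Signed error vector.
#' @param e_th Error threshold `E_th >= 0`.
#' @return Logical scalar.
#' @export
neurogenesis_triggered <- function(errors, e_th) {
  stopifnot(e_th >= 0)
  max(abs(errors)) > e_th
}

#' Surprise-driven input selection
#'
#' Builds a combined expected input by weighting each class's expectation by
#' the softmax activation of its output and summing across classes (only
#' classes with a defined mean at an input contribute there). An input is
#' selected when no class has any stored record of it yet (selected by
#' default), or when the absolute discrepancy between the expected and the
#' actual value exceeds the surprise threshold.
#'
#' @param inputs Normalized input vector.
#' @param expectations An [class_expectation()] accumulator.
#' @param class_softmax Softmax of the current forward pass (one probability
#'   per class).
#' @param s_th Surprise threshold `s_th >= 0`.
#' @return Integer vector of selected input indices (possibly empty).
#' @export
select_inputs_surprise <- function(inputs, expectations, class_softmax, s_th) {
  defined <- expectations$count > 0L
  means <- expectations$sum / ifelse(defined, expectations$count, 1)
  means[!defined] <- 0
  e <- as.numeric(crossprod(means, class_softmax)) # per-input expected value
  any_defined <- colSums(defined) > 0L
  surprise <- abs(e - inputs)
  which(!any_defined | surprise > s_th)
}

#' Random input selection without replacement
#'
#' Alternative to surprise selection: draw a uniformly random subset of the
#' inputs to form the afferent synapses of the new neuron.
#'
#' @param n_inputs Number of inputs.
#' @param n_select Number of inputs to select, `1 <= n_select <= n_inputs`.
#' @return Integer vector of `n_select` distinct indices (sorted).
#' @export
select_inputs_random <- function(n_inputs, n_select) {
  if (n_select < 1 || n_select > n_inputs) {
    stop("`n_select` must lie in 1..n_inputs", call. = FALSE)
  }
  sort(sample.int(n_inputs, n_select))
}

#' Create a memory neuron from the current sample and error
#'
#' Afferent synapses copy the current values of the selected inputs; efferent
#' connections are formed only to outputs whose error magnitude exceeds the
#' error threshold, with the signed error itself as the weight. An empty
#' selection is a soft no-op and creates nothing (the network stagnates for
#' that sample).
#'
#' @param network An [edn_network()].
#' @param inputs Normalized input vector.
#' @param selected Integer vector of input indices to store.
#' @param errors Signed error vector (one entry per output).
#' @param e_th Error threshold gating which outputs get connections.
#' @return The network, with one appended neuron if `selected` is non-empty.
#' @export
create_neuron <- function(network, inputs, selected, errors, e_th) {
  if (length(selected) == 0L) {
    return(network)
  }
  eff <- which(abs(errors) > e_th)
  add_neuron(network,
             aff_index = selected, aff_value = inputs[selected],
             eff_index = eff, eff_weight = errors[eff])
}

#' Record stored inputs in the class expectation
#'
#' Called once per neurogenesis event with the true label of the triggering
#' sample: the stored values are added to that class's running sums and the
#' per-input counts incremented. Other classes and unselected inputs are
#' untouched.
#'
#' @param expectations An [class_expectation()].
#' @param label True class index.
#' @param selected Input indices stored on the new neuron.
#' @param inputs Normalized input vector.
#' @return The updated accumulator.
#' @export
update_expectation <- function(expectations, label, selected, inputs) {
  if (length(selected) > 0L) {
    expectations$sum[label, selected] <-
      expectations$sum[label, selected] + inputs[selected]
    expectations$count[label, selected] <-
      expectations$count[label, selected] + 1L
  }
  expectations
}

#' One online classification training step
#'
#' Runs the forward pass, predicts (before any update, so learning curves
#' reflect one-shot behavior honestly), computes the softmax error, and, if
#' the error clears the threshold, selects inputs, creates a neuron and
#' updates the class expectation. Existing neurons are never modified.
#'
#' @param network An [edn_network()].
#' @param expectations An [class_expectation()] (used and updated under
#'   surprise selection; still updated under other modes so expectations
#'   remain available for introspection).
#' @param inputs Normalized input vector.
#' @param label True class index.
#' @param selection Input-selection mode: `"all"`, `"surprise"`, or
#'   `"random"`.
#' @param n_select Subset size for random selection.
#' @return List with elements `network`, `expectations`, `prediction`
#'   (class index or `NA` for abstain, evaluated before the update), and
#'   `errors`.
#' @export
train_classification_step <- function(network, expectations, inputs, label,
                                      selection = c("all", "surprise",
                                                    "random"),
                                      n_select = NULL) {
  selection <- match.arg(selection)
  out <- output_activations(network, inputs)
  prediction <- predict_class(out)
  sm <- softmax_outputs(out)
  errors <- classification_error(out, label)
  if (neurogenesis_triggered(errors, network$error_threshold)) {
    selected <- switch(selection,
      all = seq_len(network$n_inputs),
      surprise = select_inputs_surprise(inputs, expectations, sm,
                                        network$surprise_threshold),
      random = select_inputs_random(network$n_inputs,
                                    n_select %||% network$n_inputs)
    )
    if (length(selected) > 0L) {
      network <- create_neuron(network, inputs, selected, errors,
                               network$error_threshold)
      expectations <- update_expectation(expectations, label, selected,
                                         inputs)
    }
  }
  list(network = network, expectations = expectations,
       prediction = prediction, errors = errors)
}

#' Online classification training over a sample stream
#'
#' Presents the rows of `x` once, in order, applying
#' [train_classification_step()] to each. Returns the trained network, the
#' class expectations, and a per-step log (step, pre-update prediction,
#' max error magnitude, neuron and synapse counts).
#'
#' @param network An [edn_network()].
#' @param x Numeric matrix of normalized features (rows are samples).
#' @param y Integer class labels in `1..n_outputs`.
#' @param selection,n_select See [train_classification_step()].
#' @param expectations Optional accumulator to continue from; a fresh one is
#'   created by default.
#' @return List with `network`, `expectations`, and `log` (a data frame).
#' @export
train_classification <- function(network, x, y,
                                 selection = c("all", "surprise", "random"),
                                 n_select = NULL, expectations = NULL) {
  selection <- match.arg(selection)
  stopifnot(nrow(x) == length(y))
  if (is.null(expectations)) {
    expectations <- class_expectation(network$n_inputs, network$n_outputs)
  }
  n <- nrow(x)
  log <- data.frame(step = seq_len(n), prediction = NA_integer_,
                    max_error = NA_real_, neurons = NA_integer_,
                    synapses = NA_integer_)
  for (i in seq_len(n)) {
    st <- train_classification_step(network, expectations, x[i, ], y[i],
                                    selection, n_select)
    network <- st$network
    expectations <- st$expectations
    log$prediction[i] <- st$prediction
    log$max_error[i] <- max(abs(st$errors))
    log$neurons[i] <- n_neurons(network)
    log$synapses[i] <- n_synapses(network)
  }
  list(network = network, expectations = expectations, log = log)
}

#' Classify a matrix of samples with a trained network
#'
#' @param network An [edn_network()].
#' @param x Numeric matrix of normalized features (rows are samples).
#' @return Integer vector of predicted class indices (`NA` = abstain).
#' @export
classify <- function(network, x) {
  apply(x, 1L, function(row) predict_class(output_activations(network, row)))
}
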