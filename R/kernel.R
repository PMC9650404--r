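#' Triangle kernel synapse activation
#'
#' The synaptic non-linearity at the heart of the network: a piecewise-linear
#' bump centered on the stored value `v`, falling to zero at a distance of one
#' spread. Activation is `max(0, 1 - |v - x| / s)`, so it is 1 exactly when the
#' input reproduces the stored value, and 0 once the input is at least `s`
#' away.
#'
#' @param x Input value(s), normalized activation in `[0, 1]` for afferent
#'   synapses (the function itself accepts any real value).
#' @param v Stored kernel center(s).
#' @param s Kernel spread (half-width), a single positive number shared across
#'   the whole network.
#' @return Activation(s) in `[0, 1]`, vectorized over `x` and `v`.
#' @examples
#' kernel_activation(0.3, 0.5, 0.4) # 0.5: half a spread away
#' @export
kernel_activation <- function(x, v, s) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s <= 0) {
    stop("`s` (kernel spread) must be a single positive number", call. = FALSE)
  }
  pmax(0, 1 - abs(v - x) / s)
}

#' Neuron activation: mean kernel similarity over stored afferents
#'
#' A neuron's activation is the average triangle-kernel activation of its
#' afferent synapses, each comparing the current value of one input against
#' the value stored at creation time. The average runs over the neuron's own
#' afferent set (which may be a subset of the inputs), making activation a
#' 0-1 similarity between the current input and the stored pattern.
#'
#' @param inputs Full normalized input vector presented to the network.
#' @param neuron An [edn_neuron()].
#' @param s Kernel spread.
#' @return A single activation in `[0, 1]`; 1 iff every watched input matches
#'   its stored center exactly.
#' @export
neuron_activation <- function(inputs, neuron, s) {
  idx <- neuron$aff_index
  if (any(idx > length(inputs))) {
    stop("afferent index out of range for the presented input vector",
         call. = FALSE)
  }
  mean(kernel_activation(inputs[idx], neuron$aff_value, s))
}

#' Output activations of the network
#'
#' Each output is a weighted sum over hidden neurons. A neuron's contribution
#' passes through a second triangle kernel with a fixed center of 1 (the
#' efferent synapse), which thresholds out neurons whose activation is at most
#' `1 - s`: only neurons closely matching their stored pattern reach the
#' outputs at all. An empty network returns all zeros.
#'
#' @param network An [edn_network()].
#' @param inputs Normalized input vector of length `n_inputs`.
#' @return Numeric vector of `n_outputs` signed output activations.
#' @export
output_activations <- function(network, inputs) {
  if (length(inputs) != network$n_inputs) {
    stop(sprintf("input vector has length %d but the network expects %d",
                 length(inputs), network$n_inputs), call. = FALSE)
  }
  out <- numeric(network$n_outputs)
  s <- network$spread
  for (nu in network$neurons) {
    a <- neuron_activation(inputs, nu, s)
    k <- kernel_activation(a, 1, s)
    if (k > 0) {
      out[nu$eff_index] <- out[nu$eff_index] + nu$eff_weight * k
    }
  }
  out
}

#' Per-neuron activations for the current input
#'
#' Forward-pass helper returning the activation of every neuron (used by the
#' reinforcement-learning reward update, which credits each neuron in
#' proportion to its activity).
#'
#' @inheritParams output_activations
#' @return Numeric vector, one activation per neuron in network order.
#' @export
neuron_activations <- function(network, inputs) {
  vapply(network$neurons, neuron_activation, numeric(1),
         inputs = inputs, s = network$spread)
}

#' Softmax of the output vector
#'
#' Standard exponential normalization, computed with the max-shift trick for
#' numerical stability. The all-zero vector (an empty network) maps to the
#' uniform distribution.
#'
#' @param outputs Signed output activations.
#' @return Probability vector of the same length, summing to 1.
#' @export
softmax_outputs <- function(outputs) {
  if (length(outputs) == 0L) {
    stop("cannot take the softmax of an empty output vector", call. = FALSE)
  }
  e <- exp(outputs - max(outputs))
  e / sum(e)
}

#' Predicted class, or abstention
#'
#' The predicted class is the argmax of the raw output activations. When every
#' output is exactly zero the network carries no information about the input
#' (nothing in its stored memory is close enough to respond) and it abstains,
#' returned as `NA_integer_`. Ties are broken toward the lowest index.
#'
#' @param outputs Signed output activations.
#' @return Class index in `1..n_outputs`, or `NA_integer_` when the network
#'   abstains.
#' @export
predict_class <- function(outputs) {
  if (all(outputs == 0)) {
    return(NA_integer_)
  }
  which.max(outputs)
}
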