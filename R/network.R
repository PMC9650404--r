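#' Construct an empty error-driven-neurogenesis network
#'
#' The network starts empty and grows one neuron at a time as training errors
#' exceed the error threshold. All neurons share a single kernel spread.
#'
#' @param n_inputs Number of input features (after normalization to `[0, 1]`).
#' @param n_outputs Number of outputs: classes for classification, 2 for
#'   regression (real/inverse pair), actions for reinforcement learning.
#' @param spread Kernel half-width `s`, shared network-wide. Controls the
#'   generalization radius: small values overfit (neurons respond only to
#'   near-exact repeats), large values over-generalize.
#' @param error_threshold Minimum per-output error magnitude `E_th` for
#'   neurogenesis to trigger and for an output connection to be formed.
#' @param surprise_threshold Minimum discrepancy `s_th` between an input and
#'   its class-expectation prediction for the input to be stored on a new
#'   neuron (surprise-driven input selection).
#' @param max_size Optional cap on neuron count; `NULL` means unbounded.
#'   Used with reward-based pruning in reinforcement learning.
#' @return An object of class `edn_network`.
#' @export
edn_network <- function(n_inputs, n_outputs, spread = 0.4,
                        error_threshold = 0.1, surprise_threshold = 0.05,
                        max_size = NULL) {
  stopifnot(n_inputs >= 1, n_outputs >= 1)
  if (spread <= 0) stop("`spread` must be positive", call. = FALSE)
  if (error_threshold < 0) stop("`error_threshold` must be >= 0", call. = FALSE)
  if (surprise_threshold < 0) {
    stop("`surprise_threshold` must be >= 0", call. = FALSE)
  }
  if (!is.null(max_size) && max_size < 1) {
    stop("`max_size` must be >= 1 when set", call. = FALSE)
  }
  structure(
    list(
      n_inputs = as.integer(n_inputs),
      n_outputs = as.integer(n_outputs),
      spread = as.numeric(spread),
      error_threshold = as.numeric(error_threshold),
      surprise_threshold = as.numeric(surprise_threshold),
      max_size = if (is.null(max_size)) NULL else as.integer(max_size),
      neurons = list(),
      next_id = 1L
    ),
    class = "edn_network"
  )
}

#' Construct a single memory neuron
#'
#' A neuron bundles afferent synapses (input index -> stored center `v`),
#' efferent connections (output index -> signed weight `w`), and an
#' accumulated reward `R`. Afferents and efferents are fixed at creation;
#' the reward is the only field that is ever updated afterwards.
#'
#' @param id Unique integer id, monotone in creation order.
#' @param aff_index Integer vector of watched input indices (1-based).
#' @param aff_value Stored centers, same length as `aff_index`, in `[0, 1]`.
#' @param eff_index Integer vector of connected output indices (1-based).
#' @param eff_weight Signed connection weights, same length as `eff_index`;
#'   zero-weight connections are never stored.
#' @param reward Accumulated reward, defaults to 0.
#' @return An object of class `edn_neuron`.
#' @export
edn_neuron <- function(id, aff_index, aff_value, eff_index, eff_weight,
                       reward = 0) {
  if (length(aff_index) == 0L || length(eff_index) == 0L) {
    stop("a neuron needs at least one afferent and one efferent synapse",
         call. = FALSE)
  }
  stopifnot(length(aff_index) == length(aff_value),
            length(eff_index) == length(eff_weight))
  if (any(eff_weight == 0)) {
    stop("zero-weight output connections are never created", call. = FALSE)
  }
  structure(
    list(
      id = as.integer(id),
      aff_index = as.integer(aff_index),
      aff_value = as.numeric(aff_value),
      eff_index = as.integer(eff_index),
      eff_weight = as.numeric(eff_weight),
      reward = as.numeric(reward)
    ),
    class = "edn_neuron"
  )
}

# Append a neuron, assigning the next id. Internal: training loops use this.
add_neuron <- function(network, aff_index, aff_value, eff_index, eff_weight,
                       reward = 0) {
  nu <- edn_neuron(network$next_id, aff_index, aff_value,
                   eff_index, eff_weight, reward)
  network$neurons[[length(network$neurons) + 1L]] <- nu
  network$next_id <- network$next_id + 1L
  network
}

#' Number of neurons in the network
#' @param network An [edn_network()].
#' @return Integer neuron count.
#' @export
n_neurons <- function(network) length(network$neurons)

#' Total number of afferent synapses stored in the network
#' @param network An [edn_network()].
#' @return Integer synapse count (sum over neurons of afferent-set sizes).
#' @export
n_synapses <- function(network) {
  if (n_neurons(network) == 0L) return(0L)
  sum(vapply(network$neurons, function(nu) length(nu$aff_index), integer(1)))
}

#' @export
print.edn_network <- function(x, ...) {
  cat(sprintf(
    "<edn_network> %d inputs -> %d outputs | s=%g E_th=%g s_th=%g%s\n",
    x$n_inputs, x$n_outputs, x$spread, x$error_threshold,
    x$surprise_threshold,
    if (is.null(x$max_size)) "" else sprintf(" cap=%d", x$max_size)
  ))
  cat(sprintf("  %d neurons, %d afferent synapses\n",
              n_neurons(x), n_synapses(x)))
  invisible(x)
}

EDN_SERIAL_VERSION <- "edn-model-1"

#' Serialize a network to a versioned JSON string
#'
#' The document lists the hyperparameters and, per neuron, its id, afferent
#' `(index, v)` pairs, efferent `(index, w)` pairs and accumulated reward.
#' Doubles are written with 17 significant digits so the round-trip through
#' text is lossless at full double precision.
#'
#' @param network An [edn_network()].
#' @return A single JSON string.
#' @seealso [write_edn()], [read_edn()]
#' @export
serialize_edn <- function(network) {
  doc <- list(
    format = EDN_SERIAL_VERSION,
    n_inputs = network$n_inputs,
    n_outputs = network$n_outputs,
    spread = network$spread,
    error_threshold = network$error_threshold,
    surprise_threshold = network$surprise_threshold,
    max_size = network$max_size,
    next_id = network$next_id,
    neurons = lapply(network$neurons, function(nu) {
      list(id = nu$id,
           aff_index = nu$aff_index, aff_value = nu$aff_value,
           eff_index = nu$eff_index, eff_weight = nu$eff_weight,
           reward = nu$reward)
    })
  )
  as.character(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                                null = "null"))
}

#' Restore a network from its serialized JSON form
#' @param json A JSON string produced by [serialize_edn()].
#' @return An [edn_network()].
#' @export
deserialize_edn <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(doc$format, EDN_SERIAL_VERSION)) {
    stop(sprintf("unsupported model format: %s", doc$format %||% "<missing>"),
         call. = FALSE)
  }
  net <- edn_network(doc$n_inputs, doc$n_outputs, doc$spread,
                     doc$error_threshold, doc$surprise_threshold,
                     doc$max_size)
  net$neurons <- lapply(doc$neurons, function(nu) {
    edn_neuron(nu$id,
               unlist(nu$aff_index), unlist(nu$aff_value),
               unlist(nu$eff_index), unlist(nu$eff_weight),
               nu$reward)
  })
  net$next_id <- as.integer(doc$next_id)
  net
}

#' Write / read a network model file
#'
#' @param network An [edn_network()].
#' @param path File path for the JSON model document.
#' @return `write_edn` returns `path` invisibly; `read_edn` returns the
#'   restored network.
#' @export
write_edn <- function(network, path) {
  writeLines(serialize_edn(network), path)
  invisible(path)
}

#' @rdname write_edn
#' @export
read_edn <- function(path) {
  deserialize_edn(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
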