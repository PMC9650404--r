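#' Regression scale
#'
#' Bounds of the task-unit target range. Network activity encodes a position
#' on `[0, 1]` which is affinely mapped onto this scale.
#'
#' @param min,max Lowest and highest representable target values
#'   (`max > min`).
#' @return An object of class `edn_scale`.
#' @export
regression_scale <- function(min, max) {
  if (!(max > min)) stop("`max` must exceed `min`", call. = FALSE)
  structure(list(min = as.numeric(min), max = as.numeric(max)),
            class = "edn_scale")
}

#' Fit a regression scale from observed targets
#'
#' @param targets Training-set target values.
#' @param margin Optional symmetric margin as a fraction of the observed
#'   range (default 0), so that slightly out-of-range test targets remain
#'   representable.
#' @return An [regression_scale()].
#' @export
fit_scale <- function(targets, margin = 0) {
  lo <- min(targets)
  hi <- max(targets)
  pad <- margin * (hi - lo)
  regression_scale(lo - pad, hi + pad)
}

scale_position <- function(x, scale) (x - scale$min) / (scale$max - scale$min)

#' Decode paired real/inverse outputs to a target value
#'
#' A continuous value is represented by two non-negative magnitudes: the
#' "real" output `r` and the "inverse" output `i`. The position on the scale
#' is their ratio `r / (r + i)`, which is independent of overall activity
#' level -- activity becomes a confidence, not a value shift. When both
#' magnitudes are zero the network abstains (`NA`).
#'
#' @param real,inverse Non-negative output magnitudes.
#' @param scale An [regression_scale()].
#' @return Decoded task-unit value, or `NA_real_` when `r + i == 0`.
#' @export
decode_outputs <- function(real, inverse, scale) {
  total <- real + inverse
  if (total == 0) {
    return(NA_real_)
  }
  p <- min(max(real / total, 0), 1)
  scale$min + p * (scale$max - scale$min)
}

#' Encode a target value as real/inverse connection weights
#'
#' The target's position `p` on the scale splits the error magnitude `E`
#' between the real weight `E * p` and the inverse weight `E * (1 - p)`, so
#' the two always sum to `E` and their ratio recovers the position exactly.
#' Targets outside the scale are clamped to the boundary with a warning.
#'
#' @param x Target value in task units.
#' @param e Error magnitude `E > 0` produced by the network for this sample.
#' @param scale An [regression_scale()].
#' @return Named numeric vector `c(w_r = ..., w_i = ...)`.
#' @export
encode_target <- function(x, e, scale) {
  stopifnot(e > 0)
  if (x < scale$min || x > scale$max) {
    warning(sprintf("target %g outside scale [%g, %g]; clamped",
                    x, scale$min, scale$max), call. = FALSE)
    x <- min(max(x, scale$min), scale$max)
  }
  p <- scale_position(x, scale)
  c(w_r = e * p, w_i = e * (1 - p))
}

#' Regression error on the normalized scale
#'
#' Both the prediction and the target are mapped to `[0, 1]` via the scale;
#' the error is their absolute difference (default) or its square. An
#' abstaining prediction is scored against the scale midpoint, so that early
#' empty-network steps still carry enough error to trigger neurogenesis.
#'
#' @param predicted Decoded prediction in task units, or `NA` (abstain).
#' @param target True value in task units.
#' @param scale An [regression_scale()].
#' @param type `"absolute"` (default) or `"squared"` error on the 0-1 scale.
#' @return Error magnitude `E >= 0`.
#' @export
regression_error <- function(predicted, target, scale,
                             type = c("absolute", "squared")) {
  type <- match.arg(type)
  p_target <- scale_position(target, scale)
  p_pred <- if (is.na(predicted)) 0.5 else scale_position(predicted, scale)
  e <- abs(p_target - p_pred)
  if (type == "squared") e^2 else e
}

#' Forward pass of a regression network
#'
#' Output 1 carries the real magnitude, output 2 the inverse. Raw outputs are
#' clamped below at 0 before decoding (negative sums would break the ratio).
#'
#' @param network An [edn_network()] with exactly 2 outputs.
#' @param inputs Normalized input vector.
#' @param scale An [regression_scale()].
#' @return Decoded prediction in task units, or `NA` (abstain).
#' @export
predict_regression <- function(network, inputs, scale) {
  out <- pmax(output_activations(network, inputs), 0)
  decode_outputs(out[1], out[2], scale)
}

#' One online regression training step
#'
#' Forward pass, decode, score against the target; if the error exceeds the
#' error threshold, store the sample: a new neuron watches all inputs and
#' connects to the real/inverse outputs with weights from [encode_target()],
#' so a repeat presentation of the same input decodes to the stored target.
#'
#' @param network An [edn_network()] with exactly 2 outputs.
#' @param inputs Normalized input vector.
#' @param target True value in task units.
#' @param scale An [regression_scale()].
#' @param error_type Passed to [regression_error()].
#' @return List with `network`, `prediction` (pre-update), and `error`.
#' @export
train_regression_step <- function(network, inputs, target, scale,
                                  error_type = c("absolute", "squared")) {
  error_type <- match.arg(error_type)
  if (network$n_outputs != 2L) {
    stop("regression networks need exactly 2 outputs (real, inverse)",
         call. = FALSE)
  }
  prediction <- predict_regression(network, inputs, scale)
  e <- regression_error(prediction, target, scale, error_type)
  if (e > network$error_threshold) {
    w <- encode_target(target, e, scale)
    eff_index <- c(1L, 2L)[w != 0]
    network <- add_neuron(network,
                          aff_index = seq_along(inputs), aff_value = inputs,
                          eff_index = eff_index, eff_weight = w[w != 0])
  }
  list(network = network, prediction = prediction, error = e)
}

#' Online regression training over a sample stream
#'
#' @param network An [edn_network()] with exactly 2 outputs.
#' @param x Numeric matrix of normalized features.
#' @param y Target values in task units.
#' @param scale An [regression_scale()]; fitted from `y` when `NULL`.
#' @param error_type Passed to [regression_error()].
#' @return List with `network`, `scale`, and a per-step `log` data frame
#'   (step, pre-update prediction, error, neuron count).
#' @export
train_regression <- function(network, x, y, scale = NULL,
                             error_type = c("absolute", "squared")) {
  error_type <- match.arg(error_type)
  stopifnot(nrow(x) == length(y))
  if (is.null(scale)) scale <- fit_scale(y)
  n <- nrow(x)
  log <- data.frame(step = seq_len(n), prediction = NA_real_,
                    error = NA_real_, neurons = NA_integer_)
  for (i in seq_len(n)) {
    st <- train_regression_step(network, x[i, ], y[i], scale, error_type)
    network <- st$network
    log$prediction[i] <- st$prediction
    log$error[i] <- st$error
    log$neurons[i] <- n_neurons(network)
  }
  list(network = network, scale = scale, log = log)
}
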