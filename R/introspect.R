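#' Field image: per-input values extracted from stored synapses
#'
#' Container for introspection results: one value per input (an expectation
#' mean or a weighted sum) plus a coverage count saying how many stored
#' records contributed. Inputs with zero coverage carry `NA`, never a silent
#' zero. Optional 2-D shape metadata supports raster display.
#'
#' @param values Numeric vector, one entry per input (`NA` where coverage
#'   is 0).
#' @param coverage Integer vector of contributing record counts.
#' @param shape Optional `c(rows, cols)` for image-shaped inputs.
#' @return An object of class `edn_field`.
#' @export
edn_field <- function(values, coverage, shape = NULL) {
  stopifnot(length(values) == length(coverage))
  structure(list(values = values, coverage = as.integer(coverage),
                 shape = shape),
            class = "edn_field")
}

#' @export
print.edn_field <- function(x, ...) {
  cat(sprintf("<edn_field> %d inputs, %d covered\n",
              length(x$values), sum(x$coverage > 0L)))
  invisible(x)
}

#' Expectation image for one class
#'
#' The per-input mean of the values stored for a class across all its
#' neurogenesis events: what the network "expects" that class to look like.
#' Inputs never stored for the class are undefined (`NA`).
#'
#' @param expectations An [class_expectation()] accumulator.
#' @param label Class index with at least one recorded event.
#' @param shape Optional raster shape metadata.
#' @return An [edn_field()].
#' @export
class_expectation_image <- function(expectations, label, shape = NULL) {
  if (label < 1 || label > expectations$n_classes) {
    stop(sprintf("label must be a class index in 1..%d",
                 expectations$n_classes), call. = FALSE)
  }
  counts <- expectations$count[label, ]
  if (all(counts == 0L)) {
    stop(sprintf("class %d has no recorded neurogenesis events", label),
         call. = FALSE)
  }
  values <- ifelse(counts > 0L, expectations$sum[label, ] / counts, NA_real_)
  edn_field(values, counts, shape)
}

#' Signed receptive field of an output
#'
#' For each input, sums `w * v` over neurons connected to the output, where
#' `w` is the neuron's efferent weight to that output and `v` its stored
#' center for that input. With `include_negative = FALSE` only positively
#' weighted neurons contribute (a weighted expectation of the class); with
#' it on, inhibitory structure appears as negative values. Raw weighted sums
#' are reported without renormalization.
#'
#' @param network An [edn_network()].
#' @param output_index Output to extract, in `1..n_outputs`.
#' @param include_negative Include negatively weighted neurons (default
#'   `TRUE`).
#' @param shape Optional raster shape metadata.
#' @return An [edn_field()].
#' @export
receptive_field <- function(network, output_index, include_negative = TRUE,
                            shape = NULL) {
  values <- numeric(network$n_inputs)
  coverage <- integer(network$n_inputs)
  for (nu in network$neurons) {
    pos <- match(output_index, nu$eff_index)
    if (is.na(pos)) next
    w <- nu$eff_weight[pos]
    if (!include_negative && w <= 0) next
    values[nu$aff_index] <- values[nu$aff_index] + w * nu$aff_value
    coverage[nu$aff_index] <- coverage[nu$aff_index] + 1L
  }
  values[coverage == 0L] <- NA_real_
  edn_field(values, coverage, shape)
}

#' Decision-boundary raster for a 2-D network
#'
#' Evaluates [predict_class()] at the center of every grid cell over a 2-D
#' box. Cells where the network abstains (all outputs exactly zero, the
#' white no-class region) are `NA`.
#'
#' @param network An [edn_network()] with `n_inputs == 2`.
#' @param bounds Box as `c(x_min, x_max, y_min, y_max)`.
#' @param resolution Cells per axis.
#' @return A `resolution x resolution` integer matrix of class indices
#'   (`NA` = abstain); rows index the first input, columns the second.
#' @export
decision_grid <- function(network, bounds = c(0, 1, 0, 1), resolution = 50) {
  if (network$n_inputs != 2L) {
    stop("decision grids are defined for 2-input networks only",
         call. = FALSE)
  }
  centers_x <- bounds[1] + (seq_len(resolution) - 0.5) / resolution *
    (bounds[2] - bounds[1])
  centers_y <- bounds[3] + (seq_len(resolution) - 0.5) / resolution *
    (bounds[4] - bounds[3])
  grid <- matrix(NA_integer_, nrow = resolution, ncol = resolution)
  for (i in seq_len(resolution)) {
    for (j in seq_len(resolution)) {
      grid[i, j] <- predict_class(
        output_activations(network, c(centers_x[i], centers_y[j])))
    }
  }
  grid
}

#' Export a field image as delimited text
#'
#' Writes `(input, value, coverage)` rows as CSV; undefined values appear as
#' empty cells.
#'
#' @param field An [edn_field()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  df <- data.frame(input = seq_along(field$values),
                   value = field$values, coverage = field$coverage)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export a decision grid as delimited text
#'
#' @param grid Matrix from [decision_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  utils::write.table(grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}
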