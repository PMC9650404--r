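#' Gaussian blob classification fixture
#'
#' Draws isotropic Gaussian clusters, one per class, emulating a cleanly
#' separable low-dimensional classification task. Deterministic under seed.
#'
#' @param centers Numeric matrix of class centers (rows are classes).
#' @param spread Isotropic standard deviation per class (recycled).
#' @param n_per_class Samples per class (recycled).
#' @param seed Integer seed.
#' @return List with `x` (feature matrix, rows interleaved by class) and
#'   `y` (integer labels in `1..n_classes`).
#' @export
make_blobs <- function(centers = rbind(c(0.2, 0.25), c(0.8, 0.25),
                                       c(0.5, 0.8)),
                       spread = 0.05, n_per_class = 20, seed = 1) {
  n_classes <- nrow(centers)
  stopifnot(all(spread >= 0), all(n_per_class > 0))
  spread <- rep_len(spread, n_classes)
  n_per_class <- rep_len(as.integer(n_per_class), n_classes)
  set.seed(seed)
  xs <- list()
  ys <- list()
  for (c in seq_len(n_classes)) {
    pts <- matrix(stats::rnorm(n_per_class[c] * ncol(centers),
                               mean = 0, sd = spread[c]),
                  ncol = ncol(centers), byrow = TRUE)
    xs[[c]] <- sweep(pts, 2L, centers[c, ], `+`)
    ys[[c]] <- rep(c, n_per_class[c])
  }
  x <- do.call(rbind, xs)
  y <- unlist(ys)
  ord <- sample.int(length(y)) # shuffle so classes interleave in the stream
  list(x = x[ord, , drop = FALSE], y = y[ord])
}

#' Non-linear regression surface fixture
#'
#' `x` uniform on the unit square, `y = sin(2*pi*x1) * x2` plus Gaussian
#' noise: a smooth non-linear map with interacting inputs.
#'
#' @param n Sample count.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return List with `x` (n x 2 matrix) and `y` (numeric targets).
#' @export
make_regression_surface <- function(n = 300, noise_sd = 0.05, seed = 1) {
  stopifnot(n > 0, noise_sd >= 0)
  set.seed(seed)
  x <- matrix(stats::runif(2 * n), ncol = 2, byrow = TRUE)
  y <- sin(2 * pi * x[, 1]) * x[, 2]
  if (noise_sd > 0) y <- y + stats::rnorm(n, sd = noise_sd)
  list(x = x, y = y)
}

glyph_templates <- function(size = 8L) {
  mid <- ceiling(size / 2)
  bar <- matrix(0, size, size)
  bar[, mid] <- 1
  cross <- matrix(0, size, size)
  cross[mid, ] <- 1
  cross[, mid] <- 1
  box <- matrix(0, size, size)
  box[c(2, size - 1), 2:(size - 1)] <- 1
  box[2:(size - 1), c(2, size - 1)] <- 1
  diagonal <- diag(size)
  list(bar = bar, cross = cross, box = box, diagonal = diagonal)
}

#' Glyph image classification fixture
#'
#' Small binary rasters (vertical bar, cross, box outline, diagonal) with
#' optional integer pixel translation jitter and additive intensity noise,
#' flattened to `[0, 1]` vectors. Probes high-dimensional input selection
#' and the method's sensitivity to spatial shifts.
#'
#' @param classes Subset of `c("bar", "cross", "box", "diagonal")`.
#' @param n_per_class Samples per class.
#' @param jitter Maximum absolute translation in pixels (integer, >= 0).
#' @param noise_sd Additive Gaussian intensity noise (clamped to `[0, 1]`).
#' @param size Raster side length.
#' @param seed Integer seed.
#' @return List with `x` (samples x pixels matrix), `y` (labels), and
#'   `shape` (`c(size, size)`).
#' @export
make_glyphs <- function(classes = c("bar", "cross", "box", "diagonal"),
                        n_per_class = 10, jitter = 0, noise_sd = 0,
                        size = 8L, seed = 1) {
  stopifnot(jitter >= 0, noise_sd >= 0)
  templates <- glyph_templates(size)
  classes <- match.arg(classes, names(templates), several.ok = TRUE)
  set.seed(seed)
  n_total <- length(classes) * n_per_class
  x <- matrix(0, nrow = n_total, ncol = size * size)
  y <- integer(n_total)
  row <- 1L
  for (c in seq_along(classes)) {
    template <- templates[[classes[c]]]
    for (i in seq_len(n_per_class)) {
      img <- template
      if (jitter > 0) {
        dr <- sample(-jitter:jitter, 1)
        dc <- sample(-jitter:jitter, 1)
        img <- shift_raster(img, dr, dc)
      }
      if (noise_sd > 0) {
        img <- img + matrix(stats::rnorm(size * size, sd = noise_sd),
                            size, size)
        img <- pmin(pmax(img, 0), 1)
      }
      x[row, ] <- as.numeric(img)
      y[row] <- c
      row <- row + 1L
    }
  }
  ord <- sample.int(n_total)
  list(x = x[ord, , drop = FALSE], y = y[ord],
       shape = c(size, size), classes = classes)
}

# Integer translation with zero padding.
shift_raster <- function(img, dr, dc) {
  out <- matrix(0, nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) - dr
  src_c <- seq_len(ncol(img)) - dc
  ok_r <- src_r >= 1 & src_r <= nrow(img)
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[which(ok_r), which(ok_c)] <- img[src_r[ok_r], src_c[ok_c]]
  out
}
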