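#' Fit a min-max normalizer on training features
#'
#' Records each feature's minimum and range on the training rows. Applying
#' the normalizer maps the training minimum to 0 and maximum to 1; values
#' outside the training range (unseen test data) clamp to `[0, 1]`, and
#' constant features map to 0. Always fit on the training split only.
#'
#' @param x Numeric feature matrix (rows are samples).
#' @return An object of class `edn_normalizer`.
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  structure(
    list(min = apply(x, 2L, min), range = apply(x, 2L, max) - apply(x, 2L, min)),
    class = "edn_normalizer"
  )
}

#' @rdname fit_normalizer
#' @param normalizer A fitted `edn_normalizer`.
#' @return `apply_normalizer` returns the normalized matrix in `[0, 1]`.
#' @export
apply_normalizer <- function(normalizer, x) {
  if (!inherits(normalizer, "edn_normalizer")) {
    stop("fit the normalizer with `fit_normalizer()` before applying it",
         call. = FALSE)
  }
  x <- as.matrix(x)
  out <- sweep(x, 2L, normalizer$min, `-`)
  rng <- ifelse(normalizer$range == 0, 1, normalizer$range)
  out <- sweep(out, 2L, rng, `/`)
  out[, normalizer$range == 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Read a delimited feature/label table
#'
#' Expects delimited text with a header row. All non-label columns must be
#' numeric and become the feature matrix.
#'
#' @param path File path.
#' @param label_column Name of the label column, or `NULL` for a
#'   features-only table.
#' @param sep Field separator (default comma).
#' @return List with `x` (numeric matrix) and `y` (label vector, `NULL` when
#'   no label column was requested).
#' @export
read_tabular <- function(path, label_column = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  y <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df)) {
      stop(sprintf("label column '%s' not found; available columns: %s",
                   label_column, paste(names(df), collapse = ", ")),
           call. = FALSE)
    }
    y <- df[[label_column]]
    df[[label_column]] <- NULL
  }
  list(x = as.matrix(df), y = y)
}

#' Write a feature/label table as delimited text
#'
#' @param x Numeric feature matrix.
#' @param y Optional label vector, written as a `label` column.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_tabular <- function(x, y = NULL, path, sep = ",") {
  df <- as.data.frame(x)
  if (is.null(colnames(x))) {
    names(df) <- paste0("x", seq_len(ncol(x)))
  }
  if (!is.null(y)) df$label <- y
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write IDX raster files
#'
#' The IDX format stores a magic number (two zero bytes, a type code, the
#' number of dimensions), big-endian 32-bit dimension sizes, then the raw
#' data. Only the unsigned-byte type (0x08) is supported; pixel values are
#' scaled from `0..255` to `[0, 1]` on read.
#'
#' @param path File path.
#' @return `read_idx` returns a numeric array (first dimension indexes
#'   items) with values in `[0, 1]`.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (length(magic) < 4L || magic[1] != 0L || magic[2] != 0L) {
    stop(sprintf("'%s' is not an IDX file (bad magic at offset 0)", path),
         call. = FALSE)
  }
  if (magic[3] != 0x08) {
    stop(sprintf("unsupported IDX type code 0x%02x at offset 2 (only ubyte)",
                 magic[3]), call. = FALSE)
  }
  ndim <- magic[4]
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  n <- prod(dims)
  raw_vals <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
  if (length(raw_vals) < n) {
    stop(sprintf("'%s' truncated: expected %d data bytes, found %d",
                 path, n, length(raw_vals)), call. = FALSE)
  }
  # IDX is row-major (last index fastest); R arrays are column-major
  arr <- aperm(array(raw_vals / 255, dim = rev(dims)),
               perm = rev(seq_along(dims)))
  arr
}

#' @rdname read_idx
#' @param data Numeric array with values in `[0, 1]` (first dimension
#'   indexes items); quantized to bytes on write.
#' @return `write_idx` returns `path`, invisibly.
#' @export
write_idx <- function(data, path) {
  if (is.null(dim(data))) dim(data) <- length(data)
  dims <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0, 0, 0x08, length(dims))), con)
  writeBin(as.integer(dims), con, size = 4L, endian = "big")
  vals <- as.integer(round(aperm(data, rev(seq_along(dims))) * 255))
  writeBin(as.raw(vals), con)
  invisible(path)
}

#' Stratified k-fold plan
#'
#' Seeded, deterministic partition of the rows into `k` folds whose per-fold
#' class proportions match the global ones to within one sample per class.
#'
#' @param labels Class label vector.
#' @param k Fold count (>= 2).
#' @param seed Integer seed.
#' @return An object of class `edn_folds`: a list with `k`, `seed`, and
#'   `folds`, where each fold holds `$test` and `$train` row indices.
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1) {
  n <- length(labels)
  if (k < 2 || k > n) {
    stop("`k` must lie in 2..length(labels)", call. = FALSE)
  }
  if (min(table(labels)) < k) {
    warning("some class has fewer than k members; stratification is best-effort",
            call. = FALSE)
  }
  set.seed(seed)
  test_sets <- caret::createFolds(factor(labels), k = k, list = TRUE,
                                  returnTrain = FALSE)
  folds <- lapply(test_sets, function(test) {
    list(test = sort(test), train = setdiff(seq_len(n), test))
  })
  names(folds) <- NULL
  structure(list(k = as.integer(k), seed = as.integer(seed), folds = folds),
            class = "edn_folds")
}
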