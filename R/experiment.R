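#' Default experiment configuration
#'
#' Returns the full set of recognized configuration keys with their
#' defaults. User configs (R lists or YAML files) override these; unknown
#' keys are rejected with the offending name.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    task = "classify",          # classify | regress | cartpole
    data = list(source = "fixture", fixture = NULL, # default fits the task
                path = NULL, label_column = "label"),
    spread = 0.4,
    error_threshold = 0.1,
    surprise_threshold = 0.05,
    selection = "all",          # all | surprise | random
    n_select = NULL,
    error_type = "absolute",    # regression error on the 0-1 scale
    memory = 10,                # RL failure window
    max_size = NULL,            # RL neuron cap (NULL = no deletion)
    tau = 0.9999,
    max_trials = 2000,
    folds = 10,
    seeds = 1,
    epochs = 1,
    eval_every = 10,            # per-step test evaluation cadence
    out_dir = NULL
  )
}

#' Load an experiment configuration from a YAML file
#'
#' @param path YAML file; keys override [default_config()].
#' @param overrides Optional named list applied on top (CLI flags).
#' @return The resolved configuration list.
#' @export
read_config <- function(path = NULL, overrides = NULL) {
  config <- default_config()
  apply_over <- function(config, over) {
    bad <- setdiff(names(over), names(config))
    if (length(bad) > 0L) {
      stop(sprintf("unknown configuration key(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    utils::modifyList(config, over)
  }
  if (!is.null(path)) config <- apply_over(config, yaml::read_yaml(path))
  if (!is.null(overrides)) config <- apply_over(config, overrides)
  config
}

resolve_data <- function(config, seed) {
  d <- config$data
  if (identical(d$source, "file")) {
    tab <- read_tabular(d$path, d$label_column %||% "label")
    list(x = tab$x, y = tab$y)
  } else {
    default_fixture <- if (identical(config$task, "regress")) "surface"
                       else "blobs"
    switch(d$fixture %||% default_fixture,
      blobs = {
        b <- make_blobs(seed = seed)
        list(x = b$x, y = b$y)
      },
      surface = {
        r <- make_regression_surface(seed = seed)
        list(x = r$x, y = r$y)
      },
      glyphs = {
        g <- make_glyphs(n_per_class = 15, seed = seed)
        list(x = g$x, y = g$y)
      },
      stop(sprintf("unknown fixture '%s'", d$fixture), call. = FALSE)
    )
  }
}

#' Run a configured experiment
#'
#' Dispatches on `config$task`:
#' * `classify`: stratified k-fold; per fold the normalizer is fitted on the
#'   training rows only, the network is trained online for `epochs` passes,
#'   and held-out accuracy is recorded every `eval_every` steps.
#' * `regress`: k-fold with held-out mean squared error curves.
#' * `cartpole`: one training run per seed, recording per-trial balance
#'   length and neuron count.
#'
#' When `config$out_dir` is set, the resolved configuration (YAML), per-fold
#' or per-seed curves (CSV) and a summary (CSV) are written there.
#'
#' @param config Configuration list; see [default_config()] for keys.
#' @return List with `config`, `curves` (data frame), and `summary`
#'   (data frame).
#' @export
run_experiment <- function(config = default_config()) {
  config <- read_config(overrides = config)
  result <- switch(config$task,
    classify = run_classify_experiment(config),
    regress = run_regress_experiment(config),
    cartpole = run_cartpole_experiment(config),
    stop(sprintf("unknown task '%s' (key: task)", config$task),
         call. = FALSE)
  )
  result$config <- config
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(config, file.path(config$out_dir, "config.yaml"))
    utils::write.csv(result$curves, file.path(config$out_dir, "curves.csv"),
                     row.names = FALSE)
    utils::write.csv(result$summary, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  result
}

run_classify_experiment <- function(config) {
  seed <- config$seeds[1]
  data <- resolve_data(config, seed)
  y <- as.integer(factor(data$y))
  n_classes <- max(y)
  plan <- stratified_kfold(y, k = config$folds, seed = seed)
  curves <- list()
  finals <- list()
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    norm <- fit_normalizer(data$x[fold$train, , drop = FALSE])
    x_train <- apply_normalizer(norm, data$x[fold$train, , drop = FALSE])
    x_test <- apply_normalizer(norm, data$x[fold$test, , drop = FALSE])
    y_train <- y[fold$train]
    y_test <- y[fold$test]
    net <- edn_network(ncol(x_train), n_classes, spread = config$spread,
                       error_threshold = config$error_threshold,
                       surprise_threshold = config$surprise_threshold)
    exps <- class_expectation(net$n_inputs, n_classes)
    set.seed(seed + f)
    rows <- list()
    step <- 0L
    for (epoch in seq_len(config$epochs)) {
      for (i in seq_along(y_train)) {
        st <- train_classification_step(net, exps, x_train[i, ], y_train[i],
                                        config$selection, config$n_select)
        net <- st$network
        exps <- st$expectations
        step <- step + 1L
        if (step %% config$eval_every == 0L ||
            step == config$epochs * length(y_train)) {
          preds <- classify(net, x_test)
          acc <- mean(!is.na(preds) & preds == y_test) # abstain = error
          rows[[length(rows) + 1L]] <- data.frame(
            fold = f, step = step, accuracy = acc,
            neurons = n_neurons(net), synapses = n_synapses(net))
        }
      }
    }
    curve <- do.call(rbind, rows)
    curves[[f]] <- curve
    finals[[f]] <- curve[nrow(curve), ]
  }
  final <- do.call(rbind, finals)
  list(curves = do.call(rbind, curves),
       summary = data.frame(
         folds = config$folds,
         mean_accuracy = mean(final$accuracy),
         mean_neurons = mean(final$neurons),
         mean_synapses = mean(final$synapses)))
}

run_regress_experiment <- function(config) {
  seed <- config$seeds[1]
  data <- resolve_data(config, seed)
  set.seed(seed)
  test_sets <- caret::createFolds(data$y, k = config$folds, list = TRUE,
                                  returnTrain = FALSE)
  curves <- list()
  finals <- numeric(0)
  for (f in seq_along(test_sets)) {
    test <- sort(test_sets[[f]])
    train <- setdiff(seq_along(data$y), test)
    norm <- fit_normalizer(data$x[train, , drop = FALSE])
    x_train <- apply_normalizer(norm, data$x[train, , drop = FALSE])
    x_test <- apply_normalizer(norm, data$x[test, , drop = FALSE])
    y_train <- data$y[train]
    y_test <- data$y[test]
    scale <- fit_scale(y_train)
    net <- edn_network(ncol(x_train), 2L, spread = config$spread,
                       error_threshold = config$error_threshold)
    rows <- list()
    step <- 0L
    mid <- (scale$min + scale$max) / 2
    for (epoch in seq_len(config$epochs)) {
      for (i in seq_along(y_train)) {
        st <- train_regression_step(net, x_train[i, ], y_train[i], scale,
                                    config$error_type)
        net <- st$network
        step <- step + 1L
        if (step %% config$eval_every == 0L ||
            step == config$epochs * length(y_train)) {
          preds <- vapply(seq_along(y_test), function(j) {
            p <- predict_regression(net, x_test[j, ], scale)
            if (is.na(p)) mid else p
          }, numeric(1))
          rows[[length(rows) + 1L]] <- data.frame(
            fold = f, step = step, mse = mean((preds - y_test)^2),
            neurons = n_neurons(net))
        }
      }
    }
    curve <- do.call(rbind, rows)
    curves[[f]] <- curve
    finals <- c(finals, curve$mse[nrow(curve)])
  }
  list(curves = do.call(rbind, curves),
       summary = data.frame(folds = config$folds,
                            mean_mse = mean(finals)))
}

run_cartpole_experiment <- function(config) {
  curves <- list()
  summary_rows <- list()
  for (seed in config$seeds) {
    run <- run_cartpole_training(
      spread = config$spread, memory = config$memory,
      max_size = config$max_size, tau = config$tau,
      max_trials = config$max_trials, seed = seed)
    curves[[length(curves) + 1L]] <- data.frame(
      seed = seed, trial = seq_along(run$balance),
      balance = run$balance, neurons = run$neurons)
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      seed = seed, trials_to_solve = run$trials_to_solve,
      solved = run$solved,
      final_balance = mean(utils::tail(run$balance, 100)))
  }
  list(curves = do.call(rbind, curves),
       summary = do.call(rbind, summary_rows))
}
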