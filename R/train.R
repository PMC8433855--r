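#' Optimizer and stopping options
#'
#' Adam with the canonical default moment decays (0.9, 0.999) and epsilon
#' 1e-8; only the learning rate is meant to be tuned. Training stops when
#' either the cost threshold or the maximum iteration count — both set in
#' advance — is reached, whichever comes first.
#'
#' @param learning_rate Adam step size.
#' @param adam_beta1,adam_beta2,adam_epsilon Adam moment decays and
#'   numerical floor (fixed defaults; rarely changed).
#' @param max_iterations Upper bound on Adam iterations.
#' @param cost_threshold Stop once the iteration's cost falls to or below
#'   this value (0 disables the rule).
#' @param batch_size Minibatch size per iteration.
#' @param seed Seed controlling batch sampling (and dropout, if any).
#' @return A `train_options` list.
#' @export
train_options <- function(learning_rate = 0.001, adam_beta1 = 0.9,
                          adam_beta2 = 0.999, adam_epsilon = 1e-8,
                          max_iterations = 2000, cost_threshold = 0,
                          batch_size = 64, seed = 1L) {
  structure(list(
    learning_rate = check_scalar_number(learning_rate, "learning_rate", lower = 1e-12),
    adam_beta1 = check_scalar_number(adam_beta1, "adam_beta1", 0, 1 - 1e-12),
    adam_beta2 = check_scalar_number(adam_beta2, "adam_beta2", 0, 1 - 1e-12),
    adam_epsilon = check_scalar_number(adam_epsilon, "adam_epsilon", lower = 0),
    max_iterations = as.integer(check_scalar_number(max_iterations, "max_iterations", lower = 1)),
    cost_threshold = if (identical(cost_threshold, Inf)) Inf else
      check_scalar_number(cost_threshold, "cost_threshold", lower = 0),
    batch_size = as.integer(check_scalar_number(batch_size, "batch_size", lower = 1)),
    seed = as.integer(check_scalar_number(seed, "seed"))
  ), class = "train_options")
}

# Flatten a nested parameter tree to one numeric vector and back.
flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  rec <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) return(lapply(x, rec))
    n <- length(x)
    out <- vec[pos + seq_len(n)]
    pos <<- pos + n
    dim(out) <- dim(x)
    out
  }
  rec(skeleton)
}

#' Train a TCN or LSTM on a windowed dataset
#'
#' Minimizes the mean-squared-error cost on (normalized) targets with Adam,
#' sampling one minibatch per iteration. The loss history records the cost
#' of every iteration; runs are bit-reproducible given `opts$seed`.
#'
#' @param model A [tcn_init()] or [lstm_init()] model.
#' @param dataset A [make_pairs()] dataset whose inputs/targets are already
#'   normalized.
#' @param opts A [train_options()].
#' @return A `trained_model` list: `model` (with updated parameters),
#'   `history` (tibble: iteration, cost), `opts`.
#' @export
train_model <- function(model, dataset, opts = train_options()) {
  stopifnot(inherits(model, "motion_model"))
  N <- nrow(dataset$targets)
  if (N < 1) stop_argument("Cannot train on an empty dataset.")
  config <- model$config
  if (dataset$t_delay != config$input_window) {
    stop_config(sprintf("Dataset windows have %d samples but the model expects %d.",
                        dataset$t_delay, config$input_window))
  }
  shift_cache <- new.env(parent = emptyenv())
  loss_grad <- if (model$family == "tcn") {
    function(par, Xb, Yb, B) {
      tcn_loss_grad(par, config, block_matrix(Xb, config$input_window), Yb, B,
                    shift_cache = shift_cache)
    }
  } else {
    function(par, Xb, Yb, B) lstm_loss_grad(par, config, Xb, Yb)
  }

  skeleton <- model$params
  theta <- flatten_params(skeleton)
  m <- numeric(length(theta))
  v <- numeric(length(theta))
  history <- numeric(opts$max_iterations)
  n_done <- 0L

  with_seed(opts$seed, {
    params <- skeleton
    for (it in seq_len(opts$max_iterations)) {
      idx <- if (N <= opts$batch_size) seq_len(N) else
        sample.int(N, opts$batch_size)
      Xb <- dataset$inputs[idx, , , drop = FALSE]
      Yb <- dataset$targets[idx, , drop = FALSE]
      lg <- loss_grad(params, Xb, Yb, length(idx))
      if (!is.finite(lg$loss)) {
        stop_training(sprintf("Training diverged (non-finite cost) at iteration %d.", it),
                      iteration = it)
      }
      history[it] <- lg$loss
      n_done <- it
      g <- flatten_params(lg$grads)
      m <- opts$adam_beta1 * m + (1 - opts$adam_beta1) * g
      v <- opts$adam_beta2 * v + (1 - opts$adam_beta2) * g^2
      mhat <- m / (1 - opts$adam_beta1^it)
      vhat <- v / (1 - opts$adam_beta2^it)
      theta <- theta - opts$learning_rate * mhat / (sqrt(vhat) + opts$adam_epsilon)
      params <- unflatten_params(theta, skeleton)
      if (lg$loss <= opts$cost_threshold) break
    }
    model$params <- params
  })
  structure(list(
    model = model,
    history = tibble(iteration = seq_len(n_done), cost = history[seq_len(n_done)]),
    opts = opts
  ), class = "trained_model")
}

#' Fit a motion-prediction model to one treatment fraction
#'
#' The end-to-end per-fraction pipeline: split at `t_s`, fit the per-channel
#' normalizer on the training segment only, build sliding-window pairs, and
#' train the chosen network. The returned fit predicts with
#' [predict_tumor()] and carries everything needed to reproduce itself.
#'
#' @param frac A `fraction` tibble.
#' @param family `"tcn"` or `"lstm"`.
#' @param spec A [window_spec()]. Its `t_delay` overrides the model config's
#'   `input_window`.
#' @param config A [tcn_config()] / [lstm_config()]; defaults to the
#'   grid-search-selected architecture of the chosen family. Its `seed` is
#'   replaced by one derived from `opts$seed`, so a single run seed
#'   determines initialization and batching together.
#' @param opts A [train_options()]; default learning rate follows the
#'   family (0.001 TCN, 0.01 LSTM).
#' @param markers Marker indices feeding the input (default all).
#' @return A `motion_fit` object.
#' @examples
#' \donttest{
#' frac <- simulate_fraction(synthetic_config(duration_s = 60, seed = 1))
#' fit <- fit_motion_model(frac, "tcn",
#'   spec = window_spec(t_delay = 15, ahead_ms = 400, t_s = 1000),
#'   config = tcn_config(channels_per_layer = 8),
#'   opts = train_options(max_iterations = 100)
#' )
#' glance(fit)
#' }
#' @export
fit_motion_model <- function(frac, family = c("tcn", "lstm"), spec = NULL,
                             config = NULL, opts = NULL, markers = NULL) {
  family <- match.arg(family)
  if (is.null(markers)) markers <- seq_len(n_markers(frac))
  n_ch <- 3L * length(markers)
  rate <- sampling_rate_hz(frac)
  if (is.null(spec)) {
    spec <- window_spec(t_delay = if (family == "tcn") 15 else 20,
                        ahead_ms = 400, sampling_rate_hz = rate,
                        t_s = min(nrow(frac) - 1L, as.integer(180 * rate)))
  }
  if (is.null(config)) {
    config <- if (family == "tcn") tcn_config() else lstm_config()
  }
  config$input_window <- spec$t_delay
  config$n_input_channels <- n_ch
  if (is.null(opts)) {
    opts <- train_options(learning_rate = if (family == "tcn") 0.001 else 0.01)
  }
  # one run seed drives everything: weight init is derived from it so that
  # repeated fits differ in init, not just batch order
  config$seed <- derive_seeds(opts$seed, 1)
  parts <- split_train_test(frac, spec$t_s)
  normalizer <- fit_normalizer(parts$train)
  train_norm <- apply_normalizer(parts$train, normalizer)
  ds <- make_pairs(train_norm, spec, markers = markers)
  model <- if (family == "tcn") tcn_init(config) else lstm_init(config)
  trained <- train_model(model, ds, opts)
  structure(list(
    family = family,
    model = trained$model,
    history = trained$history,
    normalizer = normalizer,
    spec = spec,
    markers = markers,
    opts = opts,
    fraction_id = fraction_id(frac),
    sampling_rate_hz = rate
  ), class = "motion_fit")
}

#' @export
print.motion_fit <- function(x, ...) {
  cat(sprintf(
    "<motion_fit>  %s on '%s': window %d, horizon %d samples, %d iterations, final cost %.3g\n",
    toupper(x$family), x$fraction_id, x$spec$t_delay, x$spec$t_ahead,
    nrow(x$history), x$history$cost[nrow(x$history)]
  ))
  invisible(x)
}

#' Full-factorial hyperparameter grid space
#'
#' `tcn_grid_space()` and `lstm_grid_space()` return the four tuned axes of
#' each family with the published option values; `grid_search()` evaluates
#' their full Cartesian product (625 TCN configurations; the LSTM's printed
#' axes multiply to 750).
#'
#' @param ... Named axes overriding the defaults, each a non-empty vector.
#' @return A `grid_space` (named list of axes).
#' @export
tcn_grid_space <- function(...) {
  make_grid_space(list(
    n_layers = c(4, 5, 6, 7, 8),
    filter_size = c(1, 3, 5, 7, 9),
    input_window = c(5, 10, 15, 20, 25),
    learning_rate = c(0.0001, 0.001, 0.005, 0.01, 0.1)
  ), ...)
}

#' @rdname tcn_grid_space
#' @export
lstm_grid_space <- function(...) {
  make_grid_space(list(
    n_layers = c(1, 2, 3, 4, 5),
    learning_rate = c(0.0001, 0.001, 0.005, 0.01, 0.1),
    hidden_units = c(10, 50, 100, 150, 200, 250),
    input_window = c(5, 10, 15, 20, 25)
  ), ...)
}

make_grid_space <- function(defaults, ...) {
  over <- list(...)
  space <- utils::modifyList(defaults, over)
  if (any(vapply(space, length, integer(1)) == 0)) {
    stop_config("Every grid axis must be non-empty.")
  }
  structure(space, class = "grid_space")
}

# Validation 3D RMSE of one candidate configuration on one tuning fraction:
# temporal holdout — the last `holdout_frac` of the training segment is the
# validation set; its windows never touch parameter updates.
evaluate_candidate <- function(row, family, frac, opts, holdout_frac,
                               model_args = list()) {
  rate <- sampling_rate_hz(frac)
  t_train_end <- min(nrow(frac) - 1L, as.integer(180 * rate))
  t_fit <- as.integer(floor(t_train_end * (1 - holdout_frac)))
  spec_fit <- window_spec(t_delay = row$input_window, t_ahead = opts$t_ahead,
                          t_s = t_fit)
  train_part <- frac[seq_len(t_train_end), , drop = FALSE]
  parts <- split_train_test(train_part, t_fit)
  normalizer <- fit_normalizer(parts$train)
  ds_fit <- make_pairs(apply_normalizer(parts$train, normalizer), spec_fit)
  cfg_args <- utils::modifyList(list(
    input_window = as.integer(row$input_window),
    n_input_channels = 3L * n_markers(frac),
    seed = opts$train$seed
  ), model_args)
  if (family == "tcn") {
    cfg_args$n_layers <- as.integer(row$n_layers)
    cfg_args$filter_size <- as.integer(row$filter_size)
    model <- tcn_init(do.call(tcn_config, cfg_args))
  } else {
    cfg_args$n_layers <- as.integer(row$n_layers)
    cfg_args$hidden_units <- as.integer(row$hidden_units)
    model <- lstm_init(do.call(lstm_config, cfg_args))
  }
  topts <- opts$train
  topts$learning_rate <- row$learning_rate
  trained <- tryCatch(
    train_model(model, ds_fit, topts),
    respredict_training_error = function(e) NULL
  )
  if (is.null(trained)) return(Inf)
  ds_val <- make_pairs(apply_normalizer(parts$test, normalizer), spec_fit)
  pred_norm <- forward_model(trained$model, ds_val$inputs)
  pred <- invert_normalizer(pred_norm, normalizer, channels = tumor_cols())
  rmse_3d(ds_val$targets, pred)
}

forward_model <- function(model, inputs) {
  if (model$family == "tcn") tcn_forward(model, inputs) else lstm_forward(model, inputs)
}

#' Full-factorial grid search over a hyperparameter space
#'
#' Evaluates every combination of the four axes jointly (never axis-by-axis
#' with the others fixed). Each candidate is trained on the first
#' `1 - holdout_frac` of each tuning fraction's training segment and scored
#' by 3D RMSE on the held-back tail (a temporal holdout that respects time
#' ordering); the score of a candidate is the mean across tuning fractions.
#' Ties are broken towards the smaller model, then the lower learning rate.
#'
#' @param family `"tcn"` or `"lstm"`.
#' @param space A [tcn_grid_space()]-style `grid_space`.
#' @param fractions List of tuning `fraction` tibbles (the study tuned on 5).
#' @param t_ahead Prediction horizon in samples during tuning.
#' @param train_opts [train_options()] applied to every candidate (its
#'   learning rate is overridden by the axis value).
#' @param holdout_frac Fraction of the training segment held back for
#'   validation (temporal tail).
#' @param model_args Extra fixed config fields (e.g. smaller
#'   `channels_per_layer` for desk-scale runs).
#' @param evaluator Optional `function(row, fraction) -> validation RMSE`
#'   replacing the train-and-score step (used to enumerate or mock).
#' @return A `grid_search_result`: list with `results` (one row per
#'   combination: axes, per-fraction RMSE, `mean_rmse`) and `best_config`
#'   (one-row tibble).
#' @export
grid_search <- function(family = c("tcn", "lstm"), space, fractions,
                        t_ahead = 10, train_opts = NULL, holdout_frac = 0.2,
                        model_args = list(), evaluator = NULL) {
  family <- match.arg(family)
  if (!inherits(space, "grid_space")) stop_config("`space` must be a grid_space.")
  if (length(fractions) < 1) stop_argument("Need at least one tuning fraction.")
  if (is.null(train_opts)) train_opts <- train_options()
  grid <- tidyr::expand_grid(!!!as.list(space))
  opts <- list(t_ahead = as.integer(t_ahead), train = train_opts)

  frac_names <- paste0("rmse_", seq_along(fractions))
  scores <- matrix(NA_real_, nrow(grid), length(fractions))
  for (r in seq_len(nrow(grid))) {
    row <- as.list(grid[r, ])
    for (fi in seq_along(fractions)) {
      scores[r, fi] <- if (!is.null(evaluator)) {
        evaluator(row, fractions[[fi]])
      } else {
        evaluate_candidate(row, family, fractions[[fi]], opts, holdout_frac,
                           model_args)
      }
    }
  }
  colnames(scores) <- frac_names
  results <- dplyr::bind_cols(grid, as_tibble(scores))
  results$mean_rmse <- rowMeans(scores)

  size_of <- function(df) {
    if (family == "tcn") {
      df$n_layers * df$filter_size + df$input_window
    } else {
      df$n_layers * df$hidden_units + df$input_window
    }
  }
  ord <- order(results$mean_rmse, size_of(results), results$learning_rate)
  best <- results[ord[1], , drop = FALSE]
  structure(list(family = family, results = results, best_config = best),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result>  %s, %d configurations evaluated\n",
              toupper(x$family), nrow(x$results)))
  cat("best configuration:\n")
  print(x$best_config)
  invisible(x)
}
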