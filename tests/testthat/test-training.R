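tiny_dataset <- function(n_pairs = 8, t_delay = 6, C = 3, seed = 1) {
  set.seed(seed)
  list(inputs = array(rnorm(n_pairs * t_delay * C), c(n_pairs, t_delay, C)),
       targets = matrix(rnorm(n_pairs * 3), n_pairs, 3),
       target_index = seq_len(n_pairs) + t_delay,
       t_delay = t_delay, t_ahead = 0L)
}

test_that("Adam drives a small TCN to overfit a tiny dataset", {
  ds <- tiny_dataset()
  cfg <- tcn_config(n_layers = 2, filter_size = 3, channels_per_layer = 8,
                    input_window = 6, n_input_channels = 3, seed = 2)
  tr <- train_model(tcn_init(cfg), ds,
                    train_options(learning_rate = 0.01, max_iterations = 800, seed = 3))
  expect_lt(tr$history$cost[nrow(tr$history)], 1e-3)
})

test_that("training is bit-reproducible and the stopping rules hold", {
  ds <- tiny_dataset(n_pairs = 40)
  cfg <- lstm_config(n_layers = 1, hidden_units = 6, input_window = 6,
                     n_input_channels = 3, seed = 5)
  opts <- train_options(learning_rate = 0.01, max_iterations = 30,
                        batch_size = 16, seed = 11)
  t1 <- train_model(lstm_init(cfg), ds, opts)
  t2 <- train_model(lstm_init(cfg), ds, opts)
  expect_identical(t1$history, t2$history)
  expect_identical(t1$model$params, t2$model$params)
  expect_identical(nrow(t1$history), 30L)

  # an infinite cost threshold is met by the very first iteration
  one <- train_model(lstm_init(cfg), ds,
                     train_options(max_iterations = 50, cost_threshold = Inf, seed = 1))
  expect_identical(nrow(one$history), 1L)

  # divergence raises a classed error carrying the iteration
  err <- tryCatch(
    train_model(tcn_init(tcn_config(n_layers = 1, filter_size = 2,
                                    channels_per_layer = 4, input_window = 6,
                                    n_input_channels = 3, seed = 1)),
                ds, train_options(learning_rate = 1e130, max_iterations = 400, seed = 1)),
    respredict_training_error = function(e) e
  )
  expect_s3_class(err, "respredict_training_error")
  expect_true(is.finite(err$iteration))
})

test_that("samples after the split never influence the trained weights", {
  frac <- desk_fraction(seed = 61, duration_s = 40)
  spec <- window_spec(t_delay = 10, t_ahead = 5, t_s = 700)
  cfg <- tcn_config(n_layers = 2, filter_size = 3, channels_per_layer = 6)
  opts <- desk_opts(seed = 7, max_iterations = 25)
  fit1 <- fit_motion_model(frac, "tcn", spec = spec, config = cfg, opts = opts)

  shuffled <- frac
  post <- (spec$t_s + 1):nrow(frac)
  set.seed(1)
  for (cn in setdiff(names(frac), "time_s")) {
    shuffled[[cn]][post] <- sample(shuffled[[cn]][post])
  }
  fit2 <- fit_motion_model(shuffled, "tcn", spec = spec, config = cfg, opts = opts)
  expect_identical(fit1$model$params, fit2$model$params)
})

test_that("grid search enumerates the full factorial product", {
  frac <- desk_fraction(seed = 62, duration_s = 20)
  stub <- function(row, frac) row$n_layers + row$filter_size / 10

  gs <- grid_search("tcn", tcn_grid_space(), list(frac), evaluator = stub)
  expect_identical(nrow(gs$results), 625L) # 5^4 combinations, jointly
  expect_identical(nrow(gs$results), nrow(dplyr::distinct(gs$results[1:4])))

  gl <- grid_search("lstm", lstm_grid_space(), list(frac),
                    evaluator = function(row, frac) 1)
  expect_identical(nrow(gl$results), 750L) # 5 x 5 x 6 x 5 as printed

  single <- grid_search("tcn",
                        tcn_grid_space(n_layers = 5, filter_size = 9,
                                       input_window = 15, learning_rate = 0.001),
                        list(frac), evaluator = stub)
  expect_identical(nrow(single$results), 1L)
  expect_equal(single$best_config$filter_size, 9)
})

test_that("grid search selects an engineered optimum and breaks ties sensibly", {
  frac <- desk_fraction(seed = 63, duration_s = 20)
  space <- tcn_grid_space(n_layers = c(4, 5), filter_size = c(3, 9),
                          input_window = c(10, 15),
                          learning_rate = c(0.001, 0.1))
  dominant <- function(row, frac) {
    if (row$n_layers == 5 && row$filter_size == 9 &&
        row$input_window == 15 && row$learning_rate == 0.001) 0.05 else 2
  }
  gs <- grid_search("tcn", space, list(frac), evaluator = dominant)
  expect_equal(unlist(gs$best_config[1, c("n_layers", "filter_size",
                                          "input_window", "learning_rate")]),
               c(n_layers = 5, filter_size = 9, input_window = 15,
                 learning_rate = 0.001))

  # constant scores: ties resolve to the smallest model, then the lowest rate
  tie <- grid_search("tcn", space, list(frac), evaluator = function(row, frac) 1)
  expect_equal(unlist(tie$best_config[1, c("n_layers", "filter_size",
                                           "input_window", "learning_rate")]),
               c(n_layers = 4, filter_size = 3, input_window = 10,
                 learning_rate = 0.001))

  expect_error(grid_search("tcn", tcn_grid_space(n_layers = numeric(0)),
                           list(frac), evaluator = dominant),
               class = "respredict_config_error")
})

test_that("a real (tiny) grid search trains, scores and returns finite RMSEs", {
  frac <- desk_fraction(seed = 64, duration_s = 60)
  space <- tcn_grid_space(n_layers = 2, filter_size = 3, input_window = 10,
                          learning_rate = c(0.001, 0.01))
  gs <- grid_search("tcn", space, list(frac),
                    train_opts = train_options(max_iterations = 40, seed = 2),
                    model_args = list(channels_per_layer = 6))
  expect_identical(nrow(gs$results), 2L)
  expect_true(all(is.finite(gs$results$mean_rmse)))
  expect_identical(nrow(tidy(gs)), 2L)
  expect_identical(glance(gs)$n_configurations, 2L)
})
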