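#' Stacked LSTM configuration
#'
#' The recurrent baseline: `n_layers` vanilla LSTM layers (input, forget and
#' output gates, no peepholes) consume the input window step by step; the
#' prediction is a linear map of the top layer's final hidden state. Hidden
#' and cell states are zeroed for every window — the sliding-window protocol
#' treats windows as independent. Defaults are the grid-search-selected
#' architecture: 2 layers, 200 hidden units, 20-sample input window.
#'
#' @param n_layers Number of stacked LSTM layers (>= 1).
#' @param hidden_units Hidden units per layer (>= 1).
#' @param input_window Input window length `t_delay`, samples.
#' @param n_input_channels Input channels per step (3 per marker).
#' @param output_dim Output dimension (3: SI, AP, LR).
#' @param seed Seed for weight initialization.
#' @return An `lstm_config` list.
#' @export
lstm_config <- function(n_layers = 2, hidden_units = 200, input_window = 20,
                        n_input_channels = 9, output_dim = 3, seed = 1L) {
  cfg <- list(
    n_layers = as.integer(check_scalar_number(n_layers, "n_layers", lower = 1)),
    hidden_units = as.integer(check_scalar_number(hidden_units, "hidden_units", lower = 1)),
    input_window = as.integer(check_scalar_number(input_window, "input_window", lower = 1)),
    n_input_channels = as.integer(check_scalar_number(n_input_channels, "n_input_channels", lower = 1)),
    output_dim = as.integer(check_scalar_number(output_dim, "output_dim", lower = 1)),
    seed = as.integer(check_scalar_number(seed, "seed"))
  )
  structure(cfg, class = "lstm_config")
}

#' Initialize an LSTM model
#'
#' Gate weights are stored as blocks `[i | f | g | o]` (input gate, forget
#' gate, candidate, output gate) of one `(in + hidden) x 4*hidden` affine
#' map per layer, drawn fan-in-scaled uniform from the config seed.
#'
#' @param config An [lstm_config()].
#' @return An `lstm_model` list with elements `config` and `params`.
#' @export
lstm_init <- function(config) {
  stopifnot(inherits(config, "lstm_config"))
  with_seed(config$seed, {
    H <- config$hidden_units
    layers <- vector("list", config$n_layers)
    c_in <- config$n_input_channels
    for (l in seq_len(config$n_layers)) {
      bound <- 1 / sqrt(H)
      layers[[l]] <- list(
        Wx = matrix(stats::runif(c_in * 4 * H, -bound, bound), c_in, 4 * H),
        Wh = matrix(stats::runif(H * 4 * H, -bound, bound), H, 4 * H),
        b = numeric(4 * H)
      )
      c_in <- H
    }
    bound <- 1 / sqrt(H)
    params <- list(
      layers = layers,
      Wout = matrix(stats::runif(H * config$output_dim, -bound, bound),
                    H, config$output_dim),
      bout = numeric(config$output_dim)
    )
    structure(list(family = "lstm", config = config, params = params),
              class = c("lstm_model", "motion_model"))
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One LSTM cell update
#'
#' The standard gated update: `i, f, o` are logistic gates of affine maps of
#' `(x_t, h_prev)`, the candidate `g` is a tanh of the same kind of map, the
#' cell state is `c_t = f * c_prev + i * g` and the hidden state
#' `h_t = o * tanh(c_t)`.
#'
#' @param x_t Input at time t: a vector of length `in`, or a `B x in` batch
#'   matrix.
#' @param h_prev,c_prev Previous hidden/cell state, matching shape
#'   (`hidden` vector or `B x hidden`).
#' @param params List with `Wx` (`in x 4*hidden`), `Wh`
#'   (`hidden x 4*hidden`), `b` (`4*hidden`), gate block order
#'   `[i | f | g | o]`.
#' @return List with `h` and `c` (same shape as `h_prev`).
#' @export
lstm_step <- function(x_t, h_prev, c_prev, params) {
  vec_in <- !is.matrix(x_t)
  if (vec_in) {
    x_t <- matrix(x_t, 1)
    h_prev <- matrix(h_prev, 1)
    c_prev <- matrix(c_prev, 1)
  }
  if (ncol(x_t) != nrow(params$Wx) || ncol(h_prev) != nrow(params$Wh)) {
    stop_argument("lstm_step: input/state dimensions do not match the parameters.")
  }
  st <- lstm_step_cached(x_t, h_prev, c_prev, params)
  if (vec_in) list(h = drop(st$h), c = drop(st$c)) else list(h = st$h, c = st$c)
}

lstm_step_cached <- function(x_t, h_prev, c_prev, params) {
  H <- nrow(params$Wh)
  G <- x_t %*% params$Wx + h_prev %*% params$Wh +
    matrix(params$b, nrow(x_t), 4 * H, byrow = TRUE)
  i <- sigmoid(G[, 1:H, drop = FALSE])
  f <- sigmoid(G[, (H + 1):(2 * H), drop = FALSE])
  g <- tanh(G[, (2 * H + 1):(3 * H), drop = FALSE])
  o <- sigmoid(G[, (3 * H + 1):(4 * H), drop = FALSE])
  c_t <- f * c_prev + i * g
  tc <- tanh(c_t)
  list(h = o * tc, c = c_t, i = i, f = f, g = g, o = o, tc = tc,
       x = x_t, h_prev = h_prev, c_prev = c_prev)
}

lstm_forward_cached <- function(params, config, X) {
  # X: B x T x C array
  B <- dim(X)[1]
  T_len <- dim(X)[2]
  H <- config$hidden_units
  caches <- vector("list", config$n_layers)
  inp <- lapply(seq_len(T_len), function(t) {
    matrix(X[, t, ], nrow = B, ncol = dim(X)[3])
  })
  for (l in seq_len(config$n_layers)) {
    h <- matrix(0, B, H)
    c <- matrix(0, B, H)
    steps <- vector("list", T_len)
    for (t in seq_len(T_len)) {
      st <- lstm_step_cached(inp[[t]], h, c, params$layers[[l]])
      h <- st$h
      c <- st$c
      steps[[t]] <- st
    }
    caches[[l]] <- steps
    inp <- lapply(steps, `[[`, "h")
  }
  pred <- inp[[T_len]] %*% params$Wout +
    matrix(params$bout, B, config$output_dim, byrow = TRUE)
  list(pred = pred, caches = caches, h_top = inp[[T_len]])
}

#' LSTM forward pass (inference)
#'
#' @param model An [lstm_init()] result.
#' @param window A `t_delay x C` matrix or an `N x t_delay x C` array.
#' @return Numeric `N x output_dim` prediction matrix. Deterministic.
#' @export
lstm_forward <- function(model, window) {
  config <- model$config
  if (is.matrix(window)) window <- array(window, dim = c(1L, nrow(window), ncol(window)))
  if (length(dim(window)) != 3 || dim(window)[2] != config$input_window ||
      dim(window)[3] != config$n_input_channels) {
    stop_argument(sprintf(
      "Window must be %d samples x %d channels; got %s.",
      config$input_window, config$n_input_channels,
      paste(dim(window)[-1], collapse = " x ")
    ))
  }
  out <- lstm_forward_cached(model$params, config, window)$pred
  colnames(out) <- tumor_cols()[seq_len(config$output_dim)]
  out
}

# Backpropagation through time for the MSE loss on one batch.
lstm_loss_grad <- function(params, config, X, Y, ...) {
  fw <- lstm_forward_cached(params, config, X)
  err <- fw$pred - Y
  loss <- mean(err^2)
  dpred <- 2 * err / length(err)
  B <- dim(X)[1]
  T_len <- dim(X)[2]
  H <- config$hidden_units

  grads <- params
  grads$Wout <- crossprod(fw$h_top, dpred)
  grads$bout <- colSums(dpred)

  # dh_seq[[t]]: gradient flowing into layer l's hidden output at step t
  dh_seq <- rep(list(matrix(0, B, H)), T_len)
  dh_seq[[T_len]] <- dpred %*% t(params$Wout)

  for (l in rev(seq_len(config$n_layers))) {
    lp <- params$layers[[l]]
    steps <- fw$caches[[l]]
    in_dim <- nrow(lp$Wx)
    dWx <- matrix(0, in_dim, 4 * H)
    dWh <- matrix(0, H, 4 * H)
    db <- numeric(4 * H)
    dx_seq <- vector("list", T_len)
    dh_next <- matrix(0, B, H)
    dc_next <- matrix(0, B, H)
    for (t in rev(seq_len(T_len))) {
      st <- steps[[t]]
      dh <- dh_seq[[t]] + dh_next
      do <- dh * st$tc
      dc <- dh * st$o * (1 - st$tc^2) + dc_next
      di <- dc * st$g
      df <- dc * st$c_prev
      dg <- dc * st$i
      dc_next <- dc * st$f
      dG <- cbind(di * st$i * (1 - st$i),
                  df * st$f * (1 - st$f),
                  dg * (1 - st$g^2),
                  do * st$o * (1 - st$o))
      dWx <- dWx + crossprod(st$x, dG)
      dWh <- dWh + crossprod(st$h_prev, dG)
      db <- db + colSums(dG)
      dx_seq[[t]] <- dG %*% t(lp$Wx)
      dh_next <- dG %*% t(lp$Wh)
    }
    grads$layers[[l]]$Wx <- dWx
    grads$layers[[l]]$Wh <- dWh
    grads$layers[[l]]$b <- db
    dh_seq <- dx_seq
  }
  list(loss = loss, grads = grads, pred = fw$pred)
}
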