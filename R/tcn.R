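#' Temporal convolutional network configuration
#'
#' The network stacks `n_layers` residual levels of causal dilated 1D
#' convolutions. Level `l` uses dilation `dilation_base^(l - 1)` (so the
#' lowest level samples every signal, the next every second one, and so on),
#' every hidden layer keeps the temporal length of the input window, and the
#' prediction is read linearly from the final time step's features. The
#' defaults are the grid-search-selected architecture: 5 levels, filter size
#' 9, 15-sample input window.
#'
#' @param n_layers Number of residual levels `n` (>= 1).
#' @param filter_size Convolution kernel size `k` (>= 1).
#' @param dilation_base Base of the dilation schedule (2).
#' @param channels_per_layer Hidden feature channels per level.
#' @param input_window Input window length `t_delay`, samples.
#' @param n_input_channels Input channels `C` (3 per marker; 9 for 3 markers).
#' @param output_dim Output dimension (3: SI, AP, LR).
#' @param dropout_rate Dropout probability inside residual branches
#'   (training only; 0 by default).
#' @param use_residual If `FALSE`, residual skip connections are removed
#'   (ablation mode) and each level is just its convolutional branch.
#' @param convs_per_block Convolutions per residual branch (1 or 2;
#'   canonical TCN blocks use 2).
#' @param seed Seed for weight initialization.
#' @return A `tcn_config` list.
#' @export
tcn_config <- function(n_layers = 5, filter_size = 9, dilation_base = 2,
                       channels_per_layer = 32, input_window = 15,
                       n_input_channels = 9, output_dim = 3,
                       dropout_rate = 0, use_residual = TRUE,
                       convs_per_block = 2, seed = 1L) {
  cfg <- list(
    n_layers = as.integer(check_scalar_number(n_layers, "n_layers", lower = 1)),
    filter_size = as.integer(check_scalar_number(filter_size, "filter_size", lower = 1)),
    dilation_base = as.integer(check_scalar_number(dilation_base, "dilation_base", lower = 1)),
    channels_per_layer = as.integer(check_scalar_number(channels_per_layer, "channels_per_layer", lower = 1)),
    input_window = as.integer(check_scalar_number(input_window, "input_window", lower = 1)),
    n_input_channels = as.integer(check_scalar_number(n_input_channels, "n_input_channels", lower = 1)),
    output_dim = as.integer(check_scalar_number(output_dim, "output_dim", lower = 1)),
    dropout_rate = check_scalar_number(dropout_rate, "dropout_rate", 0, 1 - 1e-9),
    use_residual = isTRUE(use_residual),
    convs_per_block = as.integer(check_scalar_number(convs_per_block, "convs_per_block", 1, 2)),
    seed = as.integer(check_scalar_number(seed, "seed"))
  )
  structure(cfg, class = "tcn_config")
}

#' Receptive field of a TCN configuration
#'
#' The span of past input samples that can influence one output value:
#' `1 + convs_per_block * (k - 1) * (base^n - 1) / (base - 1)` for filter
#' size `k`, `n` levels and dilations `base^(l-1)`. For the selected
#' architecture (n = 5, k = 9, 2 convs per block, base 2) this is 497
#' samples — far wider than the 15-sample input window, so the window, not
#' the architecture, is the binding context limit.
#'
#' @param config A [tcn_config()].
#' @return Integer number of samples.
#' @export
receptive_field <- function(config) {
  b <- config$dilation_base
  dil_sum <- if (b == 1) config$n_layers else (b^config$n_layers - 1) / (b - 1)
  as.integer(1 + config$convs_per_block * (config$filter_size - 1) * dil_sum)
}

#' Causal dilated convolution of a single sequence
#'
#' Computes `y[t] = sum_{i=0}^{k-1} kernel[i + 1] * x[t - i * d]`, treating
#' `x[j]` as 0 for `j < 1` (left zero-padding), so the output has the same
#' length as the input and `y[t]` never depends on any `x[j]` with `j > t`:
#' no leakage from the future into the past. `kernel[1]` is the tap on the
#' current sample.
#'
#' @param x Numeric input sequence.
#' @param kernel Numeric kernel of length `k`.
#' @param d Dilation factor (sampling spacing of the taps), >= 1.
#' @return Numeric sequence of `length(x)`.
#' @examples
#' causal_dilated_conv(c(1, 2, 3, 4), kernel = c(1, 1), d = 2) # 1 2 4 6
#' @export
causal_dilated_conv <- function(x, kernel, d = 1) {
  if (length(x) == 0) stop_argument("`x` must be a non-empty sequence.")
  if (length(kernel) < 1) stop_argument("`kernel` must have at least one tap.")
  d <- as.integer(check_scalar_number(d, "d", lower = 1))
  T_len <- length(x)
  y <- numeric(T_len)
  for (i in seq_along(kernel) - 1L) {
    s <- i * d
    if (s >= T_len) break
    y[(s + 1L):T_len] <- y[(s + 1L):T_len] + kernel[i + 1L] * x[1:(T_len - s)]
  }
  y
}

# ---- batched internals -------------------------------------------------
# A batch of N sequences of length T with C channels is stored as an
# (N*T) x C matrix with time fastest within each sequence block.

block_matrix <- function(windows, T_len) {
  if (is.matrix(windows)) {
    windows <- array(windows, dim = c(1L, nrow(windows), ncol(windows)))
  }
  stopifnot(length(dim(windows)) == 3)
  N <- dim(windows)[1]
  C <- dim(windows)[3]
  matrix(aperm(windows, c(2, 1, 3)), nrow = N * dim(windows)[2], ncol = C)
}

# Shift each length-T block by s samples (s > 0: towards later times,
# zero-filled at the start; s < 0: the adjoint, zero-filled at the end).
# Row indices are memoized per (s, T, B) in `cache` across the many calls a
# training run makes.
shift_indices <- function(s, T_len, B, cache = NULL) {
  key <- paste0("s", s, "_", T_len, "_", B)
  if (!is.null(cache)) {
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  t_idx <- seq_len(T_len)
  src <- t_idx - s
  bad_t <- src < 1L | src > T_len
  src[bad_t] <- 1L # placeholder; rows zeroed afterwards
  offsets <- (seq_len(B) - 1L) * T_len
  n_bad <- sum(bad_t)
  out <- list(
    idx = rep.int(offsets, rep.int(T_len, B)) + rep.int(src, B),
    bad = rep.int(offsets, rep.int(n_bad, B)) + rep.int(t_idx[bad_t], B)
  )
  if (!is.null(cache)) cache[[key]] <- out
  out
}

shift_block <- function(M, s, T_len, B, cache = NULL) {
  if (s == 0L) return(M)
  ix <- shift_indices(s, T_len, B, cache)
  out <- M[ix$idx, , drop = FALSE]
  if (length(ix$bad) > 0) out[ix$bad, ] <- 0
  out
}

# Convolution weights are stored stacked: a (k * C_in) x C_out matrix whose
# row block i holds the tap on x[t - (i-1) * d]. The forward pass is then a
# single GEMM on the column-stacked shifted input.
conv_block_forward <- function(X, W, b, k, d, T_len, B, cache = NULL) {
  Cin <- ncol(X)
  n <- nrow(X)
  if (k == 1L) {
    return(list(Y = X %*% W + rep(b, each = n), Xstack = X))
  }
  Xstack <- matrix(0, n, k * Cin)
  Xstack[, seq_len(Cin)] <- X
  for (i in seq_len(k)[-1L]) {
    s <- (i - 1L) * d
    if (s >= T_len) break # taps entirely left of the padded input contribute 0
    Xstack[, ((i - 1L) * Cin + 1L):(i * Cin)] <- shift_block(X, s, T_len, B, cache)
  }
  list(Y = Xstack %*% W + rep(b, each = n), Xstack = Xstack)
}

conv_block_backward <- function(Xstack, W, k, d, T_len, B, dY, Cin, cache = NULL) {
  dW <- crossprod(Xstack, dY)
  dXs <- dY %*% t(W)
  dX <- dXs[, seq_len(Cin), drop = FALSE]
  if (k > 1L) {
    for (i in seq_len(k)[-1L]) {
      s <- (i - 1L) * d
      if (s >= T_len) break
      dX <- dX + shift_block(dXs[, ((i - 1L) * Cin + 1L):(i * Cin), drop = FALSE],
                             -s, T_len, B, cache)
    }
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

init_conv_weights <- function(k, c_in, c_out) {
  bound <- 1 / sqrt(k * c_in)
  matrix(stats::runif(k * c_in * c_out, -bound, bound), k * c_in, c_out)
}

#' Initialize a TCN model
#'
#' Weights are drawn fan-in-scaled uniform from the config seed; the same
#' seed always yields the same model. A 1x1 projection is allocated on the
#' skip path of any residual level whose input and output channel counts
#' differ (normally just the first).
#'
#' @param config A [tcn_config()].
#' @return A `tcn_model` list with elements `config` and `params`.
#' @export
tcn_init <- function(config) {
  stopifnot(inherits(config, "tcn_config"))
  with_seed(config$seed, {
    k <- config$filter_size
    ch <- config$channels_per_layer
    levels <- vector("list", config$n_layers)
    c_in <- config$n_input_channels
    for (l in seq_len(config$n_layers)) {
      convs <- vector("list", config$convs_per_block)
      cc <- c_in
      for (j in seq_len(config$convs_per_block)) {
        convs[[j]] <- list(W = init_conv_weights(k, cc, ch), b = numeric(ch))
        cc <- ch
      }
      P <- NULL
      if (config$use_residual && c_in != ch) {
        bound <- 1 / sqrt(c_in)
        P <- matrix(stats::runif(c_in * ch, -bound, bound), c_in, ch)
      }
      levels[[l]] <- list(convs = convs, P = P)
      c_in <- ch
    }
    bound <- 1 / sqrt(ch)
    params <- list(
      levels = levels,
      Wout = matrix(stats::runif(ch * config$output_dim, -bound, bound),
                    ch, config$output_dim),
      bout = numeric(config$output_dim)
    )
    structure(list(family = "tcn", config = config, params = params),
              class = c("tcn_model", "motion_model"))
  })
}

relu <- function(x) x * (x > 0)

# Full forward pass keeping the per-level caches needed for backprop.
tcn_forward_cached <- function(params, config, Xblock, B, training = FALSE,
                               shift_cache = NULL) {
  T_len <- config$input_window
  d_base <- config$dilation_base
  p_drop <- if (training) config$dropout_rate else 0
  H <- Xblock
  caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    lv <- params$levels[[l]]
    d <- d_base^(l - 1L)
    cache <- list(H_in = H, Z = list(), A = list(), masks = list(), Xstack = list())
    A <- H
    for (j in seq_along(lv$convs)) {
      cv <- conv_block_forward(A, lv$convs[[j]]$W, lv$convs[[j]]$b,
                               config$filter_size, d, T_len, B, shift_cache)
      Z <- cv$Y
      cache$Z[[j]] <- Z
      cache$Xstack[[j]] <- cv$Xstack
      cache$Cin[[j]] <- ncol(A)
      A <- relu(Z)
      if (p_drop > 0) {
        mask <- matrix(stats::runif(length(A)) >= p_drop, nrow(A), ncol(A)) / (1 - p_drop)
        cache$masks[[j]] <- mask
        A <- A * mask
      }
      cache$A[[j]] <- A
    }
    if (config$use_residual) {
      S <- if (is.null(lv$P)) H else H %*% lv$P
      pre <- S + A
    } else {
      pre <- A
    }
    cache$pre <- pre
    H <- relu(pre)
    caches[[l]] <- cache
  }
  last_rows <- seq_len(B) * T_len
  Hlast <- H[last_rows, , drop = FALSE]
  pred <- Hlast %*% params$Wout + matrix(params$bout, B, config$output_dim, byrow = TRUE)
  list(pred = pred, H = H, Hlast = Hlast, caches = caches, last_rows = last_rows)
}

#' TCN forward pass (inference)
#'
#' @param model A [tcn_init()] result (or the model inside a fitted object).
#' @param window A `t_delay x C` matrix for one window, or an
#'   `N x t_delay x C` array for a batch.
#' @return A numeric `N x output_dim` matrix of predictions (one row for a
#'   single window). Deterministic: dropout is inactive at inference.
#' @export
tcn_forward <- function(model, window) {
  config <- model$config
  single <- is.matrix(window)
  if (single) window <- array(window, dim = c(1L, nrow(window), ncol(window)))
  if (length(dim(window)) != 3 || dim(window)[2] != config$input_window ||
      dim(window)[3] != config$n_input_channels) {
    stop_argument(sprintf(
      "Window must be %d samples x %d channels; got %s.",
      config$input_window, config$n_input_channels,
      paste(dim(window)[-1], collapse = " x ")
    ))
  }
  B <- dim(window)[1]
  out <- tcn_forward_cached(model$params, config, block_matrix(window, config$input_window),
                            B, training = FALSE)$pred
  colnames(out) <- tumor_cols()[seq_len(config$output_dim)]
  out
}

# Mean-squared-error loss and parameter gradients for one batch.
tcn_loss_grad <- function(params, config, Xblock, Y, B, training = TRUE,
                          shift_cache = NULL) {
  fw <- tcn_forward_cached(params, config, Xblock, B, training = training,
                           shift_cache = shift_cache)
  err <- fw$pred - Y
  loss <- mean(err^2)
  dpred <- 2 * err / length(err)
  T_len <- config$input_window

  grads <- params
  grads$Wout <- crossprod(fw$Hlast, dpred)
  grads$bout <- colSums(dpred)
  dH <- matrix(0, nrow(fw$H), ncol(fw$H))
  dH[fw$last_rows, ] <- dpred %*% t(params$Wout)

  for (l in rev(seq_len(config$n_layers))) {
    lv <- params$levels[[l]]
    cache <- fw$caches[[l]]
    d <- config$dilation_base^(l - 1L)
    dpre <- dH * (cache$pre > 0)
    dA <- dpre
    dH_in <- matrix(0, nrow(cache$H_in), ncol(cache$H_in))
    if (config$use_residual) {
      if (is.null(lv$P)) {
        dH_in <- dH_in + dpre
      } else {
        grads$levels[[l]]$P <- crossprod(cache$H_in, dpre)
        dH_in <- dH_in + dpre %*% t(lv$P)
      }
    }
    for (j in rev(seq_along(lv$convs))) {
      if (config$dropout_rate > 0 && training && length(cache$masks) >= j) {
        dA <- dA * cache$masks[[j]]
      }
      dZ <- dA * (cache$Z[[j]] > 0)
      bk <- conv_block_backward(cache$Xstack[[j]], lv$convs[[j]]$W,
                                config$filter_size, d, T_len, B, dZ,
                                cache$Cin[[j]], shift_cache)
      grads$levels[[l]]$convs[[j]]$W <- bk$dW
      grads$levels[[l]]$convs[[j]]$b <- bk$db
      dA <- bk$dX
    }
    dH <- dH_in + dA
  }
  list(loss = loss, grads = grads, pred = fw$pred)
}

#' Apply one residual block to a single multichannel sequence
#'
#' The block computes `Activation(X + F(X))`, where `F` is
#' `convs_per_block` rounds of causal dilated convolution followed by the
#' activation (and dropout when configured). With `use_residual = FALSE` the
#' skip path is removed and the block returns `Activation(F(X))` — the
#' ablation variant. A 1x1 projection `P` maps the skip path when channel
#' counts differ.
#'
#' @param x `T x C_in` matrix: one sequence.
#' @param params List with `convs` (each `list(W, b)` where `W` is a
#'   stacked `(k * C_in) x C_out` matrix — row block `i` is the tap on
#'   `x[t - (i - 1) * d]` — or equivalently a list of `k` `C_in x C_out`
#'   matrices; `b` is `numeric(C_out)`) and optional skip projection `P`.
#' @param dilation Dilation factor for every convolution in the block.
#' @param use_residual Keep the skip connection?
#' @param activation `"relu"` or `"identity"`.
#' @return `T x C_out` matrix.
#' @export
residual_block <- function(x, params, dilation = 1, use_residual = TRUE,
                           activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  act <- if (activation == "relu") relu else identity
  x <- as.matrix(x)
  T_len <- nrow(x)
  A <- x
  for (cv in params$convs) {
    W <- if (is.list(cv$W)) do.call(rbind, cv$W) else cv$W
    k <- nrow(W) %/% ncol(A)
    A <- act(conv_block_forward(A, W, cv$b, k, dilation, T_len, 1L)$Y)
  }
  if (use_residual) {
    c_out <- ncol(A)
    S <- if (!is.null(params$P)) {
      x %*% params$P
    } else if (ncol(x) == c_out) {
      x
    } else {
      stop_config(sprintf(
        "Residual skip needs a projection: input has %d channels, branch emits %d.",
        ncol(x), c_out
      ))
    }
    act(S + A)
  } else {
    act(A)
  }
}

n_params <- function(model) {
  length(unlist(model$params, use.names = FALSE))
}
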