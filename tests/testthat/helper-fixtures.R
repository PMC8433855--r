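# Desk-scale study conditions shared across tests: 80-s fractions at 25 Hz
# (60 s training + 20 s test), the selected TCN architecture at reduced
# channel width, 300 Adam iterations.

desk_fraction <- function(seed, duration_s = 80, ...) {
  simulate_fraction(synthetic_config(duration_s = duration_s, seed = seed, ...))
}

desk_spec <- function(ahead_ms = 400, t_delay = 15, t_s = 1500) {
  window_spec(t_delay = t_delay, ahead_ms = ahead_ms, t_s = t_s)
}

desk_tcn <- function(...) tcn_config(channels_per_layer = 8, ...)

desk_opts <- function(seed, max_iterations = 300, ...) {
  train_options(max_iterations = max_iterations, seed = seed, ...)
}

# Brute-force evaluation of the dilated causal convolution, written as the
# double loop it is defined by; the independent oracle for the vectorized op.
conv_oracle <- function(x, kernel, d) {
  T_len <- length(x)
  y <- numeric(T_len)
  for (t in seq_len(T_len)) {
    for (i in seq_along(kernel) - 1L) {
      j <- t - i * d
      if (j >= 1) y[t] <- y[t] + kernel[i + 1L] * x[j]
    }
  }
  y
}

# Scalar evaluation of the LSTM gate equations, element by element.
lstm_step_oracle <- function(x, h_prev, c_prev, Wx, Wh, b) {
  H <- length(h_prev)
  h <- numeric(H)
  cc <- numeric(H)
  sig <- function(z) 1 / (1 + exp(-z))
  for (u in seq_len(H)) {
    pre <- function(block) {
      col <- (block - 1L) * H + u
      sum(x * Wx[, col]) + sum(h_prev * Wh[, col]) + b[col]
    }
    i_u <- sig(pre(1))
    f_u <- sig(pre(2))
    g_u <- tanh(pre(3))
    o_u <- sig(pre(4))
    cc[u] <- f_u * c_prev[u] + i_u * g_u
    h[u] <- o_u * tanh(cc[u])
  }
  list(h = h, c = cc)
}

# Exact two-sided signed-rank p by enumerating every sign assignment.
wilcoxon_enum_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Vs >= v), mean(Vs <= v)))
}
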