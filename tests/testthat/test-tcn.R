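test_that("causal dilated convolution matches hand and brute-force oracles", {
  expect_equal(causal_dilated_conv(c(1, 2, 3, 4), c(1, 1), d = 2), c(1, 2, 4, 6))
  x <- rnorm(20)
  expect_identical(causal_dilated_conv(x, 1, d = 5), x) # k = 1 is the identity
  expect_error(causal_dilated_conv(numeric(0), 1), class = "respredict_argument_error")

  set.seed(11)
  for (case in 1:100) {
    T_len <- sample(1:64, 1)
    k <- sample(1:5, 1)
    d <- sample(1:8, 1)
    x <- rnorm(T_len)
    kern <- rnorm(k)
    expect_equal(causal_dilated_conv(x, kern, d), conv_oracle(x, kern, d),
                 tolerance = 1e-12)
  }
})

test_that("the batched convolution path agrees with the sequence primitive", {
  set.seed(12)
  for (case in 1:20) {
    T_len <- sample(5:40, 1)
    k <- sample(1:5, 1)
    d <- sample(1:6, 1)
    B <- sample(1:4, 1)
    X <- array(rnorm(B * T_len), c(B, T_len, 1))
    kern <- rnorm(k)
    out <- respredict:::conv_block_forward(
      respredict:::block_matrix(X, T_len), matrix(kern, k, 1), 0, k, d, T_len, B
    )$Y
    for (b in seq_len(B)) {
      expect_equal(out[(b - 1) * T_len + seq_len(T_len), 1],
                   causal_dilated_conv(X[b, , 1], kern, d), tolerance = 1e-12)
    }
  }
})

test_that("residual blocks satisfy the O = Activation(X + F(X)) contract", {
  x <- matrix(rnorm(20), 10, 2)
  zero <- list(convs = list(list(W = matrix(0, 6, 2), b = numeric(2))))
  expect_equal(residual_block(x, zero, dilation = 1, activation = "identity"), x)
  expect_equal(residual_block(x, zero, dilation = 1, activation = "relu"),
               pmax(x, 0), ignore_attr = TRUE)
  # without the skip path the zero branch collapses to zero
  expect_equal(residual_block(x, zero, dilation = 1, use_residual = FALSE,
                              activation = "identity"),
               matrix(0, 10, 2), ignore_attr = TRUE)

  # random block equals re-composition from the primitive ops
  set.seed(3)
  k <- 3
  W1 <- matrix(rnorm(k * 2 * 2), k * 2, 2)
  b1 <- rnorm(2)
  params <- list(convs = list(list(W = W1, b = b1)))
  d <- 2
  got <- residual_block(x, params, dilation = d, activation = "relu")
  conv_manual <- matrix(0, 10, 2)
  for (co in 1:2) {
    acc <- rep(b1[co], 10)
    for (tap in 1:k) {
      for (ci in 1:2) {
        acc <- acc + causal_dilated_conv(x[, ci], W1[(tap - 1) * 2 + ci, co] *
                                           c(rep(0, tap - 1), 1), d)
      }
    }
    conv_manual[, co] <- acc
  }
  expect_equal(got, pmax(x + pmax(conv_manual, 0), 0), tolerance = 1e-12,
               ignore_attr = TRUE)

  # channel mismatch without a projection is a configuration error
  wide <- list(convs = list(list(W = matrix(0.1, 2, 4), b = numeric(4))))
  expect_error(residual_block(x, wide, dilation = 1), class = "respredict_config_error")
})

test_that("receptive field formula matches an impulse probe of the network", {
  expect_identical(receptive_field(tcn_config(n_layers = 1, filter_size = 2,
                                              convs_per_block = 1)), 2L)
  expect_identical(receptive_field(tcn_config(n_layers = 5, filter_size = 9)), 497L)
  expect_identical(receptive_field(tcn_config(n_layers = 4, filter_size = 1)), 1L)

  # impulse probe: with all-positive weights, bumping the input inside the
  # receptive field moves the output; outside, it cannot
  cfg <- tcn_config(n_layers = 2, filter_size = 2, channels_per_layer = 1,
                    n_input_channels = 1, input_window = 10, seed = 5)
  rf <- receptive_field(cfg) # 7 < 10
  model <- tcn_init(cfg)
  model$params <- rapply(model$params, abs, how = "replace")
  w <- array(abs(rnorm(10)), c(1, 10, 1))
  base <- tcn_forward(model, w)
  bump <- function(pos) {
    w2 <- w
    w2[1, pos, 1] <- w2[1, pos, 1] + 1
    tcn_forward(model, w2)
  }
  expect_false(isTRUE(all.equal(bump(10 - rf + 1), base)))
  expect_identical(bump(10 - rf), base)
})

test_that("the network is causal and length-preserving at every level", {
  cfg <- tcn_config(n_layers = 3, filter_size = 3, channels_per_layer = 6,
                    n_input_channels = 4, input_window = 12, seed = 9)
  model <- tcn_init(cfg)
  set.seed(20)
  X <- array(rnorm(12 * 4), c(1, 12, 4))
  t0 <- 7L
  X2 <- X
  X2[1, (t0 + 1):12, ] <- X2[1, (t0 + 1):12, ] + rnorm(length(X2[1, (t0 + 1):12, ]))

  fw1 <- respredict:::tcn_forward_cached(model$params, cfg,
                                         respredict:::block_matrix(X, 12), 1L)
  fw2 <- respredict:::tcn_forward_cached(model$params, cfg,
                                         respredict:::block_matrix(X2, 12), 1L)
  for (l in seq_len(cfg$n_layers)) {
    h1 <- respredict:::relu(fw1$caches[[l]]$pre)
    h2 <- respredict:::relu(fw2$caches[[l]]$pre)
    expect_identical(nrow(h1), 12L) # hidden length = input window length
    expect_identical(h1[seq_len(t0), ], h2[seq_len(t0), ]) # exact causality
  }
  expect_false(isTRUE(all.equal(fw1$pred, fw2$pred))) # the future does matter
})

test_that("seeding, readout and parameter accounting behave as specified", {
  cfg <- tcn_config(n_layers = 2, filter_size = 3, channels_per_layer = 5,
                    n_input_channels = 9, input_window = 8, seed = 31)
  w <- array(rnorm(8 * 9), c(1, 8, 9))
  expect_identical(tcn_forward(tcn_init(cfg), w), tcn_forward(tcn_init(cfg), w))

  model <- tcn_init(cfg)
  model$params$Wout[] <- 0
  model$params$bout <- c(1.5, -2, 0.25)
  expect_equal(as.vector(tcn_forward(model, w)), c(1.5, -2, 0.25))
  expect_error(tcn_forward(model, array(0, c(1, 7, 9))),
               class = "respredict_argument_error")

  # residual on/off differ only by the skip projection at the first level
  n_on <- respredict:::n_params(tcn_init(cfg))
  cfg_off <- tcn_config(n_layers = 2, filter_size = 3, channels_per_layer = 5,
                        n_input_channels = 9, input_window = 8, seed = 31,
                        use_residual = FALSE)
  n_off <- respredict:::n_params(tcn_init(cfg_off))
  expect_identical(n_on - n_off, 9L * 5L)
})

test_that("analytic TCN gradients match central finite differences", {
  cfg <- tcn_config(n_layers = 2, filter_size = 3, channels_per_layer = 4,
                    input_window = 8, n_input_channels = 3, seed = 3)
  model <- tcn_init(cfg)
  set.seed(4)
  B <- 5
  X <- array(rnorm(B * 8 * 3), c(B, 8, 3))
  Y <- matrix(rnorm(B * 3), B, 3)
  Xb <- respredict:::block_matrix(X, 8)
  lg <- respredict:::tcn_loss_grad(model$params, cfg, Xb, Y, B)
  th <- respredict:::flatten_params(model$params)
  g <- respredict:::flatten_params(lg$grads)
  eps <- 1e-6
  idx <- sample(length(th), 60)
  for (i in idx) {
    tp <- th; tp[i] <- tp[i] + eps
    tm <- th; tm[i] <- tm[i] - eps
    num <- (respredict:::tcn_loss_grad(respredict:::unflatten_params(tp, model$params),
                                       cfg, Xb, Y, B)$loss -
            respredict:::tcn_loss_grad(respredict:::unflatten_params(tm, model$params),
                                       cfg, Xb, Y, B)$loss) / (2 * eps)
    expect_lt(abs(g[i] - num), 1e-6)
  }
})
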