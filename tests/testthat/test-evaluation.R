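test_that("RMSE metrics match closed forms and the direct-formula oracle", {
  set.seed(31)
  A <- matrix(rnorm(60), 20, 3)
  expect_equal(unname(rmse_by_direction(A, A)), c(0, 0, 0))
  shifted <- A
  shifted[, 1] <- shifted[, 1] + 2 # 2 mm SI offset only
  expect_equal(unname(rmse_by_direction(A, shifted)), c(2, 0, 0))
  expect_equal(rmse_3d(A, shifted), 2)
  pyth <- A
  pyth[, 1] <- pyth[, 1] + 3
  pyth[, 2] <- pyth[, 2] + 4
  expect_equal(rmse_3d(A, pyth), 5)

  B <- A + matrix(rnorm(60, sd = 0.5), 20, 3)
  oracle <- vapply(1:3, function(k) sqrt(sum((A[, k] - B[, k])^2) / 20), numeric(1))
  expect_equal(unname(rmse_by_direction(A, B)), oracle, tolerance = 1e-12)
  # root-sum-of-squares identity ties the 3D error to the per-direction ones
  expect_equal(rmse_3d(A, B), sqrt(sum(oracle^2)), tolerance = 1e-12)
  expect_gte(rmse_3d(A, B), max(oracle))

  expect_error(rmse_by_direction(A, B[1:10, ]), class = "respredict_argument_error")
})

test_that("correlation follows the product-moment form and flags constants", {
  set.seed(32)
  A <- matrix(rnorm(60), 20, 3)
  expect_equal(unname(trace_correlation(A, A)), c(1, 1, 1))
  centered <- sweep(A, 2, colMeans(A))
  expect_equal(unname(trace_correlation(centered, -centered)), c(-1, -1, -1))

  x <- c(1, 2, 4, 7)
  y <- c(2, 1, 5, 6)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- trace_correlation(cbind(x, x, x), cbind(y, y, y))
  expect_equal(unname(got), rep(manual, 3), tolerance = 1e-12)

  const <- A
  const[, 2] <- 1
  expect_warning(cc <- trace_correlation(const, A),
                 class = "respredict_degenerate_correlation")
  expect_true(is.na(cc[["AP"]]))
})

test_that("the no-prediction baseline is the pure latency error", {
  # pure sine SI motion: closed form RMSE = A * sqrt(2) * |sin(pi * delta / tau)|
  rate <- 25
  n <- 4000
  tau <- 4
  amp <- 10
  t <- (seq_len(n) - 1) / rate
  si <- amp * sin(2 * pi * t / tau)
  frac <- fraction(markers = cbind(si, si, si), tumor = cbind(si, 0 * si, 0 * si),
                   sampling_rate_hz = rate, fraction_id = "sine")
  spec <- window_spec(t_delay = 15, t_ahead = 10, t_s = 1000)
  bl <- no_prediction_baseline(frac, spec)
  delta <- spec$t_ahead / rate
  closed <- amp * sqrt(2) * abs(sin(pi * delta / tau))
  expect_equal(unname(rmse_by_direction(bl)[["SI"]]), closed, tolerance = 0.01)

  zero <- no_prediction_baseline(frac, window_spec(t_delay = 15, t_ahead = 0, t_s = 1000))
  expect_equal(rmse_3d(zero), 0)

  # latency error grows with the horizon on the default synthetic trace
  synth <- desk_fraction(seed = 41)
  sweep_rmse <- vapply(c(4, 10, 15, 25), function(ta) {
    rmse_3d(no_prediction_baseline(synth, window_spec(t_delay = 15, t_ahead = ta,
                                                      t_s = 1500)))
  }, numeric(1))
  expect_true(all(diff(sweep_rmse) > 0))
})

test_that("percent reduction reproduces the reported comparisons", {
  expect_equal(percent_reduction(1.36, 0.67), 51)
  expect_equal(percent_reduction(1.36, 0.73), 46)
  expect_equal(percent_reduction(2.5, 2.5), 0)
  expect_warning(out <- percent_reduction(0, 1),
                 class = "respredict_degenerate_reduction")
  expect_true(is.na(out))
})

test_that("the paired signed-rank test matches exact enumeration", {
  expect_warning(deg <- wilcoxon_paired(1:6, 1:6),
                 class = "respredict_degenerate_test")
  expect_true(is.na(deg$p_value))

  # n = 6, all differences positive: the smallest attainable two-sided p
  a <- c(5, 6, 7, 8, 9, 10)
  b <- a - c(1, 2, 1.5, 0.7, 2.2, 1.1)
  out <- wilcoxon_paired(a, b)
  expect_equal(out$p_value, 2 / 2^6)

  set.seed(33)
  for (case in 1:20) {
    n <- sample(5:10, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(wilcoxon_paired(x, y)$p_value, wilcoxon_enum_p(x, y),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_paired(1:4, 1:5), class = "respredict_argument_error")
})

test_that("prediction, baseline and reports align on the stated test range", {
  frac <- desk_fraction(seed = 42, duration_s = 60)
  spec <- window_spec(t_delay = 12, t_ahead = 8, t_s = 1000)
  fit <- fit_motion_model(frac, "tcn", spec = spec,
                          config = desk_tcn(n_layers = 2, filter_size = 3),
                          opts = desk_opts(seed = 5, max_iterations = 40))
  pr <- predict_tumor(fit, frac)
  expect_identical(pr$index[1], 1000L + 12L + 8L) # t_s + t_delay + t_ahead
  expect_identical(pr$index[nrow(pr)], nrow(frac))
  bl <- no_prediction_baseline(frac, spec)
  expect_identical(bl$index, pr$index)
  expect_equal(bl$pred_SI, frac$T_SI[bl$index - 8L])

  ev <- evaluate_prediction(pr)
  expect_identical(nrow(ev), 1L)
  expect_gte(ev$rmse_3d, max(ev$rmse_si, ev$rmse_ap, ev$rmse_lr))
})

test_that("the experiment driver produces the report shapes of the study", {
  cohort <- lapply(51:53, function(s) desk_fraction(seed = s, duration_s = 40))
  subsets <- list(1:3, c(1, 2), c(1, 3), c(2, 3), 1, 2, 3)
  res <- run_experiment(cohort, models = "none", ahead_ms = 400,
                        marker_sets = subsets, t_s = 700, seed = 9)
  expect_identical(nrow(res), 3L * 7L)
  tab <- report_table(res, by = "markers")
  expect_identical(nrow(tab), 4L) # AP, LR, SI, 3D
  expect_identical(ncol(tab), 8L) # direction + 7 marker subsets
  expect_identical(as.character(tab$direction), c("AP", "LR", "SI", "3D"))

  res2 <- run_experiment(cohort[1:2],
                         models = list(
                           tcn = list(family = "tcn", config = desk_tcn(n_layers = 1, filter_size = 3)),
                           none = list(family = "none")
                         ),
                         ahead_ms = c(160, 400),
                         t_s = 700,
                         train_opts = desk_opts(seed = 1, max_iterations = 10),
                         seed = 10)
  expect_identical(nrow(res2), 2L * 2L * 2L)
  expect_setequal(unique(res2$ahead_ms), c(160, 400))
  w <- compare_conditions(res2[res2$ahead_ms == 400, ], "tcn", "none")
  expect_identical(w$n, 2L)
  expect_error(run_experiment(list()), class = "respredict_argument_error")
})
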