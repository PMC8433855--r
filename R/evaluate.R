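#' Predict the tumor trace over a fraction's test segment
#'
#' Slides the fitted model over the test segment exactly as during training:
#' the first prediction targets sample `t_s + t_delay + t_ahead` and the last
#' targets the final sample, so predicted and true positions align one-to-one
#' over that range.
#'
#' @param fit A [fit_motion_model()] result.
#' @param frac The `fraction` to predict on (typically the one it was fit
#'   to; the stored split index `t_s` is reused).
#' @return A `prediction_result` tibble with columns `index` (absolute
#'   sample), `time_s`, true `T_SI`/`T_AP`/`T_LR` and predicted
#'   `pred_SI`/`pred_AP`/`pred_LR`, all mm.
#' @export
predict_tumor <- function(fit, frac) {
  stopifnot(inherits(fit, "motion_fit"))
  spec <- fit$spec
  parts <- split_train_test(frac, spec$t_s)
  test_norm <- apply_normalizer(parts$test, fit$normalizer)
  ds <- make_pairs(test_norm, spec, markers = fit$markers)
  pred_norm <- forward_model(fit$model, ds$inputs)
  pred <- invert_normalizer(pred_norm, fit$normalizer, channels = tumor_cols())
  truth <- tumor_matrix(parts$test)[ds$target_index, , drop = FALSE]
  new_prediction_result(
    truth, pred,
    index = spec$t_s + ds$target_index,
    rate = sampling_rate_hz(frac),
    fraction_id = fraction_id(frac),
    model = toupper(fit$family),
    t_ahead = spec$t_ahead
  )
}

new_prediction_result <- function(truth, pred, index, rate, fraction_id,
                                  model, t_ahead) {
  out <- tibble(
    index = as.integer(index),
    time_s = (index - 1) / rate,
    T_SI = truth[, 1], T_AP = truth[, 2], T_LR = truth[, 3],
    pred_SI = pred[, 1], pred_AP = pred[, 2], pred_LR = pred[, 3]
  )
  attr(out, "fraction_id") <- fraction_id
  attr(out, "model") <- model
  attr(out, "t_ahead") <- as.integer(t_ahead)
  attr(out, "ahead_ms") <- 1000 * t_ahead / rate
  class(out) <- c("prediction_result", class(out))
  out
}

#' The no-prediction (pure latency) baseline
#'
#' Models an uncompensated tracking system: the position it acts on at time
#' `t` is the true tumor position at `t - t_ahead`. Its error is exactly the
#' latency error, the quantity prediction is meant to remove; with
#' `t_ahead = 0` it is error-free by construction. The evaluated range is
#' the same as the model's ([predict_tumor()]), so RMSEs are directly
#' comparable.
#'
#' @param frac A `fraction` tibble.
#' @param spec A [window_spec()].
#' @return A `prediction_result` tibble.
#' @export
no_prediction_baseline <- function(frac, spec) {
  n <- nrow(frac)
  t_start <- spec$t_s + spec$t_delay + spec$t_ahead
  if (t_start > n) stop_argument("Test segment too short for this window spec.")
  index <- seq.int(t_start, n)
  Yt <- tumor_matrix(frac)
  new_prediction_result(
    truth = Yt[index, , drop = FALSE],
    pred = Yt[index - spec$t_ahead, , drop = FALSE],
    index = index,
    rate = sampling_rate_hz(frac),
    fraction_id = fraction_id(frac),
    model = "no prediction",
    t_ahead = spec$t_ahead
  )
}

truth_estimate <- function(truth, estimate) {
  if (missing(estimate) && inherits(truth, "prediction_result")) {
    estimate <- as.matrix(truth[, c("pred_SI", "pred_AP", "pred_LR")])
    truth <- as.matrix(truth[, c("T_SI", "T_AP", "T_LR")])
  }
  truth <- as.matrix(truth)
  estimate <- as.matrix(estimate)
  if (!all(dim(truth) == dim(estimate))) {
    stop_argument("True and predicted traces must have identical dimensions.")
  }
  if (nrow(truth) < 1) stop_argument("Traces must be non-empty.")
  list(truth = truth, estimate = estimate)
}

#' Root-mean-square error per anatomical direction
#'
#' `sqrt(mean((T - T')^2))` per direction over the evaluated range, mm.
#'
#' @param truth A `prediction_result` tibble (then `estimate` is taken from
#'   it), or an n-by-3 matrix of true positions (SI, AP, LR).
#' @param estimate An n-by-3 matrix of predicted positions.
#' @return Named numeric vector `c(SI=, AP=, LR=)`, mm.
#' @export
rmse_by_direction <- function(truth, estimate) {
  te <- truth_estimate(truth, estimate)
  out <- sqrt(colMeans((te$truth - te$estimate)^2))
  names(out) <- DIRECTIONS
  out
}

#' Root-mean-square error of the 3D position
#'
#' The root of the time-average squared Euclidean distance between true and
#' predicted 3D positions. Algebraically, `rmse_3d()^2` equals the sum of
#' the three squared per-direction RMSEs over a common time range, so the 3D
#' value is never smaller than any single direction's.
#'
#' @inheritParams rmse_by_direction
#' @return A single value, mm.
#' @export
rmse_3d <- function(truth, estimate) {
  te <- truth_estimate(truth, estimate)
  sqrt(mean(rowSums((te$truth - te$estimate)^2)))
}

#' Product-moment correlation per direction
#'
#' Pearson correlation between true and predicted traces about their
#' respective means, per direction. A constant trace makes the correlation
#' undefined: the affected direction is returned as `NA` with a classed
#' warning rather than an error.
#'
#' @inheritParams rmse_by_direction
#' @return Named numeric vector `c(SI=, AP=, LR=)` in `[-1, 1]` (or `NA`).
#' @export
trace_correlation <- function(truth, estimate) {
  te <- truth_estimate(truth, estimate)
  if (nrow(te$truth) < 2) stop_argument("Correlation needs at least 2 points.")
  out <- vapply(1:3, function(k) {
    x <- te$truth[, k]
    y <- te$estimate[, k]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warn(sprintf("Correlation undefined for constant %s trace.", DIRECTIONS[k]),
           class = "respredict_degenerate_correlation")
      return(NA_real_)
    }
    stats::cor(x, y)
  }, numeric(1))
  names(out) <- DIRECTIONS
  out
}

#' Percent RMSE reduction relative to a baseline
#'
#' `100 * (1 - model / baseline)`, rounded to whole percent by default (the
#' reporting convention; pass `digits = NULL` for the raw value).
#'
#' @param baseline Baseline RMSE (> 0), mm.
#' @param model Model RMSE, mm.
#' @param digits Rounding digits, or `NULL` for none.
#' @return Percentage (positive = improvement over the baseline).
#' @examples
#' percent_reduction(1.36, 0.67) # 51
#' @export
percent_reduction <- function(baseline, model, digits = 0) {
  if (!is.numeric(baseline) || !is.numeric(model)) {
    stop_argument("RMSEs must be numeric.")
  }
  out <- ifelse(baseline > 0, 100 * (1 - model / baseline), NA_real_)
  if (any(baseline <= 0)) {
    warn("Percent reduction undefined for a zero baseline RMSE.",
         class = "respredict_degenerate_reduction")
  }
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Paired Wilcoxon signed-rank test across fractions
#'
#' Two-sided signed-rank test on the paired differences of per-fraction
#' scores; zero differences are dropped and ties mid-ranked. The exact null
#' distribution is used for up to 25 effective pairs (unless ties force the
#' approximation), the normal approximation with continuity correction
#' above. If every difference is zero the test is degenerate and `NA`s are
#' returned with a classed warning.
#'
#' @param a,b Equal-length numeric vectors of paired per-fraction scores.
#' @return One-row tibble: `statistic` (V), `p_value`, `n` (pairs),
#'   `n_effective` (non-zero differences), `method`.
#' @export
wilcoxon_paired <- function(a, b) {
  if (length(a) != length(b)) stop_argument("Paired samples must have equal length.")
  d <- a - b
  n_eff <- sum(d != 0)
  if (n_eff == 0) {
    warn("All paired differences are zero; the signed-rank test is degenerate.",
         class = "respredict_degenerate_test")
    return(tibble(statistic = NA_real_, p_value = NA_real_,
                  n = length(a), n_effective = 0L, method = "degenerate"))
  }
  exact <- n_eff <= 25
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, exact = exact, correct = TRUE)
  )
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
         n = length(a), n_effective = as.integer(n_eff), method = ht$method)
}

#' Per-fraction evaluation summary
#'
#' @param result A `prediction_result` tibble.
#' @return One-row tibble: identifiers, `n` evaluated points, per-direction
#'   and 3D RMSE (mm), per-direction correlation.
#' @export
evaluate_prediction <- function(result) {
  stopifnot(inherits(result, "prediction_result"))
  r <- rmse_by_direction(result)
  cc <- withCallingHandlers(
    trace_correlation(result),
    respredict_degenerate_correlation = function(w) invokeRestart("muffleWarning")
  )
  tibble(
    fraction_id = attr(result, "fraction_id"),
    model = attr(result, "model"),
    ahead_ms = attr(result, "ahead_ms"),
    n = nrow(result),
    rmse_si = r[["SI"]], rmse_ap = r[["AP"]], rmse_lr = r[["LR"]],
    rmse_3d = rmse_3d(result),
    r_si = cc[["SI"]], r_ap = cc[["AP"]], r_lr = cc[["LR"]]
  )
}

#' Run a cohort experiment: models x ahead times x marker subsets
#'
#' The driver behind the package's comparison tables: for every fraction,
#' model variant, ahead time and marker subset it trains (or, for
#' `"none"`, lags), predicts the test segment and scores RMSEs. Marker
#' subsets retrain with `3 * |subset|` input channels. Ablation studies are
#' expressed as extra model variants (e.g. a TCN with
#' `use_residual = FALSE` or a different `filter_size`).
#'
#' @param cohort List of `fraction` tibbles.
#' @param models Character subset of `c("tcn", "lstm", "none")`, or a named
#'   list of variants `list(label = list(family =, config =, t_delay =,
#'   opts =))`.
#' @param ahead_ms Vector of ahead times, milliseconds.
#' @param marker_sets List of marker index vectors (e.g.
#'   `list(1, c(1, 2), 1:3)`).
#' @param t_s Train/test split index; default 180 s worth of samples
#'   (capped to leave a test segment).
#' @param train_opts Default [train_options()] for trainable variants.
#' @param seed Master seed; per-run seeds are derived from it.
#' @return An `experiment_result` tibble: one row per (fraction, variant,
#'   ahead time, marker subset) with the [evaluate_prediction()] columns
#'   plus `markers`.
#' @export
run_experiment <- function(cohort, models = c("tcn", "lstm", "none"),
                           ahead_ms = 400, marker_sets = NULL, t_s = NULL,
                           train_opts = NULL, seed = 1L) {
  if (length(cohort) < 1) stop_argument("Cohort must contain at least one fraction.")
  if (is.character(models)) {
    models <- stats::setNames(lapply(models, function(m) list(family = m)), models)
  }
  if (is.null(marker_sets)) marker_sets <- list(seq_len(n_markers(cohort[[1]])))
  grid <- tidyr::expand_grid(
    frac_i = seq_along(cohort),
    model_i = seq_along(models),
    ahead = ahead_ms,
    set_i = seq_along(marker_sets)
  )
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    frac <- cohort[[grid$frac_i[g]]]
    variant <- models[[grid$model_i[g]]]
    label <- names(models)[grid$model_i[g]]
    markers <- marker_sets[[grid$set_i[g]]]
    rate <- sampling_rate_hz(frac)
    t_split <- t_s %||% min(nrow(frac) - 50L, as.integer(180 * rate))
    fam <- variant$family
    t_delay <- variant$t_delay %||% (if (identical(fam, "lstm")) 20L else 15L)
    spec <- window_spec(t_delay = t_delay, ahead_ms = grid$ahead[g],
                        sampling_rate_hz = rate, t_s = t_split)
    res <- if (identical(fam, "none")) {
      no_prediction_baseline(frac, spec)
    } else {
      opts <- variant$opts %||% train_opts %||%
        train_options(learning_rate = if (fam == "tcn") 0.001 else 0.01)
      opts$seed <- seeds[g]
      cfg <- variant$config
      if (!is.null(cfg)) cfg$seed <- seeds[g]
      fit <- fit_motion_model(frac, fam, spec = spec, config = cfg,
                              opts = opts, markers = markers)
      predict_tumor(fit, frac)
    }
    ev <- evaluate_prediction(res)
    ev$model <- label
    ev$markers <- paste(markers, collapse = "+")
    rows[[g]] <- ev
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("experiment_result", class(out))
  out
}

#' Summarize an experiment as a direction-by-condition report table
#'
#' Cohort-mean RMSE (unweighted over fractions) per direction and in 3D,
#' one column per condition, values rounded to 2 decimals mm — the layout
#' of the package's comparison tables.
#'
#' @param res An [run_experiment()] result.
#' @param by Condition column: `"model"`, `"markers"` or `"ahead_ms"`.
#' @param digits Rounding digits (2 by convention).
#' @return A tibble with a `direction` column (AP, LR, SI, 3D) and one
#'   column per condition.
#' @export
report_table <- function(res, by = "model", digits = 2) {
  if (!by %in% names(res)) stop_argument(paste0("No such column: ", by))
  means <- res |>
    dplyr::group_by(.data[[by]]) |>
    dplyr::summarise(
      AP = mean(.data$rmse_ap), LR = mean(.data$rmse_lr),
      SI = mean(.data$rmse_si), `3D` = mean(.data$rmse_3d),
      .groups = "drop"
    )
  out <- means |>
    tidyr::pivot_longer(c("AP", "LR", "SI", "3D"),
                        names_to = "direction", values_to = "rmse") |>
    tidyr::pivot_wider(names_from = dplyr::all_of(by), values_from = "rmse") |>
    dplyr::mutate(dplyr::across(-"direction", ~ round(.x, digits)))
  out$direction <- factor(out$direction, levels = c("AP", "LR", "SI", "3D"))
  dplyr::arrange(out, .data$direction)
}

#' Paired comparison of two conditions in an experiment
#'
#' Pairs the per-fraction scores of two conditions and applies
#' [wilcoxon_paired()].
#'
#' @param res An [run_experiment()] result.
#' @param a,b Condition labels (values of `by`).
#' @param by Condition column, default `"model"`.
#' @param metric Score column, default `"rmse_3d"`.
#' @return One-row tibble from [wilcoxon_paired()].
#' @export
compare_conditions <- function(res, a, b, by = "model", metric = "rmse_3d") {
  sa <- dplyr::arrange(res[res[[by]] == a, ], .data$fraction_id)
  sb <- dplyr::arrange(res[res[[by]] == b, ], .data$fraction_id)
  if (nrow(sa) == 0 || nrow(sb) == 0 || nrow(sa) != nrow(sb)) {
    stop_argument("Conditions are missing or not paired across fractions.")
  }
  wilcoxon_paired(sa[[metric]], sb[[metric]])
}
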