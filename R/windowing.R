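#' Windowing specification for supervised pair construction
#'
#' `t_delay` is the input window length in samples (the marker history each
#' prediction sees), `t_ahead` the prediction horizon in samples (the system
#' latency being compensated), and `t_s` the train/test split index: samples
#' `1..t_s` train the model and samples `t_s+1..n` evaluate it. Horizons are
#' more naturally quoted in milliseconds; `ahead_ms` is converted through the
#' sampling rate (400 ms at 25 Hz is 10 samples).
#'
#' @param t_delay Input window length, samples (>= 1).
#' @param t_ahead Prediction horizon, samples (>= 0). Ignored when
#'   `ahead_ms` is given.
#' @param t_s Train/test split index, samples.
#' @param ahead_ms Optional horizon in milliseconds.
#' @param sampling_rate_hz Rate used to convert `ahead_ms`.
#' @return A `window_spec` list with integer fields `t_delay`, `t_ahead`,
#'   `t_s`.
#' @examples
#' window_spec(t_delay = 15, ahead_ms = 400, t_s = 4500) # t_ahead = 10
#' @export
window_spec <- function(t_delay = 15, t_ahead = 10, t_s = 4500,
                        ahead_ms = NULL, sampling_rate_hz = 25) {
  if (!is.null(ahead_ms)) {
    t_ahead <- ahead_to_samples(ahead_ms, sampling_rate_hz)
  }
  spec <- list(
    t_delay = as.integer(check_scalar_number(t_delay, "t_delay", lower = 1)),
    t_ahead = as.integer(check_scalar_number(t_ahead, "t_ahead", lower = 0)),
    t_s = as.integer(check_scalar_number(t_s, "t_s", lower = 1))
  )
  structure(spec, class = "window_spec")
}

#' Convert a horizon in milliseconds to samples
#'
#' @param ahead_ms Horizon in milliseconds.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return Integer number of samples (rounded to nearest).
#' @export
ahead_to_samples <- function(ahead_ms, sampling_rate_hz = 25) {
  as.integer(round(ahead_ms / 1000 * sampling_rate_hz))
}

#' Split a fraction into training and test segments
#'
#' Samples `1..t_s` form the training segment, `t_s+1..n` the test segment;
#' the two never overlap.
#'
#' @param fraction A `fraction` tibble.
#' @param t_s Split index in samples, `1 <= t_s < n`.
#' @return A list with `fraction` tibbles `train` and `test`.
#' @export
split_train_test <- function(fraction, t_s) {
  n <- nrow(fraction)
  t_s <- check_scalar_number(t_s, "t_s")
  if (t_s < 1 || t_s >= n || t_s != round(t_s)) {
    stop_argument(sprintf("t_s must be an integer in [1, %d); got %s.", n, format(t_s)))
  }
  list(
    train = fraction[seq_len(t_s), , drop = FALSE],
    test = fraction[(t_s + 1):n, , drop = FALSE]
  )
}

#' Build supervised sliding-window pairs from an aligned segment
#'
#' Each pair couples a `t_delay`-sample window of marker positions (all
#' selected markers, all 3 directions, stacked as `C = 3 * n_markers`
#' channels) with the tumor 3-vector `t_ahead` samples after the window's
#' end. Windows slide with stride 1, so a segment of length `L` yields
#' `L - t_delay - t_ahead + 1` pairs and the final pair's target is the
#' segment's last sample. No input window reaches past
#' `target_index - t_ahead`: the construction is causal by design.
#'
#' @param segment A `fraction` tibble (typically one side of
#'   [split_train_test()]).
#' @param spec A [window_spec()] (only `t_delay` and `t_ahead` are used).
#' @param markers Integer vector selecting which markers feed the input
#'   (default: all present).
#' @return A `windowed_dataset`: list with `inputs` (N x t_delay x C array),
#'   `targets` (N x 3 matrix, SI/AP/LR), `target_index` (absolute index of
#'   each target within the segment), plus `t_delay`, `t_ahead`,
#'   `channel_names`.
#' @examples
#' frac <- simulate_fraction(synthetic_config(duration_s = 10, seed = 1))
#' ds <- make_pairs(frac, window_spec(t_delay = 15, t_ahead = 10, t_s = 1))
#' dim(ds$inputs)
#' @export
make_pairs <- function(segment, spec, markers = NULL) {
  L <- nrow(segment)
  t_delay <- spec$t_delay
  t_ahead <- spec$t_ahead
  n_pairs <- L - t_delay - t_ahead + 1L
  if (n_pairs < 1) {
    stop_argument(sprintf(
      "Segment too short for windowing: need at least t_delay + t_ahead = %d samples, got %d.",
      t_delay + t_ahead, L
    ))
  }
  if (is.null(markers)) markers <- seq_len(n_markers(segment))
  X <- channel_matrix(segment, markers)  # L x C
  C <- ncol(X)
  Y <- tumor_matrix(segment)
  target_index <- seq.int(t_delay + t_ahead, L)
  # inputs[i, j, ] = X[i - 1 + j, ] for window rows j = 1..t_delay
  inputs <- array(NA_real_, dim = c(n_pairs, t_delay, C))
  for (j in seq_len(t_delay)) {
    inputs[, j, ] <- X[seq.int(j, j + n_pairs - 1L), , drop = FALSE]
  }
  structure(list(
    inputs = inputs,
    targets = Y[target_index, , drop = FALSE],
    target_index = target_index,
    t_delay = t_delay,
    t_ahead = t_ahead,
    channel_names = colnames(X)
  ), class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf(
    "<windowed_dataset>  %d pairs, window %d samples x %d channels, horizon %d samples\n",
    nrow(x$targets), x$t_delay, dim(x$inputs)[3], x$t_ahead
  ))
  invisible(x)
}

#' Per-channel z-score normalizer fit on the training segment only
#'
#' Network inputs and targets are standardized channel-by-channel with the
#' training segment's mean and standard deviation; the test segment reuses
#' those statistics, so no test information leaks into training. A constant
#' channel gets scale 1 (its standardized values are all zero).
#'
#' @param segment A `fraction` tibble: the training segment.
#' @return A `trace_normalizer` with named `center` and `scale` vectors
#'   covering every marker and tumor channel present.
#' @export
fit_normalizer <- function(segment) {
  cols <- setdiff(names(segment), "time_s")
  if (nrow(segment) < 1) stop_argument("Cannot fit a normalizer on an empty segment.")
  center <- vapply(cols, function(cn) mean(segment[[cn]]), numeric(1))
  scale <- vapply(cols, function(cn) stats::sd(segment[[cn]]), numeric(1))
  scale[!is.finite(scale) | scale <= 0] <- 1
  structure(list(center = center, scale = scale), class = "trace_normalizer")
}

#' Apply or invert a trace normalizer
#'
#' `apply_normalizer()` standardizes a fraction/segment or the channels of a
#' matrix; `invert_normalizer()` maps standardized values back to mm.
#' `invert(apply(x))` is the identity to floating precision.
#'
#' @param x A `fraction` tibble, or a numeric matrix whose columns are named
#'   channels (e.g. predicted `T_SI`, `T_AP`, `T_LR`).
#' @param normalizer A [fit_normalizer()] result.
#' @param channels For matrix input: the channel names of the columns.
#' @return Same shape as `x`.
#' @export
apply_normalizer <- function(x, normalizer, channels = colnames(x)) {
  transform_normalizer(x, normalizer, channels, invert = FALSE)
}

#' @rdname apply_normalizer
#' @export
invert_normalizer <- function(x, normalizer, channels = colnames(x)) {
  transform_normalizer(x, normalizer, channels, invert = TRUE)
}

transform_normalizer <- function(x, normalizer, channels, invert) {
  stopifnot(inherits(normalizer, "trace_normalizer"))
  if (is.data.frame(x)) {
    cols <- intersect(names(x), names(normalizer$center))
    for (cn in cols) {
      x[[cn]] <- if (invert) {
        x[[cn]] * normalizer$scale[[cn]] + normalizer$center[[cn]]
      } else {
        (x[[cn]] - normalizer$center[[cn]]) / normalizer$scale[[cn]]
      }
    }
    x
  } else {
    x <- as.matrix(x)
    if (is.null(channels)) stop_argument("Matrix input needs `channels` names.")
    missing <- setdiff(channels, names(normalizer$center))
    if (length(missing) > 0) {
      stop_argument(paste0("Normalizer has no statistics for: ",
                           paste(missing, collapse = ", ")))
    }
    ctr <- normalizer$center[channels]
    scl <- normalizer$scale[channels]
    if (invert) {
      sweep(sweep(x, 2, scl, "*"), 2, ctr, "+")
    } else {
      sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
    }
  }
}
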