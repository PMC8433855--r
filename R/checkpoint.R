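#' Save or load a fitted model checkpoint
#'
#' Checkpoints are versioned JSON text files holding the model family, its
#' configuration, the window spec, the marker selection, the normalizer
#' statistics and the flat parameter vector at 17 significant digits, so a
#' reloaded model bit-reproduces inference.
#'
#' @param fit A [fit_motion_model()] result.
#' @param path File path for the checkpoint.
#' @return `save_checkpoint()` the path invisibly; `load_checkpoint()` a
#'   `motion_fit` (without training history).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "motion_fit"))
  payload <- list(
    format = "respredict-checkpoint",
    version = 1L,
    family = fit$family,
    config = unclass(fit$model$config),
    spec = unclass(fit$spec),
    markers = fit$markers,
    normalizer = list(
      channels = names(fit$normalizer$center),
      center = unname(fit$normalizer$center),
      scale = unname(fit$normalizer$scale)
    ),
    fraction_id = fit$fraction_id,
    sampling_rate_hz = fit$sampling_rate_hz,
    params = flatten_params(fit$model$params)
  )
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_argument(paste0("No such checkpoint: ", path))
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(payload$format, "respredict-checkpoint")) {
    stop_format("Not a respredict checkpoint file.")
  }
  family <- payload$family
  cfg <- payload$config
  model <- if (family == "tcn") {
    cfg$use_residual <- isTRUE(cfg$use_residual)
    tcn_init(do.call(tcn_config, cfg))
  } else {
    lstm_init(do.call(lstm_config, cfg))
  }
  model$params <- unflatten_params(as.numeric(payload$params), model$params)
  normalizer <- structure(list(
    center = stats::setNames(payload$normalizer$center, payload$normalizer$channels),
    scale = stats::setNames(payload$normalizer$scale, payload$normalizer$channels)
  ), class = "trace_normalizer")
  structure(list(
    family = family,
    model = model,
    history = tibble(iteration = integer(), cost = numeric()),
    normalizer = normalizer,
    spec = do.call(window_spec, payload$spec[c("t_delay", "t_ahead", "t_s")]),
    markers = as.integer(payload$markers),
    opts = NULL,
    fraction_id = payload$fraction_id,
    sampling_rate_hz = payload$sampling_rate_hz
  ), class = "motion_fit")
}
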