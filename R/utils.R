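#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Canonical anatomical direction order, used everywhere (storage, APIs, reports).
DIRECTIONS <- c("SI", "AP", "LR")

marker_cols <- function(m) paste0("M", m, "_", DIRECTIONS)
tumor_cols <- function() paste0("T_", DIRECTIONS)

stop_argument <- function(msg) abort(msg, class = "respredict_argument_error")
stop_format <- function(msg) abort(msg, class = "respredict_format_error")
stop_validation <- function(msg) abort(msg, class = "respredict_validation_error")
stop_config <- function(msg) abort(msg, class = "respredict_config_error")
stop_training <- function(msg, iteration = NA_integer_) {
  abort(msg, class = "respredict_training_error", iteration = iteration)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop_argument("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive independent sub-seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    stop_argument(sprintf("`%s` must be a single finite number in [%s, %s].",
                          name, format(lower), format(upper)))
  }
  x
}
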