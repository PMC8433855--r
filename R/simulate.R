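#' Configuration for the synthetic respiratory-motion generator
#'
#' The generator emulates the statistical structure of Synchrony-style
#' treatment-fraction logs: a quasi-periodic latent breathing signal drives
#' an SI-dominant internal tumor trace and 1-3 external marker traces that
#' are noisy, gain-scaled and slightly time-lagged copies of it, plus a slow
#' baseline drift and additive sensor noise.
#'
#' The latent waveform is a cosine raised to an even power,
#' `b(t) = cos(pi * phase)^(2p)`, valued in `[0, 1]`: flat around the trough
#' and sharp at the peak, a standard idealization of tidal breathing. Its
#' period and depth are re-drawn every breathing cycle (`period_jitter_frac`,
#' `amplitude_jitter_frac`) to mimic cycle-to-cycle variability.
#'
#' @param duration_s Trace duration in seconds. Default 210 s: about 3
#'   minutes of training signal plus 30 s of test signal per fraction.
#' @param sampling_rate_hz Sampling rate, Hz (25 as in the source logs).
#' @param period_s Mean breathing period tau in seconds (typical 3-6).
#' @param shape_exponent Positive integer `p`; the waveform is `cos^(2p)`.
#' @param tumor_amplitude_mm Length-3 (SI, AP, LR) peak-to-trough tumor
#'   amplitudes, mm. SI-dominant by default; lung/liver tumors can move up
#'   to ~3 cm, so the 10 mm default is mid-range.
#' @param drift_mm_per_min Length-3 linear baseline drift, mm per minute.
#' @param period_jitter_frac Per-cycle relative period jitter in `[0, 1)`.
#' @param amplitude_jitter_frac Per-cycle relative depth jitter in `[0, 1)`.
#' @param marker_gains n_markers-by-3 matrix coupling each marker/direction
#'   to the latent signal, mm per unit of `b`.
#' @param marker_lag_s Per-marker time lag of the latent signal, seconds
#'   (surrogate motion leads/lags internal motion).
#' @param noise_sd_mm Standard deviation of i.i.d. Gaussian sensor noise, mm.
#' @param seed Integer seed; the seed fully determines the output.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(duration_s = 210,
                             sampling_rate_hz = 25,
                             period_s = 4,
                             shape_exponent = 2,
                             tumor_amplitude_mm = c(10, 4, 3),
                             drift_mm_per_min = c(1, 0.3, 0.2),
                             period_jitter_frac = 0.05,
                             amplitude_jitter_frac = 0.1,
                             marker_gains = default_marker_gains(),
                             marker_lag_s = c(0.04, 0.08, 0.16),
                             noise_sd_mm = 0.15,
                             seed = 1L) {
  cfg <- list(
    duration_s = check_scalar_number(duration_s, "duration_s", lower = 1e-9),
    sampling_rate_hz = check_scalar_number(sampling_rate_hz, "sampling_rate_hz", lower = 1e-9),
    period_s = check_scalar_number(period_s, "period_s", lower = 1e-9),
    shape_exponent = as.integer(check_scalar_number(shape_exponent, "shape_exponent", lower = 1)),
    tumor_amplitude_mm = as.numeric(tumor_amplitude_mm),
    drift_mm_per_min = as.numeric(drift_mm_per_min),
    period_jitter_frac = check_scalar_number(period_jitter_frac, "period_jitter_frac", 0, 1 - 1e-9),
    amplitude_jitter_frac = check_scalar_number(amplitude_jitter_frac, "amplitude_jitter_frac", 0, 1 - 1e-9),
    marker_gains = as.matrix(marker_gains),
    marker_lag_s = as.numeric(marker_lag_s),
    noise_sd_mm = check_scalar_number(noise_sd_mm, "noise_sd_mm", lower = 0),
    seed = as.integer(check_scalar_number(seed, "seed"))
  )
  if (length(cfg$tumor_amplitude_mm) != 3 || any(!is.finite(cfg$tumor_amplitude_mm)) ||
      any(cfg$tumor_amplitude_mm < 0)) {
    stop_config("tumor_amplitude_mm must be 3 nonnegative finite values (SI, AP, LR).")
  }
  if (length(cfg$drift_mm_per_min) != 3 || any(!is.finite(cfg$drift_mm_per_min))) {
    stop_config("drift_mm_per_min must be 3 finite values (SI, AP, LR).")
  }
  nm <- nrow(cfg$marker_gains)
  if (is.null(nm) || nm < 1 || nm > 3 || ncol(cfg$marker_gains) != 3 ||
      any(!is.finite(cfg$marker_gains))) {
    stop_config("marker_gains must be a finite (1-3)-by-3 matrix (marker x direction).")
  }
  if (length(cfg$marker_lag_s) != nm || any(!is.finite(cfg$marker_lag_s))) {
    stop_config("marker_lag_s must supply one finite lag per marker.")
  }
  structure(cfg, class = "synthetic_config")
}

default_marker_gains <- function() {
  # Chest/abdomen surrogates: SI-dominant like the tumor, differing gains
  # per marker so channels are correlated but not identical.
  matrix(c(8, 3.0, 2.0,
           6, 2.5, 1.5,
           7, 2.0, 2.5),
         nrow = 3, byrow = TRUE,
         dimnames = list(paste0("M", 1:3), DIRECTIONS))
}

# Latent breathing signal as a function of continuous time (seconds).
# Cycles are drawn left of t = 0 so lagged evaluation stays in range.
make_breathing_signal <- function(period_s, shape_exponent,
                                  period_jitter_frac, amplitude_jitter_frac,
                                  t_min, t_max) {
  span <- t_max - t_min + 4 * period_s
  n_cycles <- ceiling(span / (period_s * (1 - period_jitter_frac))) + 4L
  periods <- period_s * (1 + stats::runif(n_cycles, -period_jitter_frac, period_jitter_frac))
  depths <- pmax(0, 1 + stats::runif(n_cycles, -amplitude_jitter_frac, amplitude_jitter_frac))
  starts <- t_min - 2 * period_s + c(0, cumsum(periods[-n_cycles]))
  function(t) {
    j <- findInterval(t, starts)
    j[j < 1L] <- 1L
    j[j > n_cycles] <- n_cycles
    phase <- (t - starts[j]) / periods[j]
    depths[j] * cos(pi * phase)^(2L * shape_exponent)
  }
}

#' Simulate one synthetic treatment fraction
#'
#' Tumor trace (direction k): `amplitude[k] * b(t) + drift[k] * t + noise`;
#' marker m, direction k: `gains[m, k] * b(t - lag[m]) + noise`, with
#' independent Gaussian noise per channel. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A `fraction` tibble.
#' @examples
#' frac <- simulate_fraction(synthetic_config(duration_s = 30, seed = 7))
#' frac
#' @export
simulate_fraction <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  with_seed(config$seed, {
    n <- round(config$duration_s * config$sampling_rate_hz)
    if (n < 1) stop_config("duration_s x sampling_rate_hz must give at least 1 sample.")
    t <- (seq_len(n) - 1) / config$sampling_rate_hz
    max_lag <- max(c(0, config$marker_lag_s))
    b <- make_breathing_signal(config$period_s, config$shape_exponent,
                               config$period_jitter_frac, config$amplitude_jitter_frac,
                               t_min = -max_lag, t_max = max(t))
    bt <- b(t)
    drift <- outer(t / 60, config$drift_mm_per_min)
    tumor <- outer(bt, config$tumor_amplitude_mm) + drift
    if (config$noise_sd_mm > 0) {
      tumor <- tumor + matrix(stats::rnorm(n * 3, sd = config$noise_sd_mm), n, 3)
    }
    nm <- nrow(config$marker_gains)
    markers <- lapply(seq_len(nm), function(m) {
      bl <- b(t - config$marker_lag_s[m])
      tr <- outer(bl, config$marker_gains[m, ])
      if (config$noise_sd_mm > 0) {
        tr <- tr + matrix(stats::rnorm(n * 3, sd = config$noise_sd_mm), n, 3)
      }
      tr
    })
    fraction(markers, tumor,
             sampling_rate_hz = config$sampling_rate_hz,
             fraction_id = sprintf("synthetic-%d", config$seed))
  })
}

#' Simulate a cohort of synthetic fractions
#'
#' Draws `n_fractions` fractions whose breathing period, amplitudes and drift
#' are independently perturbed around `base_config`, emulating between-session
#' and between-patient variability. Deterministic given `seed`.
#'
#' @param n_fractions Number of fractions (the emulated study used 69).
#' @param base_config A [synthetic_config()] supplying the central values.
#' @param variability List of spreads: `period_s` (additive, uniform +/-),
#'   `amplitude_frac` and `drift_frac` (multiplicative, uniform
#'   `1 +/- frac`). Use zeros for a homogeneous cohort.
#' @param seed Master seed; per-fraction seeds are derived from it.
#' @return A list of `fraction` tibbles, named by fraction id.
#' @export
simulate_cohort <- function(n_fractions,
                            base_config = synthetic_config(),
                            variability = list(period_s = 1, amplitude_frac = 0.3,
                                               drift_frac = 0.5),
                            seed = 1L) {
  n_fractions <- as.integer(check_scalar_number(n_fractions, "n_fractions", lower = 1))
  if (!inherits(base_config, "synthetic_config")) {
    base_config <- do.call(synthetic_config, base_config)
  }
  v <- utils::modifyList(list(period_s = 0, amplitude_frac = 0, drift_frac = 0),
                         as.list(variability))
  draws <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1L, n_fractions),
    period = stats::runif(n_fractions, -v$period_s, v$period_s),
    amp = stats::runif(n_fractions, 1 - v$amplitude_frac, 1 + v$amplitude_frac),
    drift = stats::runif(n_fractions, 1 - v$drift_frac, 1 + v$drift_frac)
  ))
  out <- lapply(seq_len(n_fractions), function(i) {
    cfg <- base_config
    cfg$period_s <- max(0.5, cfg$period_s + draws$period[i])
    cfg$tumor_amplitude_mm <- cfg$tumor_amplitude_mm * draws$amp[i]
    cfg$marker_gains <- cfg$marker_gains * draws$amp[i]
    cfg$drift_mm_per_min <- cfg$drift_mm_per_min * draws$drift[i]
    cfg$seed <- draws$seeds[i]
    frac <- simulate_fraction(cfg)
    attr(frac, "fraction_id") <- sprintf("synthetic-%03d", i)
    frac
  })
  names(out) <- vapply(out, fraction_id, character(1))
  out
}
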