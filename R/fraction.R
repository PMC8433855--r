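#' Build a treatment-fraction trace table
#'
#' A fraction is one radiotherapy treatment session's worth of aligned motion
#' traces: the 3D positions (superior-inferior, anterior-posterior, left-right;
#' always in that order, always in millimetres) of one to three external chest
#' or abdomen markers and of the internal tumor, sampled at a fixed rate
#' (25 Hz for CyberKnife Synchrony logs). Time is implicit: sample `i`
#' corresponds to `(i - 1) / sampling_rate_hz` seconds.
#'
#' The returned object is a tibble with columns `time_s`, `M<m>_SI`, `M<m>_AP`,
#' `M<m>_LR` for each marker `m`, and `T_SI`, `T_AP`, `T_LR` for the tumor,
#' carrying `fraction_id` and `sampling_rate_hz` as attributes. All tibble
#' verbs work on it; functions in this package that need the metadata take the
#' fraction itself.
#'
#' @param markers A single n-by-3 matrix (or data frame) of marker positions,
#'   or a list of up to three such matrices, columns ordered (SI, AP, LR), mm.
#' @param tumor An n-by-3 matrix (or data frame) of tumor positions, same
#'   column order, mm.
#' @param sampling_rate_hz Sampling rate in Hz; 25 matches the source logs.
#' @param fraction_id Identifier string for the session.
#' @return A `fraction` tibble (see Details).
#' @examples
#' b <- sin(seq(0, 4 * pi, length.out = 200))
#' frac <- fraction(
#'   markers = list(cbind(8 * b, 3 * b, 2 * b)),
#'   tumor = cbind(10 * b, 4 * b, 3 * b)
#' )
#' frac
#' @export
fraction <- function(markers, tumor, sampling_rate_hz = 25,
                     fraction_id = "fraction-1") {
  if (is.matrix(markers) || is.data.frame(markers)) markers <- list(markers)
  if (!is.list(markers)) stop_argument("`markers` must be a matrix or a list of matrices.")
  markers <- lapply(markers, as_position_matrix)
  tumor <- as_position_matrix(tumor)
  report <- validate_fraction_parts(markers, tumor, sampling_rate_hz)
  if (nrow(report) > 0) {
    stop_validation(paste0(
      "Invalid fraction:\n", paste0("- ", report$message, collapse = "\n")
    ))
  }
  n <- nrow(tumor)
  cols <- list(time_s = (seq_len(n) - 1) / sampling_rate_hz)
  for (m in seq_along(markers)) {
    cn <- marker_cols(m)
    for (k in 1:3) cols[[cn[k]]] <- markers[[m]][, k]
  }
  tn <- tumor_cols()
  for (k in 1:3) cols[[tn[k]]] <- tumor[, k]
  out <- as_tibble(cols)
  attr(out, "fraction_id") <- as.character(fraction_id)
  attr(out, "sampling_rate_hz") <- as.numeric(sampling_rate_hz)
  class(out) <- c("fraction", class(out))
  out
}

as_position_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 3)
  if (ncol(x) != 3) stop_argument("Position traces must have 3 columns (SI, AP, LR).")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.fraction <- function(x, ...) {
  cat(sprintf(
    "<fraction '%s'>  %d marker(s), %d samples @ %g Hz (%.1f s)\n",
    fraction_id(x), n_markers(x), nrow(x), sampling_rate_hz(x),
    nrow(x) / sampling_rate_hz(x)
  ))
  NextMethod()
}

#' Fraction metadata accessors
#'
#' @param fraction A `fraction` tibble.
#' @return `fraction_id()` a string; `sampling_rate_hz()` Hz;
#'   `n_markers()` the number of external markers present (1-3).
#' @export
fraction_id <- function(fraction) {
  attr(fraction, "fraction_id") %||% "fraction"
}

#' @rdname fraction_id
#' @export
sampling_rate_hz <- function(fraction) {
  as.numeric(attr(fraction, "sampling_rate_hz") %||% 25)
}

#' @rdname fraction_id
#' @export
n_markers <- function(fraction) {
  length(grep("^M[0-9]+_SI$", names(fraction)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numeric matrix of the selected channels; markers may be a subset like c(1, 3).
channel_matrix <- function(fraction, markers = seq_len(n_markers(fraction))) {
  cols <- unlist(lapply(markers, marker_cols))
  missing <- setdiff(cols, names(fraction))
  if (length(missing) > 0) {
    stop_argument(paste0("Marker columns not present: ", paste(missing, collapse = ", ")))
  }
  as.matrix(fraction[, cols, drop = FALSE])
}

tumor_matrix <- function(fraction) {
  as.matrix(fraction[, tumor_cols(), drop = FALSE])
}

# Shared checks for both the constructor-parts form and the tibble form.
validate_fraction_parts <- function(markers, tumor, sampling_rate_hz) {
  findings <- list()
  add <- function(check, message) {
    findings[[length(findings) + 1L]] <<- tibble(check = check, message = message)
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    add("sampling_rate", "sampling_rate_hz must be a single positive finite number")
  }
  nm <- length(markers)
  if (nm < 1 || nm > 3) {
    add("marker_count", sprintf("expected 1-3 markers, got %d", nm))
  }
  n <- nrow(tumor)
  if (is.null(n) || n < 1) {
    add("n_samples", "traces must contain at least one sample (n_samples > 0)")
  }
  lens <- vapply(markers, nrow, integer(1))
  if (length(lens) > 0 && any(lens != n)) {
    add("length_mismatch", sprintf(
      "all traces must have equal length: tumor has %d samples, markers have %s",
      n, paste(lens, collapse = ", ")
    ))
  }
  for (m in seq_along(markers)) {
    bad <- which(!is.finite(markers[[m]]), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      add("non_finite", sprintf(
        "marker %d has non-finite values (first at row %d, direction %s)",
        m, bad[1, 1], DIRECTIONS[bad[1, 2]]
      ))
    }
  }
  bad <- which(!is.finite(tumor), arr.ind = TRUE)
  if (!is.null(nrow(bad)) && nrow(bad) > 0) {
    add("non_finite", sprintf(
      "tumor trace has non-finite values (first at row %d, direction %s)",
      bad[1, 1], DIRECTIONS[bad[1, 2]]
    ))
  }
  if (length(findings) == 0) {
    tibble(check = character(), message = character())
  } else {
    dplyr::bind_rows(findings)
  }
}

#' Validate a fraction and report every invariant violation
#'
#' A reporting operation: it never raises on malformed content. An empty
#' report means the fraction satisfies all invariants (equal trace lengths,
#' positive sampling rate, 1-3 markers, at least one sample, finite values).
#'
#' @param fraction A `fraction` tibble, or a list with elements `markers`
#'   (list of n-by-3 matrices), `tumor` (n-by-3 matrix) and
#'   `sampling_rate_hz` — the pre-assembly form, which allows reporting on
#'   traces of unequal length that could never form a rectangular table.
#' @return A tibble with columns `check` and `message`, one row per finding.
#' @examples
#' frac <- fraction(matrix(0, 10, 3), matrix(0, 10, 3))
#' validate_fraction(frac) # zero rows
#' @export
validate_fraction <- function(fraction) {
  if (is.data.frame(fraction)) {
    nm <- n_markers(fraction)
    markers <- if (nm >= 1) {
      lapply(seq_len(nm), function(m) {
        as_position_matrix(fraction[, marker_cols(m), drop = FALSE])
      })
    } else {
      list()
    }
    has_tumor <- all(tumor_cols() %in% names(fraction))
    tumor <- if (has_tumor) tumor_matrix(fraction) else matrix(numeric(), 0, 3)
    rep <- validate_fraction_parts(markers, tumor, sampling_rate_hz(fraction))
    if (!has_tumor) {
      rep <- dplyr::bind_rows(rep, tibble(
        check = "missing_column",
        message = paste0("tumor columns missing: ",
                         paste(setdiff(tumor_cols(), names(fraction)), collapse = ", "))
      ))
    }
    rep
  } else if (is.list(fraction)) {
    validate_fraction_parts(
      fraction$markers %||% list(),
      fraction$tumor %||% matrix(numeric(), 0, 3),
      fraction$sampling_rate_hz %||% NA_real_
    )
  } else {
    tibble(check = "type", message = "not a fraction tibble or parts list")
  }
}

#' Read and write per-fraction trace files
#'
#' Trace files are plain delimited text: `#`-prefixed header lines carry
#' `fraction_id`, `sampling_rate_hz` and `n_markers`; a tab-separated column
#' header and one row per sample follow, column order fixed as
#' `time_s, M1_SI, M1_AP, M1_LR, ..., T_SI, T_AP, T_LR`. Values are written
#' with 17 significant digits so that a write/read cycle reproduces the
#' fraction bit-exactly.
#'
#' @param path File path.
#' @param expected_markers If given, the file's marker count must match.
#' @return `read_fraction()` a validated `fraction` tibble;
#'   `write_fraction()` the path, invisibly.
#' @examples
#' frac <- fraction(matrix(rnorm(30), 10, 3), matrix(rnorm(30), 10, 3))
#' tf <- tempfile(fileext = ".tsv")
#' write_fraction(frac, tf)
#' identical(read_fraction(tf), frac)
#' @export
read_fraction <- function(path, expected_markers = NULL) {
  if (!file.exists(path)) stop_argument(paste0("No such trace file: ", path))
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), header, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub(paste0("^#\\s*", key, "\\s*:"), "", hit[1]))
  }
  rate <- as.numeric(meta("sampling_rate_hz") %||% "25")
  id <- meta("fraction_id") %||% basename(path)
  nm_declared <- meta("n_markers")

  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop_format("Trace file has no data rows.")
  df <- utils::read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                          header = TRUE, check.names = FALSE,
                          colClasses = "numeric")
  nm <- if (!is.null(nm_declared)) as.integer(nm_declared) else {
    length(grep("^M[0-9]+_SI$", names(df)))
  }
  if (!is.null(expected_markers) && nm != expected_markers) {
    stop_config(sprintf("Trace file declares %d markers; expected %d.",
                        nm, expected_markers))
  }
  required <- c(unlist(lapply(seq_len(nm), marker_cols)), tumor_cols())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_format(paste0("Trace file is missing column(s): ",
                       paste(missing, collapse = ", ")))
  }
  for (col in required) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0) {
      stop_validation(sprintf(
        "Non-finite value in column %s at data row %d.", col, bad[1]
      ))
    }
  }
  fraction(
    markers = lapply(seq_len(nm), function(m) as.matrix(df[, marker_cols(m)])),
    tumor = as.matrix(df[, tumor_cols()]),
    sampling_rate_hz = rate,
    fraction_id = id
  )
}

#' @param fraction A valid `fraction` tibble.
#' @rdname read_fraction
#' @export
write_fraction <- function(fraction, path) {
  rep <- validate_fraction(fraction)
  if (nrow(rep) > 0) {
    stop_validation(paste0("Refusing to write invalid fraction:\n",
                           paste0("- ", rep$message, collapse = "\n")))
  }
  cols <- names(fraction)
  data_lines <- do.call(paste, c(
    lapply(cols, function(cn) sprintf("%.17g", fraction[[cn]])),
    sep = "\t"
  ))
  out <- c(
    "# respredict trace v1",
    paste0("# fraction_id: ", fraction_id(fraction)),
    sprintf("# sampling_rate_hz: %.17g", sampling_rate_hz(fraction)),
    paste0("# n_markers: ", n_markers(fraction)),
    paste(cols, collapse = "\t"),
    data_lines
  )
  tryCatch(
    writeLines(out, path),
    error = function(e) abort(paste0("Cannot write trace file: ", conditionMessage(e)),
                              class = "respredict_io_error")
  )
  invisible(path)
}
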