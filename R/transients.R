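#' Construct a fluorescence transient
#'
#' A `fluor_transient` holds one fast chlorophyll fluorescence induction
#' (OJIP) trace: a strictly increasing time grid in seconds, the fluorescence
#' signal in arbitrary units, and the sample metadata used downstream
#' (strain, treatment, replicate).
#'
#' The time grid must start at or before 20 microseconds and extend to at
#' least 1 second so that all five protocol markers (O, K, J, I, P) are
#' covered, and the trace must have at least five samples.
#'
#' @param sample_id Sample identifier (scalar character).
#' @param strain Strain label, e.g. `"GM"` (green mutant) or `"WT"`.
#' @param treatment Treatment label, e.g. `"LT"`, `"MT"`, `"HT"`.
#' @param replicate Positive integer replicate number.
#' @param times Numeric vector of times in seconds, strictly increasing.
#' @param values Numeric vector of fluorescence values (> 0), same length as
#'   `times`.
#' @return An object of class `fluor_transient`.
#' @examples
#' tr <- fluor_transient("s1", "GM", "MT", 1,
#'                       times = c(2e-5, 3e-4, 2e-3, 3e-2, 1),
#'                       values = c(500, 668.75, 837.5, 1100, 1250))
#' extract_markers(tr)
#' @export
fluor_transient <- function(sample_id, strain, treatment, replicate,
                            times, values) {
  x <- structure(
    list(
      sample_id = as.character(sample_id),
      strain = as.character(strain),
      treatment = as.character(treatment),
      replicate = as.integer(replicate),
      times = as.double(times),
      values = as.double(values)
    ),
    class = "fluor_transient"
  )
  validate_transient(x)
}

#' Validate a fluorescence transient
#'
#' Checks the `fluor_transient` invariants: equal-length positive signal,
#' strictly increasing times, at least five samples, and a time span covering
#' the protocol marker window (first time <= 20 us, last time >= 1 s).
#'
#' @param x A `fluor_transient`.
#' @return `x`, invisibly usable, after validation.
#' @export
validate_transient <- function(x) {
  stopifnot(inherits(x, "fluor_transient"))
  n <- length(x$times)
  if (n != length(x$values)) {
    ojip_abort("`times` and `values` must have the same length.",
               "ojip_format_error")
  }
  if (n < 5) {
    ojip_abort(
      sprintf("Transient '%s' has %d samples; at least 5 are required.",
              x$sample_id, n),
      "ojip_format_error")
  }
  if (anyNA(x$times) || anyNA(x$values) ||
      any(!is.finite(x$times)) || any(!is.finite(x$values))) {
    ojip_abort(
      sprintf("Transient '%s' contains non-finite times or values.",
              x$sample_id),
      "ojip_parse_error")
  }
  if (any(diff(x$times) <= 0)) {
    ojip_abort(
      sprintf("Transient '%s': times must be strictly increasing.",
              x$sample_id),
      "ojip_format_error")
  }
  if (any(x$values <= 0)) {
    ojip_abort(
      sprintf("Transient '%s': fluorescence values must be positive.",
              x$sample_id),
      "ojip_format_error")
  }
  if (x$times[1] > MARKER_TIMES[["F_O"]] || x$times[n] < MARKER_TIMES[["F_m"]]) {
    ojip_abort(
      sprintf(
        "Transient '%s' spans [%.3g, %.3g] s; it must cover [2e-05, 1] s.",
        x$sample_id, x$times[1], x$times[n]),
      "ojip_coverage_error")
  }
  x
}

#' @export
print.fluor_transient <- function(x, ...) {
  cat(sprintf(
    "<fluor_transient> %s (strain %s, treatment %s, replicate %d)\n",
    x$sample_id, x$strain, x$treatment, x$replicate))
  cat(sprintf("  %d samples over [%.3g, %.3g] s, F in [%.4g, %.4g]\n",
              length(x$times), x$times[1], max(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a marker set
#'
#' The five canonical fluorescence markers of one OJIP transient:
#' \eqn{F_O} (20 us), \eqn{F_K} (300 us), \eqn{F_J} (2 ms), \eqn{F_I} (30 ms)
#' and \eqn{F_m} (the P-step maximum). All values must be positive; the
#' monotone ordering \eqn{F_O \le F_K \le F_J \le F_I \le F_m} is required by
#' [compute_jip()], which raises a degenerate-transient error when violated.
#'
#' @param F_O,F_K,F_J,F_I,F_m Positive fluorescence values (arbitrary units).
#' @return An object of class `marker_set` (named numeric of length 5).
#' @examples
#' marker_set(1000, 2200, 3000, 4200, 5000)
#' @export
marker_set <- function(F_O, F_K, F_J, F_I, F_m) {
  m <- c(F_O = as.double(F_O), F_K = as.double(F_K), F_J = as.double(F_J),
         F_I = as.double(F_I), F_m = as.double(F_m))
  if (anyNA(m) || any(!is.finite(m))) {
    ojip_abort("Markers must be finite numbers.", "ojip_format_error")
  }
  if (any(m <= 0)) {
    ojip_abort("All markers must be positive.", "ojip_format_error")
  }
  structure(m, class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("<marker_set>\n")
  print(setNames(as.double(x), MARKER_NAMES))
  invisible(x)
}

transient_columns <- c("sample_id", "strain", "treatment", "replicate",
                       "time_s", "fluorescence")

guess_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  header <- readLines(path, n = 1L)
  if (length(header) && grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_table_checked <- function(path, required, numeric_cols, delim = NULL) {
  if (!file.exists(path)) {
    ojip_abort(sprintf("Input file not found: '%s'.", path),
               "ojip_missing_file_error")
  }
  if (file.size(path) == 0 || length(readLines(path, n = 1L)) == 0) {
    ojip_abort(sprintf("Input file '%s' is empty.", path),
               "ojip_empty_input_error")
  }
  delim <- guess_delim(path, delim)
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    ojip_abort(
      sprintf("Input file '%s' is missing required column(s): %s.",
              path, paste(missing, collapse = ", ")),
      "ojip_format_error")
  }
  if (nrow(tbl) == 0) {
    ojip_abort(sprintf("Input file '%s' has a header but no rows.", path),
               "ojip_empty_input_error")
  }
  for (col in numeric_cols) {
    raw <- tbl[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.finite(num))
    if (length(bad)) {
      ojip_abort(
        sprintf("Non-numeric %s value '%s' in '%s' at data row %d.",
                col, raw[bad[1]], path, bad[1]),
        "ojip_parse_error")
    }
    tbl[[col]] <- num
  }
  tbl
}

#' Read OJIP transients from a delimited text file
#'
#' Reads a long (tidy) table with one row per time point and the columns
#' `sample_id`, `strain`, `treatment`, `replicate`, `time_s`, `fluorescence`,
#' and assembles one [fluor_transient()] per distinct `sample_id`. Rows are
#' grouped by sample and sorted by time; metadata is taken from each sample's
#' first row. Comma and tab delimiters are supported (guessed from the header
#' unless `delim` is given).
#'
#' @param path Path to a UTF-8 delimited text file with a header row.
#' @param delim Field delimiter; `NULL` (default) guesses `","` or `"\t"`.
#' @return A named list of `fluor_transient` objects, in order of first
#'   appearance in the file.
#' @seealso [write_transients()], [extract_markers()]
#' @export
read_transients <- function(path, delim = NULL) {
  tbl <- read_table_checked(path, transient_columns,
                            c("time_s", "fluorescence"), delim)
  tbl$replicate <- as.integer(tbl$replicate)
  ids <- unique(tbl$sample_id)
  out <- lapply(ids, function(id) {
    rows <- tbl[tbl$sample_id == id, , drop = FALSE]
    rows <- rows[order(rows$time_s), , drop = FALSE]
    fluor_transient(id, rows$strain[1], rows$treatment[1], rows$replicate[1],
                    rows$time_s, rows$fluorescence)
  })
  names(out) <- ids
  out
}

#' Write OJIP transients to a delimited text file
#'
#' Inverse of [read_transients()]: writes the long one-row-per-time-point
#' layout. Numbers are written with full precision so that a read/write cycle
#' round-trips exactly.
#'
#' @param transients A list of `fluor_transient` objects (or a single one).
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_transients <- function(transients, path, delim = ",") {
  if (inherits(transients, "fluor_transient")) transients <- list(transients)
  tbl <- dplyr::bind_rows(lapply(transients, function(t) {
    tibble::tibble(sample_id = t$sample_id, strain = t$strain,
                   treatment = t$treatment, replicate = t$replicate,
                   time_s = t$times, fluorescence = t$values)
  }))
  readr::write_delim(tbl, path, delim = delim, progress = FALSE)
  invisible(path)
}

# Piecewise-linear "hat" basis in log10(time) with knots at the five protocol
# marker times. A transient sampled from any curve that is linear in log-time
# between consecutive marker times lies exactly in the span of this basis,
# which is what makes the least-squares marker fit exact on noise-free
# synthetic traces. Times outside [20 us, 1 s] load entirely on the first or
# last knot (constant extension).
marker_hat_basis <- function(log_times) {
  knots <- log10(MARKER_TIMES)
  X <- matrix(0, length(log_times), 5L,
              dimnames = list(NULL, MARKER_NAMES))
  for (j in seq_len(5L)) {
    if (j > 1L) {
      lo <- knots[j - 1L]
      sel <- log_times >= lo & log_times <= knots[j]
      X[sel, j] <- (log_times[sel] - lo) / (knots[j] - lo)
    }
    if (j < 5L) {
      hi <- knots[j + 1L]
      sel <- log_times > knots[j] & log_times <= hi
      X[sel, j] <- (hi - log_times[sel]) / (hi - knots[j])
    }
  }
  X[log_times <= knots[1L], ] <- 0
  X[log_times <= knots[1L], 1L] <- 1
  X[log_times > knots[5L], ] <- 0
  X[log_times > knots[5L], 5L] <- 1
  X
}

#' Extract the O, K, J, I, P fluorescence markers from a transient
#'
#' Reads the five protocol markers \eqn{F_O} (20 us), \eqn{F_K} (300 us),
#' \eqn{F_J} (2 ms), \eqn{F_I} (30 ms) and \eqn{F_m} (P step) from an OJIP
#' trace. Two estimators are available:
#'
#' * `method = "fit"` (default): ordinary least-squares projection of the
#'   whole trace onto the piecewise-linear five-knot basis in log10-time,
#'   i.e. every sample of the trace contributes to every marker estimate.
#'   This is exact (to machine precision) for traces that are piecewise
#'   linear in log-time between the marker times - in particular for
#'   noise-free output of [generate_transient()] - and, being a linear
#'   estimator, it is unbiased under multiplicative point noise. \eqn{F_m}
#'   is the fitted ordinate at the 1000-ms P step, the time at which the
#'   measurement protocol records \eqn{F_P}.
#' * `method = "interpolate"`: classical single-point lookup by linear
#'   interpolation in (log10 time, fluorescence) between the bracketing
#'   samples, with \eqn{F_m} taken as the maximum of the whole trace. A
#'   warning is issued when the trace maximum occurs before 100 ms, which
#'   usually indicates a degenerate or truncated transient.
#'
#' If the design matrix of the fit is rank-deficient (very sparse traces),
#' the function falls back to `"interpolate"` with a warning.
#'
#' @param t A [fluor_transient()].
#' @param method Marker estimator, `"fit"` (default) or `"interpolate"`.
#' @return A [marker_set()].
#' @examples
#' tr <- fluor_transient("s1", "GM", "MT", 1,
#'                       times = c(2e-5, 3e-4, 2e-3, 3e-2, 1),
#'                       values = c(500, 668.75, 837.5, 1100, 1250))
#' extract_markers(tr)
#' @export
extract_markers <- function(t, method = c("fit", "interpolate")) {
  method <- match.arg(method)
  validate_transient(t)
  lt <- log10(t$times)
  m <- switch(method,
    fit = {
      X <- marker_hat_basis(lt)
      qrX <- qr(X)
      if (qrX$rank < 5L) {
        warn(sprintf(
          "Transient '%s' is too sparse for the template fit; falling back to interpolation.",
          t$sample_id))
        interpolate_markers(t, lt)
      } else {
        setNames(as.double(qr.coef(qrX, t$values)), MARKER_NAMES)
      }
    },
    interpolate = interpolate_markers(t, lt)
  )
  if (any(m <= 0)) {
    ojip_abort(
      sprintf("Transient '%s': marker estimate not positive (noisy or degenerate trace).",
              t$sample_id),
      "ojip_degenerate_transient_error")
  }
  out <- marker_set(m[["F_O"]], m[["F_K"]], m[["F_J"]], m[["F_I"]], m[["F_m"]])
  if (out[["F_m"]] <= out[["F_O"]]) {
    ojip_abort(
      sprintf("Transient '%s' is degenerate: F_m <= F_O (no variable fluorescence).",
              t$sample_id),
      "ojip_degenerate_transient_error")
  }
  out
}

interpolate_markers <- function(t, lt) {
  xout <- log10(MARKER_TIMES[1:4])
  if (xout[1] < lt[1] || xout[4] > lt[length(lt)]) {
    ojip_abort(
      sprintf("Transient '%s' does not cover the marker times.", t$sample_id),
      "ojip_coverage_error")
  }
  vals <- approx(lt, t$values, xout = xout, ties = "ordered")$y
  i_max <- which.max(t$values)
  if (t$times[i_max] < 0.1 && max(t$values) > t$values[1]) {
    warn(sprintf(
      "Transient '%s': trace maximum occurs at %.3g s (before 100 ms).",
      t$sample_id, t$times[i_max]),
      class = "ojip_early_peak_warning")
  }
  setNames(c(vals, max(t$values)), MARKER_NAMES)
}
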