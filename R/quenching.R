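#' Non-photochemical quenching from a dark/light fluorescence pair
#'
#' Stern-Volmer NPQ: \eqn{NPQ = (F_m - F_m')/F_m'}, where \eqn{F_m} is the
#' maximal fluorescence of the dark-adapted sample and \eqn{F_m'} the maximal
#' fluorescence in the light-adapted steady state. Vectorised.
#'
#' A pair with \eqn{F_m' > F_m} yields a negative NPQ; this is flagged with a
#' warning (it usually indicates swapped columns or an unquenched sample) but
#' not treated as an error.
#'
#' @param fm_dark Dark-adapted maximal fluorescence \eqn{F_m} (> 0).
#' @param fm_light Light-adapted maximal fluorescence \eqn{F_m'} (> 0).
#' @return Dimensionless NPQ value(s).
#' @examples
#' compute_npq(1000, 500) # 1
#' @export
compute_npq <- function(fm_dark, fm_light) {
  if (anyNA(fm_dark) || anyNA(fm_light) ||
      any(fm_light <= 0) || any(fm_dark <= 0)) {
    ojip_abort("F_m and F_m' must be positive.",
               "ojip_invalid_measurement_error")
  }
  if (any(fm_light > fm_dark)) {
    warn("Some pairs have F_m' > F_m; the corresponding NPQ values are negative.",
         class = "ojip_negative_npq_warning")
  }
  (fm_dark - fm_light) / fm_light
}

#' Fold change between two positive quantities
#'
#' Plain ratio `after/before`, as used to report e.g. an NPQ rise "from 0.19
#' to 0.57" as a 3.0-fold increase. Use [format_fold()] for the one-decimal
#' reporting convention.
#'
#' @param before Baseline value (> 0).
#' @param after New value.
#' @return Dimensionless ratio(s).
#' @examples
#' fold_change(0.19, 0.57) # 3
#' @export
fold_change <- function(before, after) {
  if (anyNA(before) || any(before <= 0)) {
    ojip_abort("`before` must be positive.", "ojip_domain_error")
  }
  after / before
}

#' Round half-up to a fixed number of decimals
#'
#' Reporting helper matching the usual manuscript convention (2.25 -> 2.3 at
#' one decimal), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a fold change for reporting
#'
#' Rounds half-up to one decimal and renders e.g. `"1.3-fold"`.
#'
#' @param x Fold-change ratio(s).
#' @return Character vector.
#' @examples
#' format_fold(fold_change(0.57, 0.73)) # "1.3-fold"
#' @export
format_fold <- function(x) {
  sprintf("%.1f-fold", round_half_up(x, 1))
}

#' Read quenching pairs (or pre-computed NPQ values) from a delimited file
#'
#' Expects columns `sample_id`, `strain`, `treatment`, `replicate` and either
#' the pair `fm_dark`, `fm_light` (NPQ is then computed with [compute_npq()])
#' or a pre-computed `npq` column (used as is).
#'
#' @inheritParams read_transients
#' @return A tibble with the metadata columns and an `npq` column (plus
#'   `fm_dark`/`fm_light` when present).
#' @export
read_quenching <- function(path, delim = NULL) {
  meta <- c("sample_id", "strain", "treatment", "replicate")
  if (!file.exists(path)) {
    ojip_abort(sprintf("Input file not found: '%s'.", path),
               "ojip_missing_file_error")
  }
  if (file.size(path) == 0) {
    ojip_abort(sprintf("Input file '%s' is empty.", path),
               "ojip_empty_input_error")
  }
  header <- names(readr::read_delim(
    path, delim = guess_delim(path, delim), n_max = 0, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())))
  if ("npq" %in% header) {
    tbl <- read_table_checked(path, c(meta, "npq"), "npq", delim)
  } else {
    tbl <- read_table_checked(path, c(meta, "fm_dark", "fm_light"),
                              c("fm_dark", "fm_light"), delim)
    tbl$npq <- compute_npq(tbl$fm_dark, tbl$fm_light)
  }
  tbl$replicate <- as.integer(tbl$replicate)
  tbl
}
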