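#' Percent change of a treatment mean relative to a control mean
#'
#' \eqn{100 (t - c)/c}, signed: negative values mean the treatment decreased
#' relative to the control. Vectorised. Use [round_half_up()] (0 decimals) for
#' the integer-percent reporting convention; the raw value should always be
#' kept in output tables.
#'
#' @param control_mean Control mean (> 0).
#' @param treatment_mean Treatment mean.
#' @return Signed percent change(s).
#' @examples
#' percent_change(1.00, 1.62) # +62
#' percent_change(0.55, 0.462) # -16
#' @export
percent_change <- function(control_mean, treatment_mean) {
  if (anyNA(control_mean) || any(control_mean <= 0)) {
    ojip_abort("`control_mean` must be positive.", "ojip_domain_error")
  }
  100 * (treatment_mean - control_mean) / control_mean
}

#' Read oxidative-stress assay measurements from a delimited file
#'
#' Expects columns `sample_id`, `strain`, `treatment`, `replicate`,
#' `analyte`, `value` and (optionally) `unit`. Analytes must belong to the
#' panel `OFR`, `MDA`, `SOD`, `POD`, `CAT`; values must be non-negative
#' numbers in kit units.
#'
#' @inheritParams read_transients
#' @return A tibble of assay measurements.
#' @export
read_assays <- function(path, delim = NULL) {
  tbl <- read_table_checked(
    path, c("sample_id", "strain", "treatment", "replicate", "analyte", "value"),
    "value", delim)
  tbl$replicate <- as.integer(tbl$replicate)
  bad <- setdiff(unique(tbl$analyte), ASSAY_ANALYTES)
  if (length(bad)) {
    ojip_abort(
      sprintf("Unknown analyte(s): %s. Expected one of %s.",
              paste(bad, collapse = ", "),
              paste(ASSAY_ANALYTES, collapse = ", ")),
      "ojip_format_error")
  }
  if (any(tbl$value < 0)) {
    ojip_abort("Assay values must be non-negative.", "ojip_format_error")
  }
  if (!"unit" %in% names(tbl)) tbl$unit <- NA_character_
  tbl
}
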