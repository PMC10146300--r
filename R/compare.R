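#' Mean, sample standard deviation and count of a vector
#'
#' The replicate summary used throughout reporting: arithmetic mean, sample
#' (n - 1 denominator) standard deviation, and n. A single value has sd 0.
#'
#' @param values Numeric vector with at least one finite value.
#' @return A list with elements `mean`, `sd`, `n`.
#' @examples
#' summarize_values(c(0.5, 0.6, 0.7)) # mean 0.6, sd 0.1, n 3
#' @export
summarize_values <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) {
    ojip_abort("Cannot summarise an empty collection.",
               "ojip_empty_input_error")
  }
  list(mean = mean(values), sd = if (n == 1) 0 else sd(values), n = n)
}

#' Two-sided Welch unequal-variance t-test p-value
#'
#' Welch's t-test with Welch-Satterthwaite degrees of freedom, the default
#' treatment-vs-control test of the package (robust at n = 3, no
#' equal-variance assumption). Degenerate inputs are resolved explicitly:
#' if both groups have zero variance the p-value is 1 when the means are
#' equal and 0 otherwise.
#'
#' @param control,treatment Numeric vectors with at least two values each.
#' @return Two-sided p-value.
#' @export
welch_test <- function(control, treatment) {
  control <- control[!is.na(control)]
  treatment <- treatment[!is.na(treatment)]
  if (length(control) < 2 || length(treatment) < 2) {
    ojip_abort("Welch's test needs at least two replicates per group.",
               "ojip_insufficient_replicates_error")
  }
  if (var(control) == 0 && var(treatment) == 0) {
    return(if (mean(control) == mean(treatment)) 1 else 0)
  }
  unname(t.test(control, treatment, var.equal = FALSE)$p.value)
}

#' Significance label for a p-value
#'
#' `"**"` for p < `alpha2` (default 0.01), `"*"` for p < `alpha` (default
#' 0.05), otherwise `"ns"`.
#'
#' @param p P-value(s).
#' @param alpha,alpha2 Significance thresholds, `0 < alpha2 < alpha < 1`.
#' @return Character vector.
#' @export
significance_label <- function(p, alpha = 0.05, alpha2 = 0.01) {
  if (!(alpha2 > 0 && alpha2 < alpha && alpha < 1)) {
    ojip_abort("Thresholds must satisfy 0 < alpha2 < alpha < 1.",
               "ojip_config_error")
  }
  ifelse(p < alpha2, "**", ifelse(p < alpha, "*", "ns"))
}

# Canonical row order for comparison tables: JIP parameters in table order,
# then NPQ, then the assay panel; anything else keeps alphabetical order at
# the end.
parameter_order <- function(parameters) {
  canonical <- c(jip_parameters(), "NPQ", ASSAY_ANALYTES)
  extra <- sort(setdiff(unique(parameters), canonical))
  factor(parameters, levels = c(canonical, extra))
}

#' Compare every treatment against the control, per strain and parameter
#'
#' Takes a long table of per-replicate values (columns `strain`, `treatment`,
#' `replicate`, `parameter`, `value`) and produces one comparison row per
#' strain x non-control treatment x parameter: group means and SDs, percent
#' change and fold change of the treatment mean relative to the control mean,
#' the Welch two-sided p-value and a significance flag. Rows are ordered by
#' strain, treatment, then canonical parameter order (JIP parameters, NPQ,
#' assay analytes).
#'
#' @param data Long tibble/data frame of per-replicate values.
#' @param control Control treatment label (default `"MT"`).
#' @param alpha,alpha2 Significance thresholds passed to
#'   [significance_label()].
#' @return A tibble of condition comparisons.
#' @export
compare_conditions <- function(data, control = "MT",
                               alpha = 0.05, alpha2 = 0.01) {
  needed <- c("strain", "treatment", "parameter", "value")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    ojip_abort(sprintf("`data` is missing column(s): %s.",
                       paste(missing, collapse = ", ")),
               "ojip_format_error")
  }
  strains <- unique(data$strain)
  for (s in strains) {
    if (!control %in% data$treatment[data$strain == s]) {
      ojip_abort(
        sprintf("Strain '%s' has no rows for control treatment '%s'.",
                s, control),
        "ojip_config_error")
    }
  }
  grid <- dplyr::distinct(
    data[data$treatment != control, c("strain", "treatment", "parameter")])
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$strain[i]; tr <- grid$treatment[i]; p <- grid$parameter[i]
    ctl <- data$value[data$strain == s & data$treatment == control &
                        data$parameter == p]
    trt <- data$value[data$strain == s & data$treatment == tr &
                        data$parameter == p]
    cs <- summarize_values(ctl)
    ts <- summarize_values(trt)
    pval <- welch_test(ctl, trt)
    tibble::tibble(
      parameter = p, strain = s,
      control_label = control, treatment_label = tr,
      control_mean = cs$mean, control_sd = cs$sd,
      treatment_mean = ts$mean, treatment_sd = ts$sd,
      n_control = cs$n, n_treatment = ts$n,
      percent_change = percent_change(cs$mean, ts$mean),
      fold_change = fold_change(cs$mean, ts$mean),
      p_value = pval,
      significance = significance_label(pval, alpha, alpha2))
  })
  out <- dplyr::bind_rows(rows)
  out$parameter <- as.character(out$parameter)
  ord <- order(out$strain, out$treatment_label,
               parameter_order(out$parameter))
  out[ord, , drop = FALSE]
}
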