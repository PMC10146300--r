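#' Names of the derived JIP-test parameters, in canonical order
#'
#' Order follows the standard JIP-test parameter table: relative variable
#' fluorescences, the OEC-damage indicator, the initial slope, quantum yields
#' and efficiencies, specific energy fluxes per reaction centre, the density
#' of active reaction centres per cross-section, and the performance index.
#'
#' @return Character vector of length 15.
#' @export
jip_parameters <- function() {
  c("V_J", "V_I", "V_K", "W_K", "Mo", "FvFm", "phi_Eo", "phi_Ro", "Psi_o",
    "ABS_RC", "ETo_RC", "TRo_RC", "DIo_RC", "RC_CSo", "PI_abs")
}

#' Compute the derived JIP-test parameters from a marker set
#'
#' Given the five OJIP markers, derives the full JIP-test parameter set:
#' \deqn{V_J = (F_J - F_O)/(F_m - F_O), \quad V_I = (F_I - F_O)/(F_m - F_O),}
#' \deqn{V_K = (F_K - F_O)/(F_m - F_O), \quad W_K = (F_K - F_O)/(F_J - F_O),}
#' \deqn{M_o = 4 (F_K - F_O)/(F_m - F_O), \quad \varphi_{Po} = F_V/F_m = 1 - F_O/F_m,}
#' \deqn{\Psi_o = 1 - V_J, \quad \varphi_{Eo} = \varphi_{Po} (1 - V_J), \quad
#'       \varphi_{Ro} = \varphi_{Po} (1 - V_I),}
#' \deqn{TR_o/RC = M_o/V_J, \quad ABS/RC = (M_o/V_J)/\varphi_{Po}, \quad
#'       ET_o/RC = (M_o/V_J)(1 - V_J),}
#' \deqn{DI_o/RC = ABS/RC - TR_o/RC, \quad RC/CS_o = \varphi_{Po} (V_J/M_o) F_O,}
#' \deqn{PI_{abs} = \frac{\varphi_{Po} V_J}{M_o} \cdot
#'       \frac{\varphi_{Po}}{1 - \varphi_{Po}} \cdot \frac{\Psi_o}{1 - \Psi_o}.}
#'
#' Two conventions that the parameter table leaves ambiguous are resolved as
#' follows (see the methods vignette): `ABS/RC` is \eqn{(M_o/V_J)/\varphi_{Po}},
#' the standard JIP-test form, which keeps \eqn{DI_o/RC \ge 0} and
#' \eqn{\varphi_{Po} = TR_o/ABS}; and `RC/CSo` uses the usual approximation
#' \eqn{ABS/CS \approx F_O}.
#'
#' Degenerate markers (non-monotone ordering, \eqn{F_m \le F_O},
#' \eqn{F_J \le F_O}) raise a typed `ojip_degenerate_transient_error` rather
#' than propagating `NaN`.
#'
#' @param m A [marker_set()].
#' @return A named list of class `jip_result` with the 15 parameters of
#'   [jip_parameters()].
#' @examples
#' compute_jip(marker_set(1000, 2200, 3000, 4200, 5000))$PI_abs # 4/3
#' @export
compute_jip <- function(m) {
  stopifnot(inherits(m, "marker_set"))
  F_O <- m[["F_O"]]; F_K <- m[["F_K"]]; F_J <- m[["F_J"]]
  F_I <- m[["F_I"]]; F_m <- m[["F_m"]]
  if (F_m <= F_O) {
    ojip_abort("Degenerate markers: F_m <= F_O (no variable fluorescence).",
               "ojip_degenerate_transient_error")
  }
  if (F_J <= F_O) {
    ojip_abort("Degenerate markers: F_J <= F_O (flat O-J rise).",
               "ojip_degenerate_transient_error")
  }
  if (F_K < F_O || F_J < F_K || F_I < F_J || F_m < F_I) {
    ojip_abort(
      "Degenerate markers: ordering F_O <= F_K <= F_J <= F_I <= F_m violated.",
      "ojip_degenerate_transient_error")
  }
  fv <- F_m - F_O
  V_J <- (F_J - F_O) / fv
  V_I <- (F_I - F_O) / fv
  V_K <- (F_K - F_O) / fv
  W_K <- (F_K - F_O) / (F_J - F_O)
  Mo <- 4 * (F_K - F_O) / fv
  phi_Po <- 1 - F_O / F_m
  if (phi_Po <= 0 || phi_Po >= 1) {
    ojip_abort("Degenerate markers: FvFm outside (0, 1).",
               "ojip_degenerate_transient_error")
  }
  Psi_o <- 1 - V_J
  TRo_RC <- Mo / V_J
  res <- list(
    V_J = V_J,
    V_I = V_I,
    V_K = V_K,
    W_K = W_K,
    Mo = Mo,
    FvFm = phi_Po,
    phi_Eo = phi_Po * (1 - V_J),
    phi_Ro = phi_Po * (1 - V_I),
    Psi_o = Psi_o,
    ABS_RC = TRo_RC / phi_Po,
    ETo_RC = TRo_RC * (1 - V_J),
    TRo_RC = TRo_RC,
    DIo_RC = TRo_RC / phi_Po - TRo_RC,
    RC_CSo = phi_Po * (V_J / Mo) * F_O,
    PI_abs = (phi_Po * V_J / Mo) * (phi_Po / (1 - phi_Po)) *
      (Psi_o / (1 - Psi_o))
  )
  res <- res[jip_parameters()]
  structure(res, class = "jip_result")
}

#' @export
print.jip_result <- function(x, ...) {
  cat("<jip_result>\n")
  print(unlist(x))
  invisible(x)
}

#' Derive a per-sample JIP parameter table from a collection of transients
#'
#' Applies [extract_markers()] and [compute_jip()] to every transient and
#' binds the results into a tidy table with one row per sample. Samples with
#' degenerate transients are skipped with a warning (their ids are kept in
#' the `"failures"` attribute) so that one bad trace does not abort a batch.
#'
#' @param transients List of [fluor_transient()] objects (e.g. from
#'   [read_transients()]).
#' @inheritParams extract_markers
#' @return A tibble with columns `sample_id`, `strain`, `treatment`,
#'   `replicate` and the 15 parameters of [jip_parameters()], plus an
#'   attribute `failures` naming skipped samples.
#' @export
jip_table <- function(transients, method = c("fit", "interpolate")) {
  method <- match.arg(method)
  if (inherits(transients, "fluor_transient")) transients <- list(transients)
  failures <- character(0)
  rows <- lapply(transients, function(t) {
    res <- tryCatch(
      compute_jip(extract_markers(t, method = method)),
      ojip_degenerate_transient_error = function(e) {
        warn(sprintf("Skipping sample '%s': %s", t$sample_id,
                     conditionMessage(e)))
        NULL
      })
    if (is.null(res)) {
      failures <<- c(failures, t$sample_id)
      return(NULL)
    }
    tibble::tibble(sample_id = t$sample_id, strain = t$strain,
                   treatment = t$treatment, replicate = t$replicate,
                   !!!unclass(res))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "failures") <- failures
  out
}

#' Normalise a JIP parameter table to the control condition
#'
#' For spider (radar) plots: within each strain, every parameter's mean in the
#' control treatment is scaled to exactly 1 and treatment values become ratios
#' to that control mean, preserving the canonical parameter order of
#' [jip_parameters()].
#'
#' @param jip_tbl A per-sample parameter table as returned by [jip_table()].
#' @param control Control treatment label (default `"MT"`).
#' @return A tibble with columns `strain`, `treatment`, `parameter`
#'   (ordered factor) and `value` (ratio to control mean).
#' @export
spider_normalize <- function(jip_tbl, control = "MT") {
  params <- intersect(jip_parameters(), names(jip_tbl))
  if (!length(params)) {
    ojip_abort("No JIP parameter columns found in `jip_tbl`.",
               "ojip_format_error")
  }
  if (!control %in% jip_tbl$treatment) {
    ojip_abort(sprintf("Control treatment '%s' not present.", control),
               "ojip_config_error")
  }
  long <- tidyr::pivot_longer(
    jip_tbl[, c("strain", "treatment", params)],
    cols = dplyr::all_of(params),
    names_to = "parameter", values_to = "value")
  means <- dplyr::summarise(
    dplyr::group_by(long, .data$strain, .data$treatment, .data$parameter),
    value = mean(.data$value), .groups = "drop")
  ctrl <- dplyr::filter(means, .data$treatment == control)
  zero <- ctrl$parameter[ctrl$value == 0]
  if (length(zero)) {
    ojip_abort(
      sprintf("Control mean is zero for parameter(s): %s.",
              paste(unique(zero), collapse = ", ")),
      "ojip_normalization_error")
  }
  ctrl <- dplyr::select(ctrl, "strain", "parameter", control_mean = "value")
  out <- dplyr::left_join(means, ctrl, by = c("strain", "parameter"))
  out$value <- out$value / out$control_mean
  out$control_mean <- NULL
  out$parameter <- factor(out$parameter, levels = params)
  dplyr::arrange(out, .data$strain, .data$treatment, .data$parameter)
}
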