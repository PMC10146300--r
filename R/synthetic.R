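#' Targets for constructing a synthetic marker set
#'
#' A condition is specified in parameter space - maximum photochemical
#' quantum yield (`phi_po`), performance index (`pi_abs`), OEC-damage
#' indicator (`w_k`), I-step relative variable fluorescence (`v_i`) - plus
#' absolute anchors for the fluorescence scale. Either `f_m` is given and
#' `f_o = f_m (1 - phi_po)` follows, or `f_o` is given and `f_m` is rescaled
#' to honour it.
#'
#' @param phi_po Target \eqn{F_V/F_m}, in (0, 1).
#' @param pi_abs Target performance index, > 0.
#' @param w_k Target OEC-damage indicator, in (0, 1].
#' @param v_i Target I-step relative variable fluorescence, in (0, 1].
#' @param f_m Absolute maximal fluorescence anchor (default 1250).
#' @param f_o Optional absolute minimal fluorescence anchor; when given it
#'   takes precedence and `f_m` is rescaled.
#' @return An object of class `preset_targets`.
#' @export
preset_targets <- function(phi_po, pi_abs, w_k, v_i, f_m = 1250, f_o = NULL) {
  if (!(phi_po > 0 && phi_po < 1)) {
    ojip_abort("`phi_po` must be in (0, 1).", "ojip_infeasible_targets_error")
  }
  if (pi_abs <= 0 || w_k <= 0 || w_k > 1 || v_i <= 0 || v_i > 1) {
    ojip_abort("`pi_abs` must be > 0, `w_k` and `v_i` in (0, 1].",
               "ojip_infeasible_targets_error")
  }
  if (!is.null(f_o)) f_m <- f_o / (1 - phi_po)
  if (f_m <= 0) {
    ojip_abort("`f_m` must be positive.", "ojip_infeasible_targets_error")
  }
  structure(list(phi_po = phi_po, pi_abs = pi_abs, w_k = w_k, v_i = v_i,
                 f_m = f_m),
            class = "preset_targets")
}

#' Solve a marker set from JIP parameter targets
#'
#' Inverts the performance-index identity
#' \deqn{PI_{abs} = \frac{\varphi_{Po}}{4 W_K} \cdot
#'       \frac{\varphi_{Po}}{1-\varphi_{Po}} \cdot \frac{\Psi_o}{1-\Psi_o}}
#' for the electron-transport odds,
#' \eqn{\Psi_o/(1-\Psi_o) = 4 W_K PI_{abs} (1-\varphi_{Po})/\varphi_{Po}^2},
#' then reconstructs the five markers:
#' \eqn{V_J = 1 - \Psi_o}, \eqn{F_O = F_m (1 - \varphi_{Po})},
#' \eqn{F_J = F_O + V_J (F_m - F_O)}, \eqn{F_K = F_O + W_K V_J (F_m - F_O)},
#' \eqn{F_I = F_O + V_I (F_m - F_O)}. Running [compute_jip()] on the result
#' reproduces the targets exactly.
#'
#' Targets whose solution leaves the valid marker region (\eqn{\Psi_o} or
#' \eqn{V_J} outside (0, 1), or \eqn{V_I < V_J}) raise an
#' `ojip_infeasible_targets_error` naming the offending combination.
#'
#' @param targets A [preset_targets()].
#' @return A [marker_set()].
#' @examples
#' solve_preset(preset_targets(0.6, 0.55, 0.5, 0.8, f_m = 1250))
#' @export
solve_preset <- function(targets) {
  stopifnot(inherits(targets, "preset_targets"))
  with(targets, {
    odds <- 4 * w_k * pi_abs * (1 - phi_po) / phi_po^2
    psi_o <- odds / (1 + odds)
    v_j <- 1 - psi_o
    eps <- 1e-6
    if (!is.finite(psi_o) || psi_o <= eps || psi_o >= 1 - eps ||
        v_i < v_j) {
      ojip_abort(
        sprintf(paste0(
          "Infeasible targets (phi_po=%g, pi_abs=%g, w_k=%g, v_i=%g): ",
          "solved Psi_o=%.6g, V_J=%.6g violate 0 < V_J <= V_I <= 1."),
          phi_po, pi_abs, w_k, v_i, psi_o, v_j),
        "ojip_infeasible_targets_error")
    }
    f_o <- f_m * (1 - phi_po)
    fv <- f_m - f_o
    marker_set(F_O = f_o,
               F_K = f_o + w_k * v_j * fv,
               F_J = f_o + v_j * fv,
               F_I = f_o + v_i * fv,
               F_m = f_m)
  })
}

#' Construct a generator preset for one strain x treatment condition
#'
#' Bundles the noise-free condition markers with the quenching and assay
#' means and the noise model used by [generate_transient()] and
#' [generate_dataset()].
#'
#' @param strain,treatment Condition labels.
#' @param markers A [marker_set()] of noise-free condition means.
#' @param npq_mean Non-negative mean NPQ of the condition.
#' @param assay_means Named numeric vector/list of positive assay means, names
#'   from `OFR`, `MDA`, `SOD`, `POD`, `CAT`.
#' @param noise_cv Coefficient of variation of the multiplicative per-point
#'   noise (default 0.02).
#' @param replicate_sd Log-scale SD of the per-replicate scale factor
#'   (default 0.05), modelling culture-to-culture variation.
#' @param n_timepoints Number of log-spaced time points per simulated trace
#'   (default 120).
#' @return An object of class `generator_preset`.
#' @export
generator_preset <- function(strain, treatment, markers, npq_mean,
                             assay_means, noise_cv = 0.02,
                             replicate_sd = 0.05, n_timepoints = 120) {
  stopifnot(inherits(markers, "marker_set"))
  if (is.unsorted(as.double(markers))) {
    ojip_abort("Preset markers must be monotone non-decreasing.",
               "ojip_infeasible_targets_error")
  }
  if (npq_mean < 0 || noise_cv < 0 || replicate_sd < 0 || n_timepoints < 5) {
    ojip_abort("Invalid preset: negative noise/NPQ or too few time points.",
               "ojip_config_error")
  }
  assay_means <- unlist(assay_means)
  bad <- setdiff(names(assay_means), ASSAY_ANALYTES)
  if (length(bad) || any(assay_means <= 0)) {
    ojip_abort("`assay_means` must be positive and named by panel analytes.",
               "ojip_config_error")
  }
  structure(list(strain = as.character(strain),
                 treatment = as.character(treatment),
                 markers = markers, npq_mean = npq_mean,
                 assay_means = assay_means, noise_cv = noise_cv,
                 replicate_sd = replicate_sd,
                 n_timepoints = as.integer(n_timepoints)),
            class = "generator_preset")
}

#' @export
print.generator_preset <- function(x, ...) {
  cat(sprintf("<generator_preset> %s/%s  NPQ %.3g  noise_cv %.3g  replicate_sd %.3g\n",
              x$strain, x$treatment, x$npq_mean, x$noise_cv, x$replicate_sd))
  print(setNames(as.double(x$markers), MARKER_NAMES))
  invisible(x)
}

# Deterministic, order-independent stream seed derived from the run seed and
# the condition labels: a polynomial string hash folded into [0, 2^31 - 2].
stream_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "|")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(key)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a private RNG stream without disturbing the caller's
# RNG state.
with_stream <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Noise-free condition curve: monotone piecewise-linear interpolation in
# (log10 time, fluorescence) through the five marker knots, evaluated on a
# log-spaced grid over [20 us, 1 s].
preset_curve <- function(preset) {
  grid <- seq(log10(MARKER_TIMES[["F_O"]]), log10(MARKER_TIMES[["F_m"]]),
              length.out = preset$n_timepoints)
  values <- approx(log10(MARKER_TIMES), as.double(preset$markers),
                   xout = grid, rule = 2)$y
  list(times = 10^grid, values = values)
}

#' Simulate one OJIP transient from a generator preset
#'
#' Builds the noise-free condition curve (monotone piecewise-linear in
#' log10-time through the five marker knots, `n_timepoints` log-spaced
#' samples over 20 us - 1 s), applies one lognormal per-replicate scale
#' factor (log-scale SD `replicate_sd`) and i.i.d. multiplicative Gaussian
#' point noise (CV `noise_cv`), floored at a small positive value. The
#' result is deterministic given `(seed, strain, treatment, replicate)` and
#' independent of generation order.
#'
#' @param preset A [generator_preset()].
#' @param seed Integer run seed.
#' @param replicate Positive integer replicate number.
#' @return A [fluor_transient()].
#' @export
generate_transient <- function(preset, seed, replicate) {
  stopifnot(inherits(preset, "generator_preset"))
  curve <- preset_curve(preset)
  s <- stream_seed(seed, preset$strain, preset$treatment, replicate,
                   "transient")
  values <- with_stream(s, {
    scale <- rlnorm(1, meanlog = 0, sdlog = preset$replicate_sd)
    noise <- 1 + rnorm(preset$n_timepoints, mean = 0, sd = preset$noise_cv)
    curve$values * scale * noise
  })
  values <- pmax(values, 1e-6 * max(curve$values))
  fluor_transient(
    sprintf("%s_%s_r%02d", preset$strain, preset$treatment, replicate),
    preset$strain, preset$treatment, replicate,
    curve$times, values)
}

#' Simulate a full study dataset (transients, quenching pairs, assays)
#'
#' Emits the three tidy tables of the study design: one OJIP transient, one
#' dark/light quenching pair and one row per assay analyte for every
#' preset x replicate. Quenching pairs are built as
#' \eqn{F_m^{dark} = F_m L_1} and \eqn{F_m^{light} = F_m L_2/(1 + NPQ)} with
#' independent lognormal replicate factors \eqn{L_1, L_2} (log-scale SD
#' `replicate_sd`), so per-replicate NPQ scatters around the preset mean.
#' Assay values are mean-one lognormal deviates around the preset assay
#' means with CV `noise_cv`.
#'
#' @param presets List of [generator_preset()] objects covering every
#'   strain x treatment condition (duplicates are an error).
#' @param n_replicates Replicates per condition (default 3, the study design).
#' @param seed Integer run seed; every random stream derives from it.
#' @return A list with tibbles `transients`, `quenching`, `assays`.
#' @export
generate_dataset <- function(presets, n_replicates = 3, seed = 1) {
  if (inherits(presets, "generator_preset")) presets <- list(presets)
  keys <- vapply(presets, function(p) paste(p$strain, p$treatment, sep = "/"),
                 character(1))
  if (anyDuplicated(keys)) {
    ojip_abort(
      sprintf("Duplicate presets for condition(s): %s.",
              paste(unique(keys[duplicated(keys)]), collapse = ", ")),
      "ojip_config_error")
  }
  if (n_replicates < 1) {
    ojip_abort("`n_replicates` must be at least 1.", "ojip_config_error")
  }
  transients <- list(); quenching <- list(); assays <- list()
  for (p in presets) {
    f_m <- p$markers[["F_m"]]
    sdlog_assay <- sqrt(log(1 + p$noise_cv^2))
    for (r in seq_len(n_replicates)) {
      tr <- generate_transient(p, seed, r)
      transients[[length(transients) + 1L]] <- tibble::tibble(
        sample_id = tr$sample_id, strain = tr$strain,
        treatment = tr$treatment, replicate = tr$replicate,
        time_s = tr$times, fluorescence = tr$values)
      q <- with_stream(stream_seed(seed, p$strain, p$treatment, r, "quench"), {
        c(rlnorm(1, 0, p$replicate_sd), rlnorm(1, 0, p$replicate_sd))
      })
      quenching[[length(quenching) + 1L]] <- tibble::tibble(
        sample_id = tr$sample_id, strain = p$strain,
        treatment = p$treatment, replicate = r,
        fm_dark = f_m * q[1],
        fm_light = f_m * q[2] / (1 + p$npq_mean))
      a <- with_stream(stream_seed(seed, p$strain, p$treatment, r, "assay"), {
        p$assay_means * rlnorm(length(p$assay_means),
                               meanlog = -sdlog_assay^2 / 2,
                               sdlog = sdlog_assay)
      })
      assays[[length(assays) + 1L]] <- tibble::tibble(
        sample_id = tr$sample_id, strain = p$strain,
        treatment = p$treatment, replicate = r,
        analyte = names(p$assay_means), value = unname(a),
        unit = "kit units")
    }
  }
  list(transients = dplyr::bind_rows(transients),
       quenching = dplyr::bind_rows(quenching),
       assays = dplyr::bind_rows(assays))
}

apply_multiplier <- function(base, mult) {
  if (is.null(mult)) base else base * mult
}

#' Build generator presets from a structured preset file
#'
#' Reads a YAML preset file with a `baseline` block (parameter-space targets
#' and per-strain NPQ/assay baselines) and a `conditions` block of per
#' strain x treatment multipliers, and solves each condition's marker set
#' with [solve_preset()]. The packaged default file
#' (`system.file("extdata", "presets.yaml", package = "ojip")`) encodes the
#' two-strain (green mutant GM, wild type WT) x three-temperature
#' (LT 8, MT 20, HT 30 degC) design calibrated to the study's printed
#' percent and fold changes; see the methods vignette.
#'
#' @param path Path to a YAML preset file; default is the packaged file.
#' @return Named list of [generator_preset()] objects.
#' @export
read_presets <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "presets.yaml", package = "ojip")
  }
  if (!nzchar(path) || !file.exists(path)) {
    ojip_abort(sprintf("Preset file not found: '%s'.", path),
               "ojip_missing_file_error")
  }
  cfg <- yaml::read_yaml(path)
  base <- cfg$baseline
  noise_cv <- cfg$noise_cv %||% 0.02
  replicate_sd <- cfg$replicate_sd %||% 0.05
  n_timepoints <- cfg$n_timepoints %||% 120
  presets <- list()
  for (strain in names(cfg$conditions)) {
    for (treatment in names(cfg$conditions[[strain]])) {
      cond <- cfg$conditions[[strain]][[treatment]]
      targets <- preset_targets(
        phi_po = apply_multiplier(base$phi_po, cond$phi_po),
        pi_abs = apply_multiplier(base$pi_abs, cond$pi_abs),
        w_k = apply_multiplier(base$w_k, cond$w_k),
        v_i = apply_multiplier(base$v_i, cond$v_i),
        f_m = apply_multiplier(base$f_m, cond$f_m))
      assay_means <- unlist(base$assays)
      for (an in names(cond$assays %||% list())) {
        assay_means[[an]] <- assay_means[[an]] * cond$assays[[an]]
      }
      npq <- cond$npq_value %||% base$npq[[strain]]
      key <- paste(strain, treatment, sep = "_")
      presets[[key]] <- generator_preset(
        strain, treatment, solve_preset(targets), npq, assay_means,
        noise_cv = noise_cv, replicate_sd = replicate_sd,
        n_timepoints = n_timepoints)
    }
  }
  presets
}

#' Packaged study-design presets
#'
#' Convenience wrapper: [read_presets()] on the packaged preset file.
#'
#' @return Named list of [generator_preset()] objects (six conditions).
#' @export
default_presets <- function() read_presets()

`%||%` <- function(a, b) if (is.null(a)) b else a
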