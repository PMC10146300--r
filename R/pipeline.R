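#' Pipeline configuration
#'
#' Assembles (and validates) the configuration shared by the pipeline
#' commands [run_simulate()], [run_jip()], [run_compare()] and
#' [run_report()]. All paths default to files under `out_dir`.
#'
#' @param out_dir Output directory (created on demand).
#' @param control_label Control treatment label (default `"MT"`, 20 degC).
#' @param alpha,alpha2 Significance thresholds (defaults 0.05 and 0.01).
#' @param seed Integer run seed for simulation.
#' @param n_replicates Replicates per condition for simulation (default 3).
#' @param noise_cv,replicate_sd Optional overrides of the preset noise model.
#' @param presets_file Optional preset YAML path (default: packaged presets).
#' @param transients_file,quenching_file,assays_file,jip_file,compare_file
#'   Table paths; defaults live under `out_dir`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = ".",
                            control_label = "MT",
                            alpha = 0.05, alpha2 = 0.01,
                            seed = 7, n_replicates = 3,
                            noise_cv = NULL, replicate_sd = NULL,
                            presets_file = NULL,
                            transients_file = file.path(out_dir, "transients.csv"),
                            quenching_file = file.path(out_dir, "quenching.csv"),
                            assays_file = file.path(out_dir, "assays.csv"),
                            jip_file = file.path(out_dir, "jip_parameters.csv"),
                            compare_file = file.path(out_dir, "comparisons.csv")) {
  if (!(alpha2 > 0 && alpha2 < alpha && alpha < 1)) {
    ojip_abort("Thresholds must satisfy 0 < alpha2 < alpha < 1.",
               "ojip_config_error")
  }
  if (n_replicates < 1) {
    ojip_abort("`n_replicates` must be at least 1.", "ojip_config_error")
  }
  structure(list(out_dir = out_dir, control_label = control_label,
                 alpha = alpha, alpha2 = alpha2, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, replicate_sd = replicate_sd,
                 presets_file = presets_file,
                 transients_file = transients_file,
                 quenching_file = quenching_file,
                 assays_file = assays_file,
                 jip_file = jip_file, compare_file = compare_file,
                 marker_times = MARKER_TIMES),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys keep their
#' defaults. `overrides` (a named list, e.g. from command-line flags) wins
#' over the file.
#'
#' @param path Path to a YAML config file, or `NULL` for defaults.
#' @param overrides Named list of overrides.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  opts <- if (!is.null(path)) {
    if (!file.exists(path)) {
      ojip_abort(sprintf("Config file not found: '%s'.", path),
                 "ojip_missing_file_error")
    }
    yaml::read_yaml(path)
  } else {
    list()
  }
  opts <- modifyList(opts, overrides[!vapply(overrides, is.null, logical(1))])
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(opts), known)
  if (length(unknown)) {
    ojip_abort(sprintf("Unknown config key(s): %s.",
                       paste(unknown, collapse = ", ")),
               "ojip_config_error")
  }
  do.call(pipeline_config, opts)
}

ensure_out_dir <- function(config) {
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
}

load_presets_for <- function(config) {
  presets <- read_presets(config$presets_file)
  for (nm in names(presets)) {
    if (!is.null(config$noise_cv)) presets[[nm]]$noise_cv <- config$noise_cv
    if (!is.null(config$replicate_sd)) {
      presets[[nm]]$replicate_sd <- config$replicate_sd
    }
  }
  presets
}

#' Simulate the study dataset and write the three input tables
#'
#' Generates transients, quenching pairs and assay values from the presets
#' (packaged defaults unless `config$presets_file` is set) and writes
#' `transients.csv`, `quenching.csv` and `assays.csv` under the configured
#' paths. Row counts are logged to standard error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the named vector of written paths.
#' @export
run_simulate <- function(config = pipeline_config()) {
  ensure_out_dir(config)
  presets <- load_presets_for(config)
  ds <- generate_dataset(presets, n_replicates = config$n_replicates,
                         seed = config$seed)
  readr::write_csv(ds$transients, config$transients_file, progress = FALSE)
  readr::write_csv(ds$quenching, config$quenching_file, progress = FALSE)
  readr::write_csv(ds$assays, config$assays_file, progress = FALSE)
  inform(sprintf(
    "simulate: %d transient rows (%d samples), %d quenching pairs, %d assay rows (seed %d)",
    nrow(ds$transients), length(unique(ds$transients$sample_id)),
    nrow(ds$quenching), nrow(ds$assays), config$seed))
  invisible(c(transients = config$transients_file,
              quenching = config$quenching_file,
              assays = config$assays_file))
}

#' Derive the per-sample JIP parameter table from the transients file
#'
#' Reads the transients table, extracts markers and computes all JIP-test
#' parameters per sample, and writes the parameter table. Degenerate samples
#' are skipped and counted on standard error; an empty result is an error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the written path.
#' @export
run_jip <- function(config = pipeline_config()) {
  ensure_out_dir(config)
  transients <- read_transients(config$transients_file)
  tbl <- jip_table(transients)
  failures <- attr(tbl, "failures")
  inform(sprintf("jip: %d samples computed, %d skipped",
                 nrow(tbl), length(failures)))
  if (nrow(tbl) == 0) {
    ojip_abort("No samples could be processed (0 samples).",
               "ojip_empty_input_error")
  }
  readr::write_csv(tbl, config$jip_file, progress = FALSE)
  invisible(config$jip_file)
}

# Long per-replicate value table across JIP parameters, NPQ and assays.
assemble_long <- function(config) {
  jip <- readr::read_csv(config$jip_file, show_col_types = FALSE,
                         progress = FALSE)
  long <- tidyr::pivot_longer(
    jip[, c("strain", "treatment", "replicate",
            intersect(jip_parameters(), names(jip)))],
    cols = -c("strain", "treatment", "replicate"),
    names_to = "parameter", values_to = "value")
  if (file.exists(config$quenching_file)) {
    q <- read_quenching(config$quenching_file)
    long <- dplyr::bind_rows(long, tibble::tibble(
      strain = q$strain, treatment = q$treatment, replicate = q$replicate,
      parameter = "NPQ", value = q$npq))
  }
  if (file.exists(config$assays_file)) {
    a <- read_assays(config$assays_file)
    long <- dplyr::bind_rows(long, tibble::tibble(
      strain = a$strain, treatment = a$treatment, replicate = a$replicate,
      parameter = a$analyte, value = a$value))
  }
  long
}

#' Compare treatments against the control and write the comparison table
#'
#' Assembles per-replicate values from the JIP parameter table plus (when
#' present) the quenching and assay tables, runs [compare_conditions()]
#' against the configured control, and writes the comparison table.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the written path.
#' @export
run_compare <- function(config = pipeline_config()) {
  ensure_out_dir(config)
  long <- assemble_long(config)
  cmp <- compare_conditions(long, control = config$control_label,
                            alpha = config$alpha, alpha2 = config$alpha2)
  readr::write_csv(cmp, config$compare_file, progress = FALSE)
  inform(sprintf("compare: %d comparison rows (%d significant at p < %g)",
                 nrow(cmp), sum(cmp$significance != "ns"), config$alpha))
  invisible(config$compare_file)
}

#' Write the spider-normalised table and the report plots
#'
#' Produces `spider.csv` (control-normalised JIP parameter means), a radar
#' plot of those profiles, a transient overlay on a log10 time axis in the
#' conventional colours (LT blue, MT black, HT red), and bar charts of NPQ
#' and assay values with significance stars from the comparison table.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the named vector of written paths.
#' @export
run_report <- function(config = pipeline_config()) {
  ensure_out_dir(config)
  jip <- readr::read_csv(config$jip_file, show_col_types = FALSE,
                         progress = FALSE)
  spider <- spider_normalize(jip, control = config$control_label)
  spider_file <- file.path(config$out_dir, "spider.csv")
  readr::write_csv(spider, spider_file, progress = FALSE)
  paths <- c(spider = spider_file)
  paths["spider_plot"] <- plot_file(
    plot_spider(spider), file.path(config$out_dir, "spider.png"),
    width = 9, height = 4.5)
  if (file.exists(config$transients_file)) {
    transients <- read_transients(config$transients_file)
    paths["transients_plot"] <- plot_file(
      plot_transients(transients),
      file.path(config$out_dir, "transients.png"), width = 9, height = 4.5)
  }
  if (file.exists(config$compare_file)) {
    cmp <- readr::read_csv(config$compare_file, show_col_types = FALSE,
                           progress = FALSE)
    bars <- cmp[cmp$parameter %in% c("NPQ", ASSAY_ANALYTES), , drop = FALSE]
    if (nrow(bars)) {
      paths["bars_plot"] <- plot_file(
        plot_comparison_bars(bars),
        file.path(config$out_dir, "npq_assays.png"), width = 9, height = 6)
    }
  }
  inform(sprintf("report: wrote %s", paste(basename(paths), collapse = ", ")))
  invisible(paths)
}

treatment_colors <- c(LT = "#2166ac", MT = "black", HT = "#b2182b")

treatment_color_scale <- function(treatments) {
  known <- intersect(names(treatment_colors), treatments)
  extra <- setdiff(treatments, names(treatment_colors))
  values <- c(treatment_colors[known],
              setNames(grDevices::hcl.colors(max(length(extra), 1L), "Dark 3")[
                seq_along(extra)], extra))
  ggplot2::scale_color_manual(values = values)
}

plot_file <- function(p, path, width, height) {
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  path
}

#' Overlay simulated or measured OJIP transients on a log time axis
#'
#' @param transients List of [fluor_transient()] objects.
#' @return A ggplot object (one panel per strain, colour by treatment).
#' @export
plot_transients <- function(transients) {
  tbl <- dplyr::bind_rows(lapply(transients, function(t) {
    tibble::tibble(sample_id = t$sample_id, strain = t$strain,
                   treatment = t$treatment, time_s = t$times,
                   fluorescence = t$values)
  }))
  ggplot2::ggplot(tbl, ggplot2::aes(.data$time_s, .data$fluorescence,
                                    group = .data$sample_id,
                                    color = .data$treatment)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::scale_x_log10() +
    treatment_color_scale(unique(tbl$treatment)) +
    ggplot2::facet_wrap(~strain) +
    ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)",
                  color = "treatment") +
    ggplot2::theme_bw()
}

#' Radar (spider) plot of control-normalised JIP parameters
#'
#' @param spider Output of [spider_normalize()].
#' @return A ggplot object using polar coordinates, one panel per strain.
#' @export
plot_spider <- function(spider) {
  ggplot2::ggplot(spider, ggplot2::aes(.data$parameter, .data$value,
                                       group = .data$treatment,
                                       color = .data$treatment)) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_polar() +
    treatment_color_scale(unique(as.character(spider$treatment))) +
    ggplot2::facet_wrap(~strain) +
    ggplot2::labs(x = NULL, y = "ratio to control mean", color = "treatment") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 7))
}

#' Bar chart of NPQ and assay comparisons with significance stars
#'
#' @param cmp Comparison rows (from [compare_conditions()]) for NPQ and/or
#'   assay analytes.
#' @return A ggplot object.
#' @export
plot_comparison_bars <- function(cmp) {
  cmp$star <- ifelse(cmp$significance == "ns", "", cmp$significance)
  ggplot2::ggplot(cmp, ggplot2::aes(.data$treatment_label,
                                    .data$treatment_mean,
                                    fill = .data$treatment_label)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$treatment_mean - .data$treatment_sd,
      ymax = .data$treatment_mean + .data$treatment_sd), width = 0.3) +
    ggplot2::geom_text(ggplot2::aes(
      y = .data$treatment_mean + .data$treatment_sd, label = .data$star),
      vjust = -0.4) +
    ggplot2::facet_grid(parameter ~ strain, scales = "free_y") +
    ggplot2::labs(x = "treatment", y = "mean +/- SD") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_bw()
}
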