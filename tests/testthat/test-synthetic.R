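test_that("solve_preset reconstructs the control markers in closed form", {
  m <- solve_preset(preset_targets(0.6, 0.55, 0.5, 0.8, f_m = 1250))
  expect_equal(as.double(m), c(500, 668.75, 837.5, 1100, 1250),
               tolerance = 1e-12)
  # the F_O anchor is honoured by rescaling F_m
  m2 <- solve_preset(preset_targets(0.6, 0.55, 0.5, 0.8, f_o = 500))
  expect_equal(as.double(m2), as.double(m), tolerance = 1e-12)
})

test_that("solve_preset / compute_jip round-trips random feasible targets", {
  set.seed(13)
  n_done <- 0
  while (n_done < 200) {
    t <- list(phi_po = runif(1, 0.3, 0.85), pi_abs = runif(1, 0.05, 5),
              w_k = runif(1, 0.2, 1), v_i = runif(1, 0.5, 1),
              f_m = runif(1, 500, 5000))
    mk <- tryCatch(solve_preset(do.call(preset_targets, t)),
                   ojip_infeasible_targets_error = function(e) NULL)
    if (is.null(mk)) next # infeasible draw (V_I < solved V_J)
    r <- compute_jip(mk)
    expect_equal(r$FvFm, t$phi_po, tolerance = 1e-9)
    expect_equal(r$PI_abs, t$pi_abs, tolerance = 1e-9)
    expect_equal(r$W_K, t$w_k, tolerance = 1e-9)
    expect_equal(r$V_I, t$v_i, tolerance = 1e-9)
    n_done <- n_done + 1
  }
})

test_that("infeasible targets raise a typed error", {
  # enormous performance index at phi_po near 1 collapses the J step
  expect_error(solve_preset(preset_targets(0.999, 1e9, 0.5, 0.8)),
               class = "ojip_infeasible_targets_error")
  # solved V_J above the requested V_I
  expect_error(solve_preset(preset_targets(0.6, 0.01, 0.5, 0.3)),
               class = "ojip_infeasible_targets_error")
  expect_error(preset_targets(1.2, 0.5, 0.5, 0.8),
               class = "ojip_infeasible_targets_error")
})

test_that("noise-free transients return the preset markers exactly", {
  presets <- default_presets()
  for (p in presets) {
    p$noise_cv <- 0
    p$replicate_sd <- 0
    tr <- generate_transient(p, seed = 5, replicate = 1)
    m <- extract_markers(tr)
    expect_equal(as.double(m), as.double(p$markers), tolerance = 1e-9)
    expect_false(is.unsorted(tr$values)) # monotone without noise
    expect_true(all(tr$values > 0))
  }
})

test_that("generation is deterministic and order-independent", {
  p <- default_presets()$GM_HT
  t1 <- generate_transient(p, seed = 7, replicate = 2)
  t2 <- generate_transient(p, seed = 7, replicate = 2)
  expect_identical(t1$values, t2$values)
  t3 <- generate_transient(p, seed = 8, replicate = 2)
  expect_false(identical(t1$values, t3$values))
  # replicate streams differ
  t4 <- generate_transient(p, seed = 7, replicate = 3)
  expect_false(identical(t1$values, t4$values))
})

test_that("ensemble-mean markers stay within 1% of the preset markers", {
  p <- default_presets()$GM_MT
  p$replicate_sd <- 0 # isolate point noise (cv = 0.02)
  mk <- sapply(1:50, function(r) {
    as.double(extract_markers(generate_transient(p, seed = 19, replicate = r)))
  })
  expect_equal(rowMeans(mk), as.double(p$markers), tolerance = 0.01)
})

test_that("generate_dataset emits the full replicated design", {
  presets <- default_presets()
  ds <- generate_dataset(presets, n_replicates = 3, seed = 7)
  expect_equal(length(unique(ds$transients$sample_id)), 18)
  expect_equal(nrow(ds$quenching), 18)
  expect_equal(nrow(ds$assays), 18 * 5)
  expect_setequal(unique(ds$assays$analyte),
                  c("OFR", "MDA", "SOD", "POD", "CAT"))
  # duplicate conditions are rejected
  expect_error(generate_dataset(c(presets, presets["GM_MT"]), 3, 7),
               class = "ojip_config_error")
})

test_that("a zero-noise dataset reproduces the preset changes exactly", {
  presets <- default_presets()
  for (nm in names(presets)) {
    presets[[nm]]$noise_cv <- 0
    presets[[nm]]$replicate_sd <- 0
  }
  tbl <- simulate_jip_table(presets, n_replicates = 2, seed = 3)
  expect_equal(recovered_change(tbl, "PI_abs", "GM", "HT"), -16,
               tolerance = 1e-9)
  expect_equal(recovered_change(tbl, "PI_abs", "WT", "HT"), -37,
               tolerance = 1e-9)
  expect_equal(recovered_change(tbl, "FvFm", "GM", "LT"), -22,
               tolerance = 1e-9)
  # NPQ and assays are exact too
  ds <- generate_dataset(presets, n_replicates = 2, seed = 3)
  npq <- compute_npq(ds$quenching$fm_dark, ds$quenching$fm_light)
  expect_equal(npq[ds$quenching$strain == "GM" &
                     ds$quenching$treatment == "HT"], c(0.57, 0.57),
               tolerance = 1e-12)
  ofr <- ds$assays[ds$assays$analyte == "OFR", ]
  expect_equal(
    percent_change(
      mean(ofr$value[ofr$strain == "WT" & ofr$treatment == "MT"]),
      mean(ofr$value[ofr$strain == "WT" & ofr$treatment == "HT"])),
    62, tolerance = 1e-9)
})

test_that("datasets with the same seed are byte-identical on disk", {
  presets <- default_presets()
  d1 <- withr::local_tempfile(fileext = ".csv")
  d2 <- withr::local_tempfile(fileext = ".csv")
  ds1 <- generate_dataset(presets, 2, seed = 99)
  ds2 <- generate_dataset(presets, 2, seed = 99)
  readr::write_csv(ds1$transients, d1, progress = FALSE)
  readr::write_csv(ds2$transients, d2, progress = FALSE)
  expect_identical(readLines(d1), readLines(d2))
})

test_that("preset files drive the generator configuration", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "noise_cv: 0.0",
    "replicate_sd: 0.0",
    "n_timepoints: 40",
    "baseline:",
    "  phi_po: 0.5",
    "  pi_abs: 0.4",
    "  w_k: 0.6",
    "  v_i: 0.9",
    "  f_m: 1000",
    "  npq: {AA: 0.2}",
    "  assays: {OFR: 2.0, MDA: 1.0, SOD: 1.0, POD: 1.0, CAT: 1.0}",
    "conditions:",
    "  AA:",
    "    MT: {}",
    "    HT: {pi_abs: 0.5, npq_value: 0.4, assays: {OFR: 1.5}}"), p)
  presets <- read_presets(p)
  expect_named(presets, c("AA_MT", "AA_HT"))
  expect_equal(presets$AA_MT$n_timepoints, 40L)
  expect_equal(presets$AA_HT$assay_means[["OFR"]], 3.0)
  expect_equal(presets$AA_HT$npq_mean, 0.4)
  expect_equal(presets$AA_MT$npq_mean, 0.2)
  r <- compute_jip(presets$AA_HT$markers)
  expect_equal(r$PI_abs, 0.4 * 0.5, tolerance = 1e-9)
  expect_equal(r$FvFm, 0.5, tolerance = 1e-9)
})
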