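test_that("transient construction enforces the protocol invariants", {
  t5 <- protocol_times
  expect_s3_class(fluor_transient("a", "GM", "MT", 1, t5, 1:5 * 100),
                  "fluor_transient")
  # too short
  expect_error(fluor_transient("a", "GM", "MT", 1, t5[1:4], 1:4 * 100),
               class = "ojip_format_error")
  # non-increasing times
  expect_error(fluor_transient("a", "GM", "MT", 1, rev(t5), 1:5 * 100),
               class = "ojip_format_error")
  # non-positive fluorescence
  expect_error(fluor_transient("a", "GM", "MT", 1, t5, c(-1, 2:5) * 100),
               class = "ojip_format_error")
  # window not covered (stops at 30 ms)
  expect_error(fluor_transient("a", "GM", "MT", 1, t5[1:4] * c(1, 1, 1, 1),
                               1:4 * 100),
               class = "ojip_format_error")
  expect_error(
    fluor_transient("a", "GM", "MT", 1, c(t5[1:4], 0.5), 1:5 * 100),
    class = "ojip_coverage_error")
})

test_that("read_transients groups rows per sample and propagates metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  ms <- rand_marker_sets(2, seed = 42)
  tr1 <- linear_trace(ms[[1]], id = "s1", strain = "GM", treatment = "HT",
                      replicate = 1)
  tr2 <- linear_trace(ms[[2]], id = "s2", strain = "WT", treatment = "LT",
                      replicate = 2)
  write_transients(list(tr1, tr2), path)
  got <- read_transients(path)
  expect_named(got, c("s1", "s2"))
  expect_length(got$s1$times, 120)
  expect_identical(got$s2$strain, "WT")
  expect_identical(got$s2$treatment, "LT")
  expect_identical(got$s2$replicate, 2L)
})

test_that("write/read round-trips transients bit-identically", {
  path <- withr::local_tempfile(fileext = ".csv")
  presets <- default_presets()
  tr <- lapply(1:3, function(r) generate_transient(presets$GM_MT, 11, r))
  write_transients(tr, path)
  got <- read_transients(path)
  for (i in 1:3) {
    expect_identical(got[[i]]$times, tr[[i]]$times)
    expect_identical(got[[i]]$values, tr[[i]]$values)
  }
  # a second write of the re-read data is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_transients(got, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("malformed input files raise typed errors", {
  tidy_header <- "sample_id,strain,treatment,replicate,time_s,fluorescence"
  # missing column
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,strain,replicate,time_s,fluorescence",
               "a,GM,1,0.001,100"), p1)
  err <- expect_error(read_transients(p1), class = "ojip_format_error")
  expect_match(conditionMessage(err), "treatment")
  # non-numeric time cites the row
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(tidy_header,
               "a,GM,MT,1,2e-5,100",
               "a,GM,MT,1,NaN,120"), p2)
  err <- expect_error(read_transients(p2), class = "ojip_parse_error")
  expect_match(conditionMessage(err), "row 2")
  # empty file
  p3 <- withr::local_tempfile(fileext = ".csv")
  file.create(p3)
  expect_error(read_transients(p3), class = "ojip_empty_input_error")
  # header only
  p4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(tidy_header, p4)
  expect_error(read_transients(p4), class = "ojip_empty_input_error")
  # tab-delimited input is accepted
  p5 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(gsub(",", "\t", tidy_header),
               paste(c("a", "GM", "MT", "1", protocol_times[1], "100"),
                     collapse = "\t"),
               paste(c("a", "GM", "MT", "1", protocol_times[2], "150"),
                     collapse = "\t"),
               paste(c("a", "GM", "MT", "1", protocol_times[3], "200"),
                     collapse = "\t"),
               paste(c("a", "GM", "MT", "1", protocol_times[4], "250"),
                     collapse = "\t"),
               paste(c("a", "GM", "MT", "1", protocol_times[5], "300"),
                     collapse = "\t")), p5)
  expect_length(read_transients(p5), 1)
})

test_that("markers on an exact protocol grid equal the sampled values", {
  vals <- c(500, 668.75, 837.5, 1100, 1250)
  tr <- fluor_transient("a", "GM", "MT", 1, protocol_times, vals)
  for (method in c("fit", "interpolate")) {
    m <- extract_markers(tr, method = method)
    expect_equal(as.double(m), vals, tolerance = 1e-12)
  }
})

test_that("marker extraction is invariant under redundant collinear samples", {
  ms <- rand_marker_sets(5, seed = 3)
  for (mk in ms) {
    tr <- linear_trace(mk, n = 60)
    base <- extract_markers(tr, method = "interpolate")
    # insert log-time midpoints lying exactly on the trace polyline
    lt <- log10(tr$times)
    mid_lt <- (lt[-1] + lt[-length(lt)]) / 2
    mid_v <- approx(lt, tr$values, xout = mid_lt)$y
    ord <- order(c(lt, mid_lt))
    dense <- fluor_transient("a", "GM", "MT", 1,
                             10^c(lt, mid_lt)[ord], c(tr$values, mid_v)[ord])
    expect_equal(as.double(extract_markers(dense, method = "interpolate")),
                 as.double(base), tolerance = 1e-12)
    # the template fit is likewise unchanged when the inserted samples lie on
    # the underlying piecewise-linear curve
    mid_tpl <- approx(log10(protocol_times), as.double(mk), xout = mid_lt)$y
    dense_tpl <- fluor_transient("a", "GM", "MT", 1,
                                 10^c(lt, mid_lt)[ord],
                                 c(tr$values, mid_tpl)[ord])
    expect_equal(as.double(extract_markers(dense_tpl, method = "fit")),
                 as.double(mk), tolerance = 1e-9)
  }
})

test_that("monotone traces yield monotone marker sets", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    times <- c(2e-5, sort(10^runif(n - 2, log10(2.1e-5), -0.01)), 1.0)
    values <- cumsum(runif(n, 0, 50)) + runif(1, 100, 1000)
    tr <- fluor_transient("a", "GM", "MT", 1, times, values)
    m <- extract_markers(tr, method = "interpolate")
    expect_false(is.unsorted(as.double(m)))
  }
})

test_that("degenerate traces raise typed errors and odd peaks warn", {
  flat <- fluor_transient("a", "GM", "MT", 1, protocol_times, rep(1000, 5))
  expect_error(extract_markers(flat, method = "interpolate"),
               class = "ojip_degenerate_transient_error")
  expect_error(extract_markers(flat, method = "fit"),
               class = "ojip_degenerate_transient_error")
  # early peak: maximum at 50 ms, declining afterwards
  tr <- fluor_transient("a", "GM", "MT", 1,
                        c(2e-5, 3e-4, 2e-3, 5e-2, 1.0),
                        c(500, 800, 1500, 2500, 1200))
  expect_warning(extract_markers(tr, method = "interpolate"),
                 class = "ojip_early_peak_warning")
})
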