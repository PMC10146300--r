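# Shared fixtures and independent oracles, all built in code.

protocol_times <- c(20e-6, 300e-6, 2e-3, 30e-3, 1.0)

# Random valid marker sets: sampled in (phi_Po, V_K <= V_J <= V_I) space so
# the monotone ordering holds by construction.
rand_marker_sets <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    f_o <- runif(1, 200, 2000)
    phi <- runif(1, 0.3, 0.85)
    f_m <- f_o / (1 - phi)
    v_j <- runif(1, 0.2, 0.8)
    v_k <- v_j * runif(1, 0.1, 0.999)
    v_i <- runif(1, v_j, 1)
    fv <- f_m - f_o
    marker_set(f_o, f_o + v_k * fv, f_o + v_j * fv, f_o + v_i * fv, f_m)
  })
}

# Noise-free trace sampled from the piecewise-linear (in log10 t) curve
# through `markers`, built independently of the package generator.
linear_trace <- function(markers, n = 120, id = "t1", strain = "GM",
                         treatment = "MT", replicate = 1) {
  lt <- seq(log10(20e-6), 0, length.out = n)
  vals <- approx(log10(protocol_times), as.double(markers), xout = lt)$y
  fluor_transient(id, strain, treatment, replicate, 10^lt, vals)
}

# Independent textbook implementation of Welch's unequal-variance t-test
# (used as the oracle for welch_test, which goes through stats::t.test).
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(tstat), df)
}

# Percent change of ensemble-mean parameter values between two conditions of
# a per-sample parameter table.
recovered_change <- function(tbl, parameter, strain, treatment,
                             control = "MT") {
  m_ctl <- mean(tbl[[parameter]][tbl$strain == strain &
                                   tbl$treatment == control])
  m_trt <- mean(tbl[[parameter]][tbl$strain == strain &
                                   tbl$treatment == treatment])
  percent_change(m_ctl, m_trt)
}

# Per-sample JIP table for selected conditions of a preset list.
simulate_jip_table <- function(presets, n_replicates, seed) {
  transients <- list()
  for (p in presets) {
    for (r in seq_len(n_replicates)) {
      transients[[length(transients) + 1L]] <- generate_transient(p, seed, r)
    }
  }
  jip_table(transients)
}
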