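# Packaged study-design presets: two Gracilariopsis lemaneiformis strains
# (GM = green mutant, WT = wild type) x three temperatures
# (LT = 8 degC, MT = 20 degC control, HT = 30 degC), three replicates.
#
# The baseline block gives the MT (control) condition in JIP parameter space;
# each condition block gives MULTIPLIERS applied to the baseline targets
# (absent keys keep the baseline value). npq_value entries are absolute NPQ
# means. assays entries are multipliers on the baseline assay means.
#
# Absolute fluorescence levels and assay baselines are arbitrary constants
# (instrument units are not comparable across studies); only relative changes
# between conditions are meaningful. Entries marked "qualitative" encode a
# direction reported without a printed magnitude and should not be used as
# quantitative references.

noise_cv: 0.02        # CV of multiplicative per-point noise
replicate_sd: 0.05    # log-scale SD of the per-replicate culture factor
n_timepoints: 120     # samples per simulated transient (log-spaced, 20us-1s)

baseline:
  phi_po: 0.60        # Fv/Fm of the control
  pi_abs: 0.55        # performance index of the control
  w_k: 0.50           # OEC-damage indicator of the control
  v_i: 0.80           # I-step relative variable fluorescence
  f_m: 1250           # absolute F_m anchor (arbitrary units)
  npq:                # control (MT) NPQ per strain
    GM: 0.19
    WT: 0.42
  assays:             # arbitrary kit-unit baselines, one per analyte
    OFR: 1.0
    MDA: 1.0
    SOD: 1.0
    POD: 1.0
    CAT: 1.0

conditions:
  GM:
    MT: {}
    HT:
      pi_abs: 0.84            # PI_abs -16 %
      w_k: 0.95
      npq_value: 0.57
      assays: {OFR: 1.21, MDA: 1.29, SOD: 1.5, POD: 1.5, CAT: 1.5}  # SOD/POD/CAT qualitative
    LT:
      phi_po: 0.78            # Fv/Fm -22 %
      pi_abs: 0.60            # PI_abs -40 %
      w_k: 0.95
      f_m: 0.80               # overall fluorescence drop at low temperature
      npq_value: 0.10         # qualitative ("lower under low temperatures")
      assays: {OFR: 1.02, MDA: 1.28, SOD: 1.05, POD: 1.0, CAT: 1.0} # OFR ns; SOD/POD/CAT qualitative
  WT:
    MT: {}
    HT:
      pi_abs: 0.63            # PI_abs -37 %
      w_k: 1.10
      npq_value: 0.73
      assays: {OFR: 1.62, MDA: 1.80, SOD: 1.2, POD: 1.2, CAT: 1.2}  # SOD/POD/CAT qualitative
    LT:
      phi_po: 0.86            # Fv/Fm -14 %
      pi_abs: 0.76            # PI_abs -24 %
      w_k: 1.10
      f_m: 0.80
      npq_value: 0.20         # qualitative
      assays: {OFR: 1.30, MDA: 1.80, SOD: 1.10, POD: 1.0, CAT: 1.0} # OFR magnitude qualitative
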