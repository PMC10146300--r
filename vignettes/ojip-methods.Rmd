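---
title: "Methods: JIP-test derivation, treatment comparison and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: JIP-test derivation, treatment comparison and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ojip)
```

## Scope

`ojip` implements the analysis layer of a classical plant-stress phenotyping
workflow built on fast chlorophyll *a* fluorescence induction (OJIP)
transients, non-photochemical quenching (NPQ) and an oxidative-stress assay
panel. Its reference design is a two-strain x three-temperature experiment on
the red alga *Gracilariopsis lemaneiformis*: a green-pigmented mutant (GM) and
the wild type (WT), cultured at 8 degC (LT), 20 degC (MT, the control) and
30 degC (HT), with three biological replicates per condition. Because raw
instrument exports for such studies are rarely deposited, the package ships a
calibrated synthetic-data generator that emulates this design, so every stage
of the pipeline is testable offline and end to end.

## The OJIP transient and its markers

When a dark-adapted photosynthetic sample is exposed to saturating light,
chlorophyll fluorescence rises polyphasically from the origin **O** through
the inflections **K** (~300 us), **J** (~2 ms) and **I** (~30 ms) to the peak
**P** within about one second. The protocol reads five markers at fixed
times:

| marker | time | meaning |
|--------|---------|------------------------------------------|
| F_O | 20 us | minimal fluorescence, all PSII reaction centres open |
| F_K | 300 us | K step, sensitive to oxygen-evolving-complex damage |
| F_J | 2 ms | J step, reflects Q_A^- accumulation |
| F_I | 30 ms | I step, plastoquinone-pool reduction |
| F_m | 1000 ms | maximal fluorescence at the P step |

These times are protocol constants in the package (`extract_markers()` does
not take them as arguments). Dark-adaptation duration and actinic intensity
are acquisition metadata; they enter no computation.

### Marker estimation: template fit versus point lookup

`extract_markers()` offers two estimators.

`method = "interpolate"` is the textbook lookup: linear interpolation in
(log10 time, fluorescence) between the two samples bracketing each marker
time, with F_m taken as the maximum of the whole trace (a warning is raised
when that maximum falls before 100 ms, which normally indicates a truncated
or degenerate recording). This is the right tool for sparse, pre-averaged
instrument exports.

`method = "fit"` (the default) treats the five markers as the ordinates of a
piecewise-linear curve in log10 time with knots at the five protocol times,
and estimates them by ordinary least squares of the whole trace on that
five-knot hat basis. Two properties motivated this choice:

* **Exactness.** A trace that lies on such a curve - in particular any
  noise-free output of `generate_transient()` - is reproduced to machine
  precision, because the data are in the span of the basis.
* **Statistical behaviour.** With dense noisy traces, single-point lookup is
  wasteful and fragile. Under multiplicative point noise with a 2 %
  coefficient of variation, a 120-point trace read at single points gives
  per-transient PI_abs estimates with a ~14-23 % relative standard deviation
  (the K and J reads enter small differences such as F_K - F_O), and the
  max-of-trace convention for F_m inflates F_m by ~3 % on average - an
  extreme-value bias whose size depends on how flat the curve is near the
  peak, so it does not cancel between conditions being compared. The
  least-squares fit is linear in the data, hence unbiased under zero-mean
  noise, and pools every sample: per-marker standard errors drop to
  0.4-0.7 % and per-transient PI_abs noise to ~4 %, which makes
  condition-level percent changes reproducible to well under two percentage
  points with 50 replicates. F_m is estimated at the 1000-ms P knot, the
  time at which the acquisition protocol records F_P.

If a trace is too sparse for the fit (rank-deficient basis), the function
falls back to interpolation with a warning.

## The JIP-test parameter set

`compute_jip()` derives, from one marker set, the relative variable
fluorescences and the standard yields, efficiencies and specific fluxes:

* V_J = (F_J - F_O)/(F_m - F_O), V_I and V_K analogously;
* W_K = (F_K - F_O)/(F_J - F_O), the OEC-damage indicator;
* M_o = 4 (F_K - F_O)/(F_m - F_O), the approximated initial slope;
* phi_Po = F_V/F_m = 1 - F_O/F_m; Psi_o = 1 - V_J;
  phi_Eo = phi_Po Psi_o; phi_Ro = phi_Po (1 - V_I);
* TR_o/RC = M_o/V_J; ABS/RC = (M_o/V_J)/phi_Po;
  ET_o/RC = (M_o/V_J)(1 - V_J); DI_o/RC = ABS/RC - TR_o/RC;
* RC/CS_o = phi_Po (V_J/M_o) (ABS/CS);
* PI_abs = (RC/ABS) [phi_Po/(1 - phi_Po)] [Psi_o/(1 - Psi_o)],
  with RC/ABS = phi_Po V_J / M_o.

Two conventions had to be fixed where published parameter tables are
ambiguous or internally inconsistent:

* **ABS/RC.** The form "(M_o/V_J)/(1/phi_Po)" that sometimes appears in
  print equals (M_o/V_J) phi_Po and would make DI_o/RC = ABS/RC - TR_o/RC
  negative, contradicting both the definition of DI_o/RC as a dissipation
  flux and the identity phi_Po = TR_o/ABS. The package uses the standard
  form ABS/RC = (M_o/V_J)/phi_Po and does not offer the inconsistent variant.
* **ABS/CS in RC/CS_o.** The absorption flux per cross-section is an
  instrument-dependent quantity; the package uses the common approximation
  ABS/CS ~ F_O, so RC/CS_o = phi_Po (V_J/M_o) F_O. RC/CS_o is consequently
  the only parameter that scales with the (arbitrary) fluorescence units;
  all others are scale invariant, and the test suite asserts this.

Degenerate marker sets (F_m <= F_O, F_J <= F_O, non-monotone ordering) raise
typed errors rather than propagating NaN; batch helpers (`jip_table()`,
`run_jip()`) catch these per sample, skip the sample, and report which
`sample_id` failed.

`spider_normalize()` prepares radar-plot profiles by scaling each
parameter's control-condition mean to exactly 1 within each strain. Raw
parameter tables remain the primary output; normalisation is a presentation
step.

## Quenching and the assay panel

The package adopts the Stern-Volmer definition
NPQ = (F_m - F_m')/F_m', the universal convention in pulse-amplitude and
imaging fluorometry, operating on dark/light-adapted pairs (F_m, F_m').
Pairs with F_m' > F_m yield negative NPQ and a warning, not an error, since
they occur legitimately in noisy low-quenching conditions. Fold changes are
plain ratios; the reporting convention rounds half-up to one decimal
(`format_fold()`), while raw ratios are always retained.

Assay measurements (OFR - superoxide content, MDA - lipid peroxidation,
and the antioxidant enzymes SOD, POD, CAT) are modelled as numeric outcomes
in arbitrary kit units; kit chemistry is a black box. Only relative changes
between conditions are meaningful, and percent changes are computed between
condition means, matching the mean +- SD (n = 3) reporting convention.

## Treatment-versus-control statistics

`compare_conditions()` compares every non-control treatment with the same
strain's control, per parameter: group means, sample SDs, percent change,
fold change, a two-sided Welch unequal-variance t-test and a significance
flag (`*` for p < 0.05, `**` for p < 0.01, `ns` otherwise; thresholds are
configurable but default to these conventional values).

Welch's test was chosen because it is the default robust choice at n = 3
with no equal-variance assumption. No multiple-testing correction is applied
across the parameter panel - this mirrors the per-comparison starring
convention of the field's reports and is a documented limitation, not an
oversight: with 21 parameters per strain x treatment, a 5 % per-comparison
rate implies roughly one spurious star per panel under the global null.
Degenerate cases are made explicit: two zero-variance groups compare as
p = 1 when their means are equal and p = 0 otherwise, and fewer than two
replicates in either group is a typed error.

## The synthetic study design

### Construction

The generator works backwards from parameter-space targets. A condition is
specified by (phi_Po, PI_abs, W_K, V_I) plus an absolute F_m anchor;
`solve_preset()` inverts the identity

PI_abs = [phi_Po/(4 W_K)] [phi_Po/(1 - phi_Po)] [Psi_o/(1 - Psi_o)]

for the electron-transport odds Psi_o/(1 - Psi_o) =
4 W_K PI_abs (1 - phi_Po)/phi_Po^2, reconstructs V_J = 1 - Psi_o and the
five markers, and fails loudly (naming the offending combination) when the
solution leaves the feasible region 0 < V_J <= V_I <= 1. Running
`compute_jip()` on the solved markers reproduces the targets exactly, which
the test suite checks on a thousand random feasible target sets.

`generate_transient()` samples the condition curve - the monotone
piecewise-linear interpolant through the five markers in log10 time - at 120
log-spaced points over 20 us - 1 s, then applies one lognormal per-replicate
scale factor (log-scale SD 0.05, modelling culture-to-culture variation) and
i.i.d. multiplicative Gaussian point noise (CV 0.02, roughly proportional
instrument noise on a positive signal). The piecewise-linear curve was
chosen over a smooth kinetic model deliberately: the read-out layer uses
only the marker ordinates, the linear template makes noise-free round-trips
exact and noisy extraction an unbiased linear regression, and no claim about
intra-step kinetics is intended. Random streams are derived from
(seed, strain, treatment, replicate), so datasets are reproducible and
independent of generation order.

Quenching pairs are built as F_m_dark = F_m L1 and
F_m_light = F_m L2/(1 + NPQ) with independent lognormal replicate factors
L1, L2 (shared factors would make per-replicate NPQ exactly constant and the
Welch test degenerate). Assay values are mean-one lognormal deviates around
the condition means with CV 0.02.

### Calibration

The packaged presets (`inst/extdata/presets.yaml`) encode the reference
design. Absolute levels are arbitrary implementer-chosen constants
(phi_Po = 0.6, PI_abs = 0.55, W_K = 0.5, V_I = 0.8, F_m = 1250 for both
strains' controls; assay baselines 1.0); the condition multipliers encode
the study's reported relative effects: PI_abs falls 16 % (GM) and 37 % (WT)
under heat, 40 % and 24 % under cold; F_V/F_m falls 22 % (GM) and 14 % (WT)
under cold; NPQ rises from 0.19 to 0.57 (GM) and 0.42 to 0.73 (WT) under
heat; OFR rises 21 %/62 % and MDA 29 %/80 % (GM/WT) under heat, MDA
28 %/80 % under cold. Entries for which only a direction is reported (LT
NPQ levels, WT-LT OFR magnitude, all SOD/POD/CAT magnitudes) are marked
*qualitative* in the preset file and are not used as quantitative
references anywhere in the tests.

### What the generator does and does not emulate

It emulates marker-level effect sizes, replicate scatter and multiplicative
point noise. It does **not** emulate sigmoidal intra-step kinetics, post-peak
fluorescence decline, instrument integration windows (real loggers average
more at long times, so real noise is not i.i.d.), temperature dependence of
the transient shape beyond the programmed marker changes, or any mechanistic
PSII/OEC model. Passing recovery tests therefore demonstrates that the
analysis layer is unbiased and correctly plumbed under a realistic noise
budget - not that it would extract markers optimally from kinetically
realistic curves. For real data the `"interpolate"` method on the
instrument's own pre-averaged grid is the conservative choice.

## Numerical choices and degenerate inputs

* Feasibility guards in `solve_preset()`: solved Psi_o must lie in
  (1e-6, 1 - 1e-6) and V_J <= V_I; violations raise
  `ojip_infeasible_targets_error`.
* Simulated traces are floored at 1e-6 x the curve maximum so pathological
  noise settings cannot produce non-positive fluorescence.
* `welch_test()` resolves the zero-variance corner explicitly (see above)
  because `stats::t.test()` errors on constant data.
* Reporting rounds half-up (`round_half_up()`) to match manuscript
  conventions; base R's round-half-even is never user-facing.
* Ties and ordering: comparison tables are sorted by strain, treatment,
  then the canonical parameter order (JIP parameters in table order, NPQ,
  then the assay panel), so outputs are byte-stable across runs.

## Problem sizes used by the checks

The recovery checks simulate 50 replicates per condition (300 transients of
120 points), which makes ensemble means of each condition's parameters
stable to a fraction of a percent and keeps the whole suite fast on a single
CPU. The identity suites use 10,000 random marker sets and 1,000 random
feasible target sets. These sizes are the package's own choices: large
enough that failures indicate defects rather than sampling noise, small
enough to run in seconds.

## Known limitations

* The JIP parameter set is the classical one; Sm, N, t_Fmax, PI_total and
  delta_Ro are out of scope.
* Full quenching kinetics (qP, qL, Y(NPQ), Y(NO), induction/relaxation
  fitting) are out of scope; only Stern-Volmer NPQ on dark/light pairs is
  provided.
* No multiple-testing correction (documented above).
* ANOVA/post-hoc families are not provided; the comparison layer is strictly
  pairwise against the control.
* Proprietary instrument export formats are not parsed; inputs are tidy
  delimited text.
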