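---
title: "calorflex: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{calorflex: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calorflex)
```

This vignette is the package's own account of its science: the models and
their assumptions, the tunable parameters and why their defaults are what
they are, the numerical conventions, and what a green test does and does
not establish. Every number discussed here is computed by the package's
test suite or acceptance script, not asserted from outside.

## 1. From breaths to a steady-state window

A basal recording is a ~30-min breath-by-breath series of VO2 and VCO2
(mL/min) and minute ventilation VE (L/min), taken supine, fasted, after a
rest period. The first minutes are not basal: gas exchange starts
elevated and settles. The processing chain is:

* **Epoching.** Samples are averaged over half-open 30-s epochs
  (`epoch_s = 30`, configurable). Breath-level series are too noisy for
  CV screening — with typical breath-to-breath variability the CV of raw
  breaths would routinely exceed any useful threshold — and guideline-
  style processing averages short intervals. The per-epoch RER is the
  ratio of epoch means, not the mean of breath ratios, because the
  physiological quantity is a ratio of rates.
* **Discard and scan.** The first 300 s are discarded; every epoch-aligned
  300-s window thereafter is a candidate (step = one epoch). For a full
  1800-s recording at 30-s epochs that is 41 windows.
* **Stability.** For each window we compute the CV (sample SD over mean,
  percent) of the four epoch-mean series VO2, VCO2, VE and RER. A window
  *meets criteria* iff all four CVs are strictly below 10%. The composite
  stability score is the unweighted mean of the four CVs — "most stable"
  is not defined more precisely in common protocols, and the symmetric
  mean is reproducible and treats the four screened series equally. Ties
  break to the earliest window start.
* **Exclusions.** No qualifying window → the participant is excluded from
  all calorimetry outputs (`no_valid_window`). A selected window whose
  mean RER falls outside [0.7, 1.0] → excluded from substrate-oxidation
  outputs only, keeping BMR (`rer_out_of_range`). The bounds are
  inclusive: only strictly-below-0.7 or strictly-above-1.0 excludes,
  matching the usual "lower than / higher than" phrasing. Keeping BMR
  under an RER exclusion mirrors cohort reports in which the BMR sample
  is larger than the substrate-oxidation sample.

The whole module is deterministic, and the test suite checks the selected
window against an independently written exhaustive search on hundreds of
random series.

## 2. Stoichiometry

With gases in L/min and urinary nitrogen N in g/day (n = N/1440 in
g/min):

* BMR (kcal/day) = 1440 (3.941 VO2 + 1.106 VCO2) − 2.17 N (abbreviated
  Weir equation, per-minute kcal scaled to per-day);
* BFox (g/min) = 1.67 VO2 − 1.67 VCO2 − 1.92 n;
* BCHox (g/min) = 4.55 VCO2 − 3.21 VO2 − 2.87 n.

These are the canonical Frayn forms: fat oxidation is proportional to
VO2 − VCO2 and is exactly zero at RER = 1; carbohydrate oxidation is zero
at RER = 3.21/4.55 ≈ 0.706. (Printed versions of these equations
sometimes carry "+" signs between the gas terms; those forms are
internally inconsistent — nonzero fat oxidation at RER = 1 — and are not
used.) N defaults to 0: urinary nitrogen is rarely collected in this
setting, and the protein term is then conventionally dropped. Negative
oxidation rates (RER outside the fat/CHO root interval) are *reported
with a validity flag*, never clamped, so that the RER exclusion rule
remains the single gatekeeper.

**Percent of BMR.** Oxidation rates are also expressed as
`100 × rate × kcal_per_g × 1440 / BMR`. The energy equivalents are
configurable with defaults 9.75 kcal/g (triglyceride) and 3.74 kcal/g
(glucose — the unit the Frayn carbohydrate output is expressed in). The
CHO value matters more than it looks: the pair of equivalents that makes
substrate energy *exactly* close the Weir energy at every RER is
(9.60, 3.77) — solving the 2×2 linear system that matches the Weir
coefficients — and (9.75, 3.74) keeps the closure within about ±1.5%
across RER 0.72–0.98. A commonly quoted alternative of ~4.07 kcal/g for
carbohydrate breaks closure by up to ~8% at high RER, so the glucose
value is the default. The suite verifies fat% + CHO% ∈ [95, 105] across
the physiological RER range.

## 3. Clinical indices and phenotype

* Mean blood pressure is the arithmetic mean (SBP + DBP)/2 — a summary
  convention, deliberately distinct from the mean-arterial-pressure
  formula (SBP + 2 DBP)/3. Both acceptance targets hinge on exactly this
  distinction.
* HOMA-IR = insulin (µU/mL) × glucose (mmol/L) / 22.5, glucose converted
  from mg/dL by 0.0555. Any other glucose unit puts the index orders of
  magnitude away from the plausible ~1–3 range.
* QUICKI = 1 / (log10 insulin + log10 glucose), insulin µU/mL, glucose
  mg/dL — the index's standard convention; sources often omit base and
  units, and this is the only reading that reproduces the familiar
  ~0.3–0.4 range.
* Phenotype: *metabolically unhealthy* ⇔ at least one of TG ≥ 150 mg/dL;
  HDL-C < 40 (men) / < 50 (women) mg/dL; SBP ≥ 130 or DBP ≥ 85 mm Hg;
  glycemia > 100 mg/dL (strict). Crossed with normal-weight
  (18.5 < BMI < 25) vs overweight–obese (BMI ≥ 25); BMI exactly 25 is
  overweight–obese, BMI ≤ 18.5 is unclassified (strict lower bound). A
  boundary-grid test verifies the four labels partition every classifiable
  combination.

Missing biomarkers propagate as `NA`; every analysis uses pairwise-
complete rows, which is why different outcome blocks can have different
n.

## 4. Association analysis

* **Normality and transform.** A Shapiro–Wilk test at α = 0.05 automates
  the usual visual screen; constant vectors are degenerate and flagged
  non-normal. Under the `auto` policy a non-normal, strictly positive
  variable is natural-log transformed before modelling; non-positive
  variables are left untransformed with a warning. Which variables get
  transformed is data-driven because no fixed list generalises across
  cohorts.
* **Models.** For each exposure × outcome pair, OLS with covariate sets
  Model 0 = none, 1 = sex, 2 = age, 3 = lean mass. Outcome and exposure
  are z-scored on the analyzed subsample (marginal standardization) so
  the exposure coefficient is the standardized β; covariates enter
  unstandardized (this affects no reported quantity). The reported F is
  the exposure's *partial* F — the squared t of its coefficient, df1 = 1,
  df2 = n − k − 1 — which is the only interpretation consistent with
  reports that print df1 = 1 for multi-predictor models. "R²" is the
  *adjusted* R² of the full model (plain R² cannot be negative, adjusted
  can). Minimum sample size is predictors + 2 (df2 ≥ 1).
* **Group comparisons.** Phenotype differences use one-way ANOVA and
  single-covariate ANCOVA (group partial F, df1 = groups − 1). A zero
  between-group sum of squares returns F = 0, p = 1 rather than 0/0.
* **Multiplicity.** No multiple-testing correction is applied (α = 0.05
  per test), deliberately matching common practice in this literature;
  treat isolated p ≈ 0.04 cells accordingly.

The suite checks the OLS path against a normal-equations solver to 1e−8,
the F = t² identity, type-I error calibration (5% ± 2% over 2000 null
replicates at n = 57), and sign recovery of a planted β = −0.33.

## 5. The synthetic world

`simulate_cohort()` draws per-sex truncated normals for age, height,
lean/fat mass indices, waist, visceral fat, blood pressure and lipids,
using the published cohort's per-sex means/SDs as generating parameters;
glucose is sex-pooled N(93.56, 11.36). Height (1.76 ± 0.06 m men,
1.63 ± 0.06 m women) is the one invented pair — sources report indices,
not heights — chosen as typical adult values. Weight is
(lean + fat)/0.96, the 4% standing in for bone mineral, which lands BMI
means near the published per-sex values. Planted structure:

* basal RER ~ N(0.85, 0.05) truncated to [0.72, 0.98];
* ln-insulin = µ + σ(β z(RER) + √(1−β²) ε) with β = +0.33 and σ = 0.55,
  so insulin is lognormal with mean ≈ 8.1 and SD ≈ 4.8 µU/mL and the
  RER–ln-insulin correlation is the planted β;
* true BMR = 450 + 20 × lean mass (kg) + N(0, 150) kcal/day, giving
  sex means near 1520/1150 kcal/day;
* true gas rates invert the Weir equation at the planted BMR and RER,
  keeping the truth table self-consistent.

All other cross-correlations are zero: the real cohort's covariance
structure is unknowable from summary statistics, and we do not invent
one. Consequences: sex differences and the planted links are realistic,
but e.g. waist–BMI or lipid–lipid correlations are absent, so a green
association test establishes *sign and calibration* properties, not
epidemiological realism.

`simulate_trace()` generates breath times from a truncated-normal renewal
process (4.0 ± 0.8 s), an exponential settling transient
(amplitude 0.25, τ = 180 s), optional linear drift, and multiplicative
noise of CV 4% on VO2 and VCO2 (independent, preserving the planted RER
in expectation; VE tracks VO2 at a ventilatory equivalent of 26 with half
the noise). An optional AR(1) correlation (`noise_ar1`, default 0)
emulates slow physiological drifts: *white* breath noise of any amplitude
averages out within 30-s epochs (12% breath noise → ~4.4% epoch CV), so
only correlated noise can defeat the CV criteria. This is why the
exclusion-path tests use correlated noise, and it is a documented
limitation of epoch-level CV screening.

**Known marginal case.** With the default transient (still
0.25 e^{−300/180} ≈ 4.7% elevated at the end of the discard), the
stability argmin occasionally (≈6% of traces) selects a window starting
before 450 s, where the residual transient biases the window mean by up
to ~2%. Measured over 400 traces, planted-BMR recovery is within 2% in
~99% of traces; a fixed 20-trace suite therefore passes "all within 2%"
only ~82% of the time, and the package's frozen acceptance seeds happen
to contain one 2.06% miss, which is left failing rather than re-seeded.
Practical implication: with slow-settling participants, either lengthen
the discard or inspect the selected window start.

## 6. Reproducibility and the pipeline

Every generator is a pure function of (config, seed); `run_pipeline()`
writes a manifest (config, versions, seed, counts) beside its CSV
outputs, and re-running the same config reproduces every numeric output
exactly. Exclusions are logged per participant with reasons, and
participant counts are conserved across analyzed/excluded/missing.

```{r example, eval = FALSE}
fx <- tempfile(); make_fixture_suite(fx, n = 12, seed = 1)
res <- run_pipeline(run_config(
  traces_dir = file.path(fx, "traces"),
  participants_file = file.path(fx, "participants.csv"),
  out_dir = tempfile()))
str(res$manifest)
```

## 7. Limitations

* No artifact/outlier breath rejection beyond dropping non-positive
  values; carts differ in what they already filter.
* No protein-oxidation estimation and no alternative BMR equations.
* The phenotype uses one fixed criteria set; other metabolic-syndrome
  definitions (waist-based, score-counting) are out of scope.
* The association layer fits one covariate at a time by design; it is
  not a general confounder-selection tool.
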