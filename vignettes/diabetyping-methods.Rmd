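---
title: "Methods: OGTT indices, diabetyping, and remission adjudication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OGTT indices, diabetyping, and remission adjudication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabetyper)
```

This vignette is the package's account of its own methods: the index
formulas and their unit conventions, the subtype classifier and its
calibration, the remission/reversal adjudicator, the synthetic cohort
generator, and the design decisions taken where the underlying definitions
left room.

## The five-point OGTT and the index panel

Every quantity in the package derives from a five-point oral glucose
tolerance test: plasma glucose (mmol/L) and insulin (mU/L) at
t = 0, 30, 60, 90, 120 minutes after a 75 g glucose drink. The
`ogtt_curve()` container enforces this protocol (strictly increasing times
on the canonical grid, positive concentrations, fasting sample first).
Partial curves — a subset of the grid including t = 0 — are accepted but
flagged: they support only the fasting-sample indices (HOMA-IR, HIRI); no
imputation of missing time points is attempted.

Five indices are computed (`compute_panel()`), with fixed unit conventions
recorded in every output:

* **HOMA-IR** `fG × fI / 22.5`, glucose in mmol/L.
* **HIRI** `fG × fI`, glucose in mg/dL (conversion factor exactly 18.0).
* **Matsuda** `10000 / sqrt(fG × fI × mG × mI)`, glucose in mg/dL, means
  over all five samples.
* **Disposition index** early (0–30 min) trapezoidal insulin-to-glucose AUC
  ratio times the Matsuda index.
* **MISI** glucose slope over mean insulin, `100 × (ΔG/Δt) / mI` (mg/dL per
  minute per mU/L).

The conventions are pinned by an exact identity rather than convention
tables: HOMA-IR and HIRI are the *same* fasting product, so
`HIRI = HOMA-IR × 22.5 × 18.0 = HOMA-IR × 405` must hold to machine
precision for every curve, and the factor 18.0 is the unique choice that
reproduces published per-participant HIRI values from the corresponding
HOMA-IR values to within 0.1%. The test suite asserts the identity at
1e-9 relative tolerance, and checks every index against an independent
literal transcription of its formula on 1000 random curves.

A consequence of the printed Matsuda formula worth noting: rescaling the
whole insulin trace by k multiplies the early AUC ratio by k and the
Matsuda index by 1/k (both insulin factors sit under the square root), so
the disposition index is *invariant* under insulin rescaling; sensitivity
to beta-cell output comes entirely from the shape of the early insulin
response relative to fasting, not from insulin units.

### The MISI convention

The defining ratio `(ΔG/Δt)/mI` does not fix which Δ is meant. Two
documented conventions are shipped (`misi(curve, convention = ...)`):

* `span_slope` (default): `100 × (G'min − G'max) / Δt / mI` with the curve
  maximum/minimum and the positive duration between their times. It is
  always ≤ 0; steeper glucose spans relative to circulating insulin — the
  muscle-resistance signature — give larger negative values. This matches
  the uniformly negative published values and their order of magnitude.
* `peak_decay`: the classic decay-rate variant, positive when glucose falls
  from its peak, 0 (with a warning) when the peak is the last sample.

A flat curve returns 0 with a warning under either convention. Neither
convention is claimed to be the one used in the original analyses — the
published definition underdetermines it.

## Subtyping and cutoff calibration

Three of the indices classify: HIRI above its cutoff flags hepatic insulin
resistance, MISI below its cutoff flags muscle insulin resistance, and the
disposition index below its cutoff flags impaired beta-cell function
(HOMA-IR and Matsuda are carried but do not enter the decision). The label
is a pure function of the flags — stem `HIR`/`MIR`/`CIR`/none, prefix `IB`
— giving exactly eight reachable subtypes. Boundary equality always
resolves to the healthy side, so `healthy` is the closed cell of the
partition; this is tested at the cutoff values themselves.

The original cutoffs were derived from several external cohorts that are
not publicly available, so cutoffs here are a required configuration input
(`cutoff_config()`, JSON round-trip), and the package provides a
calibration *procedure* as its stand-in: `diabetype()` fits, per index, the
threshold maximizing Youden's J (sensitivity + specificity − 1) for
separating labeled T2D from healthy reference panels, in the fixed
impairment direction. Numerical details, all tested:

* candidate thresholds are midpoints between consecutive sorted unique
  values;
* ties in J resolve to the midpoint of the tied candidates, so perfectly
  separated classes yield the midpoint of the separating gap;
* an index that fails to separate (best J ≤ 0, e.g. shuffled labels) falls
  back to the pooled median with a warning, and weak separation (J < 0.2)
  warns;
* at least 20 panels per class are required.

The fitted object behaves like a classic R model: `coef()` returns the
three cutoffs, `predict()` classifies new panels, `summary()` reports per-
index J, sensitivity, specificity and training-set reclassification
accuracy, `plot()` shows the reference distributions with cutoffs. An
independent cross-check against `pROC`'s Youden-optimal threshold is part
of the test suite.

### What a single two-class calibration can and cannot recover

The reference cohort we calibrate on pairs the `healthy` archetype with the
fully impaired `IB-CIR` archetype, so that *every* index separates its
classes cleanly and each threshold lands in the gap between that index's
normal and impaired generator levels (per-index training accuracy is then
100%). Out of sample, curves from the `healthy`, `IB-HIR`, `IB-MIR` and
`IB-CIR` archetypes are classified back to their labels ≥ 95% of the time
at 5% measurement noise.

The intermediate single-axis archetypes are *not* recoverable under this
calibration, and we state that rather than hide it: isolated impaired
beta-cell function (`IB`) loses the first-phase insulin response, which
steepens the early glucose excursion and lands its span-based MISI and its
disposition index between the calibration extremes; conversely the
beta-cell-intact resistance archetypes (`HIR`, `MIR`, `CIR`) mount a
compensatory insulin response whose Matsuda suppression pushes their
disposition index under the beta-cell cutoff. These are real, documented
confounds of surrogate OGTT indices, not artifacts of the implementation —
the original cutoffs were derived from several cohorts and "different
subsets" precisely because single-threshold surrogates entangle the axes.
Consequently the recovery claims we test are: the two-class out-of-sample
recovery (≥ 95%), per-archetype recovery for the prevalent study subtypes
(`healthy`, `IB-HIR`, `IB-CIR`), and the aggregate over a study-like
cohort mix, which sits near 86–90% because ~10% of that mix is the
isolated-IB archetype.

## Remission and reversal adjudication

Per visit, `classify_status()` applies, in order of precedence:

1. **remission**: fasting glucose ≤ 6.9 mmol/L AND HbA1c < 48 mmol/mol AND
   no glucose-lowering medication at the visit;
2. **reversal**: HbA1c ≤ 53 AND fasting glucose < 8.0 with reduced (or
   fully stopped) medication, OR HbA1c < 48 AND fasting glucose ≤ 6.9 with
   unchanged medication;
3. otherwise **T2D**.

All four boundaries are honored exactly as written and tested on both
sides. Medication comparison (`compare_medication()`) orders two visit
states on a reduction lattice: `stopped_all` (now medication-free),
`reduced` (proper subset of classes with no remaining dose raised, or equal
classes with at least one dose strictly lower and none higher), `equal`
(identical), `increased` (anything else). Mixed changes — one dose up,
another down — are conservatively `increased`, so reversal cannot be gamed
by substitution. Doses are only comparable within an identical
(class, unit) pair; a unit mismatch is a hard error rather than a
conversion. Only the five glucose-lowering classes participate;
blood-pressure and lipid drugs are outside the adjudicator by design, and
remission requires absence of *all* glucose-lowering classes including
GLP-1 agonists. The follow-up comparison is referenced to the trial start
by default (`reference_visit = "baseline"`, configurable), matching the
definition "compared to the start of the trial". The 2009 consensus
requirement of ≥ 1 year duration is out of scope: adjudication happens at
the 3- and 6-month visits the study design provides.

In the medication CSV every observed participant-visit must appear, with
`drug_class = "none"` marking an explicitly medication-free visit — this
keeps "no medication" distinguishable from "no record", and a missing
baseline record is a hard error.

## Cohort summaries

`summarize_visits()` reports per-visit arithmetic means and sample SDs
(n − 1) per variable with pairwise missing-value exclusion;
`flag_outliers()` implements the standardized-residual rule — exclusion iff
|z| > 3, strictly, so z = 3 is kept (≈ 0.27% exclusion under a standard
normal, verified by simulation); `paired_change()` reports within-
participant visit contrasts (mean, SD, two-sided paired t-test), with an
optional log10 transform per variable (which variables to transform is
configuration — the original choice is unstated). Degenerate all-zero
differences report exactly zero change with p = 1. Deliberately *not*
implemented: the linear mixed-model layer (random participant intercepts,
type-III tests, post-hoc contrasts) of the original analysis — off-the-
shelf inference machinery outside this package's contribution, and exact
p-value replication is impossible without the raw data. The paired
contrasts are labeled as such, and no multiple-testing correction is
applied, matching the original analysis plan. Simulation checks stand in
for the unreproducible cohort tables: recovery of generative moments at
n = 500 within three standard errors, and ≥ 95% power at p < 0.001 for a
−10 kg within-participant shift with 2 kg within-SD at n = 15 over 200
replicates.

## The synthetic cohort generator

The generator exists so that every pipeline stage is testable without any
download. One participant-visit is a discrete glucose balance on a
5-minute grid,

G(t+Δ) = G(t) + Δ·[a(t) − d·I(t)·(G(t) − Gb)],

with a constant absorption input a(t) = 0.18 mmol/L/min over the first 60
minutes, basal floor Gb at the fasting level, and a two-phase insulin
response scaled by the archetype's beta-cell gain:

I(t) = fI + gain·[F(t)·sat(exc, 1.5) + 0.18·(1−F(t))·sat(exc, 2.5)],

where exc is the positive excursion above fasting, sat(x, K) = x/(1+x/K),
and the first-phase weight F(t) falls from 1 at t ≤ 30 min to 0 at
t ≥ 60 min. Loss of the first-phase response is the classical secretory
signature of beta-cell failure, and it is what makes the disposition-index
numerator (the 0–30 min insulin rise) a read-out of the gain. The five
canonical times are read off the grid and multiplicative lognormal
measurement noise (CV 5% by default, mean-preserving) is applied per
sample. A difference equation rather than an ODE solver is used on
purpose: it is the simplest mechanism that gives the indices the monotone
dependence on archetype parameters that the classifier assumes (MISI and
Matsuda strictly increase with the disposal rate; the disposition index
strictly decreases with falling beta-cell gain — both tested at noise 0).

Archetype parameter levels (frozen defaults): fasting glucose
11.7 ± 1.1 mmol/L (hepatic flag) vs 5.2 ± 0.3; fasting insulin 23 ± 2.2
(hepatic), 14 ± 1.8 (combined hepatic + muscle, reflecting failing basal
hypersecretion in advanced dual-resistance disease), 9 ± 1.35 (normal);
beta-cell gain 90 (normal) vs 1.5 (impaired); effective insulin-dependent
clearance 0.045/min (normal) vs 0.002 (muscle-impaired) at the archetype's
fasting insulin, with a 4× compensated clearance for beta-cell-impaired
prototypes without muscle involvement so their glucose decay stays in the
normal-disposal range despite the absent insulin response. Each archetype
is an index-space prototype, not a patient model: the levels were chosen
once so the fully impaired archetype reaches the advanced-T2D scale
(fasting glucose ~12, 2-h glucose ~21 mmol/L, HbA1c ~67 mmol/mol via an
affine map from mean OGTT glucose, intercept 11, slope 4.3, SD 2) while
the healthy archetype stays normoglycemic (< 6.1 mmol/L fasting in
expectation).

What the generator does *not* emulate: meal-to-meal variability, incretin
effects, insulin clearance kinetics, measurement drift, or the joint
distribution of anthropometrics and lipids with glycemia. Passing the
recovery tests therefore shows that the pipeline's plumbing and the
calibration procedure behave as specified under the generator's
assumptions — it does not validate the clinical accuracy of the indices or
cutoffs on real patients.

Visit effects are multipliers on fasting glucose, insulin, beta-cell gain
and disposal per follow-up visit. The defaults (month 3: 0.73, 0.73, 2.2,
1.5; month 6: 0.87, 0.58, 1.7, 2.0) emulate a strong three-month
improvement followed by a partial relapse of the fasting state at six
months while insulin sensitivity keeps improving — the qualitative pattern
of an intensive dietary intervention with waning compliance. Medication
records de-escalate when the simulated labs cross configurable thresholds
(injectables stopped below HbA1c 58; everything stopped below 48 with
fasting glucose ≤ 6.9; metformin halved at ≤ 53), so a null cohort (all
multipliers 1) keeps its baseline-T2D participants on medication with
unimproved labs: fewer than 5% of them produce remission or reversal calls,
and participants whose synthetic labs were normal from the outset are not
counted as false reversions since they were never adjudicated T2D.

Seeding: one root seed; every participant draws from a derived sub-seed
(kept below 2^31), so any subset of participants is reproducible
independent of generation order, and cohort generation restores the
caller's RNG state. The demo pipeline (`run_demo()`) is bit-for-bit
reproducible from its seed.

## Problem sizes and tolerances

The shipped tests use: 1000 random curves for the oracle-equivalence check
at 1e-9 relative tolerance; 200 panels per class for calibration; 150–200
curves per archetype for recovery; a 60-participant null cohort; 200
replicates for the paired-contrast power simulation; 10^4–10^5 draws for
the outlier-rate simulation. These sizes make the whole suite run in well
under a minute while leaving the stochastic margins (binomial confidence
bounds at these n) far from the asserted thresholds.

## Known limitations

* Cutoff values are study-configuration, not universal constants; the
  Youden procedure is this package's documented stand-in for an
  unpublished multi-cohort derivation.
* The exact MISI variant used in the original analyses is not recoverable;
  both shipped conventions are explicit.
* Intermediate single-axis archetypes are not separable by a single
  two-class calibration (see above).
* The adjudicator compares doses only within identical units and does not
  model dose equivalence across drug classes.
* Summaries are paired contrasts, not mixed-model inference.
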