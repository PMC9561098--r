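---
title: "Classifying wheelchair cushion pressure-management performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying wheelchair cushion pressure-management performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cushionbench)
```

## The measurement problem

Wheelchair cushions are prescribed, among other reasons, to manage pressure
on tissue at risk of ulceration. Bench evaluation replaces human subjects
with two compliant buttock models — an elastomer shell around a rigid
substructure abstracting the load-bearing skeleton (ischial tuberosities,
trochanters, coccyx). The **elliptical** model represents typical buttock
tissue bulk; the **trigonometric** model is more peaked, representing
reduced tissue bulk. Each model carries 12 surface force sensors at six
axisymmetric (left/right paired) locations and 3 internal pressure sensors
on the substructure. Cushions are loaded at two applied masses, 50 and
60 kg for 41–43 cm wide cushions, with 6 repeated trials per load.

Two synergistic parameters summarise a trial:

* **Pressure redistribution** — the bony fraction
  \(\%\mathrm{Bony} = \sum_{\text{bony}} p_i \, / \, \sum_{i=1}^{12} p_i\),
  the share of total surface pressure carried by the six sensors under the
  substructure protuberances (channels 1, 2, 7, 8, 9, 10). Lower is better.
* **Pressure magnitude** — SumInt, the sum of the three internal sensors,
  compared with a flat block of HR45 high-resiliency foam through the ratio
  \(\rho = \bar{x}_{\text{test}} / \bar{x}_{\text{ref}}\). The 3-inch block
  is the stricter Skin Protection reference; the 2-inch block is the General
  Use reference.

## Intervals, pooling and classification

Per-trial parameter values from *both* loads are pooled into one sample
(nominally \(n = 12\)) and summarised as
\(\mu \pm z\,\sigma/\sqrt{n}\). The multiplier `ci_multiplier` defaults to
\(z = 1\), the printed form of the protocol's interval; it is configurable
(e.g. 1.96, or a \(t\) quantile) and every classification rule uses whatever
interval it is given, so the choice is transparent. Pooling the loads is a
deliberate design: a load-sensitive cushion earns a wider interval and a
weaker classification, which is the intended penalty.

Classification is trichotomous on the interval, never the point estimate:

* Redistribution: **High** if the whole CI lies below the model criterion
  (0.50 elliptical, 0.55 trigonometric), **Low** if wholly above,
  **Moderate** if the CI includes it. The comparisons are strict, matching
  the criterion table's `<`/`>` symbols, so a bound exactly at the
  criterion is Moderate.
* Magnitude: **Superior** if the whole ratio CI is \(\le\) the lower
  equivalence limit (LEL = 0.9), **Inferior** if \(\ge\) the upper limit
  (UEL = 1.1), **Comparable** otherwise. Non-strict, matching the
  equivalence-band definitions. The 10% band width is anchored to
  literature interface-pressure dispersion: averaging
  \(1.96\cdot\mathrm{SEM}/\text{mean}\) over published cushion records
  gives about 0.153 on human subjects, and bench models are less variable,
  so 0.1 is a defensible meaningful difference. The bundled
  `ipm_literature_synthetic.csv` is a *synthetic* stand-in for those
  records (the originals are not published as a table), constructed so the
  averaged ratio reproduces 0.153; `derive_equivalence_limit()` implements
  the computation itself.

The per-model classes combine into five tiers (`assign_level()`): Level 1
requires High redistribution and Superior magnitude vs the 3-inch
reference on *both* models; Level 2 at least Moderate/Comparable on both;
Level 3 at least Moderate/Comparable on the elliptical model only; General
Use at least Comparable vs the 2-inch reference on the elliptical model;
and Below Minimum is Inferior vs the 2-inch reference — no requisite
therapeutic performance. The General Use tier specifies only a magnitude
criterion, and we implement the matrix as written. A cushion whose
higher-tier inputs are present but fail, and which has no 2-inch
comparison, cannot be placed and is reported `Indeterminate`; no inference
is made from the 3-inch comparison to the 2-inch one even though the
former is stricter.

## The ratio interval

The protocol names the ratio and its CI but no construction. The default
here is **Fieller's** interval for the ratio of two independent sample
means, which is exact under normality and respects positivity; the
first-order **delta** interval and a seeded percentile **bootstrap**
(B = 2000) are provided as cross-checks, and the test suite requires the
three to agree at bench noise levels (the bootstrap percentile estimator
at \(n = 12\) carries a systematic \(\sqrt{(n-1)/n}\) narrowing plus
Monte-Carlo noise, so agreement is asserted on the ensemble average across
seeds). If the reference mean is not significantly positive at the chosen
multiplier, Fieller's denominator changes sign and the interval is
unbounded; the package signals this and classifies Comparable, since no
directional claim is supportable.

## Outliers and the axisymmetric pairs

Surface sensors can report erroneous values on cushions with discontinuous
loading surfaces (e.g. fluid bladders). A datapoint is an outlier when it
differs from the median of its channel across the repeated trials of one
model-load condition by 50% or more of that median (`outlier_fraction`,
with `>=` so a deviation of exactly 50% is flagged). The median scope is
per channel within a condition — the only scope under which the
12 channels × 6 trials × 2 loads × 2 models accounting of datapoints is
coherent. Internal channels are not subject to the rule.

Because each buttock location carries a sensor pair, a flagged value is
replaced by its partner's value from the same trial rather than discarding
the trial; only when both members of a pair are flagged is the trial
excluded (recorded and warned, not an error). The median rule presumes
outliers are rare: if a majority of a channel's six values were corrupted
the median itself moves and sensitivity is lost. The simulator tests
therefore assert perfect recovery for injections that remain a minority
within their cell, which is the regime the rule addresses.

## The synthetic trial generator

`simulate_trials()` replaces the physical rig. It is parameterised by what
the procedure measures: a designed bony fraction per model, a total
surface-pressure budget per model and load, and a designed SumInt ratio to
a reference mean. Within a channel class the budget is shared equally —
the published analysis depends only on class sums, and per-sensor
distributions are not published — and each reading is multiplied by an
independent mean-one lognormal factor with a class CV (surface 0.05,
internal 0.02 by default). Multiplicative noise keeps pressures positive
and maps directly onto the CV scale used to report bench repeatability;
with the default CVs the simulated per-condition CVs sit comfortably
inside the reported envelope (SumInt under 4%, total surface under 7%).
Outliers are injected per surface datapoint with probability
`outlier_prob` as a multiplicative `outlier_scale` (default 2), and their
positions are recorded as ground truth. `load_shift` tilts the bony
fraction with load to exercise the pooling penalty; it defaults to 0.

Numerical defaults chosen once for realism: surface budgets of
620/720 mmHg (elliptical, 50/60 kg) and 640/745 (trigonometric) — total
readings across 12 sensors of a loaded cushion; reference SumInt means of
230/250 mmHg (3-inch foam, elliptical/trigonometric) and 285/310 (2-inch),
the thinner block loading the substructure harder. The 3-inch preset's
noise-free bony fractions are 0.50 (elliptical) and 0.56 (trigonometric),
the empirical anchor of the redistribution criteria; the 2-inch preset
follows the reference rows of the benchmark cohort (0.52/0.64).

What the generator does **not** emulate: per-sensor spatial patterns,
load-history effects (hysteresis, creep), elastomer aging, and any
cushion-construction specificity. Passing recovery tests therefore shows
the statistical pipeline recovers designed class-sum parameters under
CV-scale noise — not that the procedure handles every physical cushion.

## Borderline cases and retests

A classification is *borderline* when a CI bound lies within
`borderline_tolerance` (default 0.02, one printed-precision unit above the
worked example's 0.01 overshoot) of a decision threshold **and** shifting
or shrinking the interval by that distance would change the class; a bound
exactly on a threshold always flags. Borderline flags emit the
`add_trials` retest code — more trials tighten the CI and allow
re-assessment. A cushion Superior to the 2-inch reference on some model,
with no 3-inch comparison, emits `compare_vs_3in`: it may in fact be
comparable to the stricter standard.

## Problem sizes and determinism

The test suite and the acceptance script use 6 trials × 2 loads × 2 models
per cushion (the protocol's geometry), 100-seed replicates for the
stochastic recovery and oracle-agreement checks, 200 replicates for the
noise-envelope check, and a 400-trial-per-load pilot simulation as the
Monte-Carlo oracle for the true per-trial spread of the bony fraction
(used in the 3-standard-error recovery bound, where the per-seed sample SD
would impose \(t_{11}\) tails on a nominally normal criterion). Every
random routine takes an explicit integer seed; identical seeds give
byte-identical trial tables and reports. The bootstrap is the only seeded
stage of `evaluate_cushion()` itself.

## A worked example

```{r example}
cfg <- threshold_config()
test <- simulate_trials(virtual_cushion_spec(
  "demo-cushion",
  bony_fraction = c(elliptical = 0.46, trigonometric = 0.53),
  internal_ratio = c(elliptical = 0.78, trigonometric = 0.78),
  channel_cv = c(surface = 0.02, internal = 0.01), seed = 7))
ref3 <- make_reference("foam_3in", seed = 8)
report <- evaluate_cushion(test, ref3 = ref3, config = cfg)
report
summary(report)
```

## Known limitations

* Equal within-class budget sharing makes per-sensor values
  uninformative; only class sums are meaningful.
* The tier matrix cannot grade a cushion that fails all 3-inch tiers and
  lacks 2-inch data (`Indeterminate`).
* The equivalence-limit derivation reproduces the published 0.153 only as
  a round-trip on a synthetic table; the underlying subject-level data are
  not redistributable.
* The outlier rule's sensitivity guarantee holds for minority corruption
  within a channel-condition cell, as discussed above.
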