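---
title: "Methods: dual-dye screen scoring, dose-response and synergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-dye screen scoring, dose-response and synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sftscreen)
```

This vignette documents the models behind `sftscreen`, the parameters that
matter, the numerical choices that were genuinely open, and what the
synthetic-data generators do and do not emulate.

## Primary screen model

The raw response of the primary screen is the dead/dying-cell fraction per
well and timepoint: the dead-stain object count divided by the live-stain
object count. Counts from the imaging fields of a well are **summed before
the ratio is taken**. The alternative — averaging per-field ratios — is
noisier and produces infinities whenever a single field has a zero
live-stain count; pooled summation degrades gracefully and only fails when
the entire well has no live-stain objects, which is reported as a QC-flagged
error rather than a number.

Two imaging metrics summarize the 0/24/48/72 h time course: the trapezoidal
area under the fraction-vs-time curve (units: fraction x hours, range 0 to
72 x max fraction) and the final-timepoint fraction. The endpoint
luminescent viability reading is carried as a third metric when present.
AUC uses the raw fractions with **no baseline subtraction by default**
(`baseline_subtract = TRUE` exists); missing timepoints are errors, never
interpolated, because silent interpolation biases the integral in whichever
direction the missingness leans.

### Normalization and robust Z

Two schemes are implemented. The test-population scheme anchors each
compound's metric to the vehicle median (0% effect). The control-based
scheme additionally anchors the positive-control median at 100%, so the
vehicle median maps to exactly 0 and the positive-control median to exactly
100 by construction. "Robust mean and standard deviation" are taken as the
median and 1.4826 x MAD — the standard choice in plate-based screening
because a screen's test population is contaminated by its own actives. When
the MAD is zero the spread falls back to IQR/1.349, and if that is also zero
the population is degenerate and scoring refuses to continue rather than
emit infinities.

The hit rule is `robust Z < -3`, strict. Death-fraction metrics *increase*
with killing, while the selection rule expects killers at negative Z; the
default `killing_negative` orientation therefore negates imaging-metric
effects (luminescence already falls with killing and is left alone). The
`raw` orientation is available for users who prefer the natural sign. The
Z population is per-plate by default, with a pooled option; per-plate is
the safer default because it absorbs plate-to-plate shifts without any
positional correction model.

## Secondary triage

Suppression is defined per metric. For luminescent viability it is
`100 x (1 - rlu / median(vehicle rlu))` — vehicle-anchored, positive
control not required, negative values meaning growth stimulation. For
imaging metrics it is the control-based normalized effect (vehicle = 0%,
positive control = 100%). Both definitions are exposed as functions so a
laboratory can substitute its own transform.

The three filters are strict inequalities, matching their wording:
selectivity requires tumor-minus-control differences **> 40 percentage
points at >= 2 of the 4 doses** (not necessarily adjacent), efficacy
requires tumor suppression **> 50%** at the top dose, and off-target safety
requires control suppression **< 50%** at the top dose. Boundary equality
fails all three. Replicate wells are aggregated by median per
(compound, line, dose) before filtering. Differences are percentage points,
not ratios. Profiles cap suppression above at 100 (complete kill) and are
unbounded below.

## Dose-response model

Viability is fitted with the variable-slope four-parameter logistic

$$y(d) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
         {1 + 10^{(\log_{10} d - \log_{10} \mathrm{IC}_{50})\,h}},$$

with dose internally in nM and `log_ic50` in log10 molar. The slope
convention is `h > 0` for an inhibitor (viability non-increasing in dose);
this equals the familiar log(inhibitor)-vs-response variable-slope model
with a negative slope factor.

Numerical choices:

* **Bounded Levenberg-Marquardt** (via `minpack.lm`) over all replicate
  points — replicates are not pre-averaged, preserving the error structure.
* **Multi-start** at hill in {0.5, 1, 2}, with top/bottom started at the
  response extremes and `log_ic50` at the median log dose; best residual
  sum of squares wins, ties broken by the smallest |hill|.
* Default bounds: bottom in [-10, 60] viability points, top in [50, 150],
  hill in [0.05, 20], `log_ic50` within 3 log units of the dose range. The
  `constrained_0_100` preset pins bottom = 0 and top = 100 for
  vehicle-normalized viability; it is the recommended preset for
  combination-index work (below).
* Non-convergence from every start is an explicit error, never a silent
  best effort. Convergence tolerances are set to machine-level (1e-15 on
  the objective) so noiseless synthetic curves are recovered to ~1e-10.

ICx (the dose Dx achieving effect fraction x) defaults to the **absolute**
fraction-affected scale, `fa(d) = 1 - y(d)/100 = x`, because the
combination index requires doses achieving a *common absolute effect*
across agents; the span-relative mode is available. Inversion is closed
form; a level beyond the plateau returns `reachable = FALSE` with an NA
dose — deliberately distinct from a fit failure, so "the drug never gets
there" and "the fit broke" cannot be confused. The median-effect regression
(`fit_median_effect()`) is an independent estimator of the same quantity
and is used as a cross-check oracle in the tests, never as the primary
path.

## Synergy

All synergy computation happens on the fraction-affected percent scale
(`fa = 100 - viability%`). This is the scale on which the Chou-Talalay
formalism is defined, and using it for Loewe and HSA too keeps the three
analyses comparable.

**Combination index.** For a fixed-ratio design the combination's
viability is fitted with its own 4PL along the drug-1 dose axis; at each
effect level x, D1 is the combination fit's ICx, D2 = ratio x D1, and
Dx1/Dx2 come from the single-agent fits, giving CI = D1/Dx1 + D2/Dx2. An
unreachable ICx at one level yields an NA row for that level only. The six
interpretation bands leave boundary membership ambiguous as usually
printed ("between 0.3 and 0.7"); one convention is fixed and tested:
left-closed at 0.3, 0.7 and 0.9, right-closed at 1.1 and 1.45, so
`[0, 0.3) [0.3, 0.7) [0.7, 0.9) [0.9, 1.1] (1.1, 1.45] (1.45, Inf)`
partitions the non-negative reals.

**Loewe additivity.** The expected effect E of a dose pair solves
`d1/D1(E) + d2/D2(E) = 1`, with Di(E) the closed-form 4PL inversion.
Because the dose sum is strictly decreasing in E, E is found by bracketed
bisection (tolerance 1e-8 in effect, 200 iterations cap). When one agent's
plateau prevents it from reaching E, its dose requirement is infinite and
its reciprocal term is zero — the fallback convention used by
matrix-synergy tools when plateaus differ. If even the attainable maximum
leaves the dose sum above 1, the expected effect is capped at that maximum
and carries a `capped` attribute. Both-zero doses return 0 without a
solve. On the axes Loewe reduces exactly to the single-agent curves, and
for two identical agents the expected effect at (d, d) equals the
single-agent effect at 2d — both identities are tested.

**HSA** is simply the maximum of the single-agent effects, with zero dose
contributing zero effect.

## Synthetic-data generators

The generators define the conditions under which the pipeline is
validated; their defaults mirror the assay geometry: 384-well plates, 4
fields per well, timepoints 0/24/48/72 h, ~2,600-compound library at
5000 nM, 400 cells seeded per well (600 and 900 are the other line
presets), and the two secondary ladders 50/200/650/2000 and
125/500/1600/5000 nM.

Where no value was stated anywhere, the following were chosen once as
field-realistic and not revisited: per-compound plateau death fraction
`Normal(0.15, 0.035)` under the null (a mostly-inert library with mild
compound-to-compound variation); saturating-exponential kinetics
`f(t) = f_max (1 - e^{-kt})` with k = 0.05/h (the simplest monotone law
with a plateau; the assay reports no kinetic form); vehicle plateau 0.05;
positive-control plateau 0.92 (the positive-control concentration is not
specified anywhere, so the generator exposes the plateau as the
parameter); doubling time 48 h for live-cell growth; 16 vehicle and 16
positive wells per plate. Planted actives shift the plateau by
`effect_sigma` null SDs. Counts are Poisson (seeding and growth) with
Binomial death labelling — so the mean/variance calibration of the counts
is a testable property, and a null plate's robust-Z tail can be compared
against the Gaussian tail.

What the generators do **not** emulate: spatial plate artifacts (edge
effects, dispenser striping) — the scoring applies no positional
correction, so simulating such artifacts would only demonstrate failure
modes the pipeline does not claim to handle; compound-specific kinetics
beyond the two-parameter law; optical miscounting or segmentation errors;
overdispersion beyond Poisson (a negative-binomial knob exists in design
but is off by default). Passing tests on these simulations therefore
demonstrate correctness of the computations under the stated noise model,
not robustness to every artifact of real screens.

## Evaluation designs used by the tests and acceptance script

Problem sizes were fixed as part of the validation design: 2,600 simulated
compounds for null calibration and sensitivity (one null plate set, one
with 5% actives at 8 SD); 200 seeded noisy fits (8 doses, 4 replicates,
noise SD 5 viability points) for log-IC50 recovery; 40 paired seeded
experiments for the noisy sham combination; 104 compounds with 3 planted
passers for triage; 10,000 simulated t-tests for the power worked example.

The noisy sham-combination check summarizes CI across the 40 seeded
replicate experiments by the **median** per effect level. Per-experiment CI
is a ratio of two independent ICx estimates and is therefore right-skewed;
the median is the appropriate location summary for a "CI equals 1"
statement, while single-experiment CIs at the 0.9 level can individually
deviate by 20% or more at this noise level. Sub-seeds for independent
stages are drawn from a master seed via `sample.int` rather than as
consecutive integers, which avoids the correlated-first-draw artifact of
consecutive Mersenne-Twister seedings.

## Known limitations

* No plate-effect correction (B-score, median polish); the scoring assumes
  plates without strong positional gradients.
* The Loewe solver assumes monotone fits; non-monotone (biphasic) responses
  are out of scope.
* The published hit counts and IC tables of any particular screen cannot be
  reproduced without that screen's raw data; validation is therefore
  property-based on simulations with known truth.
* The sample-size routine covers the equal-n two-sample t-test
  (noncentral-t power, two-sided by default with a one-sided flag), not
  unequal allocation or nonparametric designs.
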