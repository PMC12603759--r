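# sftscreen

Analysis toolkit for image-based dual-dye cytotoxicity screens and the
downstream chain that turns them into ranked drug candidates: robust-Z hit
calling in a 384-well primary screen, multi-dose selectivity triage of a
secondary screen, four-parameter logistic (4PL) dose–response fitting with
ICx extraction, and drug-combination synergy scoring by the Chou–Talalay
combination index and Loewe-additivity / highest-single-agent (HSA)
expected-effect surfaces.

The intended users are screening groups who count live-stain
(CellTracker-type) and dead-stain (DRAQ7-type) objects per well over a time
course and need a reproducible, tested path from raw object counts to hit
lists, IC tables and synergy calls — for example in rare-cancer programs
such as solitary fibrous tumor where screens against engineered or primary
fusion-positive cell lines drive candidate selection.

## The computations

**Death fraction and screen metrics.** For each well and timepoint the
dead/dying fraction is the pooled dead-stain count divided by the pooled
live-stain count (fields summed before dividing). Three per-well metrics
follow: the trapezoidal area under the fraction-vs-time curve over
0/24/48/72 h (*AUC effect*), the fraction at 72 h (*final-timepoint
effect*), and an endpoint luminescent viability reading (*CTG effect*).

**Normalization and hit calling.** Effects are scaled either to the test
population (vehicle median = 0% effect) or to the controls (vehicle = 0%,
positive control = 100%). Compounds are ranked by the robust Z-score

    z_i = (x_i − median(x)) / (1.4826 · MAD(x))

over the library population, oriented so stronger killing is more negative;
hits satisfy z < −3 (strict).

**Secondary triage.** Per-dose suppression profiles in a tumor line and a
fibroblast control line pass three filters, all strict: selectivity
(tumor − control suppression > 40 points at ≥ 2 of 4 doses), efficacy
(tumor suppression > 50% at the top dose), and off-target safety (control
suppression < 50% at the top dose). The default dose ladders are
50/200/650/2000 nM and 125/500/1600/5000 nM.

**Dose–response.** Viability is fitted with the variable-slope 4PL

    y(d) = bottom + (top − bottom) / (1 + 10^((log10 d − log10 IC50) · h))

and ICx doses (IC50/IC75/IC90) are obtained by closed-form inversion on the
fraction-affected scale, with unreachable plateau levels reported as such.
A median-effect regression (log10(fa/(1−fa)) on log10 dose) is included as
an independent cross-check.

**Synergy.** For fixed-ratio combination designs the Chou–Talalay
combination index CI = D1/Dx1 + D2/Dx2 is computed at effect levels
0.5/0.75/0.9 and classified into six bands (CI < 0.3 strong synergism …
CI > 1.45 strong antagonism). For dose×dose matrices the expected surface
under Loewe additivity (solving d1/D1(E) + d2/D2(E) = 1) or HSA
(max of single-agent effects) is compared cell-by-cell with the observed
surface.

Seeded generators (`simulate_primary_plate()`, `simulate_dose_response()`,
`simulate_secondary_profiles()`, `simulate_combination_matrix()`) produce
all of these inputs with known ground truth, so every stage can be
validated end to end.

## Worked example

```r
library(sftscreen)

# one simulated 384-well plate: 352 compounds, 5% planted killers at 8 SD
sim  <- simulate_primary_plate(n_compounds = 352, active_fraction = 0.05,
                               effect_sigma = 8, seed = 42)
hits <- primary_screen_hits(sim$dataset)
head(subset(hits, metric_kind == "final_timepoint"), 2)
#>     compound_id plate_id well     metric_kind raw_value     effect  robust_z is_hit threshold
#> 353    CMPD0340  PLATE01  P12 final_timepoint 0.4791667 -0.4300132 -8.431510   TRUE        -3
#> 354    CMPD0049  PLATE01   D9 final_timepoint 0.4776903 -0.4285369 -8.393962   TRUE        -3
sum(hits$is_hit[hits$metric_kind == "final_timepoint"])
#> [1] 18    # all 18 planted actives, no false positives
```

The raw value is the 72-h death fraction, the effect is its vehicle-anchored,
killing-negative version, and both top compounds sit far below the z < −3
line. Dose–response and a sham self-combination (a drug paired with itself,
which must be exactly additive):

```r
dr  <- simulate_dose_response(log_ic50 = -8, hill = 1, noise_sd = 5, seed = 42)
fit <- fit_4pl(dr$data$dose_nM, dr$data$viability_percent,
               preset = "constrained_0_100")
fit
#> 4PL fit: bottom=0.000 top=100.000 log10(IC50 [M])=-8.0133 hill=1.000 rss=1158 (n=32)
icx(fit, 0.5)$dose_nM
#> [1] 9.698981          # nM; truth is 10 nM
combination_ci(dr$data$dose_nM / 2, dr$data$viability_percent,
               ratio = 1, fit1 = fit, fit2 = fit,
               preset = "constrained_0_100")[, c("effect_level", "ci", "band")]
#>   effect_level ci            band
#> 1         0.50  1 nearly_additive
#> 2         0.75  1 nearly_additive
#> 3         0.90  1 nearly_additive
```

CI = 1 at every effect level: the combination doses (D1, D2) are exactly
half the single-agent equi-effective doses (Dx1, Dx2), as additivity
requires.

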