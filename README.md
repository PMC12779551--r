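# neuritescreen

Longitudinal neurite phenotyping and drug-screen analytics for
iPSC-derived motor-neuron cultures.

## What this package is for

Patient-derived motor-neuron cultures degenerate spontaneously in vitro,
and *when* they degenerate is the phenotype: cultures from ALS donors lose
their neurite network earlier than healthy-control cultures, and
protective drugs delay the loss. Because mature motor neurons cluster too
densely for per-cell counting, health is read out as the **total neurite
length** per fluorescence image field, tracked daily per well.

`neuritescreen` implements the quantitative machinery of this assay for
analysts building or validating such screens:

* **Image quantification** — background subtraction by morphological
  opening, multiscale Hessian ridge (tubeness) enhancement, Otsu
  segmentation, Zhang–Suen skeletonization with spur pruning, and
  geometric skeleton length (1 / √2 step weights) in µm, plus soma counts.
* **Phenotype extraction** — per-well peak-normalized curves, growth rate
  (max % increase over 5 days), decline rate (max % decrease over 2 days),
  and the survival statistic

  **LD50** = the first observed day, at or after the well's peak, on which
  total neurite length ≤ 50% of peak (the experimental endpoint if never
  reached),

  with the three quality-control exclusion rules (< 12,500 µm at all time
  points; > 25% failed time points outside days 50–60; LD50 before day
  39) and donor aggregation (mean ± s.e.m. over ≥ 3 passing wells).
* **Screen analytics** — days of rescue (treated LD50 − DMSO LD50),
  screen-relative normalization (rescue relative to the mean LD50 of all
  drugs in a donor; zero-sum per donor), one-sided truncation at the
  screen horizon, responder fractions, fold-vs-reference ratios, and
  population summaries with Kruskal–Wallis + Dunn significance calls.
* **Calcium-transient detection** — ΔF/F against the session-median
  baseline, Savitzky–Golay smoothing, 3 × s.d. threshold crossing with
  hysteresis and merged-event splitting, frequency/amplitude summaries,
  and a Mann–Whitney U test with exact small-sample enumeration.
* **Statistics** — Kaplan–Meier curves and the log-rank test on LD50
  survival (endpoint LD50s enter as censored), clinical correlations with
  optional log transform, permutation-controlled signature correlations,
  and noncentral-t sample-size calculations.
* **Synthetic data with ground truth** — plates of logistic
  growth × decline curves with donor-level LD50 heterogeneity and
  treatment shifts, filament/soma image fields with exact arc-length
  truth, and calcium traces with injected transients. Every generator is
  seed-deterministic.

## Worked example

Simulate a small treated plate (4 control + 4 case donors, 6 wells per
donor per arm, riluzole shifting the decline by +4 days), phenotype it,
and analyze the screen:

```r
library(neuritescreen)

cfg <- sim_plate_config(n_control_donors = 4, n_case_donors = 4,
                        wells_per_donor = 6,
                        treatment_effects = c(riluzole = 4), seed = 42)
plate <- simulate_plate(cfg)
ph <- phenotype_plate(plate$wells, qc_config())
dt <- ph$donor_table[ph$donor_table$status == "ok", ]
head(dt[, c("donor", "group", "treatment", "n_wells_pass",
            "mean_ld50", "sem_ld50")])
#>    donor group treatment n_wells_pass mean_ld50 sem_ld50
#> 1 CASE01  SALS      DMSO            6     44.67   0.3333
#> 2 CASE01  SALS  riluzole            6     48.67   0.2108
#> 3 CASE02  SALS      DMSO            6     43.67   0.2108
#> 4 CASE02  SALS  riluzole            6     47.33   0.2108
#> 5 CASE03  SALS      DMSO            6     46.83   0.1667
#> 6 CASE03  SALS  riluzole            6     50.50   0.2236
```

Untreated case donors reach their LD50 around day 44 versus day 50 for
controls, and riluzole-treated wells recover roughly the simulated 4-day
shift:

```r
dmso <- dt[dt$treatment == "DMSO", ]
t.test(dmso$mean_ld50[dmso$group == "control"],
       dmso$mean_ld50[dmso$group == "SALS"])$p.value
#> 0.00115

rescue <- sapply(split(dt, dt$donor), function(d)
  days_of_rescue(d$mean_ld50[d$treatment == "riluzole"],
                 d$mean_ld50[d$treatment == "DMSO"]))
round(rescue, 2)
#> CASE01 CASE02 CASE03 CASE04 CTRL01 CTRL02 CTRL03 CTRL04
#>   4.00   3.67   3.67   4.33   4.17   3.83   3.17   4.00

logrank_test(dmso$mean_ld50[dmso$group == "control"], rep(TRUE, 4),
             dmso$mean_ld50[dmso$group == "SALS"], rep(TRUE, 4))[c("chi2", "p")]
#> $chi2  7.34
#> $p     0.00673
```

The per-donor rescues average 3.85 days against a true effect of 4 — the
residual is the ±1-day sampling resolution of a daily LD50. The same
functions drive image-based workflows: `simulate_image_field()` renders a
field with known skeleton length, and
`quantify_well(list(field), quant_config())` recovers it through the
enhance → segment → skeletonize chain.

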