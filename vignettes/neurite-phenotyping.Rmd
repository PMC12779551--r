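---
title: "Quantifying motor-neuron health: neurite length, LD50 survival and screen analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motor-neuron health: neurite length, LD50 survival and screen analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuritescreen)
```

## The measurement problem

Cultures of iPSC-derived spinal motor neurons degenerate spontaneously over
weeks in vitro, and the pace of that degeneration is the disease-relevant
readout: patient-derived (ALS) cultures lose their neurite network earlier
than healthy-control cultures, and protective drugs delay the loss. Because
mature motor neurons cluster too tightly for reliable per-cell counting,
the practical health measure is the **total neurite length** per image
field of a reporter-labelled culture, tracked daily per well of a
multi-well plate.

`neuritescreen` implements the full quantitative chain for this assay:

1. a synthetic-data layer that generates plates, image fields and calcium
   traces with known ground truth;
2. per-field image quantification (total skeleton length in µm, soma
   count);
3. per-well phenotype extraction — peak-normalized curves, growth/decline
   rates, the LD50 survival day, quality control;
4. drug-screen analytics — days of rescue, screen-relative normalization,
   truncation, responder classification, population summaries;
5. calcium-transient detection and the survival / correlation / power
   statistics used to interpret the phenotypes.

## The well trajectory model

A well's latent total neurite length over day $t$ is modelled as a product
of two logistic sigmoids,

$$L(t) = A\,\sigma\!\left(\frac{t - t_g}{\tau_g}\right)
          \sigma\!\left(\frac{t_d - t}{\tau_d}\right),$$

the simplest form with the three observed phases: growth as neurons mature
and arborize, a plateau, and a degeneration phase. $A$ is the plateau
amplitude in µm, $t_g$ and $t_d$ the growth and decline midpoints (days),
$\tau_g$ and $\tau_d$ their time scales. Observations are
$L(t)\,(1+\varepsilon_t)$ with $\varepsilon_t \sim N(0,\mathrm{cv}^2)$:
well-to-well noise in this assay scales with signal, so a multiplicative
CV model is used — this is an assumption of the generator, not a measured
property of any particular instrument. Days can additionally *fail
quantification* (e.g. a focus failure); failures are recorded as missing,
never as zero, because the quality-control rules treat the two cases
differently.

```{r curve}
p <- curve_params(peak_amplitude = 2e5, growth_midpoint = 28,
                  decline_midpoint = 48, noise_cv = 0.10)
sim <- simulate_neurite_curve(p, days = 22:60, seed = 1)
sim$true_ld50
```

`simulate_plate()` layers donor structure on top: donor-level true LD50
targets are drawn per group (defaults: control mean day 50, case mean day
44, s.d. 2 days — a clear but realistic separation on a 22–60-day
calendar), and each donor's $t_d$ is calibrated by numeric inversion so
the analytic LD50 of its latent curve equals the drawn target. Treatments
shift $t_d$ by the drug's configured effect in days. Defaults follow the
screening design the package targets: six replicate wells per donor, four
fields per well, daily acquisition from day 22 to day 60.

## The LD50 survival statistic

The **LD50** of a well is the first observed day, at or after the peak
day, on which total neurite length is at or below 50% of the well's peak;
if the series never falls that far, the experimental endpoint is reported.
Three choices deserve emphasis:

* **Post-peak restriction.** "Dropped to 50% of its peak" implies the
  search starts at the peak; a transient early dip before the network has
  finished growing is not degeneration.
* **No interpolation by default.** Imaging is daily, so the statistic is
  reported at the sampled day of first crossing; fractional donor means
  arise from averaging wells. A linear-interpolation mode exists
  (`compute_ld50(..., interpolate = TRUE)`) but is off by default.
* **No smoothing.** The statistic is defined on raw observations. On
  noiseless curves sampled daily, the estimate is within one day (the
  sampling resolution) of the analytic crossing; the test suite checks
  this over 100 random parameter draws.

Growth and decline rates are window maxima on the raw series: growth is
the maximum percentage increase over 5 days, decline the maximum
percentage decrease over 2 days, each over all ordered pairs of observed
days exactly that far apart. If a needed day failed, the pair is skipped
rather than interpolated. A 2-day growth variant can be selected via the
`window` argument for comparability with 48-hour reporting, but the 5-day
form is the operational default.

### Quality control

A well is excluded when any of three rules fires (reasons are cumulative):

| rule | default | meaning |
|---|---|---|
| `low_signal` | max < 12,500 µm | never enough neurite signal to trust |
| `failed_fraction` | > 25% of scheduled days failed | unreliable quantification; days 50–60 are exempt because failure there may simply reflect degeneration |
| `premature_ld50` | LD50 before day 39 | collapse before neuronal maturation — a culture failure, not a phenotype |

The denominator of the failed fraction is every day in the acquisition
calendar outside the exempt window; the source assay does not define the
denominator, so this explicit convention is recorded here. Donors are
summarized (mean ± s.e.m. of LD50 and rates) only when at least three
wells pass.

## Drug-screen analytics

**Days of rescue** is `treated LD50 − DMSO LD50`; positive values are
protection, negative values toxicity, and negative values are never
truncated. Primary screens that lack a dedicated per-donor DMSO
comparison use **screen-relative normalization**: each drug's LD50 is
expressed relative to the mean LD50 over all drugs screened in that donor,
under the assumption that the average treatment effect across ~100 drugs
is zero; outputs therefore sum to zero per donor. Whether DMSO belongs in
that denominator is genuinely ambiguous; the default excludes it
(`include_reference = FALSE`).

Screens run to a fixed horizon (five days past the DMSO LD50), so
quantified rescue is capped; `truncate_rescues()` applies the one-sided
cap and flags capped values. Responder fractions
(`classify_responders()`) report the percentage of donors whose rescue
exceeds a threshold (default 10 days), rounded to the nearest integer
percent — the convention that makes 13 of 15 donors read as 87%.

Population significance uses a Kruskal–Wallis omnibus over drugs followed
by Dunn's rank comparisons of each drug against the DMSO (or zero)
reference with Bonferroni adjustment, implemented from the rank formulas
(base R's `kruskal.test` serves as an independent cross-check in the test
suite). A drug is called effective when its adjusted p-value clears
`alpha` with a positive mean rescue; `percent_failed` is the rounded
percentage of tested drugs not called effective.

## Image quantification

The per-field pipeline mirrors the enhance → segment → quantify structure
of high-content neurite assays. The upstream assay's own operator chain is
unpublished, so the package standardizes on the canonical operators, all
parameterized in `quant_config()`:

1. **Enhance**: background estimated by morphological opening (disc
   radius 15 px by default) and subtracted; curvilinear structure
   amplified by a multiscale Hessian ridge ("tubeness") response — at each
   scale $s \in \{1, 1.5, 2\}$ px the field is Gaussian-smoothed and
   $s^2\max(0, -\lambda_{\min})$ of the Hessian taken, then the maximum
   across scales. The response is suppressed in a border band of
   $2\,s_{\max}+1$ px where the finite-difference stencil and PSF are
   clipped.
2. **Segment**: neurite mask by Otsu (or fixed) threshold on the ridge
   response, dropping components whose pixel extent is below 10 µm; soma
   mask by Otsu on the raw image followed by a 2 µm opening (thin
   processes vanish, cell bodies survive) and a 50 µm² area filter. Soma
   pixels plus a 4 µm exclusion ring are removed from the neurite mask so
   that the blurred halo of a cell body is not skeletonized as neurite.
3. **Measure**: the neurite mask is thinned to a one-pixel skeleton
   (Zhang–Suen, implemented in the package since no installed dependency
   provides topology-preserving thinning), spurs shorter than 5 µm are
   pruned (junction-attached branches only — isolated open curves are
   never shortened), and length is the sum over adjacent skeleton pixel
   pairs of 1 (lateral) or $\sqrt2$ (diagonal) steps × pixel size.
   Diagonal pairs whose pixels share a lateral neighbour inside the
   skeleton are skipped: in the staircase corners thinning can leave, the
   path already runs through the shared neighbour, and counting the
   shortcut too would double-count (empirically up to ~40% inflation).

Both the skeleton length and a mask-area-derived length are available in
the segmentation result; skeleton length is what the pipeline reports,
since it is the quantity with a geometric ground truth. Soma count is the
number of 8-connected components of the soma mask.

The synthetic image generator draws cubic-spline filaments and disc
somata, rasterizes at sub-pixel resolution, blurs with a Gaussian PSF and
adds Poisson noise. Its ground-truth arc length is exact by construction,
which is what makes the 10%-error acceptance bound meaningful. What it
does **not** emulate: intensity variation along neurites, branching
morphology, touching/overlapping somata, uneven illumination, and
out-of-focus light. Passing the synthetic oracle therefore shows the
geometric fidelity of the operator chain, not robustness to every real
imaging artifact.

## Calcium-transient detection

ROI fluorescence traces sampled at 10 Hz are converted to
$\Delta F/F = (F - F_0)/F_0$ with $F_0$ the session median (a raw-ratio
mode $F/F_0$ is available; both readings are consistent with the source
description, and either is invariant to rescaling the trace). Traces are
smoothed with a Savitzky–Golay filter (window 9 samples ≈ 0.9 s, order 3 —
unpublished upstream, recorded here as defaults) and events are called
against a threshold of $3\times$ the baseline s.d., estimated robustly as
$1.4826 \times \mathrm{MAD}$ of the smoothed trace so that the events
themselves barely inflate the estimate.

Two refinements to plain threshold crossing are deliberate design
choices:

* **Hysteresis.** An event epoch ends only when the smoothed trace falls
  below half the threshold. Without this, noise chatter around the
  threshold during a transient's decay is called as fresh events.
* **Merged-event splitting** (`split_merged`, default on). A transient
  arriving before the previous epoch has ended produces no new threshold
  crossing. Within an epoch, an additional onset is called where the
  *unsmoothed* ΔF/F falls and rises again by at least $3\times$ its own
  robust s.d.; the raw trace is scanned because the smoothing window
  (0.9 s) flattens exactly these shoulders. Setting
  `split_merged = FALSE` recovers the plain crossing detector.

Amplitudes are measured on the unsmoothed ΔF/F between onset and epoch
end: the filter attenuates the peak of a 0.5 s transient by roughly a
third, which would bias amplitudes systematically. Events closer than the
refractory period (5 samples) are never split — at a 0.2 Hz Poisson event
rate that alone forfeits ~9% of events, which is the dominant term in the
detector's frequency bias at high rates. The synthetic trace generator
defaults (0.2 Hz events, amplitude 0.4 ΔF/F = 8× the 0.05 noise s.d.,
0.5 s decay — a typical somatic calcium-indicator decay time) were fixed
once as the simulated study conditions.

Frequency is summarized per ROI and averaged over ROIs; amplitude is
pooled over events, so the two summaries carry different n's. Group
comparisons use a two-sided Mann–Whitney U test implemented from the rank
formulas: exact enumeration of all group assignments when the smaller
group has ≤ 8 observations *and* enumeration is tractable (≤ 200,000
arrangements — unconditional enumeration is infeasible against a large
second group), otherwise the tie-corrected normal approximation with
continuity correction.

## Survival, correlation and power statistics

LD50 days are survival times. A unit (donor by default, matching the
population screen's donor-level n; wells optionally) whose LD50 equals
the endpoint because the 50% threshold was never reached enters as
**censored**: it leaves the risk set without an event — the only
convention that does not count "no degeneration" as degeneration. The
Kaplan–Meier product-limit curve and the two-group log-rank test
(observed vs expected events with hypergeometric variance, $\chi^2_1$
reference) are implemented from their formulas; the tests verify both
against an independently coded tabulation to $10^{-9}$ and against
`survival::survdiff`.

Clinical correlations use Pearson or Spearman on pairwise-complete pairs,
with clinical variables optionally log-transformed first (the convention
when a log-normal distribution is observed). Expression-signature
comparisons report the Spearman correlation of paired log2 fold-change
vectors plus a permutation control built by randomizing the order of one
vector under a fixed seed; the analytic Spearman p-value is reported
alongside the permutation quantile, and the null should centre near zero
(the tests bound $|\bar\rho_{null}|$ by $3/\sqrt{n_{perm}}$).

`required_sample_size()` finds the smallest per-group n whose two-sample
t-test power (noncentral-t, $df = 2n-2$, $ncp = d\sqrt{n/2}$) reaches
$1-\beta$, floored at 2. The frozen regression value n = 6 at d = 2,
$\alpha = 0.05$, 80% power was verified against a 10,000-replicate
simulated-power oracle and `power.t.test` before being fixed in the tests.

## Interchange formats and the pipeline surface

Tables travel as long/tidy CSV (one row per plate–well–field–day, columns
`plate, well, donor, group, treatment, dose_uM, day, field,
total_length_um, status`); images as single-plane TIFF with a JSON sidecar
recording pixel size and intensity scale; configuration, manifests and
summaries as JSON. Days are integers (calendar day of differentiation),
lengths µm, doses µM — fixed by convention, never inferred.
`run_pipeline()` chains the stages (`simulate`, `quantify`, `phenotype`,
`screen`, `calcium`, `report`), writes each stage's outputs under one
directory and records a manifest (stages, seed, files, versions); a stage
failure aborts with an error naming the stage. The package's interface is
its functions — the pipeline runner is an R entry point, not a shell
tool.

## Numerical choices and degenerate inputs

* True LD50s of latent curves are solved on a 0.01-day grid restricted to
  post-peak times; endpoint returned when the curve never crosses.
* Ties and flat crossings: the first qualifying day wins, everywhere.
* All-failed or all-zero series raise quantification errors rather than
  returning sentinels; a failed reference day raises a reference error.
* Zero-variance traces raise an explicit detection error under the robust
  estimator.
* Every stochastic function takes a seed and restores the caller's RNG
  state; identical seeds give bit-identical output.

## Problem sizes used by the test suite

The suite exercises the study-scale configuration where it matters and
scaled-down sizes elsewhere, chosen as a sensible compromise between
fidelity and turnaround: 100 replicate screens of 22 control vs 65 case
donors for the detection-power check; 100 random curves for LD50 bias;
50 synthetic 256×256 px fields for the image oracle; 50 traces of 100 s
for detector recall (isolated 0.05 Hz regime) and 50 for frequency
recovery (0.2 Hz); 107 drugs × 16 donors × 200 null replicates for the
screen false-positive bound; 1000 replicates for test sizes.

## Known limitations

* The image pipeline is 2-D, single-channel, and reports no per-neuron or
  branch statistics; it measures total skeleton length only.
* Curve phenotypes are computed on raw observations; no curve fitting or
  mixed models, by design.
* The detector's frequency estimate is biased low at high event rates by
  the refractory period (events are not deconvolved).
* Dose–response modelling (EC50/4PL) is out of scope; screens are
  analyzed at fixed dose.
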