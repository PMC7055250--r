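---
title: "Forecasting craving and stress from GPS-derived environmental exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting craving and stress from GPS-derived environmental exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmapredict)
```

## The problem

Just-in-time adaptive interventions for substance-use disorders need to
anticipate high-risk moments — craving or stress — early enough to push
content before the moment arrives, ideally from passively collected input
only. `gmapredict` implements a complete geographical momentary assessment
(GMA) analysis for this problem: participants carry a GPS logger and answer
three random ecological momentary assessment (EMA) prompts per day rating
heroin craving, cocaine craving, and stress on a 1–5 scale; the pipeline
forecasts, 90 minutes ahead, whether a rating of 2 or higher will be
reported, using only the past 5 hours of GPS-derived environmental exposure
plus fixed person-level descriptors.

Because real study data of this kind (dense GPS tracks of people in
treatment) cannot be shared, the package ships a first-class synthetic-data
module that generates complete studies — exposure surface, participant
profiles, GPS tracks with injected signal errors, EMA responses — with a
known generative truth, so every downstream stage is testable end to end.

## The exposure measure

Environmental exposure is operationalized as property tax value, mapped in
30 m × 30 m pixels. Parcels carry a taxable value and a property category;
roads and sidewalks carry none, so road pixels are assigned value by
extending parcel values up to 50 m into the street with an inverse distance
model:

$$v_{road} = \frac{\sum_i d_i^{-p}\, v_i}{\sum_i d_i^{-p}},$$

over valued pixels within 50 m (center-to-center). The weighting exponent is
not pinned down by any external constraint; we use the conventional
$p = 2$, configurable in `fill_roads_idw()`. Road pixels farther than 50 m
from any valued pixel stay missing, and a filled pixel's category is that of
the nearest valued pixel (ties broken by scan order: nearer rows first).
Filled values are bounded by the donor range, and the fill never alters
non-road pixels. Pixel membership of a GPS point uses the floor convention
`floor((coordinate - origin) / 30)` with 0-based, half-open pixels; a pixel
center exactly on a parcel boundary belongs to the lowest-indexed containing
parcel, which makes rasterization deterministic.

## GPS cleaning

Loggers record a fix every 20 m of displacement or every 15 min, whichever
comes first, with per-fix quality indices (satellite count, HDOP, PDOP).
Cleaning has two stages:

1. **QA filtering** drops fixes with `nsat < 3`, `HDOP > 5` or `PDOP > 6`.
   These defaults follow common GPS QA practice; the pipeline is fully
   threshold-parametric (`qa_thresholds()`).
2. **Speed filtering** iteratively removes points implying an implausible
   velocity of **≥ 31.3 m/s** between adjacent fixes, until no such pair
   remains. Which member of an offending pair to drop is a genuine design
   choice; we remove the *later* point (the arriving fix) and resume the
   scan. Because a removal only alters the merged pair it creates, this is
   provably equivalent to restarting the scan from the beginning after every
   removal, which is how the test-suite reference implementation (an O(n²)
   recompute-everything filter) is written. A pair with non-positive elapsed
   time is treated as exceeding the threshold: duplicate timestamps are
   physically impossible. After filtering, per-point speed and distance
   before/after are recomputed across the surviving points.

## Linkage and feature construction

Exposure samples along the cleaned track are aggregated into clock-aligned
30-min bins (UTC :00/:30 boundaries, half-open). Each bin carries the mean
of `log10(value + 1)` — tax values are log-normal by construction and
heavy-tailed in reality — the property-category proportions, the within-bin
travel distance, and a sample count. A bin with no usable sample (including
time spent outside the covered region) is missing; missing bins are
forward-filled from the most recent observed bin within 24 h, with travel
distance reset to 0 because a filled bin represents no observed movement.

Prediction instances are anchored on the 30-min grid: every boundary `t`
with at least one EMA entry in `(t, t + 90\,\mathrm{min}]` yields one
instance per outcome. The label is the OR of the dichotomized outcome
(1 → 0, 2–5 → 1) over the window — a positive in any of the next three
30-min bins. Features are the 10 bins covering `[t - 5\,\mathrm{h}, t)`
(5 hours of exposure per prediction) plus the person-level predictors: sex,
age, race, Hispanic ethnicity, high-school graduation, years of education,
marital status, professional training, current employment, and per-drug
recent use days, lifetime years of use, and typical route of
administration. Grid-anchored instances (rather than entry-anchored ones)
match the three-bin lookahead literally and make the anchor set reproducible
from the clock alone. Instances whose entire feature window is missing are
dropped; residual missing bins stay `NA` and are median-imputed from each
training split only. We end the feature window exactly at the anchor — the
most recent information a deployed model would have at decision time.

## The tailoring protocol

The classifier is a random forest of 200 trees with `ceiling(p/3)` candidate
variables per split, fit per (target participant, run, outcome) with a
derived seed so the whole protocol is reproducible. Run `k` for a target
trains on all other participants' instances plus the target's instances from
study weeks `0..k-1`, and predicts the target's weeks `k` onward; run 0 is
the leave-one-out "off the shelf" model with no target data, and a
participant with `w` observed weeks gets runs `0..min(w, 15)` — up to 16
runs. The presence call uses the fraction of trees voting presence with an
inclusive 0.5 threshold (majority vote); no probability cutoff beyond
majority vote is imposed, and no class rebalancing is applied — the
prevalence-driven asymmetry between specificity and sensitivity is part of
what the analysis studies. Temporal leakage is asserted at run time: no
target training instance may sit at or after week `k`, and no feature bin
may overlap the label window.

## Accuracy decomposition

Each participant-run yields one confusion matrix over all remaining test
weeks (each run is a separate deployment scenario) and five measures:
overall accuracy, sensitivity, specificity, PPV, NPV. A measure with a zero
denominator is **undefined** and kept as `NA` end to end — PPV when no
presence was predicted, sensitivity when the event never occurred — and
aggregation reports per-measure n, never zero-filling. The identity
`accuracy = prevalence × sensitivity + (1 − prevalence) × specificity`
holds exactly wherever all terms are defined and is enforced by property
tests. Weekly prevalence is summarized both raw and as a cumulative
proportion (running positives over running responses); the cumulative form
smooths week-to-week sampling noise. Both series are emitted and labeled
distinctly, since either reading of a "running tally" is defensible.

## Trajectory clustering

To use outcome prevalence as a person-level predictor, weekly prevalence
trajectories are clustered with a Gaussian latent-class growth model:
$K$ classes, each a degree-2 polynomial in week, shared residual variance,
no within-class random effects — the canonical LCGM. Fitting is EM with 20
random restarts (log-likelihood monotonicity is asserted every iteration;
convergence at absolute change `< 1e-6` or 500 iterations), and $K$ is
selected by BIC over 1..5 with ties to the smaller $K$; a class whose weight
falls below $1/(10N)$ is pruned and the model refit. Treating proportions as
Gaussian observations follows LCGM convention; an empirical-logit option is
provided. The four classes of the selected model are named deterministically
— lowest mean level `low`, highest `high`, and the middle pair
`medium-decreasing` / `medium-increasing` by the sign of their fitted
first-to-last-week change — so that labels are reproducible across runs.

## Person-level correlates of accuracy

Accuracy differences by sex, race, and prevalence cluster are tested with
random-intercept multilevel models (REML): fixed effects for the group, the
centered run index, and their interaction; a random intercept per
participant. Incomplete series (undefined measures) are simply absent —
multilevel models accommodate unbalanced repeated measures without
imputation. The four-level cluster enters as a linear contrast over the
ordered cluster codes. Satterthwaite t statistics convert to effect sizes by
$d = 2t/\sqrt{df}$ with 95% limits from noncentral-t inversion (normal
approximation as a documented fallback). The joint race + cluster model
includes both main effects plus run; if apparent race differences are an
artifact of differential prevalence, adjusting for cluster should collapse
the race effect while the cluster effect persists — the package's acceptance
suite reproduces exactly that signature on confounded synthetic data.

## The synthetic-data generator

The generator encodes the study conditions rather than any particular
city's geography:

* **Surface**: a rectangular-parcel partition of a 30 m grid with a street
  grid overlay (`road_fraction`, default 0.15), per-category log-normal
  values (residential/commercial/industrial/exempt), and an east-west trend
  on log value (`poverty_gradient`) so exposure varies spatially.
* **Movement**: each participant has a home plus 2–4 anchor locations and
  walks between them (1.0–1.6 m/s) on a daily routine, dwelling otherwise;
  fixes follow the 20 m / 15 min logging rule. A fraction
  `gps_error_rate` (default 1%) of fixes become signal errors: teleport
  outliers displaced tens of kilometers (so that even a 15-min fix gap
  implies a speed over the 31.3 m/s threshold) with clean QA fields, or
  degraded-QA points that the QA stage must catch. All injections are
  recorded in a truth log that only tests may read.
* **Outcomes**: a latent logistic model. For participant $i$, outcome $o$,
  prompt at week $w$:
  $\mathrm{logit}\, p = \tau_{c_i}(w) + \delta_o + u_i + \beta_o x + \epsilon$,
  with $\tau_c$ the class trajectory (flat 5% for `low`, flat 55% for
  `high`, 10↔30% linear for the medium classes), outcome offsets
  $\delta$ = 0 / −0.7 / +0.9 (heroin, cocaine, stress — reproducing the
  observed ordering cocaine < heroin < stress), person intercepts
  $u_i \sim N(0, 0.8^2)$, exposure index $x$ = centered mean log tax value
  over the past 5 h along the *error-free* track, slope $\beta_o = 0.5$ per
  outcome by default, and person-day noise $\epsilon \sim N(0, 0.5^2)$.
  Positive responses map to ratings 2–5 by fixed thresholds on the latent
  value (cosmetic: the analysis uses only the dichotomy). Waking hours
  default to 09:00–21:00 — the generative window is fixed for
  reproducibility, not sampled per participant. Weekly dropout hazard is 2%.
  The generator simulates the three random prompts per day that the analysis
  uses; end-of-day and self-initiated entries are out of scope.

The defaults are the package's statement of "realistic study conditions":
they produce cohorts whose prevalence, heterogeneity, and exposure coupling
give the tailoring protocol something real to learn. What the generator
deliberately does **not** emulate: street-network topology, cadastral parcel
shapes, device battery artifacts, and EMA compliance dynamics beyond
dropout. Passing tests therefore demonstrate that the pipeline machinery is
correct and that the qualitative accuracy phenomena (tailoring benefit,
prevalence-accuracy artifact, race-cluster confounding) emerge under the
stated generative assumptions — not that any particular accuracy level
would be attained on field data.

## Problem sizes and numerical choices

The end-to-end checks run a 12-participant, 8-week cohort (about 130,000
fixes and 4,700 instances, ~100 forest fits) — large enough for every
protocol path to execute and the tailoring curve to be visible, small
enough to run routinely on a laptop core. The null-calibration check uses
8 exchangeable participants over 3 weeks; LCGM recovery uses 60
participants over 16 weeks with class separations of at least five residual
SDs. Forests use fixed derived seeds and single-threaded prediction, making
the entire pipeline byte-reproducible from one master seed. Degenerate
inputs are handled explicitly: empty tracks warn and pass through, tracks
of ≤1 point skip the speed filter, single-class training sets yield
constant classifiers, zero-denominator metrics stay undefined, and EM
mixtures prune vanishing classes.

## Known limitations

* The original study's headline numbers (accuracy 0.93, PPV in the high
  0.70s at 189 participants over 16 weeks) are not reproducible at package
  test scale and are not targets of the test suite; the suite checks the
  qualitative structure of the results instead.
* The planar-coordinate convention assumes an upstream projection; no CRS
  machinery is included.
* The speed filter's drop-the-later-point rule may differ from other
  implementations in edge cases (the choice is not externally constrained).
* LCGM fits assume Gaussian residuals on proportions; for very sparse weeks
  the logit option is preferable.
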