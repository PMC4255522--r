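---
title: "Methods: trial-by-trial topographic analysis of picture-naming ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-by-trial topographic analysis of picture-naming ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model behind
each stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the
methodology left room.

## The analysis problem

In overt picture naming, roughly 500–1500 ms elapse between picture onset
and articulation. The working hypothesis of topographic ERP analysis is
that this interval is tiled by a small number of quasi-stable scalp-field
configurations (microstate maps), each indexing a processing stage:
visual/conceptual analysis early, lexical selection in the middle,
phonological/phonetic encoding late. If a psycholinguistic property of the
item (say, age of acquisition) taxes one stage, the duration of the
corresponding map should lengthen on trials with that property — so
regressing single-trial map durations on item predictors localizes each
predictor's cost in time.

The pipeline is: epoch bookkeeping and artifact screening, merging of
stimulus- and response-aligned epochs into one encoding-period ERP per
trial, microstate segmentation of the grand average, backfitting of the
template maps into each single trial within fitting windows, and crossed
random-effects regression of the per-trial durations.

## Preprocessing

* **Amplitude rejection** removes a trial when any sample on any channel
  exceeds ±100 µV in either epoch. The bound is strict (a sample at
  exactly the threshold is kept); with continuous data, ties have measure
  zero, so strictness only pins down reproducible counts.
* **Reaction-time screening** removes error trials first, then correct
  trials with RT below 500 or above 1500 ms (strict bounds). Percentages
  are reported against the full trial count, in that order, so the
  bookkeeping of a 31 × 100 study with 50 errors and 62 RT outliers
  reproduces as 1.6% and 2%.
* **Bad channels** are rebuilt per epoch by spherical-spline interpolation
  (order m = 4, 20 Legendre terms, ridge 1e-5 on the spline system).
* **Merging**: the merged trial runs from picture onset to RT − 100 ms.
  Samples up to 450 ms come verbatim from the stimulus-aligned epoch; the
  rest verbatim from the tail of the response-aligned epoch (which ends
  100 ms before articulation). The stimulus-aligned signal wins the
  overlap. For RT > 1000 ms the two alignments cannot cover the interval;
  strict mode (the default for replication-style runs) drops such trials
  with a log entry, permissive mode cross-fades the gap and flags it.
* **Filtering** uses a zero-phase Butterworth band pass (order 4 per
  pass, 0.2–30 Hz), applied *after* merging so that one continuous
  encoding-period trace is filtered once, rather than two separately
  filtered segments meeting at the junction. On a sub-second epoch a
  0.2 Hz high pass is indistinguishable from removing the epoch's own
  mean topography — a map-dependent distortion. Averages (grand and
  per-subject), where that removed mean is common to every trial, get the
  full band; single trials get the 30 Hz low pass only. This placement is
  a package choice: it measurably removes a bias in single-trial map
  durations (the coefficient-recovery harness is the evidence), at the
  price of leaving slow drift in single trials — irrelevant for the
  synthetic data (white sensor noise) and worth re-examining for real
  recordings with strong drift.
* Epochs are not baseline-corrected by default; the topographic measures
  are reference-free and the merged-epoch filtering handles offsets.

## Segmentation

TAAHC starts from one cluster per frame and repeatedly atomizes the
cluster with the smallest GEV contribution, reassigning its members by
signed spatial correlation to the surviving templates (templates are
GFP-normalized means of their members' normalized maps). Two choices
matter:

* **Polarity is respected.** These are evoked responses; a map and its
  inverse are different states.
* **Lloyd refinement.** The purely greedy path can leave the recorded
  K-cluster solution far from the best K-partition, because a small but
  genuine cluster (the short map B) contributes little GEV and is
  atomized before diffuse transition clusters. At each recorded K the
  solution is therefore polished by reassign-recompute iterations until
  stable (`refine = 25`; `refine = 0` recovers the strict hierarchy in
  which the K−1 solution is the K solution minus one cluster).

Model order is chosen from the dispersion curve W (summed squared
topographic distance of each normalized frame to its template). The
Krzanowski–Lai ratio uses the channel count as the dimensionality
exponent. Two guards are applied, both documented consequences of the
estimator's known pathologies rather than tuning:

* KL is undefined at the boundary K values.
* A candidate K is eligible only if its own dispersion drop
  W(K−1) − W(K) is at least 5% of the total drop over the explored range;
  as W flattens, DIFF(q+1) → 0 and the raw ratio explodes at cluster
  numbers that explain almost nothing.

The CV criterion uses polarity-sensitive projection (residual variance
after projecting each frame on its assigned unit-norm template). When the
KL peak and CV minimum disagree, the KL peak is used and a warning is
emitted — the combination rule is a package choice, as the criteria's
originators specify none. Selected maps shorter than 20 ms are dissolved
frame-by-frame into whichever flanking map correlates better (one run per
pass, iterated to a fixpoint). Finally maps are relabeled A, B, C, … by
their median time of occurrence.

## Backfitting

Within each fitting window, each frame is labeled with the allowed
template of highest signed correlation. No temporal smoothing and no
correlation floor are applied — the measurement is deliberately the
simplest one, so durations are sums of frame counts times 1000/fs. Window
borders are half-open in time ([start, end)); ties, including zero-GFP
frames (which correlate 0 with everything), go to the lowest allowed
index and are deterministic. Windows shorter than 2 frames after
resolution exclude that trial from that window with a logged count.

The replication windows are 50–180 ms (maps A, B), 180–460 ms (B, C, D)
and 460 ms to RT − 100 (D, E). Note a structural property: a state
boundary that coincides with a window border whose far side disallows the
neighbor (the B/C boundary at 180 ms) is *censored* — variability of that
boundary below the border cannot be observed. This is inherited from the
window design, not a bug; the validation harness therefore measures
coefficient recovery with boundary-interior windows (50–460 ms allowing
A–D; 460 to RT − 100 allowing D, E), where every generative boundary lies
strictly inside a window containing both neighbors.

## Topographic consistency test

At one frame, the observed statistic is the GFP of the across-trial mean
map; the null shuffles channel values independently within each trial
(each trial's GFP is preserved, shared spatial structure is destroyed);
p = (1 + #{null ≥ observed}) / (n_perm + 1). Defaults: 999 permutations,
α = 0.05, and a 20 ms minimum run length for a period to count as
consistent (matching the segmentation's minimum map duration). The scan
runs per item, since trials of one item share stimulus-relative timing.
With 99 permutations the attainable p-grid makes the exact type-I rate
4% at nominal 5%; the calibration check's acceptance band (3–7%)
brackets this.

## Mixed models

Latency and per-map duration models share the fixed-effect entry order:
LD20, positional segment frequency, positional diphone frequency, log
lexical frequency (book or film counts — both supported, book entered by
default), concept familiarity, visual complexity, image agreement, name
agreement (% modal name; the entropy H is carried but not entered, to
keep a single name-agreement row), age of acquisition. Participants and
items are crossed random intercepts; by-participant random slopes start
with the reported-effect terms (AoA, IAgr, NAgr) and are removed in
reverse entry order until the optimizer converges and the slope
covariance is non-singular (a singular intercepts-only fit — a variance
estimated at zero — is accepted and flagged, which also makes the
zero-variance/OLS equivalence hold). Each model is fitted twice, the
second time without observations whose conditional residuals exceed 2.5
residual SDs (strict bound); reported coefficients come from the refit.
Significance uses Satterthwaite degrees of freedom; α is 0.05 for the
latency model and 0.01 per map-duration model (Bonferroni over five
maps). Marginal/conditional R² partition variance as
var(fixed)/(var fixed + random + residual), with the random-effect
variance computed exactly from the fitted covariance (mean per-observation
diagonal of ZΣZᵀ), which is valid under random slopes. Tolerances
(1 − R² of each predictor on the others) flag collinearity below 0.5. A
variant latency model swaps the neighborhood/phonotactic measures for the
syllable count, which correlates with them above 0.6 by design of the
norms generator.

The phonotactic score aggregates the per-position frequency ratios by
arithmetic mean, and log frequencies are expected strictly positive
(log10 of frequency per million + 1) — both flagged choices, since the
verbal definition fixes only the per-position ratio. LD20 excludes one
exact-form lexicon occurrence as the word's own entry
(`exclude_self = FALSE` when the lexicon is known not to contain the
word, in which case identical forms are genuine homophone neighbors).

## The synthetic-data generator

The generator emulates the statistical structure of a 30-participant,
100-item high-density (128-channel, 512 Hz) study:

* **Templates** are mutually orthogonal smooth maps (a random rotation of
  an orthonormalized basis of first- and second-order functions of
  electrode position). Orthogonality comfortably satisfies the pairwise
  dissimilarity floor (DISS ≥ 0.8) and keeps transition mixtures from
  imitating a third map.
* **Norms** come from a Gaussian copula reproducing the reported
  correlation structure (lexical frequency: −0.366 with image agreement,
  0.283 with familiarity, −0.260 with age of acquisition; syllable count
  above 0.6 in magnitude with LD20 and the phonotactic scores; the rest
  near zero), with marginals on each predictor's natural scale.
* **Durations** follow the linear model per state with effects lifted
  as defaults: visual complexity −1.92 ms/unit on map
  B; image agreement −8.67, name agreement −1.08 and AoA +9.92 on map D;
  name agreement −0.67 and AoA +7.6 on map E (predictors centered at
  scale midpoints). Mean durations 90/40/200/240/85 ms plus a 150 ms
  offset give a mean RT near 805 ms. Trial-to-trial variability has
  per-state residuals, crossed participant/item intercepts, and a shared
  per-trial speed component weighted toward the late states.
* **Signal**: the active state's template times a half-sine amplitude
  bump with a 0.3 floor (components wax and wane; GFP dips at
  transitions but does not vanish), baseline before 50 ms and after
  articulation − 100 ms, plus white sensor noise. Epochs are then cut to
  the raw stimulus-aligned (0–450 ms) and response-aligned (−550 to
  +100 ms) windows, so merging and screening are exercised for real.

Deliberate simplifications, and hence what passing tests do *not* show
about real data: the state sequence is strictly serial A→E with no
re-entries; sensor noise is spatially and temporally white (an option for
spatially smooth noise exists); there is no ocular/muscular artifact
morphology beyond injected amplitude transients; templates are exactly
orthogonal, which is cleaner than real component overlap; and the
trial-level variance allocation keeps early boundaries tightly
stimulus-locked and late ones response-locked, so the realized RT SD
(~110–160 ms depending on configuration) sits below the ~180 ms of real
naming studies. That allocation is what lets a grand average over jittered
trials retain all five maps — with more early-boundary jitter the short
map B blurs out of the average, which is a statement about grand
averaging, not about the backfitting of single trials.

Two constraints are enforced by resampling a trial's durations (bounded
retries): all state durations positive (≥ 4 ms) and RT within
(500, 1500) ms. Resampling conditions the accepted distribution; with the
default variances the acceptance probability is high enough that the
generative coefficients are preserved (the ground-truth refit inside the
validation harness checks exactly this).

## Validation harnesses and problem sizes

`k_selection_rate()` simulates studies and reports the KL/CV-selected K;
the packaged checks run 10 seeds at 12 × 40 trials, 32 channels, 256 Hz.
`coefficient_recovery()` runs the full pipeline (permissive merging — the
strict gap rule would truncate the RT distribution at 1000 ms and bias
every RT-correlated coefficient; latency model on the full behavioral
set; boundary-interior windows; segmentation at the generative K) and
reports per-coefficient estimates, Satterthwaite confidence intervals,
and significance; the packaged checks use 3 seeds at the full
30 × 100 size with 32 channels at 256 Hz and sensor noise chosen so the
single-trial frame-to-template correlation sits near 0.5 — the channel
count and rate are reduced from the 128/512 defaults purely to keep the
checks fast, with noise rescaled to preserve that correlation regime.
`tct_type1()` calibrates the consistency test (500 null repetitions, 99
permutations). The acceptance script (`scripts/acceptance.R`) strings all
of these together from one seed.

## Known limitations

* TAAHC with refinement is deterministic but still a local optimizer;
  pathological inputs can yield suboptimal partitions at some K.
* The KL eligibility guard (5% of total drop) is a heuristic; for data
  whose true structure produces genuinely tiny late drops it would mask a
  legitimate peak.
* Importing real recordings is limited to the plain-text epoch container;
  binary EEG formats are expected to be converted upstream.
* The regression layer assumes Gaussian responses; durations are sums of
  frame counts and can be granular for very short maps at low sampling
  rates.
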