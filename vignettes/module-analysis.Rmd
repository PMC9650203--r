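---
title: "Muscle co-excitation modules, gait symmetry and motor-pathway asymmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle co-excitation modules, gait symmetry and motor-pathway asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modwalk)
```

## The scientific problem

After a stroke, many people lose the ability to activate leg muscle groups
independently during walking and fall back on a *mass flexion-extension
co-excitation pattern*: one muscle group that fires together throughout
stance (plantarflexors, quadriceps, hamstrings, gluteus medius) and one
that fires during swing (dorsiflexors, rectus femoris). Module analysis
quantifies this. Surface EMG of eight paretic-leg muscles (TA, SO, MG, VM,
RF, MH, LH, GM) recorded during treadmill walking is factorized by
non-negative matrix factorization (NNMF) into a small number of *modules*
— co-excited muscle groups with a shared activation profile over the gait
cycle. Healthy adults typically walk with four modules; severely affected
stroke survivors with two. Whether a person is a "two-module walker" is
then related to walking performance (propulsion symmetry, step-length
symmetry, clinical scores) and to the structural integrity of two
descending motor pathways, the corticospinal tract (CST) and the
corticoreticular pathway (CRP), summarized as interhemispheric streamline
asymmetry ratios from tractography.

`modwalk` implements the full analysis pipeline plus a synthetic-subject
generator with retained ground truth, so every stage has a
parameter-recovery test surface without any subject data.

## The EMG processing chain

1. **Envelope** (`emg_envelope`): high-pass at 40 Hz, demean, full-wave
   rectify, low-pass at 4 Hz. Both filters are zero-lag: a second-order
   Butterworth design applied forward and backward, so the *net* response
   is fourth order with no phase shift. We read the conventional
   "zero-lag fourth-order" description as the net bidirectional response;
   the alternative (fourth-order design each way, eighth-order net) mainly
   sharpens the transition band and does not change any downstream
   decision on our synthetic data. Reflective padding of three settle
   lengths suppresses end transients, and residual negative ringing is
   clipped at zero because NNMF requires nonnegative input.
2. **Gait events** (`detect_gait_events`): heel strike and toe-off are
   sustained threshold crossings of the vertical ground reaction force
   (GRF). Defaults: 20 N threshold, 10 ms debounce — conventional for
   instrumented treadmills.
3. **Segmentation** (`segment_and_normalize`): each paretic
   heel-strike-to-heel-strike cycle is resampled to 101 points (0–100% of
   the cycle) by linear interpolation and averaged pointwise. Cycles are
   half-open: the 100% point of one cycle is the next cycle's first
   sample. At least 20 cycles are recommended (a warning is raised below
   that).
4. **Six bins** (`bin_average`): first double support, first/second half
   of single stance, second double support, first/second half of swing.
   The interior boundaries are the *average* percent-of-cycle timing of
   nonparetic toe-off, nonparetic heel strike and paretic toe-off, applied
   to the averaged cycle. (The alternative — per-cycle binning, then
   averaging bin values — differs only at second order in the jitter; we
   average cycles first because the averaged time-normalized cycle is the
   stated unit of further analysis.)
5. **Amplitude normalization** (`normalize_amplitude`): each muscle is
   divided by its highest bin mean, so the most active region of each
   muscle averages 1. Normalizing to the mean of the most active region
   rather than the instantaneous peak reduces between-subject
   variability. All-zero channels raise an error by default (silent
   division by zero would be worse); `on_zero = "drop"` removes the
   muscle with a warning.

Bin means are computed over all cycles of the recording before
normalization; the ordering question (normalize before vs. after cycle
averaging) is immaterial here because both operations are linear per
muscle.

## Module extraction and the VAF rule

`nnmf_fit` minimizes squared Frobenius error with multiplicative updates
(maximum 10,000 iterations; convergence when the relative SSE decrease
over 10 iterations falls below 1e-6), run from 50 seeded random restarts
by default plus a warm start (the previous `k` solution padded with a
low-magnitude random module) when available. The best-SSE solution is
returned in canonical form: weight columns scaled to unit maximum with
compensating activation scaling. Ties between restarts go to the lower
restart index, making fits bit-reproducible. The inner loop is compiled
(RcppArmadillo).

Variability accounted for is **uncentered**:
`VAF = 100 (1 - SSE / SSQ)` with SSQ the sum of squared data entries,
computed overall, per muscle (row over the whole cycle), and per bin
(columns inside the bin boundaries, pooled across muscles). The 90%/5%
thresholds in this literature were calibrated against uncentered VAF,
which is why we do not subtract means. "Cumulative VAF for all muscles in
each bin" is read as per-bin pooled across muscles, with per-muscle VAF
computed over the whole cycle.

`select_module_number` adds modules until either every muscle *and* every
bin reaches VAF ≥ 90%, or adding one more module raises no individual
muscle or bin VAF by more than 5 percentage points (the probe fit is then
discarded), with a hard cap of 8. Warm starts make the overall VAF
non-decreasing in `k`, which is asserted in the test suite. Subjects are
dichotomized as `two_modules` (k ≤ 2) versus `more_than_two`; a
one-module solution (which does not occur in realistic cohorts) falls on
the two-module side of the dichotomy by construction.

## Gait metrics

Paretic propulsion `Pp` is the paretic leg's positive anterior impulse
(trapezoidal integral of the positive part of the anterior GRF, at the
native 2,000 Hz sampling) divided by the summed positive impulse of both
legs; integration runs over the whole analyzed trial, since positive
anterior force is confined to late stance anyway. The paretic step ratio
`PSR` is mean paretic step length over mean stride length. Deviation from
symmetry is `|value - 0.5|` for both, so 0 is perfect symmetry and 0.5
the maximum.

## Streamline asymmetry and harmonization

Interhemispheric asymmetry is the ratio of streamline weights:
lesioned/non-lesioned hemisphere for stroke survivors, right/left for
controls; 1 means symmetric. Scanner-batch effects are removed by a
location–scale adjustment per feature (tract × hemisphere label): every
batch is standardized to the feature's pooled mean and SD. This removes
additive and multiplicative batch offsets and preserves within-batch rank
order; it deliberately omits the empirical-Bayes shrinkage of full
ComBat, which matters mainly for very small batches. Harmonized weights
near zero can become negative; they are not clamped, and they propagate
into the ratios — published tree cutoffs on such data can legitimately be
negative (e.g. a CST asymmetry threshold of −0.02). Ratios are computed
*after* harmonization; a zero denominator flags the subject for exclusion
from correlations rather than silently producing infinities.

## Cohort statistics

* `spearman_cor`: tie-corrected (midrank) Spearman rho with a two-sided
  t-approximation p on n − 2 degrees of freedom, pairwise-complete
  deletion. No multiplicity adjustment is applied across the correlation
  battery — the walking measures are interrelated, so the battery is
  exploratory by design.
* `mann_whitney`: U counts pairs with `a > b` plus half ties; the p-value
  is exact (null distribution of U) when there are no ties and
  `n_a n_b ≤ 10000`, otherwise a tie-corrected normal approximation
  (without continuity correction).
* `anova_posthoc`: one-way ANOVA with Bonferroni-adjusted pairwise
  t tests (pooled SD), capped at 1.
* `fit_coarse_tree`: a "coarse" CART — Gini impurity, candidate
  thresholds at midpoints between sorted distinct values, best-first
  growth, at most 4 internal splits, minimum leaf size 1. Tie-breaks are
  deterministic (lower feature index, then lower threshold, then lower
  node id), which makes training invariant to record order. The left
  branch is strict `feature < threshold`, matching how published cutoff
  rules are written. `cross_validate_tree` runs seeded class-stratified
  five-fold cross-validation and also reports the resubstitution
  confusion of the full-data tree, because published classification
  counts are typically resubstitution-style; both are labeled.
* `fma_threshold_classifier`: the comparator rule — a score below 15 on
  the 22-point synergy subsection of the lower-extremity Fugl-Meyer
  predicts a two-module pattern.
* `confusion_report`: exact counts and percentages; display values are
  truncated toward zero to whole percents (7/13 displays as 53%), the
  convention used when such counts are reported.

## The synthetic generator

`generate_emg` builds raw-like EMG by tiling ground-truth module
activations across gait cycles with lognormal duration jitter (3% SD by
default — realistic treadmill variability that does not break event
detection), mixing through the ground-truth weights, and
amplitude-modulating a band-limited (20–450 Hz) zero-mean Gaussian
carrier — the standard surface-EMG surrogate, chosen because it survives
the 40 Hz high-pass. Envelope noise is additive Gaussian scaled to a
fraction of each channel's RMS. `generate_grf` uses half-sine propulsive
lobes with identical shape on both legs scaled by `2 pp_true` and
`2 (1 - pp_true)`, so the impulse ratio equals the target analytically;
step lengths share each stride's jitter factor so the step ratio is
exact. GRF measurement noise defaults to 0.5 N, the order of a
force-plate noise floor after anti-aliasing.

The two-module template loads SO, MG, VM, LH, MH, GM on a
stance-activated module and TA, RF on a swing-activated module; three-
and four-module templates split stance along the healthy convention
(plantarflexors; quadriceps + gluteus medius; hamstrings; dorsiflexors +
rectus femoris). Activation timing uses Gaussian bumps with per-subject
jitter; cycle timing, speeds and bump widths are conventional choices,
not cohort-derived, since per-subject cycle statistics are rarely
published.

`generate_cohort` ("paper-like" scenario) draws stroke survivors in
three subgroups mirroring the published post-hoc group structure —
correctly classified multi-module walkers (A), two-module walkers whose
streamline asymmetry looks like the multi-module group (B), and severely
asymmetric two-module walkers (C) — in proportions 28/6/7 of 43, plus two
multi-module subjects with low asymmetry (the classifier's natural
errors on that class). Ipsilesional CST/CRP and contralesional CRP
Poisson means are the published group means (4.1/5.5/0.5, 8.6/10.7/3.3,
13.2/11.5/16.8). Contralesional CST means are not published; we chose
6/5/4 so that CST asymmetry separates the severe subgroup *less* cleanly
than CRP asymmetry, consistent with a classification tree whose root
split is on CRP. Scanner batches get a shift/scale distortion that the
harmonization removes. Clinical scores and the propulsion target are
linear in the subject's realized raw asymmetry ratios plus Gaussian
noise; the signs follow the observed correlation directions (better
FMA-LE, DGI, six-minute-walk, Berg balance and speed with more
symmetric pathways; larger propulsion asymmetry with less symmetric
pathways) and the magnitudes were fixed once to give moderate-to-strong
correlations (|rho| ≈ 0.5–0.65) at n ≈ 43.

What the generator does **not** emulate: musculoskeletal dynamics (GRFs
are parametric lobes, not simulated mechanics), EMG artifacts and
crosstalk, lesion anatomy, or any imaging. Passing recovery tests
therefore show that the *pipeline* is correct and well-conditioned at
realistic noise levels — not that the biological effect sizes are
validated on real cohorts.

## Numerical choices and degenerate inputs

* Bin-column selection uses a 1e-9 tolerance on the percent grid so that
  event-derived boundaries (e.g. 62.000000000000014) bin identically to
  exact ones.
* NNMF multiplicative updates guard denominators with 1e-12; warm-start
  padding uses magnitudes of 1e-3 of the data mean so the padded
  solution starts essentially at the previous optimum.
* Degenerate propulsion targets (`pp_true` of exactly 0 or 1) require an
  explicit flag and produce a zero-impulse leg; both-legs-zero impulse is
  an error rather than 0/0.
* Single-class tree training returns a one-leaf tree (not an error);
  majority ties in a leaf go to the first listed class.
* All randomness flows through per-call seeds; the caller's RNG state is
  saved and restored.

## Problem sizes used in the shipped simulations

The test suite and the acceptance script use, as the package's chosen
simulation sizes: 100 synthetic subjects per true module count (2, 3, 4)
at envelope noise 0.05 with 20 cycles each and 10 NNMF restarts (warm
starts make the selection insensitive to the restart count on these
envelopes; the default for real analyses remains 50); 51 seeded cohorts
for the tree-structure rate; 100 seeded cohorts for Spearman sign
recovery; 200 random small samples per statistic for the brute-force
oracle comparisons; and 1,050 random partitions for the VAF oracle.

## Known limitations

* The tree's printed cutoffs (CRP < 0.27, CST < −0.02) are cohort
  statistics; on synthetic cohorts the fitted thresholds vary with the
  seed, and only the *structure* (CRP at the root, CST refining) is a
  stable property. The fixture constructor `coarse_tree_from_rules`
  exists precisely to apply published cutoffs without refitting.
* The simplified harmonization is not empirical-Bayes ComBat; with many
  small batches it will under-shrink.
* Module analysis is implemented for the paretic leg only, matching the
  analysis it reproduces.
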