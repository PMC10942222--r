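---
title: "Gesture-based surgical skill assessment: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gesture-based surgical skill assessment: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Global rating scales such as GOALS give reasonable feedback on laparoscopic
skill but require expert reviewers and carry subjective bias. An
alternative is to annotate surgical video with elementary functional
gestures ("Surgestures" — hook, grasp, push, and so on) and to derive skill
from the statistics of those timed event streams. This package implements
that analysis for laparoscopic cholecystectomy (LC): it models annotated
timelines of the two technically critical phases — mobilizing the
hepatocystic triangle (MHT) and dissecting the gallbladder from the liver
bed (DGB) — extracts a fixed 63-feature representation per video, derives
competence labels from modified-GOALS (mGOALS) ratings, compares groups
statistically, and trains five classical classifiers under surgeon-grouped
cross-validation. Because clinical annotations of this kind are not
publicly released, the package ships a synthetic cohort generator so the
entire pipeline is exercised end to end by code.

```{r, eval = FALSE}
library(surgesture)
cfg <- pipeline_config(
  out_dir = "run1",
  simulate = cohort_config(seed = 1),
  augment = augment_params(seed = 1),
  seed = 1)
run_pipeline(cfg)
```

## Data model

A `surgesture_case` is one video: an ordered table of events
(`phase`, `label`, `hand`, `start_s`, `end_s`), per-phase durations, and
clinical metadata (Parkland difficulty grade, critical-view-of-safety
score, intraoperative events). Times are phase-relative seconds on
half-open intervals `[start, end)`, so an event may begin exactly when the
previous one of the same hand ends. Events of *different* hands may
overlap — a retracting grasp routinely holds while a hook dissects — but
events of the same hand may not. Parsing sorts events by (phase, start,
hand, label), a total order, so a parsed case is invariant to input row
permutations.

The default taxonomy has 14 gestures. Six are tracked per hand (grasp,
inefficient grasp, push, pull, spread, retract) and eight as single
streams (hook, inefficient hook, blunt dissection, cut, clip, coagulate,
suction, irrigate), giving 2×6 + 8 = 20 tracked categories. Only six of
the fourteen names are fixed by the published figures; the rest are
declared placeholders, and the whole vocabulary is overridable through a
YAML config (`load_taxonomy()`). Each gesture carries a functional class:
dissection = {hook, inefficient hook, blunt dissection, cut, clip,
coagulate, spread}, exposure = {grasp, inefficient grasp, push, pull,
retract, suction, irrigate}. Inefficient variants inherit the class of
their base gesture; whether they should instead be excluded from the
dissection/exposure (D/E) ratio is not documented anywhere we know of, and
inheritance is the conservative choice (it keeps every event classified).

## The 63 features

For `C` tracked categories the feature vector has `2C + 12 + 3 + 7 + 1`
entries — 63 at the default `C = 20`:

* **Counts and durations (20 + 20).** Per category, the number of events
  and their total duration (seconds), pooled over both phases.
* **Intervals (12).** For three event streams — all events, left-hand
  events, right-hand events — the gaps between consecutive events within
  a phase (never across the phase boundary), clamped at zero where pooled
  streams overlap, summarized by mean, max, min, and sample (n−1) standard
  deviation. The allocation of the 12 interval slots to 4 statistics × 3
  streams is our reading of the published feature groups (the figure-level
  evidence names a "shift frequency of right Surgestures", implying
  handed streams); it is the package default and reconfigurable in
  principle via the taxonomy. Streams with fewer than two events in every
  phase report zeros with a warning; a single gap reports SD 0.
* **Shift frequencies (3).** Label changes between consecutive events of
  each stream, per minute of manipulation time. A rate rather than a raw
  count so that it is comparable across cases with different operative
  times.
* **D/E items (7).** Counts and durations of dissection- and
  exposure-class events, their two ratios, and the per-minute rate of
  D↔E class changes along the all-events stream. Zero denominators are
  floored at 1 event / 1 s (with a warning) so feature matrices stay
  finite.
* **Manipulation time (1).** MHT + DGB duration in minutes (units cancel
  after standardization; minutes match how operative time is usually
  reported).

Every feature is checked against an independent brute-force
recomputation (plain loops over the definitions) on random small
timelines, and the shipped 12-video worked fixture has a golden feature
matrix computed by that oracle.

## Ratings, reliability, and grouping

mGOALS keeps four GOALS items — depth perception, bimanual dexterity,
efficiency, tissue handling — each an integer 1–5 (autonomy is excluded:
all contributing surgeons operate independently). A video's case score is
the mean across raters of the per-rater item sums. Rater consistency is
checked with ICC(2,1) — two-way random effects, absolute agreement,
single measure, computed from the ANOVA mean squares — with the usual
qualification threshold of 0.75, and with Kendall's W (midranks, standard
tie correction). Note that under *independent* rankings W concentrates
near 1/m for m raters, not 0; with two raters "no agreement beyond
chance" looks like W ≈ 0.5.

Surgeons (scores averaged over their videos) are cut at the empirical
0.25 and 0.75 quantiles into bottom / medium / top; competent = top ∪
medium, incompetent = bottom, and a surgeon's label propagates to each of
their videos. Two conventions are deliberate and configurable: the
quantile estimator is the linear-interpolation empirical quantile
(`stats::quantile` type 7), and scores exactly at a cut are medium (the
boundary wording of "within"/"between" a quartile is ambiguous; the
inclusive-medium rule makes the partition stable under ties). Item-level
targets, used for the four per-item classifiers, flag videos below the
item's 0.25 quantile; this mirrors the overall construction and is the
package's own definition, since no published one exists.

## Group statistics

Contingency tables of intraoperative events by skill group use the
uncorrected Pearson chi-square; reverse-engineering the published
vascular-injury table (46,3 / 18,8 → 8.245) confirms no continuity
correction was applied. Per-feature group differences use both the
Kruskal–Wallis rank test (identical to the tie-corrected Mann–Whitney
test for two groups) and a Welch t-test; constant features are skipped.
No multiple-testing adjustment is applied by default — matching the
original analysis — but `adjust = "BH"` is available. Feature–score
relations use Spearman correlation with midrank ties.

## Augmentation

The class imbalance (competent outnumbers incompetent roughly two to one)
is addressed by oversampling the minority class with perturbed copies of
its timelines, an analogue of the synonym-replacement / random-deletion /
random-insertion family of text augmentations: boundary jitter by a
truncated Gaussian (`jitter_sd_s`, default 2 s), independent event
deletion (`p_delete`, default 0.05), and duplication-with-jitter
(`p_duplicate`, default 0.05). Labels are never altered; validity is
restored by clipping (phase bounds, positive durations, same-hand
non-overlap), so every augmented case passes full validation.
Augmentation is applied **only inside training folds** during
cross-validation; anything else leaks the test distribution into
training. Every synthetic case records its source case.

## Classification

Five classical families with fixed, documented hyperparameters (all
conventional defaults, none tuned): ridge-penalized logistic regression
(C = 1), an RBF-kernel SVM (cost 1, gamma 1/p on standardized features),
a 500-tree random forest, gradient-boosted trees (100 rounds, depth 3,
learning rate 0.1), and discrete AdaBoost (SAMME) over 100 depth-1 CART
stumps, implemented in-package. Scores for ROC analysis are continuous
decision values, never hard labels. AUC is computed by the package's own
midrank formula — equal to the Mann–Whitney U statistic divided by n₁n₀ —
and is verified against a brute-force pairwise oracle.

Cross-validation is five-fold with all of a surgeon's videos in one fold
(same-surgeon videos are too correlated to split across train and test);
folds are balanced greedily on per-class counts and are deterministic
given the seed. Standardization statistics come from training rows only.
Both the fold-mean AUC and the pooled-prediction AUC are reported, since
published AUCs rarely say which convention they use. Degenerate
single-class folds are skipped and logged.

Feature importance supports two methods: native weights (absolute
coefficients, impurity importances, stump-weight sums; the RBF SVM has
none) and permutation importance (mean AUC drop over repeated
single-column shuffles, floored at 0), the cross-model default because it
is defined identically for every family. Scores are normalized to sum to
one; top-10 lists break ties by feature name.

## The synthetic cohort

The generator is the package's stand-in for the unreleased clinical
annotations; it is synthetic by construction and documented as such. Each
surgeon gets a group (incompetent with probability 26/75, the published
split) and a latent skill level; each video is a two-phase alternating
exposure/dissection semi-Markov stream: exponential class blocks whose
mean lengths set the expected D/E duration ratio, filled with lognormal
events (~3.5 s) and exponential gaps, labels drawn from the class
vocabulary with a persistence probability. Every published group contrast
is a directly configured parameter: inefficient-gesture weight ratio 2,
event-duration scale 1.5 (which also lengthens the operation — the
default cohort centres near 11 min of manipulation time), transition
intensity ratio 2, D/E fold 1.6, and vascular-injury probabilities
6.1% / 30.8%. Two simulated raters emit clipped, rounded item scores
around the latent skill (noise SD 0.35, which keeps their ICC above the
0.75 qualification bar). Setting every ratio to 1 and equalizing injury
probabilities gives an exchangeable null cohort.

What the generator does **not** emulate: real inter-feature correlation
structure (feature-driving processes are independent given skill), true
bimanual concurrency (events are laid out sequentially in time, so
cross-hand overlap never occurs in generated data, although the data
model and the fixtures exercise it), anatomy-driven difficulty, and any
CVS mechanism (CVS scores are inert metadata). Passing the synthetic
recovery checks therefore demonstrates that the pipeline measures what
the generator encodes — not that the real-data headline performance
(AUC ≈ 0.87–0.89 as published, with the Abstract and Results disagreeing
at the second decimal) is reproduced, which is impossible without the
original annotations.

## Numerical choices and problem sizes

* Quantiles: type 7; boundary scores → medium.
* Interval SD: sample (n−1); single gap → 0 with warning.
* Ratio floors: zero D/E denominators → 1 event / 1 s.
* Ties: AUC by midranks; Kendall's W by midranks with tie correction;
  importance ties by feature name; fold ties by index order.
* Seeds: every stochastic stage takes an explicit integer seed, and
  internal seeding restores the caller's RNG state. Two runs of
  `run_pipeline()` with the same config produce byte-identical artifacts
  and manifests (checksums, no timestamps).
* Verification sizes, chosen to keep Monte-Carlo error well inside each
  assertion band: null-cohort classification at ~300 videos (the
  fold-mean null AUC has a standard error near 0.03 there); default-effect
  classification and D/E fold recovery at ~150 videos (the per-video
  duration-ratio is noisy enough that the ~75-video cohort alone leaves
  the fold estimate with a standard error near 0.13);
  injury-incidence recovery on 10,000-video simulations (with the
  test suite averaging three of them, since a single draw of ~3,500
  incompetent videos has a ~0.8-point standard error); importance
  recovery over 100 seeded runs; test size calibration over 10,000 label
  permutations.

## Known limitations

The taxonomy beyond the six published gesture names is a placeholder; the
interval/shift stream allocation is an interpretation of the published
feature counts; the augmentation scheme is our concrete instantiation of
an unspecified "NLP-style" procedure; and the per-item classification
targets are package-defined. All are configurable, and each is flagged at
its definition site. Timeline-level augmentation and surgeon-grouped
folds are stricter than anything the published description commits to;
relaxing either would only inflate apparent performance.
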