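---
title: "Quantifying valence versus identity coding in conditioning calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying valence versus identity coding in conditioning calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(odorvalence)
library(dplyr)
```

## The scientific question

During olfactory classical conditioning, an odor can be read out from a
neural population in two very different ways: as a *chemical identity* (which
odorant was delivered) or as a *reward contingency* ("valence": does this
odor predict sucrose?). Distinguishing the two requires a paradigm in which
contingency is decoupled from chemistry, and a battery of analyses that ask,
at the single-neuron and population level, which variable the activity
actually carries and in how many dimensions.

`odorvalence` implements that battery for trial-structured single-neuron
calcium fluorescence: moving-window Gaussian-mixture baselining and dF/F,
framewise nonparametric responsiveness testing, pairwise auROC decoding with
permutation nulls, cross-validated population classifiers with cross-pair
generalization, PCA-restricted decoding, participation-ratio dimensionality,
response-geometry summaries, and regressions that disentangle reward
contingency from licking vigor. A synthetic-session generator emulates the
two conditioning paradigms with known per-neuron encoding classes, so every
stage can be falsified against ground truth without any recorded data.

## The conditioning paradigms

The six-odor paradigm presents three ketones and three terpenes for 2 s
each, 30 trials per odor in randomized blocks (each block contains every
odor once), with 12-18 s inter-trial intervals. Outcomes (2 ul sucrose, an
airpuff, or nothing) arrive 0.1-0.3 s after odor offset, and each
contingency group contains one ketone and one terpene, so contingency and
chemical class are crossed. From day 4 onward all contingencies are
reassigned, testing whether neural valence coding follows the new map.

The lick/no-lick paradigm decouples reward contingency from motor output:
reward probability (0 / 0.5 / 1) is crossed with lick-spout availability.
For spout-absent odors the spout retracts 0.2 s before odor onset and
returns 0.1 s before the earliest possible reward (sucrose arrives after a
longer 1.1-1.3 s delay), which delays licking by about a second without
changing the odor's value. The published description of which odor carries
which probability is internally inconsistent with the design figure's
statement that each probability occurs once per spout state; the generator
follows the crossed design, which is the property the analysis needs.

```{r}
sched <- build_conditioning_schedule("six_odor", n_blocks = 3, day = 6,
                                     seed = 1)
head(sched[, c("trial", "block", "odor_name", "contingency", "onset_s",
               "us_type", "us_time_s")])
```

## What the generator emulates (and what it does not)

Each synthetic neuron belongs to one encoding class: `valence_pos` /
`valence_neg` (signed loading on a single shared contingency template -
weights follow each odor's *current* reward probability, with a small
multiplicative jitter, default 2%, between same-contingency odors),
`identity` (fixed sparse signed tuning per odorant, independent across
neurons - full-rank across a population), `lick` (driven by lick-bout
onsets), `us_sucrose` (driven by sucrose delivery; half of them, by
default, additionally acquire a conditioned response to sucrose-paired
odors from day 3 on, emulating reward neurons that become reward-cue
neurons), `salience` (equal drive to sucrose- and airpuff-paired odors plus
a brief airpuff response - the only aversive drive, since little negative
valence coding is expected), and `silent`.

Fluorescence is built as `F0 * (1 + drift) + amplitude * (drive * kernel) +
noise`, truncated at zero: a difference-of-exponentials calcium kernel
(0.2 s rise, 1.7 s decay, slow-indicator-like; the source data give no
kinetics so these are indicator-typical values), an Ornstein-Uhlenbeck
baseline drift (100 s timescale, 5% of F0) that exercises the moving-window
baseline stage, and white Gaussian noise (3% of F0 per frame).

Trial-to-trial response variability has three parts, and the split matters:

* an independent log-normal gain per neuron per trial (sd 0.3);
* a correlated fluctuation along the population's sucrose-template pattern
  on *every* trial (sd 0.35), so reward-pattern activity also fluctuates on
  unrewarded trials;
* odor-pattern mixing noise for identity neurons (sd 0.8): each trial's
  drive mixes in random amounts of the other odors' identity patterns.

The last two are correlated across neurons and therefore *information
limiting*: without them, pooling a few hundred synthetic neurons decodes
any odor pair perfectly, which real populations do not do. Their magnitudes
were chosen once so that cross-validated population accuracies fall in the
realistic 70-95% band (intervalence comparisons near the top, intravalence
near the bottom) rather than saturating at 100%, and are configurable.

Licking is an inhomogeneous Poisson process: a low spontaneous rate, an
anticipatory ramp over the final odor second toward reward-predicting
odors - scaled by reward probability and a day-dependent learning factor
(essentially no anticipatory licking on day 1, asymptotic by day 3, a dip
and re-acquisition after the contingency switch) - and a consummatory bout
after sucrose. Lick-bout statistics are not reported for the source
paradigm, so rates (6 licks/s anticipatory peak, 7 licks/s consummatory)
were chosen as typical mouse values and are configurable. Face features are
noisy deterministic functions of the instantaneous lick state (tongue-tip
and mouth-corner tracking confidences, upper/lower lip coordinates) -
minimal structure, sufficient for the lick-detection stage. Locomotion and
eye features are placeholder streams.

What passing tests on this generator do **not** show about real data:
the generator has no neuropil contamination, no motion artifacts, no
segmentation errors, no slow representational drift within a session, and
its noise model (per-neuron white noise plus the three structured terms) is
far simpler than cortical shared variability. Recovery results bound what
the *analyses* can do when their assumptions hold, not what any particular
dataset will yield.

```{r}
pop <- sample_ground_truth_population(
  population_config(n_neurons = 40, region = "VP"), seed = 2)
ses <- synthesize_session(sched, pop, seed = 3)
ses
```

## Preprocessing choices

The baseline of each neuron is estimated per moving window (2,500 frames =
500 s at 5 Hz, stride 500 frames) by fitting a two-component Gaussian
mixture to the window's fluorescence values and taking the mean of the
lowest-mean component: quiescent frames populate the low component while
calcium transients load on the high one. The component count and the
"lowest-mean component" statistic are exposed as configuration, since only
the mixture family and window length are externally fixed. Window estimates
sit at window centers (centers span the series; edge windows are clipped)
and are linearly interpolated; degenerate fits fall back to a 20th-percentile
estimate. The EM uses a deterministic quantile initialisation (bit-reproducible
without an RNG) and, for large windows, a 256-bin weighted collapse of the
sample - quantization far below the within-component spread. With two
overlapping components on featureless noise the low-component mean sits
slightly below the quiescent mean (a fraction of the noise sd); this is a
property of the mixture definition of "baseline" and cancels in every
rank-based comparison downstream.

Frames are 0-based and cover half-open intervals `[i/fs, (i+1)/fs)`; a
window `[a, b)` contains every frame whose start time falls inside it. At
5 Hz the "last odor second" is relative frames 5-9, the 2 s pre-odor window
is frames -10..-1, and the lick/no-lick analysis window (last 0.5 s of odor
plus first 0.5 s of delay) is frames 8-12 - one shared utility supplies it
to both the behavioral and the decoding code paths.

```{r}
ses <- preprocess_session(ses, window_frames = 500, stride_frames = 100)
tens <- epoch_trials(ses)  # [-2 s, +5 s) around odor onset
tens
```

## Responsiveness testing

Each odor frame's per-trial dF/F is compared against the pooled pre-odor
distribution of that odor's trials with a two-sided Wilcoxon rank-sum test,
and Holm-Bonferroni correction is applied over the ten odor frames within
each (neuron, odor) family, controlling that family's FWER at 0.05 (the
family scope is configurable; the per-(neuron, odor) reading is the
default). A neuron is called responsive when at least four corrected-
significant frames share one direction; mixed-direction neurons are
labelled by the majority sign and flagged, since the source of the rule
does not specify the tie-break. The cross-day analysis applies the same
machinery to the 2 s after sucrose delivery (window length is this
package's choice) and reports the fraction of tracked neurons that are
US-responsive early and cue-responsive (same sign) after learning.

## Single-neuron and population decoding

Single-neuron pairwise discrimination uses the per-trial mean dF/F over the
last odor second, Z-scored across the pooled trials, scored by an in-sample
logistic classifier. For a one-predictor monotone model the classifier's
auROC equals the rank (Mann-Whitney) auROC of the feature oriented by the
fitted coefficient's sign, which is exactly how it is computed (midrank
ties); the sign of the 1-D logistic MLE coefficient equals the sign of the
feature/label covariance. Permutation nulls shuffle labels and use add-one
p-values, `(1 + #{null >= obs}) / (1 + n_shuffles)`, so p is never zero.
Neurons are categorised at threshold 0.75 (halfway between chance and
perfect) by their intervalence (sucrose-paired vs not) and intravalence
(the two sucrose-paired odors) auROCs into valence / identity /
identity-S-only / uninformative quadrants.

Population classifiers are ridge-penalised logistic regressions (fixed
small penalty, `lambda = 0.01`, on per-neuron Z-scored features) evaluated
by stratified 5-fold cross-validation; unpenalised logistic fits are
degenerate whenever neurons outnumber trials, and a small ridge is the
standard linear "logistic learner" in that regime. Feature scaling uses
training-fold statistics only. An RBF-kernel SVM (C = 1, gamma =
1 / (p * mean variance)) is available as the nonlinear control learner.

The generalization matrix trains on each of the 15 pairs and tests on every
other pair under a contingency-aligned mapping (the higher-reward class of
the training pair maps to the higher-reward class of the test pair; when a
pair has no contingency difference both orientations are scored, the
maximum reported, and the entry flagged as orientation-ambiguous). Because
two pairs can share an odor - and therefore trials - transfer models are
trained on a stratified half of every odor's trials and transfer is always
evaluated on the held-out half; otherwise shared-odor entries would partly
re-score training trials and inflate apparent generalization. Diagonal
entries are within-pair cross-validated accuracies. The "generalized
valence decoding" summary is the mean over the off-diagonal block where
both pairs differ in sucrose contingency.

PCA-restricted decoding subsamples 15 neurons, projects the (Z-scored) pair
design onto its top principal components, and cross-validates the
classifier at each dimensionality; the PCA basis is computed once per
subsample (before fold splitting), a simplification that only affects the
basis, not the evaluated labels. Because the ridge penalty is rotation
invariant, using all 15 components reproduces the unprojected accuracy.

```{r}
aurocs <- all_pair_aurocs(tens)
scores <- tibble::tibble(
  neuron = sort(unique(aurocs$neuron)),
  auroc_intervalence = aurocs$auroc[aurocs$pair == "S_K vs X_K"],
  auroc_intravalence = aurocs$auroc[aurocs$pair == "S_K vs S_T"])
quadrant_composition(categorize_quadrants(scores))
```

## Geometry and dimensionality

Distance trajectories subtract each trial's 2 s pre-odor mean, average
across trials, and report per-frame Euclidean distances between odor-pair
population vectors, normalised to the maximum over all pairs and frames
per session (so each session's maximum is exactly 1). Pooled hierarchical
clustering Z-scores each neuron's concatenated six-odor trial-averaged
trace (Z-scoring scope is ambiguous in the source; per-neuron scope over
the concatenated trace is used and exposed), averages three bins per odor
(first odor second, last odor second, first post-odor second) into an
18-element vector, and cuts a Ward-linkage Euclidean tree at K clusters;
clusters are reported in descending order of mean sucrose-cue response for
stable output.

Dimensionality is the participation ratio `PR = (sum lambda)^2 /
sum(lambda^2)` over covariance eigenvalues of the full-session dF/F time
series (epoch-restricted PR is available as an option): 1 when one
principal component carries all variance, n for isotropic spread. Because
PR depends on how many neurons were recorded, populations are compared
after repeatedly subsampling a fixed number of neurons (15, 1,000
repeats); the covariance of a column subsample is a submatrix of the full
covariance, so the full covariance is computed once and each repeat costs
one small eigendecomposition.

```{r}
participation_ratio(t(ses$dff))
subsampled_pr(t(ses$dff), k = 15, n_repeats = 200, seed = 4)
```

## Behavior and the contingency/vigor disentangling

Lick selectivity reports per-trial odor-period lick counts, the sucrose-cue
fraction of odor-period licks smoothed with a 10-trial centered moving
average (shrinking windows at the edges; windows without licks are flagged
undefined and excluded), and the anticipatory lick rate in the shared
analysis window. Face-based lick detection is a three-feature logistic
classifier (tongue-tip confidence, mouth-corner confidence, upper-lower lip
distance) trained against the lick sensor and cross-validated framewise,
then applied to spout-absent frames. The distributed lag model regresses a
target series on lagged copies of predictors (default +/-2 s, i.e. +/-10
frames - a span comfortably covering the calcium kernel), fitted on the
first 80% of the session by time and scored by out-of-sample R-squared on
the final 20% to avoid leakage.

The omission analysis fits each neuron's per-trial response (anticipatory-
window mean minus pre-odor mean, trial-level observations) to contingency
only, licking only, and both plus interaction, and reports the loss in
R-squared when either variable is omitted; for nested in-sample fits both
losses are non-negative, and neurons dominated by one variable land on one
axis of the loss-loss scatter. At the population level, pairwise classifier
accuracies are regressed on the range-normalised anticipatory-licking
difference (per session, divided by the maximum pairwise difference), the
reward-probability difference, and both plus interaction; a combined model
that outperforms both single-variable models indicates that contingency and
vigor are simultaneously present in the population code.

## Numerical choices and degenerate inputs

* Zero-variance decoding features score auROC 0.5 and are flagged.
* All-tied framewise comparisons give p = 1 with a warning.
* Neurons with zero response variance are dropped (with a count) before
  clustering; scaled response magnitudes are NaN-flagged when a neuron has
  no positive response.
* Permutation nulls refuse fewer than 100 shuffles (p resolution); the
  full-scale default is 10,000.
* Seeds propagate through every stage (`derive_seeds()` keeps child seeds
  below 2^31), and repeated runs of `run_pipeline()` under one
  configuration are byte-identical.
* Simulated cohorts used in the test suite run at reduced scale (tens of
  neurons, a few blocks) except where the analysis contrast itself is under
  test, which uses the paradigm scale: 30 trials per odor and 130/250
  neuron populations.

## Known limitations

* The generator's aversive side is minimal by design (salience-class
  airpuff drive only); analyses of negative-valence coding will find little
  signal in synthetic cohorts.
* The GMM baseline inherits the mixture definition's small negative offset
  on featureless traces; absolute dF/F levels are therefore comparable
  within a pipeline run but not across baseline configurations.
* The orientation-ambiguous entries of the generalization matrix take the
  better of two mappings and are upward-biased by construction; they are
  flagged and excluded from the valence-generalization summary.
* Cross-day analyses consume a neuron matching supplied by the user (e.g.
  from manual ROI matching); no matching algorithm is provided.
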