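---
title: "Ordering the emergence of scene representations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordering the emergence of scene representations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temporsa)
```

## The question and the approach

When a person views a scene, different kinds of information — low-level 2D
image structure, 3D geometry, semantic category, and ultimately the
navigational affordances of the space — become available to the visual
system at different times. `temporsa` implements the analysis chain that
makes this ordering measurable from epoched multi-channel recordings (EEG in
the motivating use case):

1. **Time-resolved pairwise decoding.** For every pair of stimulus
   conditions and every time point, a Fisher linear discriminant is trained
   on the channel vectors at that single time point under cross-validation.
   The cross-validated accuracy is a dissimilarity: the more differently two
   stimuli are represented at time $t$, the better they decode. Collecting
   all pairs gives one representational dissimilarity matrix (RDM) per time
   point.

2. **Model RDMs.** Each candidate feature space is summarized by its own
   RDM: for feature matrices (e.g. network activations), entry $(i,j)$ is
   $1 - r_{ij}$ with $r_{ij}$ the Pearson correlation of the two conditions'
   feature vectors; for navigational affordances, conditions are compared by
   the Euclidean distance between their 180-bin angular histograms of
   drawn exit paths (the navigational affordance map, NAM).

3. **Variance partitioning.** At each time point the neural RDM's
   lower-triangle vector is regressed on all model RDM vectors jointly
   ($R^2_{\mathrm{all}}$) and on all-but-one model family
   ($R^2_{\mathrm{all}-m}$). The *unique variance* of family $m$ is
   $R^2_{\mathrm{all}} - R^2_{\mathrm{all}-m}$, non-negative because the
   models are nested. Each family contributes its member RDMs (e.g. a
   mid-network and an output layer) as separate regressors; the averaged
   family RDM is a reporting convenience, not the regression input.

4. **Inference.** Per-time-point one-sample t-tests across participants with
   Benjamini–Hochberg FDR control (q = 0.05) flag when a family explains
   variance; peak latencies of the participant-average unique-variance curve
   get 95% percentile confidence intervals from a participant-level
   bootstrap (default 1000 iterations), and latency differences between
   families are tested with paired bootstrap p-values, FDR-corrected across
   the family pairs.

A synthetic-data generator stands in for recordings: it injects known
representational geometries at chosen latencies so that the whole chain can
be validated end to end by parameter recovery.

## The synthetic generator

`generate_epochs()` builds per-condition channel patterns from a model RDM
by classical multidimensional scaling (up to 10 embedding dimensions), mixes
them to channels with a seed-fixed random linear map, and modulates them
with a Gaussian envelope centered at the model's onset latency. Trials share
the condition pattern and differ only in independent Gaussian sensor noise
(an AR(1) option exists, off by default). This is deliberately not a forward
model — no dipoles, no volume conduction, no autocorrelated background
rhythms — so passing recovery tests demonstrates that the *analysis chain*
is correct, not that it is robust to every artifact of real recordings.

Two conventions deserve explanation because they were genuinely open:

* **Pattern amplitude.** Patterns are scaled so that the root-mean-square
  *pairwise* pattern separation equals 1; the profile amplitude is therefore
  the typical separation between two conditions' patterns in noise-SD units
  at the envelope peak. Amplitudes around 1–2 put single-trial decoding in
  its sensitive range (accuracies roughly 0.6–0.9); at amplitudes of 5 and
  above most pairs decode perfectly near the envelope center, the decoding
  RDM flattens there, and unique-variance peaks shift toward the envelope
  flanks. Latency *ordering* survives this saturation; absolute latencies
  are recovered to within one envelope width. Recovery tests that assert
  absolute latencies therefore run at amplitude 2.

* **Feature geometry.** `generate_features()` places conditions in a
  low-rank latent space (default rank 4) and reads them out to features
  through a random linear map plus feature noise. This produces structured
  RDMs whose dissimilarities span a wide range, as real network activations
  do. (A plain i.i.d. construction yields near-simplex RDMs — all pairs
  roughly equidistant — which makes all pairs saturate together during
  decoding and carries almost no recoverable geometry.) The target
  cross-model RDM correlation is hit through a shared latent component with
  mixing weight $a = \rho^{1/4}$; negative targets, which cannot be
  inherited from latent positions (pairwise structure is an even function
  of them), are built directly in the dissimilarity domain with
  simplex-weighted shared perturbations and one deterministic
  recalibration. Strongly negative targets are approximate and benefit from
  a larger `latent_dim`.

The trial schedule generator reproduces the reference paradigm's run
structure — per run, 24 blocks of 5 trials, 15 of 4, 15 of 3, 10 of 2 and 5
of 1 (69 blocks, 250 trials), with catch-trial markers between blocks; 15
runs over 50 conditions give exactly 75 repetitions per condition. Catch
trials are markers only; no epochs are generated for them. Path heatmaps
are connected pixel traces from the bottom-center pixel at random headings,
aggregated across simulated drawers and max-normalized.

## Preprocessing conventions

Windows are half-open, $[t_0, t_1)$, everywhere. This makes a
$(-0.2, 0.8)$ s window at 100 Hz contain exactly 100 samples, which is the
decoding grid the analysis standardizes on. The default baseline is the full
pre-stimulus interval $[t_\min, 0)$. Downsampling is integer decimation
behind a zero-phase order-6 Butterworth low-pass at 0.8 of the target
Nyquist, applied forward–backward with odd-reflection padding so that short
epochs do not inherit filter startup transients; a 1 Hz sinusoid sampled at
1000 Hz survives decimation to 100 Hz with error below $10^{-3}$ of its
amplitude. The default posterior channel set is the 17 posterior/occipital
electrodes of the 10-10 system (`posterior_channels`). Artifact handling
(filtering, ICA) is out of scope: inputs are assumed clean, which the
generator guarantees.

## Decoding choices

The classifier is a Fisher discriminant with the pooled within-class
covariance optionally shrunk toward a scaled identity. `"auto"` uses the
analytic (Ledoit–Wolf) intensity per training fold — with 17 channels and
tens of trials the raw covariance estimate is noisy enough that shrinkage
measurably stabilizes accuracies. Ties at the decision boundary go to the
lower condition index, for determinism.

Cross-validation defaults to single-trial leave-one-out: each fold trains on
all-but-one trials of the pair and tests the left-out trial. This makes
results exactly invariant to trial ordering, which we treat as the more
valuable property; the class-balanced alternative (`n_folds = "paired"`,
leaving out one trial of each condition per fold) is tied to the
within-condition trial order and is provided as an option, along with
stratified k-fold. Two known small-sample properties of cross-validated
accuracy matter for interpreting chance-level data: LOO estimates are
slightly pessimistic (class means move away from the left-out trial), and
accuracies are overdispersed relative to a binomial with the same trial
count (folds share training data, and the chance separation of the two
classes varies between simulated datasets — we measure an inflation of
roughly 1.4 in SD at 20 trials per condition). Chance-control tests
therefore check the mean against binomial error and use a
dispersion-corrected band for the spread, rather than pretending CV folds
were independent coin flips.

No pseudo-trial averaging is applied by default; raw single trials enter
the classifier.

## Variance partitioning and its null floor

Predictors and target are z-scored before fitting ($R^2$ is invariant; it
only aids conditioning), predictors enter as raw dissimilarities without
rank transformation, and collinear predictor sets fall back to pivoted
least squares with a warning — the projection, and hence $R^2$, is still
well defined. Negative unique variance is impossible for nested OLS and is
asserted, never clipped.

One bias is worth stating precisely because it shapes what "no effect"
looks like: for a target independent of the predictors, OLS $R^2$ with $p$
regressors on $n$ observations has expectation $p/(n-1)$, so a family
contributing $p_g$ regressors has expected null unique variance
$p_g/(n-1)$ — strictly positive. With 50 conditions ($n = 1225$ pairs) this
floor is ~0.0016 and ignorable, which is why published analyses test unique
variance against zero. At the small condition counts used in fast synthetic
validation (10 conditions, $n = 45$) the floor is ~0.045 and a t-test
against zero would flag it everywhere. `timepoint_tests()` therefore
accepts a `null_mean` argument (default 0, the published convention), and
`null_unique_mean()` supplies the analytic floor for screening
unique-variance curves at small $n$.

## Inference choices

The bootstrap resamples participants (not trials), matching the level at
which the group statistic generalizes. Confidence intervals are percentile
intervals — the simplest defensible reading of a 95% CI — and both peak
definitions are computed: the peak of the resampled average curve (primary)
and the average of resampled participants' own peaks (supplementary); on
high-signal synthetic cohorts the two agree. Paired comparisons require
literally the same resample indices (enforced, derived deterministically
from the seed), and the two-sided bootstrap p-value uses a +1 continuity
correction so that p = 0 cannot occur. FDR families are: time points, for
timecourse tests; model pairs (6 for four families), for latency
comparisons. Flat curves resolve peak ties to the earliest time.

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic
cohorts sized so the full chain stays comfortably within a desktop budget:
16 participants, 14 conditions (91 pairs), 5 trials per condition and 16
channels on the standard 100-point grid for latency-ordering recovery
(injected latencies 0.13, 0.17, 0.16 and 0.30 s for 2D, 3D, semantic and
NAM at amplitude 5). The condition count matters: with 7 regressors, the
null unique-variance floor $p_g/(n-1)$ and its fluctuations must sit well
below the weakest genuine bump (the semantic family's, squeezed between
its 2D and 3D neighbors), which 91 pairs comfortably achieve while 45 do
not. Chance-level controls use 20 trials per condition on 10 conditions;
regression oracles are checked at full precision on 50 conditions (1225
pairs). These sizes are the package's validation conditions, not limits
of the implementation — the same code runs the reference paradigm's 50
conditions and 75 repetitions unchanged, only slower.

## Known limitations

* The generator's noise is white (optionally AR(1)) and spatially
  uncorrelated; real sensor noise is neither. Passing recovery tests says
  nothing about artifact robustness.
* Unique variance is not noise-ceiling-normalized and the regressions are
  not cross-validated; both are deliberate scope choices.
* Negative cross-model similarity targets are approximate (see above).
* With heavily overlapping envelopes (latency gaps below one envelope
  width), unique-variance peaks repel each other slightly; orderings are
  preserved but absolute peak positions can shift by one or two grid steps.
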