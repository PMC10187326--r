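---
title: "Hybrid walk classification and peak-detection step counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid walk classification and peak-detection step counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristep)
```

## The problem

Counting steps from a wrist-worn accelerometer is hard in free living:
arm movement generates acceleration peaks that look like steps, and naive
peak counters routinely overcount by tens of percent outside the lab.
`wristep` implements a hybrid pipeline that addresses this by separating
*when* a person is walking from *how many* steps they take:

1. the raw triaxial signal is cut into non-overlapping 10-second epochs and
   each epoch is classified as walking or non-walking (an epoch counts as
   walking when it contains at least four steps);
2. the predicted label sequence is smoothed with a two-state hidden Markov
   model so isolated misclassifications inside a long walking (or resting)
   run are corrected;
3. steps are counted by peak detection on a conditioned signal, but only
   inside epochs whose smoothed label is walking — non-walking epochs
   contribute exactly zero steps.

Everything downstream of the classifier is deterministic signal processing,
so the pipeline can be validated piece by piece against closed-form or
brute-force references.

## Signal conditioning

Peak detection operates on a single conditioned series derived from the
calibrated triaxial signal in units of g:

* the Euclidean norm of the three axes minus 1 g (removing static gravity;
  negative values are kept),
* clipped to ±2 g (large impacts carry no extra step information),
* low-pass filtered at 5 Hz, which retains the gait band (walking cadence
  and its first harmonics) while suppressing sensor noise.

The filter is a 4th-order Butterworth applied forward and backward.
Zero-phase filtering matters here: a causal filter would shift peak
positions by a cadence-dependent lag and bias the epoch assignment of
boundary peaks. Ends are handled by odd-symmetric extension plus a
steady-state warm-up of the filter state, which keeps DC gain exactly 1
(tested to 1e-6) and avoids boundary transients that would masquerade as
step peaks in short recordings.

## Peak detection

A step candidate is a local maximum of the conditioned signal (a flat-topped
run of equal samples counts once, at its midpoint). Three heuristics decide
which candidates are steps:

* **prominence** ≥ `prominence` — the height of a peak above its lowest
  enclosing contour line, which ignores slow baseline drift;
* **width** at half prominence ≤ `width_max` — a step impact is a sharp
  event; broad swells are rejected;
* **distance** — among retained peaks closer than `distance` seconds, lower
  peaks are removed greedily in descending height order, enforcing a
  physiological cadence ceiling.

The three parameters are tuned by exhaustive grid search over
prominence 0.1–1 g, distance 0.2–2 s and width 10 ms–1 s, minimising the
per-participant mean absolute error of total step count on validation
recordings. Two choices here were genuinely open and are worth recording:

* **Gating during tuning** uses ground-truth walking labels rather than
  classifier output, so the tuned peak parameters reflect the detector's
  own error and are not confounded by classifier mistakes. The price is a
  small optimistic bias if the classifier later under-covers walking time.
* **Width semantics**: width is an upper bound only ("maximum peak width"),
  evaluated at half-prominence relative height; no lower bound is applied.
* **Ties** in the grid search are broken toward higher prominence, then
  longer distance, then smaller width — always the more conservative
  detector.

The implementation is checked against a naive O(n²) reference (explicit
contour search for prominence, scan-based widths, quadratic greedy pruning)
on hundreds of random signals; the two must agree index for index.

## The epoch classifier

State-of-the-art wrist activity classifiers use deep 1-D residual networks
pre-trained with self-supervision on very large unlabelled accelerometer
corpora. Pre-training at that scale needs GPUs, so the *default* backend
here is a
handcrafted-feature logistic model that trains in seconds on a CPU: per
epoch it uses the mean, SD and maximum of the gravity-removed magnitude,
the dominant 0.5–4 Hz frequency and its power fraction, the lag-0.25–2 s
autocorrelation maximum (stride periodicity), a burst count above 0.2 g,
and the three inter-axis covariances. A `resnet18_1d` backend with the
same training loop is provided for completeness: its encoder is randomly
initialised (or loaded from external pre-training through
`pretrained_weights`) and kept frozen while the linear head is trained —
the usual linear-probe deployment of a pre-trained encoder.

Training follows the standard recipe for this task: Adam with learning
rate 1e-4, weighted cross-entropy with class weights that re-balance
walking to 10% of the effective mass (free-living 24-h walking prevalence;
training snippets over-represent walking), random rotation plus
axis-permutation augmentation (optional for the feature backend, whose
magnitude features are rotation-invariant by construction), and early
stopping when validation loss has made no new minimum for 5 consecutive
epochs, returning the best-validation-epoch parameters. Ties count as "not
decreasing". Because Adam moves each coefficient by roughly the learning
rate per update, a linear model at lr 1e-4 needs a few thousand updates to
reach informative coefficient magnitudes; the default `max_train_epochs`
is therefore 300 with mini-batches of 64, and early stopping usually
decides the actual length. The hard-label threshold is 0.5; the HMM
consumes hard labels.

## The HMM smoother

The smoother is fitted supervised, from validation-set predictions paired
with ground truth: emissions are the row-normalised confusion counts (true
label → predicted label), transitions the row-normalised bigram counts of
the true label sequence, and the prior the smoothed label frequencies. A
pseudo-count of 1 keeps every probability positive even when a validation
fold never exhibits some transition. Decoding uses the Viterbi maximum a
posteriori path — hard labels are needed to gate peak counting — with ties
broken toward non-walking (conservative counting). Sequences are smoothed
per recording, never across participants, and bigrams are never counted
across recording boundaries. The decoder is validated against exhaustive
enumeration of all 2^T paths for short sequences.

## Cross-validation

`run_cv()` reproduces the evaluation design end to end: participants are
assigned to k folds grouped by participant (no individual's epochs can
appear on both sides of any split) and stratified by each participant's
walking-epoch fraction — exact class stratification and exact grouping are
incompatible, so participants are ordered by walking share and dealt
across folds in consecutive blocks. Within each round the non-test
participants are split 80/20 into training and validation; the classifier,
the HMM and the peak parameters are all fitted inside the round; and the
hybrid pipeline is evaluated on the held-out fold. Disjointness is
asserted inside the harness itself. Because "overall MAPE" can be read two
ways, the pooled report carries both the mean over all test participants
(`mape`) and the mean of per-fold MAPEs (`mape_fold_mean`).

## The synthetic cohort

All tests run on generated data with exact ground truth. A scenario places
non-overlapping walking bouts (controlled cadence, known step count) on a
quiet baseline: each step is a raised-cosine pulse of 0.25 s applied along
the gravity axis, so the gravity-removed magnitude rises by exactly the
pulse amplitude at the step instant — one detectable local maximum per
step after 5 Hz filtering. (A pulse orthogonal to gravity of amplitude *a*
would only raise the magnitude by √(1+a²)−1 ≈ a²/2 — a 0.4 g arm-swing
pulse would produce a 0.08 g excursion, below any plausible prominence
floor — which is why the pulse is vertical.) Per-axis Gaussian noise
emulates arm and sensor noise; non-wear gaps are carried as a
missing-sample mask, matching the imputation semantics downstream, and
epochs that are mostly missing are excluded rather than zero-filled.

Cohort defaults: 100 Hz sampling (the usual research-device rate), 8-minute
recordings, 2–4 bouts per participant at 80–125 steps/min, pulse
amplitudes 0.35–0.6 g, noise SD 0.03–0.08 g. These are deliberately
*clean* walking signals: the generator does not produce shuffling gait,
non-walking arm activity with step-like periodicity, device clock drift,
or hip-worn placement. Passing the synthetic recovery tests therefore
demonstrates that the pipeline's machinery is correct — labels gate
counting, tuning finds the constructed optimum, CV does not leak — not
that free-living error on real wrists would be this low. The
cross-validation acceptance checks use a 20-participant cohort, chosen so
the full harness (10 folds × training + tuning + evaluation, twice
including the shuffled-label control) completes in a couple of minutes.

## Deployment-side aggregation

For multi-day recordings the package mirrors the cohort pipeline: QC
exclusion when wear time is below 72 h, when some hour of day is never
covered, on a failed upstream calibration flag, or when mean
gravity-removed acceleration exceeds 100 mg; non-wear minutes imputed by
the mean of the same minute of day over the other valid days (minutes
missing on every day become 0 and are flagged); daily totals summarised as
the median over valid days (even counts: mean of the middle two); and peak
one-minute cadence as the maximum calendar-minute count per day,
summarised as the median across days. The cited cadence definition is
external to this package; the calendar-minute reading is the documented
choice, with a rolling-60 s switch exposed for sub-minute grids.

## Reference baselines

Two open-source comparison algorithms are included at contract level: an
acceleration-threshold counter (upward crossings of a fixed threshold on
the conditioned magnitude with a refractory period) and a Verisense-style
staged peak screen at its native 15 Hz (magnitude floor, periodicity
window on peak spacing, similarity cap on alternating peak heights, and a
continuity requirement that surrounding inter-peak intervals show real
movement). Their published parameter sets are deferred to supplementary
material of their original sources; every constant is therefore
config-exposed (`ducharme_config()`, `verisense_config()`) so reference
values can be dropped in without code changes, and the defaults are chosen
to reproduce the algorithms' qualitative behaviour (periodic-gait
recovery, rejection of isolated impacts).

## Numerical choices and limitations

* Epoch validity requires ≥50% non-missing samples; a trailing partial
  epoch is discarded (the classifier expects fixed-length windows).
* Resampling is linear interpolation; a resampled point is missing when a
  bracketing source sample is missing.
* Peaks on epoch boundaries belong to the epoch containing their sample
  index (half-open intervals).
* MAPE is the unweighted mean of per-participant absolute percent errors,
  and is undefined (an error) when any true count is zero.
* The ICC variant is ICC(A,1): two-way random effects, absolute agreement,
  single rater.
* The synthetic generator's single gravity-axis pulse per step means the
  tuned `width_max` is only weakly identified (all true peaks are narrow);
  on real data the width bound does real work against broad arm swells.
* The feature backend is linear; strongly nonlinear activity confusions
  (e.g. cycling vs walking) are beyond it and are the reason large-scale
  systems use deep encoders.
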