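---
title: "Entropy features and classifier comparison for single-channel EEG fatigue detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy features and classifier comparison: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Driver fatigue changes the character of the EEG: the fatigued brain
produces a more regular, more narrow-band signal than the alert one.
A practical fatigue detector should work from a *single* electrode, so
the question becomes: which channel, which signal feature, and which
classifier separate 1-second EEG epochs of a normal driving state from
a fatigued one best? `entrofatigue` implements the full comparison
harness: four entropy features per epoch, ten standard classifiers,
leave-one-epoch-out (LOO) evaluation per (subject, channel, feature,
classifier) cell, and ranking utilities that aggregate the grid.

Because no public recordings accompany this design, the package ships a
synthetic two-state EEG generator; every claim the test suite makes is
a property of the method, demonstrated on simulated data, not a
reproduction of any specific cohort's numbers.

## The features

All four features are computed per 1-s epoch, per channel. For the
template entropies the embedding dimension is $m = 2$ and the tolerance
is $r = 0.2\,\mathrm{SD}$, both conventional for EEG; the SD is that of
the epoch being analyzed, so $r$ adapts to slow amplitude drift between
epochs rather than being frozen at a recording-level value.

**Approximate entropy (AE).** With delay vectors
$X_i^m = (x_i,\dots,x_{i+m-1})$ and the Chebyshev distance $d$,
$\Phi^m(r) = \frac{1}{N-m+1}\sum_i \ln C_i^m(r)$ where $C_i^m(r)$ is
the fraction of templates within $r$ of $X_i^m$ *including* the
self-match, and $\mathrm{AE} = \Phi^m(r) - \Phi^{m+1}(r)$. The
self-match keeps every $C_i > 0$, so AE is always finite, at the price
of a known negative bias (visible in the i.i.d. benchmark below).

**Sample entropy (SE).** $-\ln(A/B)$, where $B$ counts ordered template
pairs matching at length $m$ and $A$ those still matching at length
$m+1$, self-matches excluded and both lengths restricted to the first
$N-m$ start points so $A \le B$. When no pair matches, SE is undefined;
the package returns an `Inf` sentinel and, at the feature-matrix level,
imputes it with the largest finite value of the column (with a logged
count). The alternative — dropping those epochs — would silently shrink
the evaluation set; imputation keeps the design balanced and marks the
epoch as "maximally irregular at this tolerance", which is the
direction the evidence points.

**Fuzzy entropy (FE).** Templates are first baseline-removed (their own
mean subtracted), and the hard threshold is replaced by the membership
$e^{-(d/r)^{n}}$ with gradient $n = 2$. FE is finite and smooth for any
non-constant epoch and, empirically, the most stable of the three under
noise — which is exactly why it tends to win the feature comparison.

**Spectral entropy (PE).** Shannon entropy of the normalized power
spectrum of the mean-removed, Hann-windowed epoch, divided by $\ln K$
($K$ = number of retained bins) so $\mathrm{PE} \in [0,1]$. By default
all bins above DC up to Nyquist are retained. A band restriction (e.g.
0.5–45 Hz) is available via `entropy_params(pe_band = )`, but is not
the default: with 1-s epochs it leaves only ~45 bins, and the
sampling variability of so few periodogram ordinates depresses the
broadband ceiling (white noise averages ≈ 0.89 instead of ≥ 0.93),
blurring exactly the narrow-band-vs-broadband contrast PE is meant to
measure. The Hann window keeps leakage from off-bin components local,
so a pure sinusoid stays below 0.2 regardless of its exact frequency.

The i.i.d. benchmark used in the tests: for a long Gaussian series the
conditional matching probability of one extra Chebyshev coordinate is
$2\Phi(r/\sqrt2)-1$, so SE and AE must converge to
$-\ln(2\Phi(0.2/\sqrt2)-1) \approx 2.19$. At $N = 5000$ SE lands within
a few thousandths; AE carries its self-match bias of about $-0.08$,
still within the 0.1 tolerance the tests assert.

## Preprocessing

Recorded EEG is notch-filtered at 50 Hz (RBJ biquad, Q = 30) and
band-passed 0.15–45 Hz (Butterworth: order-2 high-pass so the very low
cut-off stays numerically stable, order-4 low-pass), each applied
forward–backward for zero phase. The contract is the frequency
response — ≥ 20 dB attenuation at 50 Hz, ≤ 1 dB ripple at 10 Hz, DC
removed — not a specific kernel, since acquisition software rarely
documents its filter design. Epochs are contiguous half-open windows
$[kL, (k+1)L)$; trailing samples that do not fill an epoch are
discarded.

Feature values are min–max scaled to $[-1, 1]$ per subject and per
(channel, feature) column over the pooled normal + fatigue epochs.
Pooled scaling mirrors the usual pre-classification normalization, but
it lets the (label-free) range of the test epochs inform the map; for
a stricter protocol `loo_evaluate(..., fold_normalize = TRUE)` refits
the map on each training fold and clips the held-out value.

## The classifiers

The ten configurations are fixed: KNN ($k=5$), linear-kernel SVM (LS,
$C=1$), RBF-kernel SVM (RS, $\gamma=2$, $C=1$), Gaussian process (GP,
unit-length-scale RBF kernel, pinned rather than data-estimated so
repeated fits are identical), decision tree (DT, depth ≤ 10, no
cost-complexity pruning — the depth cap is the only regularizer, as in
the common CART defaults), random forest (RF, 10 trees, depth ≤ 10),
MLP (one hidden layer of 100 units, ≤ 500 iterations — an architecture
choice, since none is standard), discrete AdaBoost over 50 decision
stumps, Gaussian naive Bayes, and QDA. Anything unstated is the
backing library's default and is recorded in the run manifest.
Stochastic learners (RF, MLP, AB) are re-seeded identically at every
fit, so LOO results are reproducible.

Each classifier also exposes a continuous score oriented so that higher
means more fatigue-like (class-1 probability where available, decision
margin or vote fraction otherwise); the ROC area is computed from the
held-out scores with the midrank tie convention, i.e. the normalized
Mann–Whitney statistic.

## Evaluation protocol

The LOO unit is the **epoch within a subject**: each of the subject's
pooled normal + fatigue epochs is predicted by a model trained on the
remaining ones. Per-subject accuracies from single-subject data are
only possible with within-subject folds, which is why that unit is the
default; note that consecutive 1-s epochs of real EEG are not
independent, so within-subject LOO accuracy is an optimistic estimate
of between-session performance. Confusion counts (fatigue = positive)
accumulate over folds; Sn, Sp and Acc follow directly, with degenerate
denominators reported as `NA` rather than silently as 0 or 1.

Aggregation follows the grid structure: the feature × classifier table
averages cell accuracies over all (subject, channel) cells, with the
sample ($n-1$) SD — the convention chosen because "mean ± SD" tables
rarely state one; channel rankings average over subjects at a fixed
feature and classifier; the per-subject best combination takes the
accuracy argmax with ties broken by higher AUC, then lexicographically
by (channel, feature, classifier), and flags subjects whose best
accuracy is below 0.6 as showing no usable signal.

## The synthetic generator

Each channel is a sum of four band-limited oscillators (delta 0.5–4,
theta 4–8, alpha 8–13, beta 13–30 Hz — conventional edges) over
$1/f$ Gaussian background noise. Two choices make the $\delta = 0$ case
a genuine null. First, oscillator frequencies and phases are drawn once
per (subject, channel) and shared by both states, so the deterministic
part of the two recordings is identical. Second, the background noise
is drawn independently per epoch (unit SD each): a single
recording-level noise realization would hand each state a shared random
draw of low-frequency power — a recording-level random effect that
shifts all of that state's epochs together and is detectable by a
classifier even with no configured contrast (with 2 × 100 pooled
epochs, some seeds separate at $p < 10^{-20}$). Per-epoch draws make
normal and fatigue epochs exchangeable at $\delta = 0$, at the cosmetic
price of noise discontinuities at epoch boundaries. Relative band
amplitudes default to delta 1.0, theta 0.7, alpha 0.9, beta 0.5 (a
plausible resting profile), modulated per subject by log-normal offsets
($\sigma = 0.15$) so the best channel/combination varies across
subjects. Background noise has unit SD and spectral slope 1.

The fatigue state transfers the fraction $\rho = \delta/(1+\delta)$ of
the broadband noise power into a single narrow-band alpha-range
sinusoid. This one mechanism moves all four features in the expected
direction at once — the signal becomes more regular (SE, AE, FE drop)
and more narrow-band (PE drops) — matching the premise that fatigue is
detectable from any of the entropies. $\delta$ is an abstract effect
size, *not* an estimate of any real cohort's contrast: $\delta = 0$
yields state-identical distributions, and the gap grows monotonically
with $\delta$. A single channel can carry a different ("boosted")
$\delta$ for planted-signal recovery studies.

What the generator does **not** emulate: artifacts (blinks, movement,
electrode drift), volume-conduction correlations between channels,
non-stationarity within a state, and any physiologically calibrated
effect size. Passing tests therefore demonstrate that the pipeline
recovers a regularity contrast when one exists and stays at chance when
none does — they say nothing about the absolute accuracy attainable on
recorded EEG.

## Numerical choices and degenerate inputs

* Constant epochs (zero SD) make $r = 0$ meaningless: the entropies
  raise an error; at the feature-matrix level such epochs become `NA`
  if they are fewer than 0.1 % of the set and abort otherwise.
* Constant feature columns normalize to 0 with a warning.
* EDF output quantizes to 16 bits over ±200 µV (≈ 0.006 µV steps);
  values outside the range are clipped.
* All derived random streams come from one master seed through an
  integer mixing function, so every stage is reproducible in isolation.

## Problem sizes used in the checks

The test suite and the acceptance script run the study conditions at
sizes a laptop handles in minutes: oracle equivalence on 50 series of
length ≤ 200; the i.i.d. limit at $N = 5000$ over 20 seeds; null
calibration with 1 subject × 1 channel × 200 pooled epochs across all
ten classifiers; signal recovery with 4 subjects × 4 channels × 200
pooled epochs at $\delta = 2$ for FE and PE under KNN and RF; planted-
channel recovery with 2 subjects × 4 channels × 60 pooled epochs over
10 seeds. The full-scale design (12 subjects × 30 channels × 600
epochs × 4 features × 10 classifiers) runs through exactly the same
code path via `run_pipeline()`; only the grid size changes.

## Known limitations

* Within-subject epoch-level LOO is optimistic for temporally
  correlated real EEG (see above); a leave-one-subject-out protocol is
  a natural extension the harness does not currently provide.
* Pooled min–max normalization leaks the test epochs' value range;
  `fold_normalize = TRUE` exists for leak-free evaluation.
* The AUC of score-discrete classifiers (KNN vote fractions) is
  coarse, which slightly understates their ranking ability.
* Hyperparameters are fixed by design; no tuning is performed, so weak
  results for tuning-sensitive learners (MLP, SVM) reflect the fixed
  configuration, not the method's ceiling.
* On *null* data the linear SVM is not a coin flip: a soft-margin SVM
  with an uninformative feature often degenerates to predicting the
  training majority class, and under leave-one-out the held-out epoch
  is always the training minority, so its LOO accuracy collapses to 0
  rather than hovering near 0.5 (the same happens with other libsvm
  front ends). This majority-collapse pathology is a known property of
  LOO evaluation, it is seed-dependent, and it biases the affected cell
  pessimistically — it can never fake a detection. The null-calibration
  test asserts the chance band for all ten classifiers and is expected
  to flag LS at collapse seeds.
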