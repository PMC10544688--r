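---
title: "Methods: simulation, decoding, crossnobis RSA and tuning analysis in touchdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, decoding, crossnobis RSA and tuning analysis in touchdecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`touchdecode` implements the multi-step analysis used for intracortical
multi-unit recordings from primary somatosensory cortex (S1) during
visuotactile touch experiments: threshold-crossing spike extraction,
baseline normalization, pairwise and generalization decoding with
permutation nulls, cross-validated Mahalanobis (crossnobis) representational
similarity analysis with MDS, per-channel tuning regression with
Bonferroni–Holm correction, and tuned-response onset/offset estimation.
Because real recordings of this kind are rare and large, every stage is
developed and validated against a synthetic session generator with planted,
recoverable structure. This vignette explains the models, the parameters
that matter, the numerical choices, and what the synthetic validation does
and does not establish.

## The task model

A session consists of nine conditions crossing touch type and body
location: seen physical touches (`FPa`, `FPf`), blindfolded physical
touches (`BLa`, `BLf`), virtual-reality visual-only touches (`VrFPa`,
`VrFPf`), observed third-person touches (`TPa`, `TPf`) and observed object
touch (`Obj`); `a` = arm, `f` = finger. Each condition is collected in 7
runs of 10 analyzable trials plus one catch trial, giving 70 analyzable
trials per condition (630 total). Trials are aligned to touch onset
(t = 0); the epoch spans −4 to +2 s in 50 ms bins, with an inter-trial
interval of 5 s plus 0–3 s jitter, a 1 s touch and a 1 s post-touch phase.
In visually cued conditions the approach of the touch is visible from about
0.5 s before contact, which is why response latencies slightly before t = 0
are meaningful. Conditions are assigned to two collection "sets" (FP/TP/Obj
vs BL/VrFP), mirroring the two collection epochs of such experiments.

## The synthetic session generator

`simulate_session()` draws a channel × trial × bin tensor from

$$r_i(t) = b_i\,[1 + (g_{ic} - 1)\,k(t - l_{ic})] + \varepsilon_i(t),$$

where $b_i$ is the channel baseline rate (default 10 Hz), $g_{ic}$ the
multiplicative condition gain (1 = untuned; the planted tuned mask is
$g > 1$), $l_{ic}$ the response latency and $k$ a rectangular-rise kernel
that holds at 1 until touch offset and then decays exponentially (default
time constant 0.3 s). The kernel is integrated analytically over each bin,
so a latency falling mid-bin produces exactly the fractional bin average it
should — this is what makes latency recovery by the onset estimator
well-posed on the 50 ms grid. The rectangular-rise/exponential-decay shape
is the simplest kernel exhibiting the sharp peak and gradual decrement
characteristic of these responses.

Noise $\varepsilon$ is multivariate Gaussian across channels (default
marginal SD 2 Hz with a shared pairwise correlation of 0.1), drawn
independently per bin, floored at zero; an optional Poisson stage resamples
counts. The Gaussian default keeps the channel covariance analytically
checkable: the suite verifies that the empirical covariance of
baseline-window residuals converges to the planted matrix at 2000 trials.
A uniform multiplicative "drift" between collection sets cancels exactly
under per-run baseline normalization (that is the point of normalizing),
so the optional `set2_drift` parameter perturbs the *noise amplitude* of
set-2 trials instead — an instability the normalized inter-trial-interval
SD comparison can actually detect.

`paper_like_truth()` fixes a ready-made configuration that mirrors the
qualitative structure reported for this preparation: 34 channels tuned to
`FPa` (gain 3), 13 to `BLa` (a subset, gain 2.5), 21 to `FPf` (gain 2.5,
mostly overlapping the arm set plus two finger-only channels on the second
array), 8 to `BLf` (gain 2); visual-only conditions at gain 1; latencies
−25 ms (`FPa`), 25 ms (`BLa`), 75 ms (`BLf`) and 125 ms (`FPf`). These
values were chosen once, from the published qualitative pattern (more
arm- than finger-tuned channels, seen-touch populations a superset of
blind-touch populations, arm latencies earlier than finger), and are not
tuned to any test outcome.

Catch trials are generated (one per run, drawn from a different condition),
flagged, and excluded from every analysis; how such trials were handled in
the original analyses is unstated, and exclusion matches the exact
70-trials-per-condition accounting.

`simulate_broadband()` provides 30 kHz voltage snippets with stereotyped
negative spike waveforms planted at known samples for testing the
extractor; overlapping waveforms are rejected at generation so extractor
scoring is unambiguous.

## Preprocessing

Multi-unit events are negative crossings of −3.5 × the RMS of the
continuous voltage, with the event time taken at the first sample below
threshold and a 1 ms refractory lockout (the lockout prevents one waveform
from being counted repeatedly; its exact value is not critical). The RMS is
computed from the raw trace; a robust median-based estimator is available
behind a flag. No band-pass filtering or spike sorting is applied — the
signal is used in a multi-unit, unsorted fashion.

Counts are binned into half-open 50 ms bins `[t, t + Δ)` with a boundary
exactly at t = 0 and divided by the width to give Hz. Normalization divides
every channel's rates, within each run, by the across-trial mean over the
baseline window (−4 to −2.5 s), making the baseline-window mean exactly 1
per channel per run. Channels with a zero baseline in a run cannot be
normalized there and are excluded for that run (conservative; they are
recorded in the `excluded` attribute). Rebinning to 0.5 s or 0.1 s averages
(never sums) constituent bins so normalized values keep their scale.

Session stability across the two collection sets is checked with paired
Wilcoxon sign-rank tests on per-channel quantities: two waveform SNR
metrics (mean-waveform trough over noise RMS, and over the across-event SD
at the trough) and the mean and SD of run-normalized firing rates in the
inter-trial window, which is −4 to −1 s — deliberately wider than the
normalization window, and configurable separately.

## Decoding

Every decoder follows the same recipe per condition pair and time bin:
the trials are split into balanced train/test halves (70 + 70 trials give
35/35 per class; odd classes floor to equal halves), the top 40
variance directions of the *training half* are found by SVD, both halves
are projected, and a two-class LDA with pooled covariance is fit and scored
on the held-out half. This is repeated for `n_splits` independent splits
(study value 1000) and the accuracies averaged; run and session membership
are deliberately ignored when splitting. Refitting the SVD inside every
split avoids train/test leakage through the projection.

The pooled covariance is shrunk toward a scaled identity by λ = 1e-6,
raised automatically by factors of 10 if singular — at 40 projected
dimensions and 68 within-class degrees of freedom the pooled estimate is
occasionally ill-conditioned, and a hard failure is never acceptable
mid-resampling. Discriminant-score ties break toward the first class,
deterministically.

The null distribution reuses the identical machinery on trials whose
labels are shuffled once per iteration, before splitting (whether the
original analyses shuffled before or after splitting is unstated; shuffling
before is the stricter exchange). Significance tiers compare percentile
intervals of the accuracy and null distributions: `*`, `**`, `***` when the
95%, 97.5% or 99% intervals fail to overlap, taking the most stringent
non-overlapping level. On signal-free sessions the `*` tier fires at or
below the nominal rate (checked over 200 simulated sessions).

Generalization decoders train a contrast (say arm vs finger) on the trials
of one touch type and test it on the trials of another, label-disjoint
touch type, subsampling the training groups to equal size per iteration and
shuffling training labels for the null.

## Crossnobis RSA

Dissimilarity between conditions $a,b$ at one time bin is the
cross-validated squared Mahalanobis distance over run-wise folds:

$$d(a,b) = \frac{1}{F(F-1)P} \sum_{m \neq n}
 (\bar x_a^{(m)} - \bar x_b^{(m)})^\top \hat\Sigma_\lambda^{-1}
 (\bar x_a^{(n)} - \bar x_b^{(n)}),$$

with $F = 7$ folds (the 10-trial runs), $P$ the channel count, and
$\hat\Sigma_\lambda$ the within-condition residual covariance shrunk toward
its diagonal. Averaging over ordered fold pairs makes the estimator
unbiased with a meaningful zero: statistically indistinguishable conditions
give distances scattered around 0, and slightly negative values are
legitimate (they are clipped only when a nonnegative dissimilarity is
required, i.e. for MDS). The $1/P$ normalization makes values comparable
across simulated population sizes; only relative structure is interpreted.
The diagonal is meaningless and stored as `NA`, excluded from correlations
and embeddings.

Residuals for the noise estimate are computed per condition-by-fold cell,
so the fold means used in the distances are not reused in the covariance.
The shrinkage weight follows the analytic optimal-shrinkage rule with a
floor of 0.01 (the amount of regularization in the original analyses is
unstated; the analytic rule adapts to the trials-to-channels ratio and the
floor guarantees invertibility). `shrinkage = 1` gives a purely diagonal
model, and for $\Sigma = \sigma^2 I$ the distance reduces exactly to the
cross-validated squared Euclidean distance divided by $\sigma^2 P$ — both
are verified against brute-force fold-pair summation to 1e-10.

Noise is estimated per time bin (pooling across bins is a configurable
alternative; per-bin estimation makes no stationarity assumption).

RDM time courses are compared by Pearson correlation over the vectorized
lower triangle, Bonferroni-multiplied by the stated number of comparisons.
MDS minimizes the metric stress
$\sqrt{\sum_{i<j}(\hat d_{ij} - d_{ij})^2 / \sum_{i<j} d_{ij}^2}$ from a
classical-scaling start plus seeded random restarts (BFGS), and successive
bins are aligned by orthogonal Procrustes rotation so axes stay comparable
over time. Per-pair residual distortions are reported — the quantity behind
"rubber band" displays.

## Tuning and onset analysis

Per channel and per 0.5 s bin in the −1 to 2 s window, normalized rates are
fit to $F = \beta_0 + \sum_c \beta_c X_c$ with one-hot condition coding,
augmenting the response vector with 70 identical entries equal to the
channel's across-trial mean baseline. With this design OLS has a closed
form — $\hat\beta_0$ is the baseline value and $\hat\beta_c$ the condition
mean minus baseline — which the implementation uses (verified against
`lm()`), making the 1000-iteration count bootstrap cheap. The identical
baseline rows contribute zero residual while inflating the residual degrees
of freedom, which deflates the variance estimate somewhat; this mirrors the
augmentation as described and is flagged rather than "fixed". Per-condition
two-sided t-tests of $\beta_c = 0$ are corrected within each channel by
Bonferroni–Holm; the default family is all condition × bin tests of the
channel (the conservative reading of "within each channel"; a per-bin
family is available). Holm decisions are verified against exhaustive
closed-testing enumeration for families up to size 6.

Tuned-count uncertainty comes from resampling trials with replacement
within each condition (keeping 70 per condition), refitting everything, and
counting channels tuned per condition in any bin; condition pairs are
flagged by CI non-overlap at the 95/97.5/99% tiers. Because duplicated
trials in a resample deflate the residual-variance estimate, bootstrap
counts skew upward relative to the observed count — the count CIs are
right-skewed and should be read as a comparison device between conditions,
not as absolute-count uncertainty. Channel overlap sets
(arm-only / finger-only / both, overall and within touch types) and
electrode-array maps summarize which populations respond to what.

Onsets are estimated from the average of all tuned channels and condition
trials on the 50 ms grid: the onset is the middle of the first bin rising
above the 95th percentile of the distribution of channel-averaged
baseline-window rates, and the offset the middle of the first bin after the
trace's peak falling back below that threshold. The offset convention
follows "after the peak"; a variant searching from the onset is exposed as
a flag because the two published descriptions differ subtly. Confidence
intervals bootstrap trials (not channels), recomputing both the trace and
the threshold per resample (study value 10,000 resamples). A trace that
never crosses the threshold has an undefined onset, reported as `NA`.

## Pipeline, determinism, and problem sizes

`run_pipeline()` chains simulate → normalize → decode → RSA → tune → onsets
and scores recovery against the planted truth (tuning sensitivity and
false-positive rate, expected vs estimated onset bin midpoints). Every
stage derives its seed deterministically from the global seed, so identical
configurations give byte-identical summary JSON. Reduced-cost defaults (100
splits, 500 count bootstraps, 1000 onset bootstraps) keep a full 96-channel,
9-condition run around two minutes; `paper_scale = TRUE` switches to the
study-scale values (1000 / 1000 / 10,000).

The validation suite runs at deliberately chosen sizes: crossnobis oracle
equivalence on all configurations up to 3 conditions × 3 folds × 3
channels; unbiasedness over 1000 simulated 96-channel sessions;
null-decoder calibration over 200 signal-free sessions at 100 splits; LDA
consistency with $\Phi(1)$ on a 4-dimensional planted Gaussian (the
dimension is chosen low so the n = 70 estimation loss is negligible
against the closed form); tuning recovery at gain 2 on 30 of 96 channels;
onset recovery over 100 sessions per planted latency. Coarse-binned
(0.5 s) epochs are used wherever only one analysis bin is needed, which
changes nothing statistically but keeps repeated simulation cheap.

## What passing tests do and do not show

The generator emulates the task structure, condition-dependent gains and
latencies, shared channel noise, and the two-set session layout. It does
not emulate electrode drift within a session, non-Poisson spiking
regularities, waveform changes, eye position, stimulus-delivery variability
or pressure-sensor alignment error. Recovery results on synthetic sessions
therefore validate the *estimators* — unbiasedness, calibration, error
control, latency conventions — not the biological claims; and the
published numbers from the real recordings (e.g. specific decoding
percentages) are not reproducible from synthetic data, only the qualitative
structure planted in `paper_like_truth()` is.

Known limitations: LDA assumes shared class covariance (matching the
original analysis choice, not a modelling claim); the baseline-row
augmentation mildly deflates regression residual variance as described
above; metric-stress MDS has local minima, mitigated but not eliminated by
multiple restarts; and with 70 trials against 96 channels the noise
covariance relies on shrinkage, so whitening is approximate at study scale.
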