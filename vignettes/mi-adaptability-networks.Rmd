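---
title: "Motor-imagery adaptability and EEG functional networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-imagery adaptability and EEG functional networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Motor-imagery brain-computer interfaces (MI-BCI) decode imagined movements
(left hand, right hand, foot, tongue) from scalp EEG. Individuals differ
widely in how well such systems work for them; a substantial fraction of
healthy users never exceed ~70% binary accuracy. `miadapt` quantifies a
subject's *adaptability* as the mean 10-fold cross-validated accuracy over
the six pairwise task classifications, and then asks which properties of
the subject's EEG functional networks co-vary with that score across a
cohort.

Because raw human EEG for this paradigm is rarely shareable, the package
ships a first-class synthetic-data generator with known ground truth.
Every downstream stage — preprocessing, feature extraction, classification,
connectivity, graph metrics, correlation screening — is exercised against
cohorts whose class separability and network structure are planted by
construction.

## The pipeline

### Paradigm and synthetic EEG

`generate_paradigm()` reproduces the session structure: 5 sets x 40
trials, each trial 7 s of cued imagery followed by 5 s rest, each of the
four tasks appearing exactly 10 times per set in seeded random order
(200 trials, 50 per task).

`simulate_recording()` builds each channel as

* pink noise with a 1/f spectrum (exponent 1 by default), plus
* band-limited oscillations: sinusoids whose instantaneous frequency
  wanders uniformly inside the band (a random-phase-walk) and whose
  amplitude waxes and wanes under a slowly varying log-normal envelope
  (`amp_jitter_sd`, default 0.5, ~1 s timescale).

Two kinds of ground truth can be planted:

* **Phase-lagged coupling** — a coupling entry `(from, to, band, lag,
  strength, task)` replaces a fraction `strength` of the target channel's
  band component with the source's oscillation shifted by `lag` radians.
  Task-conditional entries act only inside that task's imagery windows.
  Because the emitted copy uses the source's own phase track, sources must
  not themselves be coupling targets (the generator warns otherwise).
* **Event-related desynchronization (ERD)** — an ERD entry attenuates the
  band amplitude on selected channels during matching imagery windows,
  giving the classifier a class-specific spatial power pattern.

The oscillation-to-noise ratio `snr` defaults to 1 in `synth_spec()`; the
cohort generator `cohort_spec()` uses 0.3, calibrated once so that
simulated adaptability scores span the wide range observed in human
cohorts (roughly chance to ~0.9) instead of saturating at 1. Amplitudes
are nominal microvolts; every downstream statistic (WPLI, CSP, Pearson
correlations) is scale-invariant or standardized, so the absolute scale is
irrelevant.

Seeding: one master seed; per-subject seeds are derived by a fixed counter
scheme (`master * 10007 + index mod 2^31-1`), so cohorts are reproducible
and subjects independent.

### Preprocessing

`preprocess_recording()` applies, in a fixed, logged order: channel
selection with inverse-distance interpolation of bad channels, average
re-referencing, zero-phase FIR band-pass, integer-ratio downsampling, an
optional denoising hook, and epoch extraction.

Numerical choices:

* The FIR is Hanning-windowed with order `3 * fs / transition_bw`, rounded
  to the nearest even integer (a type-I linear-phase filter whose group
  delay of order/2 samples is compensated exactly, so epoch timing never
  shifts). The default band is 1–40 Hz with a 1 Hz transition.
* Filtering precedes decimation so the decimated signal is already
  band-limited below the target Nyquist; the default target is 250 Hz.
* Bad channels are replaced by the inverse-distance-weighted mean of their
  4 nearest neighbours on a flat projected 10-20 grid. This is a
  deliberately simple scheme, adequate for synthetic data; spherical-spline
  interpolation is out of scope.
* The epoch window defaults to seconds 1–4 after imagery onset (3 s,
  750 samples at 250 Hz), skipping a 1 s reaction period; the offset is a
  configuration knob because the choice is conventional.
* Of the 50 trials per task, 35 are retained by keeping those with the
  smallest peak-to-peak amplitude (tie-broken by trial order) — a
  deterministic, artifact-motivated stand-in for manual trial rejection.
* Independent-component denoising is inherently manual; the pipeline
  provides only a pass-through `denoise_hook()`.

### Feature extraction

Four extractors, with fixed output dimensionality on a 35 + 35 epoch
two-class problem (70 samples):

* **PSD (70 x 21)** — Thomson multitaper power spectral density (Slepian
  tapers computed from the classical tridiagonal formulation; NW = 4,
  7 tapers), averaged over 8–30 Hz per channel, on a 21-channel
  sensorimotor subset (`FC5..FC6`, `C5..C6`, `CP5..CP6`). The subset is
  configuration-overridable; the three 7-electrode rows cover the
  sensorimotor strip where mu/beta modulation is expected.
* **WPD+DWT (70 x 36)** — the epochs are averaged over the same 21-channel
  subset, then decomposed with a 5-level discrete wavelet transform
  (sub-bands A5, D5..D1) and a 3-level wavelet packet decomposition, of
  which the 6 leaves with greatest spectral overlap with 8–30 Hz are kept
  (ties resolved toward lower frequencies; leaf order accounts for the
  spectral reversal of high-pass branches via the inverse Gray code). Each
  of the 12 sub-bands contributes the mean, standard deviation and mean
  power of its coefficients. The default mother wavelet is `db4`;
  Daubechies, Symlet, Haar and Coiflet filters are available. Odd-length
  levels are extended by repeating the final sample.
* **RF (70 x 12)** — per filter-bank band (six 4-Hz bands, 8–32 Hz),
  the affine-invariant Riemannian distances from each epoch's regularized
  covariance (ridge `1e-6 * trace/p`) to the two class Karcher means.
  The Karcher mean iterates tangent-space averaging with step-halving when
  the tangent norm fails to decrease (band-limited covariances can be very
  ill-conditioned). Tangent-space vectorization (`tangent_map()`) is also
  provided; the distance parameterization is the default because it
  produces the fixed 12-column layout.
* **FBCSP (70 x 24)** — common spatial patterns per filter-bank band
  (2 filter pairs, log of normalized projected variance), 6 x 4 columns.
  Per-band mutual information with the class label (plug-in estimate,
  8 equal-frequency bins) is reported for ranking but no band is dropped
  by default.

The 4-Hz filter bank is the conventional choice covering the 8–30 Hz
mu/beta range. CSP is solved by whitening the pooled covariance and
eigendecomposing the whitened class covariance, which enforces
`t(W) (C1+C2) W = I` exactly.

### Adaptability

`pairwise_accuracy()` runs seeded, stratified k-fold cross-validation of a
linear soft-margin SVM (cost 1, linear kernel — the common MI-BCI
default, and deterministic). Every trainable
quantity — feature standardization, CSP filters, Riemannian class means —
is refitted inside each training fold; band-pass filtering and per-epoch
covariances are label-independent and precomputed once. Optional repeated
cross-validation (`repeats`) averages independent fold assignments to
reduce the variance of the estimate.

`adaptability_score()` averages the six pairwise accuracies in the fixed
order LH-RH, LH-F, LH-T, RH-F, RH-T, F-T; `variant3` averages only the
three pairs without the tongue task. `method_consistency()` correlates the
per-subject scores of different extractors.

### Connectivity and graph metrics

`wpli_matrix()` implements the weighted phase lag index per channel pair:
band-pass each epoch (same FIR design rule, 1 Hz transition), form
analytic signals, and pool the instantaneous cross-spectral observations
`S_xy = x conj(y)` over all time points of all retained epochs:

    WPLI = | mean(Im S) | / mean(|Im S|)

with 0/0 defined as 0 (no imaginary cross-spectral mass, e.g. zero lag).
The index lies in [0, 1], is insensitive to per-channel amplitude scaling
and common phase rotation, and discounts zero-lag (volume-conduction-like)
contributions. Analysis bands: alpha 8–12, beta1 13–20, beta2 20–30 Hz
(the 8–12 convention is used for alpha, matching the connectivity
analysis rather than the broader introduction-level 8–13 convention).
WPLI is estimated per task from that task's retained epochs.

`threshold_top_fraction()` keeps the `round(0.10 * 1770) = 177` strongest
of the 1770 distinct pairs on the 60-channel montage, ties at the cut
resolved by (row, column) order, then binarizes.

`node_metrics()` computes, on the binary graph: degree, clustering
coefficient, nodal mean shortest-path length, local efficiency (inverse
distances within the subgraph induced by a node's neighbours), and
betweenness centrality (endpoints excluded, unnormalized, unordered
pairs). Shortest paths are unweighted hops. Pairs with no connecting path
are excluded from path-length averages and their count reported — the
finite alternative to infinite distances on sparse thresholded graphs
(a harmonic-mean variant is available). `hemisphere_summary()` averages
the five nodal metrics over 15 key electrodes per hemisphere
(F/FC/C/CP/P rows, indices 1/3/5 left and 2/4/6 right), adds the
characteristic path length over all 30 (distances measured on the full
graph, not the hemisphere subgraph), and forms left-minus-right
differences.

### Screening

`screen()` computes Pearson r and two-sided p (t transform, df = n - 2)
for every property x method cell and flags cells with `p < alpha` AND
`|r| > r_min`. The default `r_min = 0.273` equals `critical_r(0.05, 50)`;
note that the conventional `df = n - 2 = 48` for a 50-subject cohort gives
0.279 — both conventions are exposed, p-values always use `n - 2`. The
absolute value matters: strong negative correlations are flagged too. No
multiple-testing correction is applied by default, matching common
practice in this literature; a clearly-labelled Benjamini-Hochberg column
is available as an extension.

## Ground-truth recovery design

`cohort_spec(strength)` links one scalar per subject to both ends of the
chain:

* ERD depth `0.8 * strength` on task-specific channel groups
  (contralateral hand areas, midline foot area, lateral tongue area)
  drives class separability, hence adaptability;
* tongue-conditional beta2 coupling from five lateral right-hemisphere
  sources (F8, FT8, T8, TP8, P8) into the 15 key right electrodes, at
  staggered per-edge strengths (`0.4..1.3 * strength`, clipped at 1) and
  distinct lags, drives right-hemisphere nodal degree (KR) in the
  thresholded tongue/beta2 network. Staggering matters: the count of
  planted edges that clear the top-10% cut then grows smoothly with
  `strength` instead of jumping.

A cohort with a strength gradient therefore has a built-in positive
KR-adaptability correlation that the screen should recover, while
properties generated independently of the scores should be flagged at
about the nominal alpha.

## Problem sizes used by tests and the acceptance script

The packaged checks run the full-scale bookkeeping (5 x 40 paradigm,
60-channel montage, 35-epoch WPLI nulls, 177-edge thresholds) but scale
the cohort simulation down to sizes chosen for routine re-running: 10
subjects x 10 replicates, recordings simulated directly at 250 Hz, 2 sets
of 32 trials (16 per task, all retained), 3-s epochs, PSD features with
8-fold, 3-repeat cross-validation, and connectivity restricted to the
tongue/beta2 network that carries the planted effect. The full-scale
defaults remain the package defaults (`study_config()`), and nothing in
the scaled configuration changes the method — only the sample sizes.

## What passing tests do and do not show

The generator produces band-limited oscillations with exactly consistent
planted lags, stationary pink noise, and amplitude-only task modulation.
Real EEG adds volume conduction (zero-lag mixing that WPLI deliberately
discounts but which still reshapes networks), non-stationarity, ocular and
muscular artifacts, electrode drift, and inter-subject anatomical
variability — none of which are modelled. Recovery of planted effects
therefore validates the estimators and the pipeline plumbing, not the
neurophysiological claims; with ~10 subjects the screen's power is modest
and only strong planted gradients are detectable.

## Known limitations

* No spherical-spline interpolation or head model; electrode geometry is a
  flat projected grid used only for neighbour weighting.
* Independent-component denoising is a pass-through hook.
* Binary (not weighted) graph metrics, per the adjacency-based
  definitions; no small-world or modularity statistics.
* The EDF interfaces of acquisition systems are not read directly;
  recordings enter as in-memory arrays or the package's plain tabular
  text format.
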