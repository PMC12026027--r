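# miadapt

Who is well suited to a motor-imagery brain–computer interface (MI-BCI)?
Users imagine one of four movements (left hand, right hand, foot, tongue)
while 60-channel EEG is recorded; a classifier decodes the imagined
movement, and individuals differ enormously in how decodable their signals
are. `miadapt` is an R package for studying this *adaptability* and its
relationship to the brain's functional networks:

* **Adaptability score** — for each subject, the mean 10-fold
  cross-validated accuracy of a linear SVM over the six pairwise task
  classifications (LH–RH, LH–F, LH–T, RH–F, RH–T, F–T), computed under
  four standard EEG feature pipelines: multitaper band power (PSD),
  wavelet/wavelet-packet statistics (WPD+DWT), Riemannian covariance
  distances (RF), and filter-bank common spatial patterns (FBCSP).
* **Functional networks** — per task and frequency band (α 8–12,
  β1 13–20, β2 20–30 Hz), the weighted phase lag index between every
  channel pair,

  `WPLI_xy = | mean(Im S_xy) | / mean(|Im S_xy|)` ,

  where `S_xy = x·conj(y)` are instantaneous analytic cross-spectra pooled
  over the task's epochs. The strongest 10% of connections form a binary
  network (177 of 1770 edges on the 60-channel montage).
* **Graph metrics and screening** — nodal degree, clustering, path
  length, local efficiency and betweenness; hemispheric means over 15 key
  electrodes per side (e.g. `KR` = mean right-hemisphere degree) and
  left–right differences; Pearson screening of every network property
  against every adaptability method, flagged when `p < 0.05` and
  `|r| > 0.273` (the critical r for α = 0.05 at df = 50).

Because raw human EEG for this paradigm is rarely shareable, the package
includes a first-class synthetic EEG generator (pink-noise background,
band-limited oscillators, task-conditional phase-lag coupling, and
event-related desynchronization) so the whole chain runs — and is tested —
against cohorts with known ground truth.

## Worked example

Simulate one subject at the scaled-down session size (2 sets × 20 trials,
250 Hz), preprocess, score adaptability, and inspect the tongue-imagery
β2 network:

```r
library(miadapt)

sched  <- generate_paradigm(sets = 2, trials_per_set = 20,
                            imagery_s = 4, rest_s = 1, seed = 1)
spec   <- cohort_spec(strength = 0.8, fs = 250)  # strong planted effects
spec$seed <- 7
rec    <- simulate_recording(sched, spec)
epochs <- preprocess_recording(rec, per_task_keep = 10, window = c(1, 3))

subject_adaptability(epochs, "PSD", folds = 5, seed = 1)
#> <adaptability_score> subject=NA method=PSD mean=0.783 variant3=0.767
#> left_hand-right_hand       left_hand-foot     left_hand-tongue
#>                 0.75                 0.80                 0.70
#>      right_hand-foot    right_hand-tongue          foot-tongue
#>                 0.75                 0.95                 0.75

W   <- wpli_matrix(epochs_for_tasks(epochs, "tongue"), band = c(20, 30))
net <- threshold_top_fraction(W, 0.10)
net
#> <binary_network> 60 nodes, 177 edges (top 10%)
round(hemisphere_summary(node_metrics(net), net), 3)
#>      KL      CL      LL      EL     BCL      KR      CR      LR      ER     BCR
#>   4.333   0.062   2.615   0.065  26.060   7.667   0.292   2.339   0.402  60.467
#>       L      KD      CD      LD      ED     BCD
#>   2.456  -3.333  -0.231   0.275  -0.337 -34.406
```

The six pairwise accuracies average to an adaptability of 0.783 for this
subject. In the tongue/β2 network the right-hemisphere mean degree
(`KR = 7.67`) clearly exceeds the left (`KL = 4.33`): this subject was
simulated with strong right-lateralized β2 phase coupling during tongue
imagery, and the top-10% network concentrates there. Across a cohort with
a strength gradient, `run_study()` assembles the subject × property and
subject × method tables and `screen()` recovers the planted
KR–adaptability association:

```r
res <- run_study(study_config(n_subjects = 10, ...), verbose = FALSE)
res$screening$tongue_beta2    # property × method r/p grid with flags
```

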