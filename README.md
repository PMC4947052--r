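# measelect

Stimulus-selectivity analysis for cultured neuronal networks recorded on
planar microelectrode arrays (MEAs).

## The problem

Dissociated hippocampal cultures grown over an 8 × 8 grid of 64
extracellular electrodes respond to localized biphasic stimulation with
network-wide bursts lasting 100–300 ms. If responses evoked from two
different stimulation sites (S1, S2) are statistically distinguishable,
the network is *selective*: its spike trains carry information about the
stimulus location. `measelect` quantifies that selectivity at three
levels — single electrodes, single 20 ms time bins, and the whole
population pattern — and decodes the stimulation site from population
responses. It targets experimenters working with paired-site MEA
stimulation protocols (2 sites × 2 blocks × 15 stimuli, 10–20 s
inter-stimulus intervals matched to the spontaneous inter-burst
interval) and methodologists who need a fully synthetic, ground-truthed
test bed for such analyses.

## What it computes

* **Spike detection.** Raw 20 kHz traces are band-pass filtered
  (0.3–8 kHz, zero-phase Butterworth); spikes are threshold crossings of
  |x| above `T = N_S · σ`, with the robust noise estimate
  `σ = median(|x|) / 0.6745` and `N_S = 8`.
* **Response features.** Each stimulus opens a 300 ms window; spikes in
  the first 15 ms are discarded as non-synaptic. Per electrode:
  the binned *spike-rate pattern* (15 bins × 20 ms), the *activation
  time* (first retained spike latency) and the *total spike count*.
  Inclusion filters: *active* electrodes respond (≥ 1 spike / 300 ms)
  to > 80 % of stimuli; *stable* bins fire in ≥ 80 % of stimuli;
  *stationary* electrodes show no significant block-1 vs block-2
  rank-sum difference.
* **Selectivity.** Per electrode/bin cell, two measures: a two-sided
  Mann–Whitney rank-sum flag (*statistical selectivity*; p < 0.001 for
  whole-response features, p < 0.05 per bin) and the *overlap* — pooled
  responses are split by 2-means clustering, clusters are matched to the
  true site labels by minimum misclassification, and the overlap is the
  misclassified percentage `100 · N_c / (N_a + N_b)` ∈ [0 %, 50 %]
  (0 = perfectly separable, 50 = chance). The electrode × bin matrices
  of flags and overlaps are the *selectivity* and *overlap signatures*.
* **Decoding.** Site classification from population features
  (activation-time pattern, total-spike-count pattern, first-bin rate,
  full pattern) with unsupervised K-means (label-matched), K-means with
  predefined centroids (nearest class mean), and an RBF-kernel SVM with
  nested fivefold cross-validation; plus electrode-exclusion accuracy
  curves (drop lowest/highest-overlap electrode iteratively).
* **Synthetic recordings.** `generate_recording()` emulates the whole
  protocol — Bernoulli per-electrode responsiveness, inhomogeneous
  Poisson burst envelopes peaking 50–100 ms post-stimulus, truncated
  normal first-spike latencies, lognormal burst-to-burst gain,
  spontaneous bursts at 10–20 s renewal intervals — with a ground-truth
  record of which electrodes/bins were configured selective.
  `generate_raw_trace()` adds 10–40 µV spike templates to Gaussian noise
  for validating the detector.

## Worked example

```r
library(measelect)

rec <- generate_recording(seed = 42)       # default 64-electrode world
pat <- extract_patterns(rec$spikes, rec$stims)
fr  <- filter_report(pat)
fr
#> Filter report: 40 active electrodes (24 excluded as inactive)
#>   stationary: 38 (2 flagged non-stationary)
#>   stable bins per active electrode: median 4 (range 2-5)

sig <- build_signatures(pat, fr, feature = "bin_rate")
sig
#> Signatures (bin_rate, wilcox test, alpha = 0.05): 145 cells on 38 electrodes
#>   statistically selective cells: 36 (24.8 %)
#>   overlap: median 45.0 %, min 10.0 %

overlap(pat$total[pat$site == "S1", 3], pat$total[pat$site == "S2", 3])
#> Overlap: 21.67 % (13 of 60 responses misassigned)

fm <- feature_matrix(pat, "total_count", electrodes = fr$active)
reports <- classify_all(fm, seed = 42)
#> kmeans    on total_count features: accuracy 81.67 % (49/60)
#> kmeans_pc on total_count features: accuracy 88.33 % (53/60)
#> svc       on total_count features: accuracy 95.00 % (57/60)
```

Reading: of 64 electrodes, 40 respond reliably and 38 of those are
stationary across repeated blocks. 36 of 145 testable electrode × bin
cells discriminate the two sites (the generator's ground truth confines
the effect to electrodes 1–12, bins 2–6); the best cell still
misassigns 10 % of responses. One electrode's total spike count alone
misassigns ~22 % of responses, while the population pattern decodes the
site at 82–95 % accuracy depending on the classifier — the ordering
(unsupervised K-means < nearest centroid < cross-validated SVM) mirrors
what is reported for real cultures.

A command-line driver is installed as `exec/measelect`
(`measelect simulate|detect|features|selectivity|classify|run`), and
`run_pipeline()` executes all stages with a provenance manifest.

## Documentation

The methods vignette (`vignettes/mea-selectivity.Rmd`) describes the
model assumptions, the synthetic world and its calibration, numerical
choices (k-means determinism, tie handling, imputation) and known
limitations, including the resubstitution bias of the predefined-
centroid classifier.
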