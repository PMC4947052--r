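---
title: "Quantifying stimulus selectivity in MEA cultures: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stimulus selectivity in MEA cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

`measelect` analyses stimulation trials on cultured neuronal networks
over a planar 8 × 8 electrode grid (50 µm electrodes, 150 µm pitch).
Two stimulation sites are driven in alternating blocks of 15 stimuli
(two blocks per site, 30 stimuli per site), with the inter-stimulus
interval matched to the culture's spontaneous inter-burst interval
(10–20 s) so that stimulation rides on, rather than perturbs, the
ongoing bursting regime. Each stimulus evokes a population burst; the
analysis treats the signal at each electrode as a single multi-unit
event (no spike sorting — during dense network bursts the waveforms
recorded by 50 µm electrodes are superpositions that cannot be reliably
sorted into units).

Three response features are extracted per electrode and stimulus from
the 300 ms post-stimulus window, after discarding the first 15 ms
(direct, non-synaptic activation): the spike-rate pattern over fifteen
20 ms bins, the activation time (latency of the first retained spike),
and the total spike count. All window arithmetic is half-open
`[a, b)`: a spike at exactly 15 ms is synaptic, one at exactly 300 ms
is outside the window. Latencies are rounded to 10⁻⁶ ms before window
comparisons so that boundary membership does not depend on the binary
representation of times stored in seconds.

### Inclusion filters

* **Active electrode**: ≥ 1 spike within 300 ms in *more than* 80 % of
  stimuli (strict inequality — 24/30 fails, 25/30 passes).
* **Stable bin**: ≥ 1 spike in the bin in *at least* 80 % of stimuli
  (inclusive — 24/30 passes). The two criteria are deliberately
  asymmetric; both are implemented exactly as printed in the protocol
  they encode.
* **Stationary electrode**: no significant block-1 vs block-2
  difference of total spike counts for any site (two-sided Mann–Whitney,
  α = 0.05). Zero-count responses are excluded from this comparison by
  default, and electrodes with fewer than two usable responses per block
  are untestable and retained.

Whether the activity criteria apply per site or to the pooled stimuli
was an open design point; the default is per-site (an electrode must be
reliable for *both* sites to contribute to a site comparison), with a
pooled option.

## The overlap statistic

For two sets of responses A and B (one per site), the pooled values are
partitioned into two clusters by 2-means; clusters are matched to the
source labels by the assignment minimizing the misclassification count
`N_c = N_a + N_b` (set-B members captured by cluster A′ plus set-A
members captured by cluster B′), and the overlap is
`100 · N_c / (N_a + N_b + correctly assigned) = 100 · N_c / n_total`.
Minimizing over the two label assignments bounds the overlap by 50 %
(chance); 0 % means the sets are perfectly separable by a threshold.

Numerical choices:

* **Scalar responses** (per-bin counts, per-electrode totals or
  latencies): the globally optimal 2-means partition of scalars is a
  threshold split of the sorted values, found exactly by scanning all
  n − 1 splits with prefix sums. This is deterministic, O(n log n), and
  never worse than any Lloyd iteration, so no seeding enters the
  per-cell overlap values. Splits are only placed between strictly
  different values, so tied values can never be separated.
* **Multivariate patterns**: seeded k-means++ initialization with 10
  restarts and Lloyd iterations, best within-cluster SS kept. The seed
  is part of the configuration, making overlap values reproducible.
* **Ties in label matching** break toward assigning cluster 1 to site A.
* **Degenerate input** (all pooled values identical) carries no
  information; the overlap is defined as the chance level 50 % and
  flagged `degenerate`.
* The overlap is invariant under A/B relabelling and under any affine
  rescaling of scalar responses (the 2-means objective scales by c²).

Statistical selectivity uses the two-sided Mann–Whitney rank-sum test
(α = 0.001 for whole-response features, α = 0.05 per bin). The test
family follows the protocol's Methods; a two-sample t option exists for
comparison but is not the default. No multiple-testing correction is
applied — the signatures are descriptive maps, not inferential claims —
though Benjamini–Hochberg can be applied downstream by the user from
the returned p matrices. Zero-count responses *are* included in per-bin
samples: for an active electrode, silence in a bin is informative.

## Decoding the stimulation site

* `kmeans_classify()`: unsupervised 2-means over all patterns, clusters
  matched to site labels by maximum agreement. Matching folds the null
  accuracy above 50 %: with identical class distributions and n = 60
  patterns the expected accuracy is the folded-binomial mean ≈ 55 %,
  and the package's null tests assert against that analytic value, not
  against a naive 50 %.
* `kmeans_pc_classify()`: nearest class centroid, each centroid the mean
  of that site's responses. The default is resubstitution, exactly as
  the procedure is conventionally described. **This estimator is
  optimistically biased**: each pattern contributes to its own class
  centroid, and on null data with d ≈ 40–64 features and 30 patterns
  per class the bias reaches ≈ 80 % "accuracy" (roughly
  Φ(√(d/2m)) for m patterns per class). The report labels the mode, a
  held-out `mode = "split"` variant is provided, and the null
  calibration tests use the split variant — the resubstitution figure
  should be read as a descriptive, not predictive, accuracy.
* `svc_classify()`: RBF-kernel support-vector machine (in-package SMO
  solver), per-column standardization with training-fold statistics,
  kernel width from the median heuristic × {0.1, 1, 10} and cost
  ∈ {0.1, 1, 10, 100} selected by inner fivefold cross-validation,
  accuracy reported from the outer fivefold loop. The procedure is
  supervised classification with cross-validation (the historical name
  "support vector clustering" notwithstanding).
* `electrode_exclusion_curve()`: repeatedly removes the
  lowest-overlap (most selective) or highest-overlap electrode and
  recomputes the nearest-centroid accuracy on total-spike-count
  patterns, down to two electrodes (n − 1 curve points).

Missing activation times (electrode silent on a stimulus) are imputed
with the 300 ms window bound before classification: "no response" is
informatively late. The imputation count is reported on the feature
matrix.

## The synthetic world

`generate_recording()` draws, per stimulus and electrode: a Bernoulli
response indicator (p = 0.95 for the ~40 reliably responding
electrodes, 0.05 elsewhere — real trials report 36 ± 8 active
electrodes of 64); spike counts from an inhomogeneous Poisson process
over the synaptic window with a per-bin envelope peaking at bin 4
(60–80 ms, within the observed 50–100 ms rate peak; the first bin's
intensity is prorated to its retained 5 ms); and a first-spike latency
from a normal distribution (mean 30 ms, SD 6 ms) truncated to the
window, with earlier Poisson spikes discarded so that activation time
and rate are independently controllable. Spontaneous bursts recruiting
all electrodes arrive as a renewal process with uniform 10–20 s gaps
and may overlap response windows, as in the real preparation.

**Site effects** are confined to 12 electrodes (matching the ~12
statistically selective electrodes reported per trial): site 2
multiplies their per-bin rate by 3 on bins 2–6 and shifts their mean
latency by +20 ms.

**Burst-gain variability.** Each response additionally draws one
multiplicative gain g ~ Lognormal(−σ²/2, σ) with σ = `gain_spread`
= 0.3, shared across electrodes. This emulates burst-to-burst
variability (within-site response "motifs"): without it, unsupervised
K-means decodes nearly as well as the SVM, which contradicts what real
cultures show; with it, the default world reproduces the qualitative
decoding landscape of cultures — unsupervised K-means ≈ 65 %, nearest
centroid ≈ 86 %, cross-validated SVM ≈ 95 % on total-spike-count
patterns. The default effect sizes (rate ratio 3, gain spread 0.3) were
fixed once, by a calibration sweep against that landscape, before the
acceptance tests were written, and are not adjusted by any test.
Setting `gain_spread = 0`, `latency_coupled = FALSE` recovers an exact
thinned-Poisson response whose first and second moments the test suite
checks in closed form (mean p·Σλ, Fano factor 1).

What the generator does **not** emulate: biophysical membrane or
synaptic dynamics, stimulation artifacts, plasticity across blocks
(unless explicitly configured via `block2_scale`), electrode cross-talk,
non-Poisson within-bin spike correlations, and the within-burst
structure of spontaneous bursts (the evoked envelope is reused — an
assumption, since the protocol does not constrain it). A green
parameter-recovery test therefore establishes that the analysis
recovers the selectivity structure of this stochastic model at
realistic rates and sample sizes — not that it is robust to every
failure mode of biological recordings.

## Spike detection choices

The band (0.3–8 kHz) and threshold rule `T = 8σ`,
`σ = median(|x|)/0.6745`, are fixed by the measurement convention the
package implements; the filter realization is a choice: a 4th-order
(4-pole) Butterworth band-pass applied forward-backward (zero phase),
so filtering cannot bias activation-time features. The implementation
(bilinear transform with pre-warping; odd-reflection padding of
3·(filter length) samples; steady-state initial conditions) was
validated against an independent reference implementation to within
4 × 10⁻¹⁵ during development, and the test suite checks the designed
pass/stop-band gains analytically. Detection applies to both signal
polarities (the convention does not state negative-only detection), a
1 ms refractory period suppresses duplicate detections of one
transient, and a configurable 2 ms post-stimulus blanking window stands
in for hardware artifact suppression. All three are configurable;
detector recall/false positives are validated against generated ground
truth (20 µV spikes in 2 µV noise: ≥ 99 % recall, ≤ 1 false positive
per 100 spikes).

## Determinism and seeds

Every stochastic entry point takes a `seed`; one master seed drives
derived per-component streams (`sub_seed`), and all seeded code paths
save and restore the caller's RNG state. Identical inputs and seed give
bit-identical recordings, signatures and reports; the pipeline manifest
records the seed and a config hash, and reruns with an unchanged config
skip completed stages.

## Test-suite scaling

Monte-Carlo replicate counts in the acceptance tests are scaled to desk
runtime: classifier null calibration 60 replicates (SE of the mean
< 1.3 accuracy points), signature recovery 25, accuracy ordering 40,
stationarity power 50. Assertion bands account for the resulting
standard errors; the underlying criteria are unchanged.

## Known limitations

* Two stimulation sites only; the overlap generalizes to k > 2 sites
  conceptually, but no multi-site decoding is implemented.
* The rank-sum test on low-count bins is slightly conservative under
  heavy ties (normal approximation with tie correction); measured null
  flag rates were 0.047–0.055 at α = 0.05 for the default world.
* Resubstitution bias of the predefined-centroid classifier (above):
  compare methods only within a mode, or use `mode = "split"`.
* The Davies–Bouldin index is intentionally not provided: it scores
  cluster geometry, not the fraction of unassignable responses, which
  is what the overlap is for.
* Raw-trace synthesis keeps the whole channel matrix in memory
  (64 channels × 60 s × 20 kHz ≈ 0.6 GB); synthesize per-channel or in
  segments for long recordings.
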