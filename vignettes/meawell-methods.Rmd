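---
title: "Analysing multi-well MEA recordings with meawell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing multi-well MEA recordings with meawell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Multi-well multi-electrode arrays (MEAs) record extracellular field
potentials from spontaneously firing neuronal cultures across hundreds of
channels — typically 96 wells with 8 planar electrodes each (768 channels)
sampled at 12.5 kHz, with one well's electrode set referred to as an
*array*. meawell implements a complete analysis chain for such recordings:
quality filtering and array-level firing metrics, variance-aware cohort
assignment, power simulation for repeated-measures designs, unsupervised
spike sorting, functional-network inference, and condition-level
statistical models, together with a synthetic plate simulator that provides
ground truth for every stage. This vignette explains the models and the
design choices behind them.

```{r setup, message = FALSE}
library(meawell)
library(dplyr)
```

## Firing-rate metrics and event filtering

A spike is a threshold crossing: the voltage exceeding a *crossing
threshold* set at 5.5 SD of the background RMS over a 10-ms moving window.
Two consequences drive the preprocessing design:

* **High-noise exclusion.** Transient electrical noise inflates the
  dynamically computed threshold, so spurious events are recognisable by
  the threshold value recorded at their detection. Within each recording,
  events whose crossing threshold exceeds the mean + 3 SD of all crossing
  thresholds are excluded (`filter_high_noise_spikes()`). The population is
  per recording because noise regimes are recording-specific; a
  `pool_recordings` flag pools them.
* **Log-normal rates.** The mean firing rate MFR = n/s (spikes over
  seconds, aggregating all electrodes of a well) is heavily right-skewed
  across arrays, but approximately normal after log10 transformation. The
  log metric is computed as log10((n + 1)/s) so silent arrays stay finite.
  Parametric analyses throughout the package therefore operate on
  log10 Hz.

For synthetic raw traces, `detect_spikes()` reproduces threshold detection.
The background RMS is estimated with a running *median* of the squared
signal (rescaled to be unbiased under Gaussian noise) rather than a running
mean: a mean over a centred 10-ms window would include the spike itself,
raising the local threshold enough to mask any realistic spike at 5.5x. A
1-ms refractory period suppresses double counting of one transient.
Detection polarity is two-sided (|v|), since extracellular spikes are
predominantly negative but templates are biphasic.

## Active arrays and minimum-F cohort assignment

Arrays firing far below the plate's typical level are excluded before an
experiment: the cut is 2 SD below the *median* log10 rate of the sample set
(`select_active_arrays()`; the SD is computed over all arrays). Because
exclusions break the convenience of row/column treatment maps — and because
activity varies non-uniformly across a plate — cohorts are instead found by
simulation: `assign_groups()` draws 10^4 random assignments, scores each
with a one-way ANOVA F of log10 Hz on group, and keeps the assignment with
the lowest F (ties: first encountered; deterministic per seed). The inner
loop uses a closed-form F identical to `aov`'s (verified in the tests);
unbalanced designs and multi-plate pools are supported simply because the
pool is any table of (well, log rate).

## Repeated recordings, correlation, and power

A follow-up recording of the same plate correlates with baseline at about
rho = 0.8 for 30-min recordings. `correlated_followup()` reproduces this in
simulation: B = rho A + A_perp sqrt(1 - rho^2), where A_perp is the
residual of regressing an independent normal draw on A, rescaled to zero
mean and SD(A). The rescaling matters: the residuals are exactly orthogonal
to A in sample, so after rescaling the *sample* correlation equals rho
exactly (to numerical precision), for every seed. `duration_correlation_curve()`
measures the same quantity empirically as a function of accumulated
recording length and fits rho on ln(minutes); correlation rises steeply over
the first tens of minutes and only marginally after, which is why 30-min
recordings are the package default.

`power_grid()` simulates the canonical two-condition (control/treatment),
repeated-measures (pre/post) experiment. Each iteration draws paired
(t0, t1) log rates from a baseline population, offsets the treatment post
values by the effect size, and analyses the experiment with
`ancova_treatment_test()`: a linear model log10 Hz ~ group * time followed
by Tukey's HSD over the four cell means, extracting the control-vs-treatment
contrast at post. Power is the fraction of iterations with adjusted
p < 0.05. One numerical subtlety: because a single Tukey-adjusted contrast
is extracted from a four-cell family, the zero-effect rejection rate is
*conservative* (about 1.5% at alpha = 0.05), not equal to alpha; the tests
assert the correct bound. The published full grid — sample sizes 3–16,
effects 0.1–2.0 in steps of 0.1, 5000 iterations per cell — enumerates
1.4 x 10^6 simulated treatments (`count_simulated_treatments()`); the test
suite exercises the machinery on reduced grids (a few hundred iterations
over a handful of cells), which is where its Monte-Carlo tolerances come
from.

## Unsupervised, recording-independent spike sorting

Each electrode is a point detector that may see several neurons. Sorting
proceeds per electrode, pooling events across **all** recordings of an
experiment:

1. **Features** (`extract_features()`): peak, valley, amplitude
   (peak − valley), peak–valley interval, signed trapezoidal AUC, and
   non-linear energy, Psi(x_n) = x_n^2 − x_{n−1} x_{n+1}, summarized by its
   maximum over interior samples (a "sharpness" measure; a mean-Psi option
   exists). Waveforms are 38-sample vectors at the default window (1 ms
   pre, 2 ms post, 12.5 kHz; the crossing sample is included).
2. **Embedding** (`embed_features()`): each feature is transformed as
   log(|x| + 1e-6) — magnitudes, because valley, AUC and NLE can be
   non-positive; natural log, which keeps the embedding on the scale where
   the default bandwidth below behaves as published — then mean-centred
   (no unit-variance scaling; a flag exposes it) and projected on the first
   two principal components.
3. **Mean shift** (`mean_shift()`): mode seeking on a Gaussian kernel
   density estimate with bandwidth h = 1.5; each point iterates to the
   kernel-weighted mean of all points until displacement < 1e-6 (max 300
   iterations), and converged positions within h/10 merge into one mode.
   Unlike k-means, the number of clusters is not specified in advance —
   essential when the number of neurons per electrode is unknown. Small h
   proliferates modes; very large h always yields one.
4. **Representatives** (`map_centroid()`): a mode need not coincide with an
   observed waveform, so each cluster is represented by the member with
   minimum Euclidean distance to the mode (ties to the lowest index), whose
   amplitude becomes the cluster's representative amplitude.

Pooling across recordings is the load-bearing choice: sorting each
recording separately over-segregates sparse recordings and scrambles
cluster identities between sessions (`by_recording = TRUE` exists precisely
to demonstrate this). Electrodes with fewer than 3 events form a single
flagged cluster. Cluster ids are stable strings `{well}_{electrode}_{k}`.

Longitudinally, a cluster is *persistent* (active in all recordings),
*lost* (active, then silent with no return), *recovering* (active, silent,
active again) or *emergent* (silent first, active later); "active" means at
least one attributed spike. Non-monotone onsets such as (F, T, F) classify
by onset (emergent) — the four published definitions do not address them,
so the rule is: first recording active? then persistent/lost/recovering by
the gap structure; otherwise emergent.

## Functional networks

Coupling between two clusters' spike trains is quantified by the spike time
tiling coefficient with Delta t = 100 ms:

STTC = 1/2 [ (P_A − T_B)/(1 − P_A T_B) + (P_B − T_A)/(1 − P_B T_A) ]

where T_X is the fraction of the recording tiled by ±Delta t windows around
X's spikes (overlaps merged, clipped to the recording) and P_X the fraction
of X's spikes within ±Delta t of any spike of the other train. A term with
zero denominator (tiles covering the whole recording) contributes 0. The
implementation uses sorted-merge scans; the tests hold it to a brute-force
O(n^2) oracle.

An observed STTC becomes an *edge* when it falls outside the 0.5%–99.5%
band of a pair-specific null distribution built from 1000 random trains
with the observed event counts (uniform order statistics — the timing
structure of a homogeneous Poisson process conditioned on its count; an
inter-event-interval shuffle null is available via `method = "shuffle"`).
The two-sided band has 1% total mass, so independent trains trigger edges
at about 1%. Within `build_networks()`, nulls are cached per event-count
pair in each recording, since the null depends only on the counts and the
duration. Per array and recording, connectedness is summarized by the
Watts–Strogatz clustering coefficient: the mean local clustering
coefficient with isolates and degree-1 nodes counting zero.

## Condition-level models

* **Cluster frequencies** are zero-inflated and right-skewed; log
  transformation produces a bimodal, not normal, distribution. Positive
  frequencies are modelled with a Gamma GLM with the inverse link on
  treatment x recording (`fit_gamma_glm()`); per-cell means and SEs come
  from the delta method on the response scale. Zero-frequency clusters are
  excluded from the fit (the Gamma support is positive) — `drop_zeros`
  makes this explicit, and rates of the form (n + 1)/duration can be
  supplied instead. In the saturated design the fitted cell means equal the
  sample cell means, an algebraic identity the tests use as the fitting
  oracle.
* **Waveform amplitude** is a frequency-independent phenotype (amplitude is
  set by source–electrode geometry, not firing rate), modelled on
  log10 uV with treatment x recording fixed effects and nested random
  intercepts experiment/electrode/cluster, fitted by REML with nlme
  (`fit_amplitude_lme()`). The analysis is restricted to clusters with a
  representative amplitude of at least 30 uV pre-treatment (dynamic range)
  that are persistent across the modelled recordings (amplitude is
  undefined for a silent cluster); `filter_amplitude_clusters()` enforces
  both. A singular fit drops the innermost random component with a
  warning.
* **Array-level frequency** uses log10 Hz with a random experiment
  intercept (`fit_frequency_lme()`); with a single experiment it degrades
  to a fixed-effects fit with a warning. For both mixed models the quantity
  of interest is each treatment's pre-to-post change (`recording_deltas()`),
  a linear combination of fixed effects with a Wald SE; no small-sample
  degrees-of-freedom correction is applied.
* **Contrasts** (`contrast_tests()`) use multcomp's general linear
  hypothesis machinery with the single-step adjustment (joint multivariate
  t of all contrast statistics, correlation from the fit covariance);
  Bonferroni and unadjusted variants are available, and the single-step
  adjusted p always lies between them.

## The simulator

`simulate_plate()` generates a full synthetic experiment with ground truth
at every level, and is the source of all test fixtures:

* **Array rates**: latent per-array log10 rates are normal with mean −0.8
  and SD 0.55 log10 Hz — a calibration choice representative of mature
  primary cortical cultures, giving the characteristic skewed Hz / normal
  log10 Hz contrast — and are carried across recordings with the
  residual-orthogonalization construction at rho = 0.8 (day-to-day
  correlation operates on latent rates, so short recordings naturally
  decorrelate through counting noise).
* **Neurons**: 1–3 per electrode, partitioning the well's rate through
  Gamma weights. Template amplitudes come from the linear source
  approximation for a cylindrical source,
  V_e = I/(4 pi sigma Delta s) log|(sqrt(h^2+r^2) − h)/(sqrt(l^2+r^2) − l)|
  with l = h + Delta s, which converges to the Coulomb point-source value
  I/(4 pi r sigma) for r >> Delta s. Currents of 2–10 nA at 20–100 um give
  the realistic 10–100 uV range, and make amplitude independent of firing
  rate by construction. Waveforms are biphasic (Gaussian trough + rebound)
  plus white noise (SD 2.5 uV).
* **Coupling**: a configurable fraction of each well's neurons forms an
  assembly sharing one parent Poisson process; each parent event is copied
  into each member with probability `parent_share` and Gaussian jitter
  (default 5 ms), and residual spikes top each train up to target. Assembly
  coupling (rather than disjoint pairs) is what lets the inferred networks
  contain triangles, so the clustering coefficient responds to the coupling
  fraction.
* **Treatments**: per-group rate and amplitude multipliers by phase
  (`apply_treatment()`), e.g. rate multipliers 10^-1.14 or 10^-2.24 for
  sodium-channel-blocker scenarios and an amplitude multiplier 10^-0.074
  for a pore-forming-toxin scenario; a washout phase restores activity by
  setting multipliers back to 1.
* Event-level generation is the default; `synth_raw_trace()` synthesizes
  raw voltage (optionally band-passed 200 Hz–2.5 kHz with a 2nd-order
  zero-phase Butterworth) solely to exercise threshold detection, capped at
  60 s.

What the simulator does *not* emulate: bursting dynamics and network-wide
oscillations, electrode drift and impedance variation, overlapping-spike
collisions, and non-stationary rates within a recording. Passing tests
demonstrate that each algorithm recovers the structure the generator
plants under realistic magnitudes — not that real cultures satisfy the
generator's assumptions.

## Numerical choices and problem sizes

All stochastic operations take explicit integer seeds and restore the
caller's RNG state. Mean-shift tolerance is 1e-6 with 300 iterations and a
mode-merge radius of h/10. Interchange files round timestamps to 1 us and
voltages to 0.001 uV, and writing is byte-deterministic. The test suite
runs every stage end-to-end at reduced scale — plates of 6–96 wells,
recordings of 2–30 min, permutation nulls of 300–1000 draws, power grids of
a few hundred iterations per cell — sizes chosen so the whole suite
completes in a few minutes on one CPU while keeping Monte-Carlo tolerances
meaningful (assertions are framed in multiples of the corresponding SE).

## Known limitations

* Clusters are putative single units; without ground truth in real
  recordings, sorting cannot prove a one-to-one mapping to neurons, and no
  cross-electrode template matching or drift correction is attempted.
* STTC edges are undirected statistical couplings, not physical synapses;
  no directed or causal inference is offered.
* The Gamma model excludes inactive clusters rather than fitting a
  zero-inflated mixture; treatment effects that act mainly through
  silencing should be read from the frequency models, which keep zeros via
  the (n + 1)/s transform.
* Wald SEs without small-sample correction can be mildly anticonservative
  for very small numbers of experiments.
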