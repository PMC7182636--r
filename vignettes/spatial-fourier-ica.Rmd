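---
title: "Spatial Fourier ICA: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial Fourier ICA: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Ongoing EEG recorded under a continuous naturalistic stimulus (here: a piece
of music) mixes stimulus-driven cortical oscillations with spontaneous
activity and sensor noise at low SNR. `fourierica` decomposes such recordings
into *spatial-spectral* components: patterns that live jointly over cortical
source points and frequency bins, with a complex temporal weight per 1-s
analysis window.

The chain is:

1. **Conditioning.** Common-average reference; zero-phase Butterworth
   notch/band-pass filtering with decimation; a differentiate /
   median-filter / reintegrate repair for occasional DC jumps.
2. **Time-frequency tensor.** A short-time Fourier transform with 3-s Hamming
   windows on an exact 1-s hop grid gives a complex tensor
   (channels x frequencies x seconds). The 1-30 Hz band is retained.
3. **Source projection.** A depth-weighted minimum-norm inverse
   `G = R L' (L R L' + lambda^2 c I)^{-1}` maps every time-frequency slice to
   `Ns` source points (`R_vv = ||L[,v]||^{-2 gamma}`,
   `c = trace(L R L')/Nc` so `lambda^2` is unit-free).
4. **Unfolding and complex ICA.** The source tensor is unfolded to
   `X0 (Nt x Nf*Ns)`, one row per second, columns source-major. Rows are
   mean-centered, whitened by complex PCA to a chosen model order, and
   unmixed by complex FastICA (contrast `G(u) = sqrt(eps + u)` on
   `u = |w^H z|^2`, symmetric decorrelation). The result is
   `X0 ~ A S`: rows of `S` are unit-variance spatial-spectral patterns;
   column moduli of `A` are the components' Fourier amplitude envelopes at
   1 Hz.
5. **Stability (ICASSO).** FastICA is repeated under random initial
   conditions; pooled components are clustered by the absolute Pearson
   correlation of their *magnitudes* (phase is indeterminate in complex ICA)
   with average linkage, and each cluster is scored by
   `Iq = mean intra-cluster similarity - mean similarity to non-members`.
   Decompositions with `Iq > 0.7` are treated as stable; cluster
   representatives are centrotypes.
6. **Stimulus screening.** Each component envelope is correlated with five
   1-Hz musical feature series (fluctuation centroid and entropy, key
   clarity, mode, pulse clarity). The familywise threshold is the
   `1 - alpha` quantile of the max-|r| statistic over surrogate draws in
   which each feature series is circularly shifted (preserving its
   autocorrelation) against white-noise component series.
7. **Group clustering.** Retained components' spatial power maps are
   z-scored and pooled across subjects, k-means-partitioned with
   deterministic Kaufman seeding, the cluster count chosen by an MDL
   criterion, and clusters spanning fewer than half the subjects discarded.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| STFT frame / overlap | 3 / 2 | s | 1-s hop matches the 1-Hz feature series; 3 s approximates auditory sensory memory |
| FFT length | 512 | samples | 0.5-Hz bins at 256 Hz; 256 positive bins |
| Analysis band | 1-30 | Hz | informative EEG band for this paradigm; 60 bins |
| `lambda2` | 0.1 | - | ridge level after trace normalization; unit-free |
| `depthGamma` | 0.8 | - | standard depth-weighting exponent; 0 disables |
| ICA order | 20 | components | slightly above the expected source count |
| ICASSO runs | 100 | - | stability estimate; tests use 20 at reduced scale |
| `Iq` threshold | 0.7 | - | stability call for a component cluster |
| `alpha` | 0.05 | - | familywise level of the max-statistic test |
| surrogates | 1000 | draws | Monte-Carlo resolution of the threshold |
| retention fraction | 1/2 | subjects | a cluster must span at least half the study |

## The synthetic generator

`simulateSubject()` plants networks with a compact Gaussian spatial profile
on a 1-D source ring, a narrowband carrier, and an amplitude envelope
`e(t) = max(0, baseline + coupling * feature(t) + noise)` driven by a
standardized AR(1) feature series at 1 Hz. Sources mix to sensors through a
smooth random lead field (rank-preserving circular Gaussian smoothing of
i.i.d. topographies) plus white sensor noise. `simulateStudy()` shares one
feature set and the three network locations/carriers (10, 20, 2 Hz) across
subjects while lead fields, phases, and noise differ per subject.

Choices worth knowing:

* **Envelope baseline (default 2).** Fourier amplitude envelopes are
  nonnegative, hence the rectification; the baseline keeps clipping rare so
  the envelope remains linearly related to the driving feature
  (correlation near 1 at low noise). With baseline 0 the rectification
  alone caps that correlation near 0.86 for a Gaussian feature.
* **Feature smoothness** `rho = 0.9` at 1 Hz emulates slowly varying
  musical features.
* **Generator levels** (coupling 1, envelope noise 0.2, sensor noise 0.2)
  put the planted networks at SNR >= 1, the regime the recovery suite is
  defined for.

What the generator does **not** emulate: anatomical head geometry (the ring
lead field preserves only ill-posedness and neighbour correlation), ocular
and muscular artifacts, non-stationary background rhythms, and volume
conduction idiosyncrasies. Passing the recovery suite therefore shows the
algorithmic chain is correct and well-calibrated, not that real-data
performance is guaranteed.

## Numerical and design decisions

* **768-vs-512 frame mismatch.** A 3-s frame at 256 Hz holds 768 samples but
  the transform is 512-point. The windowed frame is truncated to its central
  512 samples, preserving the 0.5-Hz bin spacing and the 3-s/2-s framing.
  Zero-padding a 512-sample window was rejected because it changes the
  effective analysis length.
* **Edge handling.** Recordings are reflect-padded by half a frame so a
  D-second record yields exactly D windows; identically for audio framing.
* **Band selection.** Bins with `lo - df <= f <= hi` are kept: one guard bin
  below the nominal edge, so the conventional 1-30 Hz request at 0.5-Hz
  spacing yields 60 bins (0.5 ... 30 Hz).
* **Fluctuation centroid.** Implemented as the amplitude-weighted mean
  frequency (spectral centroid) of the 0-10 Hz fluctuation spectrum; the
  sub-band envelopes are demeaned before the transform so the DC pedestal
  does not mask the rhythm peak. Zero spectra return centroid 0 and entropy
  0 by convention.
* **Chromagram / key profiles.** FFT energy pooled to the nearest
  equal-tempered semitone over C2-B6 (A440), correlated with the 24
  Krumhansl-Kessler profiles; key clarity is the maximum correlation, mode
  the best-major minus best-minor contrast.
* **Onset strength** is the half-wave-rectified first difference of
  log-compressed sub-band envelopes with a floor relative to the frame
  maximum, making all five features exactly invariant to global gain.
* **Fixed source orientation.** One scalar per source point; the loose
  orientation constraint is not implemented (flag reserved).
* **Contrast and convergence.** `G(u) = sqrt(0.1 + u)`; symmetric (parallel)
  decorrelation rather than deflation, for order-20 stability and ICASSO
  compatibility; convergence when `1 - min diag |W_new W_old^H| < 1e-6`.
* **Iq conventions.** Similarity is |Pearson| of magnitudes (not squared
  sources); the external mean runs over all non-members; singleton
  intra-similarity is 1. Note `Iq = 1` exactly requires zero inter-cluster
  correlation; on finite data duplicated runs give intra-similarity exactly
  1 and `Iq = 1 - O(1/sqrt(m))`.
* **MDL order search** runs over `m <= floor(N/2)`: beyond that, centroids
  can copy single maps, distortion reaches zero, and the code length
  degenerates. The maps are projected to their top
  `min(N - 1, 50)`-dimensional principal subspace first, since the raw map
  dimension would swamp the penalty term.
* **Retention rule.** `ceil(nSubjects/2)` distinct subjects, consistent with
  keeping a 7-of-14 cluster. For a single-subject study the rule keeps its
  clusters (1 >= ceil(1/2)); group analysis expects at least two subjects.
* **Surrogate scheme.** Circular shifts of the feature series (offset >= 10
  samples) against white-noise component series, max-|r| over the whole
  comparison family. This calibrates the familywise error exactly when
  component series are serially uncorrelated under the null; strongly
  autocorrelated component envelopes inflate retention beyond the nominal
  level, which is visible in the recovery suite as liberal per-subject
  retention. The group stage's majority-subject rule is the backstop
  against such false positives.

## Problem sizes used by the validation suite

The recovery suite runs at a reduced scale chosen to exercise every stage
faithfully: a 200-source single-subject stability analysis (order 10, 20
ICASSO runs), a 200-subject null calibration of the familywise threshold,
and a 14-subject study on a 500-source ring at order 10 with 20 runs (512-s
recordings at 64 Hz, whose Nyquist rate comfortably contains the 1-30 Hz
band). The configuration arithmetic of the full-scale design (256 Hz,
512-point FFT) is checked directly on white noise.

## Known limitations

* The lead-field generator is a 1-D ring; no realistic geometry, no
  bad-channel interpolation, no artifact ICA (recordings are assumed clean
  or synthetic).
* Model order is fixed by configuration, not estimated.
* Per-subject ICA only; group spatial ICA (temporal concatenation) is out
  of scope.
* The surrogate threshold is calibrated for serially uncorrelated component
  series, as noted above.
* EDF and HDF5 ingestion are not provided; recordings enter as in-memory
  matrices or CSV, features as CSV, results as CSV/JSON.
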