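# fourierica

Frequency-specific cortical networks from ongoing EEG under a continuous
naturalistic stimulus.

When people listen to real music rather than repeated abstract stimuli, the
stimulus-driven part of the EEG is buried in spontaneous activity at low SNR,
and the networks of interest are *frequency-specific*: a pattern over
cortical space **and** over the 1–30 Hz spectrum, waxing and waning with the
music. `fourierica` implements the full data-driven workflow for finding
such networks:

* **Spatial Fourier ICA.** The preprocessed recording `Y0` (Nc × Np) is
  transformed to a complex STFT tensor (3-s Hamming windows, 1-s hop,
  512-point FFT), projected to `Ns` cortical source points by a
  depth-weighted minimum-norm inverse `Ŷ2 = G Ŷ1` with
  `G = R Lᵀ (L R Lᵀ + λ²cI)⁻¹`, and unfolded into `X0 (Nt × Nf·Ns)`.
  Complex PCA plus complex FastICA factor `X0 ≈ Â Ŝ`: rows of `Ŝ` are
  spatial–spectral patterns, column moduli of `Â` are the components'
  amplitude envelopes at 1 Hz.
* **Stability.** Repeated FastICA under random initial conditions
  (ICASSO), clustered on the magnitude correlation of components; cluster
  quality index `Iq = S̄ᵢₙₜ − S̄ₑₓₜ`, with `Iq > 0.7` called stable.
* **Stimulus screening.** Component envelopes are correlated with five
  long-term musical features at 1 Hz (fluctuation centroid, fluctuation
  entropy, key clarity, mode, pulse clarity — extractable from WAV audio by
  the package); significance by a Monte-Carlo max-statistic threshold over
  circularly shifted surrogates (familywise α = 0.05).
* **Group clustering.** Retained components' z-scored spatial maps are
  pooled across subjects, clustered by Kaufman-seeded k-means with an MDL
  cluster count, and clusters spanning fewer than half the subjects are
  discarded.
* **Synthetic ground truth.** A generator plants frequency-specific
  networks (compact spatial profile, narrowband carrier, feature-driven
  envelope) behind a smooth random lead field, so every stage can be
  validated by parameter recovery without any data download.

See `vignettes/spatial-fourier-ica.Rmd` for the model, parameter defaults,
and the design decisions.

## Worked example

Simulate one subject with two planted networks (10 Hz and 20 Hz, driven by
different musical features), run the per-subject workflow, and inspect the
recovery:

```r
library(fourierica)

nets <- list(
  plantedNetwork(centerSource = 30, spatialSd = 5, carrierFreq = 10,
                 featureName = "FluctuationCentroid"),
  plantedNetwork(75, 5, 20, "KeyClarity"))
scen <- scenario(nChannels = 16, nSources = 100, duration = 128, fs = 64,
                 networks = nets, sensorNoiseSd = 0.2, seed = 42)
sub <- simulateSubject(scen)
sub$recording
#> EEGRecording: 16 channels x 8192 samples @ 64 Hz ( 128 s )

cfg <- pipelineConfig(preprocess = list(enabled = FALSE),
                      stft = list(nfft = 128L),
                      ica = list(order = 6L, runs = 10L),
                      stats = list(seed = 7, nSurrogates = 1000L))
res <- runSubject(sub$recording, sub$leadfield, sub$features, cfg, subject = 1)

res$report
#> StabilityReport: 10 runs, 6 clusters; Iq range [ 0.954 , 0.971 ]
round(stabilityIndex(res$report), 3)
#> [1] 0.971 0.969 0.966 0.961 0.956 0.954
res$screen
#> CorrelationResult: 6 components x 5 features; |r| threshold 0.2781 ; 13 pairs retained
```

Every `Iq` is far above the 0.7 stability call, so the decomposition is
reproducible across random restarts. Matching components to the planted
truth:

```r
best <- which.max(sapply(res$summaries,
  function(s) cor(s$power, sub$truth[[1]]$weights^2)))
cat(sprintf("component %d: spectral peak %.1f Hz, map-truth r = %.2f, envelope r = %.2f\n",
  best, res$summaries[[best]]$peakFreq,
  cor(res$summaries[[best]]$power, sub$truth[[1]]$weights^2),
  cor(res$summaries[[best]]$timecourse, sub$truth[[1]]$envelope)))
#> component 2: spectral peak 10.5 Hz, map-truth r = 0.93, envelope r = 0.90
```

The 10-Hz planted network is recovered as one component whose spectrum peaks
within half a bin of the carrier, whose spatial power map correlates 0.93
with the planted profile, and whose envelope tracks the realized ground-truth
envelope at r = 0.90. With several subjects, `runGroup()` pools the retained
components and returns the kept spatial clusters with per-feature subject
counts.

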