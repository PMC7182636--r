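# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

# small two-network subject: 16 channels, 100 sources, 128 s at 64 Hz
smallSubject <- function() cached("smallSubject", function() {
  nets <- list(
    plantedNetwork(30, 5, 10, "FluctuationCentroid"),
    plantedNetwork(75, 5, 20, "KeyClarity"))
  scen <- scenario(16, 100, 128, 64, networks = nets,
    sensorNoiseSd = 0.2, seed = 42)
  sim <- simulateSubject(scen)
  inv <- computeInverseOperator(sim$leadfield)
  tfr <- selectBand(stftEEG(rereferenceCommonAverage(sim$recording), nfft = 128L))
  design <- buildDesignMatrix(projectTFR(tfr, inv))
  list(sim = sim, design = design, scen = scen)
})

# small FastICA fit of the cached subject at order 6
smallFit <- function() cached("smallFit", function() {
  fourierICA(smallSubject()$design, order = 6L, seed = 3L)
})

# complex random matrix helper
complexMatrix <- function(n, m, seed = 1) {
  set.seed(seed)
  matrix(complex(real = stats::rnorm(n * m), imaginary = stats::rnorm(n * m)), n, m)
}

# fraction of a component row's energy on a planted (sources x freq) support
supportEnergyFraction <- function(sRow, nf, ns, sourceIdx, freqIdx) {
  mat <- matrix(Mod(sRow)^2, nf, ns)
  sum(mat[freqIdx, sourceIdx]) / sum(mat)
}
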