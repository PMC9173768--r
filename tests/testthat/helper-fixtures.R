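# Shared fixtures, built in code at test time.

# small library: 4 fingerprints + molecules, fast order-3 systems
tinyLibrary <- function(seed = 7) {
  makeFingerprintLibrary(
    defaultFingerprintConfig(families = c(CO = 2L, DI = 1L, DN = 1L)),
    seed = seed)
}

# mid-size library matching the default fraction-field components
fieldLibrary <- function(seed = 11) {
  makeFingerprintLibrary(
    defaultFingerprintConfig(families = c(CO = 5L, DI = 1L, DN = 1L)),
    seed = seed)
}

# random normalized linear weights over the library fingerprints
randomWeights <- function(library, seed) {
  nm <- fingerprintNames(library)
  w <- cocrystalDS:::.withSeed(seed, stats::runif(length(nm), 0.05, 1))
  stats::setNames(w / sum(w), nm)
}

# design-space estimates taken directly from a fraction field (no
# spectra involved); conditions are placed at cell centers
fieldEstimates <- function(field, spec = GranulatorSpec(),
                           Ts = c(308.2, 328.6, 349, 369.4, 389.8),
                           Ms = seq(0.025, 0.975, by = 0.05),
                           tau = 2) {
  est <- list()
  for (T in Ts) for (M in Ms) {
    t <- M * spec@L / (spec@psi * tau * spec@f)
    est[[length(est) + 1L]] <- list(
      condition = ProcessCondition(T, tau, t),
      weights = WeightSet(fieldWeights(field, T, M)))
  }
  est
}
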