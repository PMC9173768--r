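test_that("default library has 21 fingerprints plus two molecule spectra", {
  lib <- makeFingerprintLibrary(seed = 1)
  expect_setequal(fingerprintNames(lib),
                  c(paste0("CO-", 1:9), paste0("DI-", 1:3), paste0("DN-", 1:9)))
  expect_length(basisSpectra(lib), 23L)
  expect_length(intensities(lib@moleculeA), 1000L)
})

test_that("library generation is deterministic given the seed", {
  a <- makeFingerprintLibrary(seed = 42)
  b <- makeFingerprintLibrary(seed = 42)
  expect_identical(lapply(basisSpectra(a), intensities),
                   lapply(basisSpectra(b), intensities))
  c2 <- makeFingerprintLibrary(seed = 43)
  expect_false(identical(intensities(basisSpectra(a)[["CO-1"]]),
                         intensities(basisSpectra(c2)[["CO-1"]])))
})

test_that("every library spectrum is exactly min-max normalized", {
  lib <- makeFingerprintLibrary(seed = 3)
  for (s in basisSpectra(lib)) {
    expect_identical(min(intensities(s)), 0)
    expect_identical(max(intensities(s)), 1)
  }
})

test_that("diagnostic marker bands are where they should be", {
  for (seed in c(1, 2, 5)) {
    lib <- makeFingerprintLibrary(seed = seed)
    co5 <- basisSpectra(lib)[["CO-5"]]
    peak5 <- wavenumbers(co5)[which.max(intensities(co5))]
    expect_gte(peak5, 2000); expect_lte(peak5, 2500)
    co2 <- basisSpectra(lib)[["CO-2"]]
    peak2 <- wavenumbers(co2)[which.max(intensities(co2))]
    expect_gte(peak2, 700); expect_lte(peak2, 1200)
  }
})

test_that("invalid configurations are rejected", {
  bad <- defaultFingerprintConfig()
  names(bad$families)[1] <- "XX"
  expect_error(makeFingerprintLibrary(bad), class = "configError")
  bad2 <- defaultFingerprintConfig(markers = c("CO-5" = 9000))
  expect_error(makeFingerprintLibrary(bad2), class = "configError")
})

test_that("mixture synthesis reduces to the basis in the identity case", {
  lib <- tinyLibrary()
  one <- CoefficientSet(linear = c("CO-1" = 1))
  m <- synthesizeMixture(lib, one, noiseSd = 0, seed = 1)
  expect_equal(intensities(m), intensities(basisSpectra(lib)[["CO-1"]]),
               tolerance = 1e-12)
  # all-zero coefficients give a constant zero signal
  expect_error(synthesizeMixture(lib, CoefficientSet(), noiseSd = 0),
               class = "degenerateSpectrum")
  expect_error(
    synthesizeMixture(lib, CoefficientSet(linear = c(nope = 1))),
    class = "nameError")
})

test_that("mixture synthesis is seeded and noise is reproducible", {
  lib <- tinyLibrary()
  coef <- CoefficientSet(linear = randomWeights(lib, 5))
  m1 <- synthesizeMixture(lib, coef, noiseSd = 0.02, seed = 9)
  m2 <- synthesizeMixture(lib, coef, noiseSd = 0.02, seed = 9)
  m3 <- synthesizeMixture(lib, coef, noiseSd = 0.02, seed = 10)
  expect_identical(intensities(m1), intensities(m2))
  expect_false(identical(intensities(m1), intensities(m3)))
})

test_that("library bundle round-trips through a directory", {
  lib <- tinyLibrary()
  d <- withr::local_tempdir()
  writeFingerprintLibrary(lib, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  lib2 <- readFingerprintLibrary(d)
  expect_identical(fingerprintNames(lib2), fingerprintNames(lib))
  for (nm in names(basisSpectra(lib)))
    expect_equal(intensities(basisSpectra(lib2)[[nm]]),
                 intensities(basisSpectra(lib)[[nm]]), tolerance = 1e-10)
})

test_that("viscosity tables cover the default conditions and are monotone", {
  tab <- makeViscosityTable(noiseRel = 0)
  expect_setequal(unique(tab$T_K), c(298, 325, 350, 375, 400))
  expect_equal(unname(table(tab$T_K)), rep(6L, 5L), ignore_attr = TRUE)
  for (T in unique(tab$T_K)) {
    sub <- tab[tab$T_K == T, ]
    sub <- sub[order(sub$shear), ]
    expect_true(all(diff(sub$viscosity_cP) < 0))  # pseudoplastic
  }
  # seeded noise reproducibility
  n1 <- makeViscosityTable(noiseRel = 0.05, seed = 4)
  n2 <- makeViscosityTable(noiseRel = 0.05, seed = 4)
  expect_identical(n1$viscosity_cP, n2$viscosity_cP)
  expect_error(makeViscosityTable(shearRates = c(1, -1)),
               class = "domainError")
})
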