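test_that("probe spectra round-trip to fractions through the control path", {
  lib <- fieldLibrary()
  wtrue <- randomWeights(lib, 2)
  R <- synthesizeMixture(lib, CoefficientSet(linear = wtrue),
                         noiseSd = 0, seed = 3)
  est <- estimateFractions(R, lib)
  expect_false(est@noiseOnly)
  # noise-robust truncation trades <1% bias for stability
  expect_lt(max(abs(weights(est) - wtrue)), 0.01)
  # exact recovery at the tight cutoff
  est2 <- estimateFractions(R, lib, rtol = 1e-10)
  expect_lt(max(abs(weights(est2) - wtrue)), 1e-6)
})

test_that("pure molecule signal is flagged as noise-only", {
  lib <- tinyLibrary()
  est <- estimateFractions(basisSpectra(lib)[["A"]], lib)
  expect_true(est@noiseOnly)
  expect_true(all(is.na(weights(est))))
})

test_that("averaged probe spectra yield intermediate weights", {
  lib <- tinyLibrary()
  w1 <- c("CO-1" = 0.8, "CO-2" = 0.2)
  w2 <- c("CO-1" = 0.2, "CO-2" = 0.8)
  R1 <- synthesizeMixture(lib, CoefficientSet(linear = w1), seed = 1)
  R2 <- synthesizeMixture(lib, CoefficientSet(linear = w2), seed = 1)
  avg <- RamanSpectrum(wavenumbers(R1),
                       (intensities(R1) + intensities(R2)) / 2, "avg")
  wa <- weights(estimateFractions(avg, lib, rtol = 1e-10))
  e1 <- weights(estimateFractions(R1, lib, rtol = 1e-10))
  e2 <- weights(estimateFractions(R2, lib, rtol = 1e-10))
  for (nm in c("CO-1", "CO-2")) {
    expect_gte(wa[[nm]], min(e1[[nm]], e2[[nm]]) - 1e-6)
    expect_lte(wa[[nm]], max(e1[[nm]], e2[[nm]]) + 1e-6)
  }
})

test_that("recommendations steer toward the optimum window and respect bounds", {
  field <- defaultFractionField()
  sp <- buildDesignSpace(fieldEstimates(field), GranulatorSpec())
  opt <- findOptimum(sp, c("CO-5", "CO-2"))
  frak <- WeightSet(fieldWeights(field, 298, 0.1))
  # below the window in both axes: recommendation raises T and M
  low <- ControllerState(temperature = 298, speed = 20, shear = 2,
                         target = c("CO-5", "CO-2"))
  rec <- recommendMove(low, frak, sp)
  expect_identical(rec@action, "adjust")
  expect_gt(rec@deltaT, 0)
  expect_lt(rec@deltaSpeed, 0)        # slower screws -> larger M
  expect_gt(stateM(applyRecommendation(low, rec)), stateM(low))
  # inside the window: hold, and hold is a fixed point
  inside <- ControllerState(
    temperature = (opt$TLo + opt$THi) / 2, speed = 2 / mean(c(opt$MLo, opt$MHi)),
    shear = 2, target = c("CO-5", "CO-2"))
  recIn <- recommendMove(inside, frak, sp)
  expect_identical(recIn@action, "hold")
  expect_identical(applyRecommendation(inside, recIn), inside)
  # unknown target fingerprint
  badState <- ControllerState(300, 20, 2, target = "ZZ-9")
  expect_error(recommendMove(badState, frak, sp),
               class = "unknownFingerprint")
  # bounds are never left
  nearMax <- ControllerState(399, 20, 2, target = c("CO-5", "CO-2"),
                             bounds = c(TMin = 298, TMax = 400,
                                        speedMin = 19.9, speedMax = 100))
  recB <- recommendMove(nearMax, frak, sp)
  stB <- applyRecommendation(nearMax, recB)
  expect_lte(stB@temperature, 400)
  expect_gte(stB@speed, 19.9)
})

test_that("zero step sizes freeze the closed loop", {
  field <- defaultFractionField()
  lib <- fieldLibrary()
  sp <- buildDesignSpace(fieldEstimates(field), GranulatorSpec())
  st <- ControllerState(300, 20, 2, target = c("CO-5", "CO-2"))
  lg <- runClosedLoop(field, lib, sp, st, steps = 3, noiseSd = 0,
                      seed = 1, stepT = 0, stepSpeedFrac = 0)
  expect_true(all(lg$T == 300))
  expect_true(all(lg$speed == 20))
})

test_that("the closed loop converges into the optimum window and holds", {
  field <- defaultFractionField()
  lib <- fieldLibrary()
  sp <- buildDesignSpace(fieldEstimates(field), GranulatorSpec())
  opt <- findOptimum(sp, c("CO-5", "CO-2"))
  st <- ControllerState(300, 20, 2, target = c("CO-5", "CO-2"))
  lg <- runClosedLoop(field, lib, sp, st, steps = 40, noiseSd = 0.01,
                      seed = 1)
  final <- lg[nrow(lg), ]
  expect_gte(final$T, opt$TLo); expect_lte(final$T, opt$THi)
  expect_gte(final$M, opt$MLo); expect_lte(final$M, opt$MHi)
  expect_true(all(utils::tail(lg$action, 5) == "hold"))
  # determinism of the trajectory
  lg2 <- runClosedLoop(field, lib, sp, st, steps = 40, noiseSd = 0.01,
                       seed = 1)
  expect_identical(lg, lg2)
})
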