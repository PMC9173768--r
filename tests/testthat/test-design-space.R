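test_that("gauge parameter M follows psi * t * tau * f / L", {
  spec <- GranulatorSpec(L = 1, f = 0.01, psi = 1)
  expect_equal(computeM(ProcessCondition(345, shear = 2, time = 50), spec), 1.0)
  expect_equal(computeM(ProcessCondition(345, shear = 2, time = 0), spec), 0)
  expect_equal(GranulatorSpec()@psi, 1)
  # strictly increasing in t, tau, f; decreasing in L
  base <- computeM(ProcessCondition(345, 1, 10), spec)
  expect_gt(computeM(ProcessCondition(345, 2, 10), spec), base)
  expect_gt(computeM(ProcessCondition(345, 1, 20), spec), base)
  expect_gt(computeM(ProcessCondition(345, 1, 10), GranulatorSpec(f = 0.02)),
            base)
  expect_lt(computeM(ProcessCondition(345, 1, 10), GranulatorSpec(L = 2)),
            base)
  expect_warning(M <- computeM(ProcessCondition(345, 10, 100), spec,
                               clamp = TRUE))
  expect_equal(M, 1)
})

test_that("design-space cells aggregate weight sets by arithmetic mean", {
  spec <- GranulatorSpec()
  cond <- ProcessCondition(345, shear = 2, time = 25)   # M = 0.5
  w1 <- WeightSet(c(F1 = 0.4, F2 = 0.6))
  w2 <- WeightSet(c(F1 = 0.6, F2 = 0.4))
  one <- buildDesignSpace(list(list(condition = cond, weights = w1)), spec)
  expect_equal(sum(one@counts), 1L)
  cell <- one@fractions[["F1"]][one@counts > 0]
  expect_equal(cell, 0.4)
  two <- buildDesignSpace(list(list(condition = cond, weights = w1),
                               list(condition = cond, weights = w2)), spec)
  expect_equal(two@fractions[["F1"]][two@counts > 0], 0.5)
  expect_equal(two@fractions[["F2"]][two@counts > 0], 0.5)
  expect_error(buildDesignSpace(list(), spec), class = "emptyInput")
  expect_error(buildDesignSpace(list(list(condition = cond, weights = w1)),
                                spec, TBins = 1L), class = "binningError")
})

test_that("cells conserve the unit mass of their weight sets", {
  spec <- GranulatorSpec()
  field <- defaultFractionField()
  sp <- buildDesignSpace(fieldEstimates(field), spec)
  total <- Reduce(`+`, sp@fractions)
  expect_true(all(abs(total[sp@counts > 0] - 1) < 1e-9))
  expect_true(all(is.na(total[sp@counts == 0])))
})

test_that("near-zero fractions are flagged blank, distinct from unvisited", {
  spec <- GranulatorSpec()
  cond <- ProcessCondition(345, 2, 25)
  w <- WeightSet(c(F1 = 0.9999999, F2 = 1e-7))
  sp <- buildDesignSpace(list(list(condition = cond, weights = w)), spec)
  bm <- blankMask(sp, "F2")
  expect_identical(sum(bm), 1L)              # the one near-zero cell
  expect_identical(sum(blankMask(sp, "F1")), 0L)
  expect_true(all(!bm[sp@counts == 0L]))     # unvisited cells are not blank
})

test_that("the optimum window recovers the encoded field maximum", {
  field <- defaultFractionField()
  sp <- buildDesignSpace(fieldEstimates(field), GranulatorSpec())
  opt <- findOptimum(sp, c("CO-5", "CO-2"))
  enc <- field@optimum
  # returned window overlaps the encoded 340-350 K, 0.4-0.55 M box
  expect_lt(opt$TLo, enc[2]); expect_gt(opt$THi, enc[1])
  expect_lt(opt$MLo, enc[4]); expect_gt(opt$MHi, enc[3])
  expect_error(findOptimum(sp, "XX-1"), class = "unknownFingerprint")
})

test_that("ties break toward lowest temperature, then lowest M", {
  spec <- GranulatorSpec()
  est <- fieldEstimates(defaultFractionField(), spec)
  flat <- lapply(est, function(e)
    list(condition = e$condition, weights = WeightSet(c(F1 = 0.5, F2 = 0.5))))
  sp <- buildDesignSpace(flat, spec)
  opt <- findOptimum(sp, "F1")
  expect_identical(unname(opt$cell), c(1L, 1L))
  expect_equal(opt$TLo, 298)
  expect_equal(opt$MLo, 0)
  # single occupied cell: that cell is the window
  one <- buildDesignSpace(list(list(condition = ProcessCondition(345, 2, 25),
                                    weights = WeightSet(c(F1 = 1)))), spec)
  o1 <- findOptimum(one, "F1")
  expect_identical(unname(o1$cell), unname(which(one@counts > 0, arr.ind = TRUE)[1, ]))
})

test_that("lookup interpolates bilinearly and flags missing neighbours", {
  spec <- GranulatorSpec()
  mk <- function(T, M, f1) list(
    condition = ProcessCondition(T, 2, M * spec@L / (2 * spec@f)),
    weights = WeightSet(c(F1 = f1, F2 = 1 - f1)))
  sp <- buildDesignSpace(list(mk(308.2, 0.125, 0.2), mk(308.2, 0.175, 0.4)),
                         spec)
  # exact cell center returns the stored value
  at <- lookupFractions(sp, 308.2, 0.125)
  expect_equal(at$fractions[["F1"]], 0.2)
  # midway between two occupied cells: the average
  mid <- lookupFractions(sp, 308.2, 0.15)
  expect_equal(mid$fractions[["F1"]], 0.3)
  expect_false(at$incomplete)
  # neighbour missing -> incomplete flag, renormalized over occupied
  edge <- lookupFractions(sp, 320, 0.125)
  expect_true(edge$incomplete)
  expect_equal(edge$fractions[["F1"]], 0.2)
  expect_error(lookupFractions(sp, 500, 0.5), class = "outOfBounds")
})

test_that("screw speed inversion is the algebraic inverse of M", {
  spec <- GranulatorSpec(L = 1, f = 0.01)
  tauPerSpeed <- 0.5
  speed0 <- 12
  tau <- tauPerSpeed * speed0
  t <- 30
  M <- computeM(ProcessCondition(345, tau, t), spec)
  expect_equal(screwSpeedForM(M, spec, t, tauPerSpeed), speed0,
               tolerance = 1e-9)
  expect_equal(screwSpeedForM(0, spec, t, tauPerSpeed), 0)
  # doubling f halves the speed needed for the same M, t
  spec2 <- GranulatorSpec(L = 1, f = 0.02)
  expect_equal(screwSpeedForM(M, spec2, t, tauPerSpeed),
               speed0 / 2, tolerance = 1e-9)
  expect_error(screwSpeedForM(M, spec, 0, tauPerSpeed), class = "domainError")
})

test_that("design spaces round-trip through the directory format", {
  sp <- buildDesignSpace(fieldEstimates(defaultFractionField()),
                         GranulatorSpec(), provenance = "fixture")
  d <- withr::local_tempdir()
  writeDesignSpace(sp, d)
  sp2 <- readDesignSpace(d)
  expect_equal(sp2@TBreaks, sp@TBreaks)
  expect_equal(sp2@fractions[["CO-5"]], sp@fractions[["CO-5"]],
               tolerance = 1e-10)
  expect_identical(sp2@counts, sp@counts)
})
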