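# brute-force oracle for the number of unique monomials of degree d in
# P variables: enumerate all index tuples and count distinct multisets
countMonomials <- function(P, d) {
  tuples <- as.matrix(do.call(expand.grid, rep(list(seq_len(P)), d)))
  keys <- apply(tuples, 1L, function(r) paste(sort(r), collapse = "-"))
  length(unique(keys))
}

test_that("design-matrix column counts match brute-force enumeration", {
  lib <- tinyLibrary()        # P = 6 basis spectra
  sub2 <- subsetFingerprintLibrary(lib, fingerprintNames(lib)[1])
  # P = 3 here (A, B + 1 fingerprint): still exercises all orders
  for (ord in 1:3) {
    rho <- buildDesignMatrix(sub2, ord)
    P <- 3L
    expected <- 1L + sum(vapply(seq_len(ord), countMonomials, integer(1), P = P))
    expect_identical(ncol(rho), expected)
  }
  # the spec'd small case: P = 2 would give 1+2+3+4 = 10 at order 3;
  # verify the closed form against the enumeration oracle
  expect_identical(1L + countMonomials(2, 1) + countMonomials(2, 2) +
                     countMonomials(2, 3), 10L)
  rho3 <- buildDesignMatrix(lib, 3)
  P <- 6L
  expect_identical(ncol(rho3),
                   1L + P + (P * (P + 1L)) %/% 2L +
                     (P * (P + 1L) * (P + 2L)) %/% 6L)
})

test_that("product columns are elementwise products of basis spectra", {
  lib <- tinyLibrary()
  rho <- buildDesignMatrix(lib, 2)
  basis <- basisSpectra(lib)
  key <- paste("CO-1", "DI-1", sep = "|")
  expect_equal(rho[, key],
               intensities(basis[["CO-1"]]) * intensities(basis[["DI-1"]]),
               ignore_attr = TRUE)
  expect_equal(rho[, "(const)"], rep(1, 1000), ignore_attr = TRUE)
})

test_that("pseudoinverse solves consistent systems exactly", {
  lib <- tinyLibrary()
  rho <- buildDesignMatrix(lib, 2)
  set.seed(1)
  a0 <- rnorm(ncol(rho), sd = 0.3)
  y <- as.numeric(rho %*% a0)
  coef <- solveCoefficients(rho, y)
  yhat <- rho %*% cocrystalDS:::.coefVector(coef, attr(rho, "index"))
  expect_lt(sqrt(sum((yhat - y)^2)) / sqrt(sum(y^2)), 1e-8)
})

test_that("rank-deficient systems return the minimum-norm solution", {
  lib <- tinyLibrary()
  rho <- buildDesignMatrix(lib, 1)
  # duplicate a fingerprint column -> exactly singular
  rho2 <- cbind(rho, dup = rho[, "CO-1"])
  attr(rho2, "index") <- c(attr(rho, "index"), list("CO-1dup"))
  y <- rho[, "CO-1"]
  sv <- svd(rho2)
  keep <- sv$d > 1e-10 * max(sv$d)
  aMin <- sv$v[, keep] %*% (crossprod(sv$u[, keep], y) / sv$d[keep])
  expect_silent(coef <- solveCoefficients(rho2, y))
  a <- cocrystalDS:::.coefVector(coef, attr(rho, "index"))
  # the duplicated pair splits the weight equally (minimum-norm signature)
  expect_equal(coef@linear[["CO-1"]], 0.5, tolerance = 1e-8)
  expect_error(solveCoefficients(rho, y[1:10]), class = "shapeError")
})

test_that("pseudoinverse agrees with independent oracles when well-posed", {
  lib <- tinyLibrary()
  sub <- subsetFingerprintLibrary(lib, fingerprintNames(lib)[1:3])
  rho <- buildDesignMatrix(sub, 2)   # P = 5, 21 columns
  set.seed(2)
  for (rep in 1:5) {
    y <- as.numeric(rho %*% rnorm(ncol(rho))) + rnorm(nrow(rho), sd = 0.01)
    coef <- solveCoefficients(rho, y)
    a <- cocrystalDS:::.coefVector(coef, attr(rho, "index"))
    aNE <- solve(crossprod(rho), crossprod(rho, y))   # normal equations
    expect_equal(a, as.numeric(aNE), tolerance = 1e-8, ignore_attr = TRUE)
  }
  skip_if_not_installed("MASS")
  aG <- MASS::ginv(rho) %*% y
  coefLast <- solveCoefficients(rho, y)
  expect_equal(cocrystalDS:::.coefVector(coefLast, attr(rho, "index")),
               as.numeric(aG), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("intuitive weights normalize over fingerprints only", {
  cs <- CoefficientSet(linear = c(A = 0.2, B = 0.1, F1 = 0.3, F2 = 0.6))
  w <- extractWeights(cs)
  expect_equal(weights(w), c(F1 = 1 / 3, F2 = 2 / 3))
  expect_equal(sum(weights(w)), 1, tolerance = 1e-12)
  expect_equal(w@noiseShare, c(A = 0.2, B = 0.1))
  expect_error(
    extractWeights(CoefficientSet(linear = c(A = 1, B = 1, F1 = 0))),
    class = "zeroDenominator")
  # negative weights reported as-is; clipped on request
  cs2 <- CoefficientSet(linear = c(F1 = 0.8, F2 = -0.2, F3 = 0.4))
  expect_equal(sum(weights(extractWeights(cs2))), 1, tolerance = 1e-12)
  wc <- extractWeights(cs2, clip = TRUE)
  expect_true(all(weights(wc) >= 0))
  expect_equal(sum(weights(wc)), 1, tolerance = 1e-12)
})

test_that("noiseless linear mixtures are recovered exactly", {
  lib <- makeFingerprintLibrary(seed = 1)
  sub <- subsetFingerprintLibrary(
    lib, c("CO-1", "CO-2", "CO-5", "DI-1", "DN-1", "DN-3"))
  for (seed in 1:3) {
    wtrue <- randomWeights(sub, seed)
    R <- synthesizeMixture(sub, CoefficientSet(linear = wtrue),
                           noiseSd = 0, seed = seed)
    fit <- unmix(sub, R, order = 3)
    expect_lt(max(abs(weights(fit) - wtrue)), 1e-6)
    expect_equal(sum(weights(fit)), 1, tolerance = 1e-9)
    expect_lt(relativeError(fit), 1e-6)
  }
})

test_that("relative error decreases with kernel order (nesting)", {
  lib <- tinyLibrary()
  coef <- CoefficientSet(
    linear = c(randomWeights(lib, 3), A = 0.1, B = 0.1),
    pairwise = c("CO-1|CO-2" = 0.2, "A|DI-1" = 0.1))
  R <- synthesizeMixture(lib, coef, noiseSd = 0.005, seed = 8)
  e <- vapply(1:3, function(o) relativeError(unmix(lib, R, order = o)),
              numeric(1))
  expect_lte(e[2], e[1] + 1e-10)
  expect_lte(e[3], e[2] + 1e-10)
})

test_that("restricted-range unmixing finds the band-dominant fingerprint", {
  lib <- makeFingerprintLibrary(seed = 1)
  sub <- subsetFingerprintLibrary(
    lib, c("CO-1", "CO-2", "CO-5", "DI-1", "DN-1", "DN-3"))
  # CO-2 carries the marker inside 700-1200; make it dominant there
  wmix <- c("CO-2" = 0.5, "CO-1" = 0.2, "CO-5" = 0.2, "DI-1" = 0.1)
  R <- synthesizeMixture(sub, CoefficientSet(linear = wmix),
                         noiseSd = 0, seed = 4)
  fit <- unmix(sub, R, order = 3, range = c(700, 1200))
  w <- weights(fit)
  expect_identical(names(which.max(w)), "CO-2")
})

test_that("molecule-only spectra carry no fingerprint weight", {
  lib <- tinyLibrary()
  RA <- basisSpectra(lib)[["A"]]
  expect_error(unmix(lib, RA, order = 2), class = "zeroDenominator")
})
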