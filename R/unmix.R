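#' @include library.R
NULL

#' Build the polynomial (Volterra) design matrix
#'
#' Each row is one wavenumber; columns are the constant 1, the P basis
#' spectra (molecules A and B plus the N fingerprints), the unique
#' pairwise elementwise products r_i * r_j (i <= j) and, at order 3, the
#' unique triple products r_i * r_j * r_k (i <= j <= k).  Duplicated
#' index orderings are collapsed to one canonical column each: they span
#' the same model space and only worsen conditioning.  Column counts are
#' therefore 1 + P + P(P+1)/2 [+ P(P+1)(P+2)/6].
#'
#' @param library a [FingerprintLibrary-class] (all spectra normalized
#'   on one shared grid).
#' @param order polynomial order, 1, 2 or 3.
#' @return numeric matrix with named columns; attribute `"index"` holds
#'   the list of name tuples (character(0) for the constant column).
#' @export
buildDesignMatrix <- function(library, order = 3L) {
  if (!order %in% 1:3) .stopc("domainError", "order must be 1, 2 or 3")
  basis <- basisSpectra(library)
  n <- length(gridWavenumbers(library@grid))
  for (s in basis)
    if (length(s@intensities) != n)
      .stopc("gridMismatch", "basis spectrum '%s' not on the shared grid",
             s@label)
  B <- vapply(basis, function(s) s@intensities, numeric(n))
  P <- ncol(B)
  nms <- colnames(B)

  cols <- list(rep(1, n))
  index <- list(character(0))
  for (i in seq_len(P)) {
    cols[[length(cols) + 1L]] <- B[, i]
    index[[length(index) + 1L]] <- nms[i]
  }
  if (order >= 2L) {
    for (i in seq_len(P)) for (j in i:P) {
      cols[[length(cols) + 1L]] <- B[, i] * B[, j]
      index[[length(index) + 1L]] <- c(nms[i], nms[j])
    }
  }
  if (order >= 3L) {
    for (i in seq_len(P)) for (j in i:P) {
      bij <- B[, i] * B[, j]
      for (k in j:P) {
        cols[[length(cols) + 1L]] <- bij * B[, k]
        index[[length(index) + 1L]] <- c(nms[i], nms[j], nms[k])
      }
    }
  }
  rho <- do.call(cbind, cols)
  colnames(rho) <- vapply(index, function(t)
    if (!length(t)) "(const)" else paste(t, collapse = "|"), character(1))
  attr(rho, "index") <- index
  rho
}

#' Solve for the kernel coefficients by pseudoinverse least squares
#'
#' Computes the minimum-norm least-squares solution of R = rho A via the
#' Moore-Penrose pseudoinverse (SVD with a relative small-singular-value
#' cutoff, default 1e-10).  Never fails on rank deficiency: singular and
#' underdetermined systems return the minimum-norm solution.
#'
#' @param rho design matrix from [buildDesignMatrix()].
#' @param R a normalized [RamanSpectrum-class] (or numeric vector) with
#'   as many points as `rho` has rows.
#' @param rtol relative cutoff for small singular values.
#' @return a [CoefficientSet-class]; attributes `"rank"` and
#'   `"condition"` report the numerical rank and the ratio of the
#'   largest to the smallest retained singular value.
#' @export
solveCoefficients <- function(rho, R, rtol = 1e-10) {
  y <- if (is(R, "RamanSpectrum")) R@intensities else as.numeric(R)
  if (length(y) != nrow(rho))
    .stopc("shapeError", "R has %d points but rho has %d rows",
           length(y), nrow(rho))
  sv <- svd(rho)
  keep <- sv$d > rtol * max(sv$d)
  a <- sv$v[, keep, drop = FALSE] %*%
    (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep])
  a <- as.numeric(a)

  index <- attr(rho, "index")
  ord <- lengths(index)
  key <- colnames(rho)
  cs <- CoefficientSet(
    constant = if (any(ord == 0L)) a[ord == 0L][1] else 0,
    linear = stats::setNames(a[ord == 1L], key[ord == 1L]),
    pairwise = stats::setNames(a[ord == 2L], key[ord == 2L]),
    triple = stats::setNames(a[ord == 3L], key[ord == 3L]))
  attr(cs, "rank") <- sum(keep)
  attr(cs, "condition") <- max(sv$d) / min(sv$d[keep])
  cs
}

#' Extract intuitive fingerprint weights from linear coefficients
#'
#' a'_i = a_i / (sum over all linear coefficients - a_A - a_B), i.e. the
#' linear coefficient of each fingerprint normalized over fingerprints
#' only; the isolated-molecule contributions are removed and treated as
#' noise.  Weights may be negative and are reported as-is unless `clip`
#' is TRUE, in which case negatives are clipped to zero and the rest
#' renormalized (useful for controller robustness).
#'
#' @param coefficients a [CoefficientSet-class] with at least one
#'   fingerprint linear coefficient.
#' @param clip clip negative weights and renormalize (default FALSE).
#' @return a [WeightSet-class]; weights sum to 1.
#' @export
extractWeights <- function(coefficients, clip = FALSE) {
  lin <- coefficients@linear
  fp <- setdiff(names(lin), c("A", "B"))
  if (!length(fp)) .stopc("missingDescriptor", "no fingerprint linear coefficients")
  den <- sum(lin[fp])
  if (abs(den) < 1e-12)
    .stopc("zeroDenominator",
           "fingerprint linear coefficients sum to ~0 (|sum| = %.3g)", abs(den))
  w <- lin[fp] / den
  if (clip) {
    w[w < 0] <- 0
    s <- sum(w)
    if (s < 1e-12) .stopc("zeroDenominator", "all weights clipped to zero")
    w <- w / s
  }
  WeightSet(w, noiseShare = c(A = if ("A" %in% names(lin)) lin[["A"]] else 0,
                              B = if ("B" %in% names(lin)) lin[["B"]] else 0))
}

#' Unmix a mixture spectrum into fingerprint weights
#'
#' The full kernel pipeline: optionally restrict both the library and
#' the measured spectrum to a wavenumber band (each restricted spectrum
#' is re-normalized, matching the convention that every dataset is
#' min-max normalized), build the polynomial design matrix, solve by
#' pseudoinverse, and extract the intuitive weights.
#'
#' With the full default library at order 3 the system is
#' underdetermined (more columns than grid points); the minimum-norm
#' solution is still returned and `rank` reported, but weight
#' identifiability then rests on the spectral distinctness of the
#' basis.
#'
#' @param library a [FingerprintLibrary-class].
#' @param R mixture spectrum on the library grid (normalized; it is
#'   normalized on entry if not already).
#' @param order polynomial order (default 3).
#' @param range optional c(lo, hi) wavenumber band, cm^-1.
#' @param clip passed to [extractWeights()].
#' @param rtol passed to [solveCoefficients()].
#' @return a [FitResult-class].
#' @examples
#' lib <- makeFingerprintLibrary(defaultFingerprintConfig(
#'   families = c(CO = 2L, DI = 1L, DN = 1L)), seed = 7)
#' coef <- CoefficientSet(linear = c("CO-1" = 0.7, "CO-2" = 0.3))
#' fit <- unmix(lib, synthesizeMixture(lib, coef, seed = 2))
#' round(weights(fit), 3)
#' @export
unmix <- function(library, R, order = 3L, range = NULL, clip = FALSE,
                  rtol = 1e-10) {
  if (!is.null(range)) {
    stopifnot(length(range) == 2L)
    restrictLib <- function(s)
      normalizeSpectrum(restrictRange(s, range[1], range[2]))
    library <- new("FingerprintLibrary",
      grid = {
        w <- gridWavenumbers(library@grid)
        keep <- w >= range[1] & w <= range[2]
        if (sum(keep) < 2L)
          .stopc("emptyRange", "fewer than 2 grid points in the range")
        SpectralGrid(min(w[keep]), max(w[keep]), sum(keep))
      },
      moleculeA = restrictLib(library@moleculeA),
      moleculeB = restrictLib(library@moleculeB),
      fingerprints = lapply(library@fingerprints, restrictLib),
      seed = library@seed)
    R <- normalizeSpectrum(restrictRange(R, range[1], range[2]))
  }
  gw <- gridWavenumbers(library@grid)
  if (length(R@wavenumbers) != length(gw) ||
      max(abs(R@wavenumbers - gw)) > 1e-6)
    .stopc("gridMismatch", "R is not sampled on the library grid")
  if (!isNormalized(R)) R <- normalizeSpectrum(R)

  rho <- buildDesignMatrix(library, order)
  coef <- solveCoefficients(rho, R, rtol = rtol)
  a <- .coefVector(coef, attr(rho, "index"))
  yhat <- as.numeric(rho %*% a)
  relErr <- 100 * sqrt(sum((R@intensities - yhat)^2)) /
    sqrt(sum(R@intensities^2))
  wts <- extractWeights(coef, clip = clip)
  new("FitResult", coefficients = coef, weights = wts,
      reconstruction = RamanSpectrum(gw, yhat, "reconstruction"),
      relativeError = relErr, rank = attr(coef, "rank"),
      conditionEstimate = attr(coef, "condition"))
}

## coefficient vector in design-matrix column order
.coefVector <- function(coef, index) {
  vapply(index, function(t) {
    if (!length(t)) return(coef@constant)
    key <- paste(t, collapse = "|")
    v <- slot(coef, c("linear", "pairwise", "triple")[length(t)])
    if (key %in% names(v)) v[[key]] else 0
  }, numeric(1))
}

#' @describeIn accessors fingerprint weights of a fit or weight set.
#' @export
setGeneric("weights")

#' @rdname accessors
#' @export
setMethod("weights", "WeightSet", function(object, ...) object@weights)

#' @rdname accessors
#' @export
setMethod("weights", "FitResult", function(object, ...) object@weights@weights)

#' @describeIn accessors fitted coefficients of a fit result.
#' @export
setGeneric("coefficients")

#' @rdname accessors
#' @export
setMethod("coefficients", "FitResult", function(object, ...) object@coefficients)

#' Relative reconstruction error of a fit, percent
#' @param fit a [FitResult-class].
#' @export
relativeError <- function(fit) fit@relativeError

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: relative error %.4g%%, rank %d, condition %.3g\n",
              object@relativeError, object@rank, object@conditionEstimate))
  if (object@weights@noiseOnly) {
    cat("  noise-only signal (isolated molecules); no fingerprint weights\n")
  } else {
    w <- sort(object@weights@weights, decreasing = TRUE)
    top <- utils::head(w, 5L)
    cat("  top weights:",
        paste(sprintf("%s=%.3f", names(top), top), collapse = " "), "\n")
  }
})

setMethod("show", "WeightSet", function(object) {
  if (object@noiseOnly) {
    cat("WeightSet: noise-only (isolated-molecule signal)\n")
  } else {
    w <- object@weights
    cat("WeightSet:", paste(sprintf("%s=%.3f", names(w), w), collapse = " "),
        "\n")
  }
})
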