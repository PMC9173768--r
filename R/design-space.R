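#' @include fraction-field.R
NULL

#' Gauge parameter M of a process condition
#'
#' M = psi * t * tau * f / L: the dimensionless group combining
#' residence/trajectory time t, shear rate tau, screw lead f, the
#' correction factor psi (default 1) and granulator length L.  It is
#' dimensionless when tau carries inverse-time units, and collapses the
#' (tau, t) pair onto one axis of the design space.
#'
#' @param cond a [ProcessCondition-class].
#' @param spec a [GranulatorSpec-class].
#' @param clamp clamp the result to `[0, 1]` (with a warning) for
#'   design-space lookup.
#' @return numeric M >= 0.
#' @examples
#' computeM(ProcessCondition(345, shear = 2, time = 50),
#'          GranulatorSpec(L = 1, f = 0.01))  # 1
#' @export
computeM <- function(cond, spec, clamp = FALSE) {
  if (spec@L <= 0 || spec@f <= 0)
    .stopc("domainError", "L and f must be positive")
  M <- spec@psi * cond@time * cond@shear * spec@f / spec@L
  if (clamp && (M < 0 || M > 1)) {
    warning(sprintf("M = %.3g clamped to [0, 1]", M))
    M <- min(max(M, 0), 1)
  }
  M
}

#' Build a design space from per-condition weight estimates
#'
#' Maps each (condition, weights) estimate to a (T, M) cell -- M via
#' [computeM()], clamped into `[0, 1]` -- and stores the arithmetic mean
#' of the contributing weight sets per cell.  Cells with no estimate are
#' NA ("not computed"), which is distinct from a true near-zero
#' fraction; see [blankMask()] for the < 1e-5 "blank" convention.
#'
#' @param estimates list of `list(condition = ProcessCondition,
#'   weights = WeightSet)`.
#' @param spec a [GranulatorSpec-class].
#' @param TBins,MBins number of cells per axis (>= 2).  Defaults: 5
#'   temperature bins spanning the 298-400 K operating range (matching
#'   the five simulated temperatures) and 20 M bins on `[0, 1]`.
#' @param TRange,MRange axis ranges.
#' @param provenance free-text id recorded in the result.
#' @return a [DesignSpace-class].
#' @export
buildDesignSpace <- function(estimates, spec = GranulatorSpec(),
                             TBins = 5L, MBins = 20L,
                             TRange = c(298, 400), MRange = c(0, 1),
                             provenance = "estimates") {
  if (!length(estimates)) .stopc("emptyInput", "no estimates supplied")
  if (TBins < 2L || MBins < 2L || diff(TRange) <= 0 || diff(MRange) <= 0)
    .stopc("binningError", "need >= 2 bins and non-degenerate axis ranges")

  TBreaks <- seq(TRange[1], TRange[2], length.out = TBins + 1L)
  MBreaks <- seq(MRange[1], MRange[2], length.out = MBins + 1L)

  allNames <- unique(unlist(lapply(estimates, function(e)
    names(e$weights@weights))))
  if (!length(allNames)) .stopc("emptyInput", "estimates carry no weights")

  sums <- lapply(allNames, function(nm) matrix(0, TBins, MBins))
  names(sums) <- allNames
  counts <- matrix(0L, TBins, MBins)

  for (e in estimates) {
    cond <- e$condition
    w <- e$weights@weights
    M <- computeM(cond, spec)
    if (M < MRange[1] || M > MRange[2]) {
      warning(sprintf("M = %.3g clamped into the M axis", M))
      M <- min(max(M, MRange[1]), MRange[2])
    }
    Tv <- min(max(cond@temperature, TRange[1]), TRange[2])
    i <- findInterval(Tv, TBreaks, rightmost.closed = TRUE, all.inside = TRUE)
    j <- findInterval(M, MBreaks, rightmost.closed = TRUE, all.inside = TRUE)
    counts[i, j] <- counts[i, j] + 1L
    for (nm in names(w)) sums[[nm]][i, j] <- sums[[nm]][i, j] + w[[nm]]
  }

  fr <- lapply(sums, function(m) {
    out <- m / counts
    out[counts == 0L] <- NA_real_
    out[!is.na(out) & out < 0 & out > -1e-9] <- 0  # round-off guard
    out
  })
  new("DesignSpace", TBreaks = TBreaks, MBreaks = MBreaks,
      TAxis = (TBreaks[-1] + TBreaks[-length(TBreaks)]) / 2,
      MAxis = (MBreaks[-1] + MBreaks[-length(MBreaks)]) / 2,
      fractions = fr, counts = counts, provenance = provenance)
}

#' @rdname accessors
#' @export
setMethod("fingerprintNames", "DesignSpace",
          function(object) names(object@fractions))

#' @describeIn accessors per-fingerprint fraction matrices of a design
#'   space.
#' @export
setMethod("fractions", "DesignSpace", function(object) object@fractions)

setMethod("show", "DesignSpace", function(object) {
  cat(sprintf("DesignSpace '%s': %d x %d cells (T %g-%g K, M %g-%g), %d/%d occupied\n",
              object@provenance, length(object@TAxis), length(object@MAxis),
              min(object@TBreaks), max(object@TBreaks),
              min(object@MBreaks), max(object@MBreaks),
              sum(object@counts > 0), length(object@counts)))
  cat("  fingerprints:", paste(fingerprintNames(object), collapse = " "), "\n")
})

#' Near-zero ("blank") cells of a design-space fraction map
#'
#' Occupied cells whose fraction is below 1e-5 are rendered blank in
#' fraction maps; this is a true near-zero value, distinct from the NA
#' of a never-visited cell.
#'
#' @param space a [DesignSpace-class].
#' @param name fingerprint name.
#' @param threshold blank threshold (default 1e-5).
#' @return logical matrix, TRUE where occupied and below threshold.
#' @export
blankMask <- function(space, name, threshold = 1e-5) {
  m <- space@fractions[[name]]
  if (is.null(m)) .stopc("unknownFingerprint", "unknown fingerprint '%s'", name)
  !is.na(m) & m < threshold
}

#' Locate the optimal operating window for target fingerprints
#'
#' Finds the occupied cell maximizing the summed fraction of the target
#' fingerprints; ties are broken toward the lowest temperature, then the
#' lowest M.  The returned window is that cell's bounds in axis units.
#'
#' @param space a [DesignSpace-class].
#' @param targets fingerprint names to maximize jointly.
#' @return list with TLo, THi, MLo, MHi, value (summed target fraction)
#'   and cell (row/col indices).
#' @export
findOptimum <- function(space, targets) {
  missing <- setdiff(targets, fingerprintNames(space))
  if (length(missing))
    .stopc("unknownFingerprint", "unknown target(s): %s",
           paste(missing, collapse = ", "))
  if (!any(space@counts > 0)) .stopc("emptySpace", "no occupied cells")
  S <- Reduce(`+`, space@fractions[targets])
  S[space@counts == 0L] <- -Inf
  best <- max(S)
  hits <- which(S == best, arr.ind = TRUE)
  ## tie-break: lowest T (row), then lowest M (col)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- hits[1, 1]; j <- hits[1, 2]
  list(TLo = space@TBreaks[i], THi = space@TBreaks[i + 1L],
       MLo = space@MBreaks[j], MHi = space@MBreaks[j + 1L],
       value = best, cell = c(row = unname(i), col = unname(j)))
}

#' Interpolate fingerprint fractions at a query point
#'
#' Bilinear interpolation between the four neighbouring cell centers;
#' unvisited (NA) neighbours are excluded and the remaining weights
#' renormalized, with `incomplete = TRUE` flagged in the result.
#' Queries outside the axis bounds raise `outOfBounds`.
#'
#' @param space a [DesignSpace-class].
#' @param temperature query T, K.
#' @param M query M.
#' @return list(fractions = named numeric, incomplete = logical).
#' @export
lookupFractions <- function(space, temperature, M) {
  if (temperature < min(space@TBreaks) || temperature > max(space@TBreaks) ||
      M < min(space@MBreaks) || M > max(space@MBreaks))
    .stopc("outOfBounds", "query (%.3g K, M = %.3g) outside the design space",
           temperature, M)
  ## clamp to the cell-center hull, then bracket
  Tq <- min(max(temperature, space@TAxis[1]), space@TAxis[length(space@TAxis)])
  Mq <- min(max(M, space@MAxis[1]), space@MAxis[length(space@MAxis)])
  bracket <- function(axis, x) {
    i <- max(which(axis <= x + 1e-12))
    i2 <- min(i + 1L, length(axis))
    t <- if (i2 == i) 0 else (x - axis[i]) / (axis[i2] - axis[i])
    list(i = i, i2 = i2, t = t)
  }
  bT <- bracket(space@TAxis, Tq); bM <- bracket(space@MAxis, Mq)
  cells <- rbind(c(bT$i, bM$i,  (1 - bT$t) * (1 - bM$t)),
                 c(bT$i, bM$i2, (1 - bT$t) * bM$t),
                 c(bT$i2, bM$i,  bT$t * (1 - bM$t)),
                 c(bT$i2, bM$i2, bT$t * bM$t))
  cells <- cells[cells[, 3] > 0, , drop = FALSE]
  occ <- apply(cells, 1L, function(r) space@counts[r[1], r[2]] > 0L)
  incomplete <- any(!occ)
  cells <- cells[occ, , drop = FALSE]
  nm <- fingerprintNames(space)
  if (!nrow(cells))
    return(list(fractions = stats::setNames(rep(NA_real_, length(nm)), nm),
                incomplete = TRUE))
  wsum <- sum(cells[, 3])
  out <- vapply(nm, function(f) {
    m <- space@fractions[[f]]
    sum(apply(cells, 1L, function(r) r[3] * m[r[1], r[2]])) / wsum
  }, numeric(1))
  list(fractions = out, incomplete = incomplete)
}

#' Screw speed delivering a target M
#'
#' Inverts [computeM()] for the shear rate at fixed residence time t,
#' then converts shear to screw speed through the user-supplied
#' proportionality `tauPerSpeed` (shear rate per unit rotation speed).
#'
#' @param M target gauge parameter (>= 0).
#' @param spec a [GranulatorSpec-class].
#' @param t residence time, s (> 0).
#' @param tauPerSpeed shear rate per rotation s^-1 (> 0).
#' @return screw speed, rotations s^-1.
#' @export
screwSpeedForM <- function(M, spec, t, tauPerSpeed) {
  if (M < 0) .stopc("domainError", "M must be >= 0")
  if (t <= 0) .stopc("domainError", "residence time t must be > 0")
  if (tauPerSpeed <= 0) .stopc("domainError", "tauPerSpeed must be > 0")
  tau <- M * spec@L / (spec@psi * t * spec@f)
  tau / tauPerSpeed
}

## ---------------------------------------------------------------------------
## Design-space serialization: a directory with axes.json + one CSV
## matrix per fingerprint.
## ---------------------------------------------------------------------------

#' Write / read a design space as a directory
#'
#' `axes.json` records breaks, counts and provenance; each fingerprint's
#' fraction matrix is one CSV (rows = T cells, columns = M cells, NA for
#' unvisited cells).
#'
#' @param space a [DesignSpace-class].
#' @param dir directory path.
#' @export
writeDesignSpace <- function(space, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(TBreaks = space@TBreaks, MBreaks = space@MBreaks,
         counts = space@counts, provenance = space@provenance,
         fingerprints = fingerprintNames(space)),
    file.path(dir, "axes.json"), auto_unbox = TRUE, digits = NA)
  for (nm in fingerprintNames(space))
    utils::write.csv(space@fractions[[nm]],
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeDesignSpace
#' @export
readDesignSpace <- function(dir) {
  ax <- jsonlite::read_json(file.path(dir, "axes.json"), simplifyVector = TRUE)
  fr <- lapply(ax$fingerprints, function(nm)
    as.matrix(utils::read.csv(file.path(dir, paste0(nm, ".csv")))))
  fr <- lapply(fr, function(m) { dimnames(m) <- NULL; m })
  names(fr) <- ax$fingerprints
  TBreaks <- ax$TBreaks; MBreaks <- ax$MBreaks
  new("DesignSpace", TBreaks = TBreaks, MBreaks = MBreaks,
      TAxis = (TBreaks[-1] + TBreaks[-length(TBreaks)]) / 2,
      MAxis = (MBreaks[-1] + MBreaks[-length(MBreaks)]) / 2,
      fractions = fr, counts = matrix(as.integer(ax$counts),
                                      nrow = length(TBreaks) - 1L),
      provenance = ax$provenance)
}
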