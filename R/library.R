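#' @include spectra.R
NULL

## Known fingerprint families: CO = drug-coformer cocrystal pairs,
## DI = drug (ibuprofen) dimers, DN = coformer (nicotinamide) dimers.
.FAMILIES <- c("CO", "DI", "DN")

#' Default configuration for the synthetic fingerprint library
#'
#' Describes the peak rules used to emulate computed fingerprint
#' spectra: each basis spectrum is a sum of Lorentzian lines, one strong
#' "marker" line at a spectrum-specific position plus a seeded handful
#' of weaker minor lines.  Marker positions are laid out evenly across
#' the grid so every basis spectrum is spectrally distinct (and the
#' unmixing problem identifiable); the `markers` entry pins chosen
#' fingerprints to fixed diagnostic bands - by default CO-5 to
#' 2250 cm^-1 (inside the 2000-2500 cm^-1 band where the cocrystal's
#' distinguishing peak appears) and CO-2 to 950 cm^-1 (inside the
#' 700-1200 cm^-1 band conventionally used for cocrystal monitoring).
#'
#' @param families named integer vector: number of fingerprints per
#'   family, names among "CO", "DI", "DN".
#' @param markers named numeric vector pinning specific fingerprint
#'   marker positions (cm^-1); entries for absent names are ignored.
#' @param nPeaks integer length 2: min/max number of minor lines.
#' @param width numeric length 2: HWHM range of lines, cm^-1.
#' @param minorAmplitude maximum amplitude of a minor line (marker
#'   amplitude is fixed at `markerAmplitude`, chosen so the marker is
#'   always the global maximum of its spectrum).
#' @param markerAmplitude amplitude of the marker line.
#' @return a list usable as `config` in [makeFingerprintLibrary()].
#' @export
defaultFingerprintConfig <- function(families = c(CO = 9L, DI = 3L, DN = 9L),
                                     markers = c("CO-5" = 2250, "CO-2" = 950),
                                     nPeaks = c(3L, 6L),
                                     width = c(8, 30),
                                     minorAmplitude = 0.4,
                                     markerAmplitude = 3) {
  list(families = families, markers = markers, nPeaks = nPeaks,
       width = width, minorAmplitude = minorAmplitude,
       markerAmplitude = markerAmplitude)
}

## Lorentzian line: amplitude at the center, HWHM g.
.lorentz <- function(w, center, g, amp) amp * g^2 / ((w - center)^2 + g^2)

.basisNames <- function(families) {
  fp <- unlist(lapply(names(families), function(fam)
    paste0(fam, "-", seq_len(families[[fam]]))), use.names = FALSE)
  c("A", "B", fp)
}

#' Generate a synthetic fingerprint library
#'
#' Builds the normalized basis spectra of the two isolated molecules and
#' all requested interaction fingerprints as seeded sums of Lorentzian
#' lines on the shared grid.  Deterministic: the same config and seed
#' always produce bit-identical libraries.
#'
#' @param config peak rules, see [defaultFingerprintConfig()].
#' @param seed integer RNG seed.
#' @param grid the shared [SpectralGrid-class].
#' @return a [FingerprintLibrary-class].
#' @examples
#' lib <- makeFingerprintLibrary(seed = 1)
#' length(fingerprintNames(lib))  # 21
#' @export
makeFingerprintLibrary <- function(config = defaultFingerprintConfig(),
                                   seed = 1L, grid = SpectralGrid()) {
  fam <- config$families
  if (is.null(names(fam)) || !all(names(fam) %in% .FAMILIES))
    .stopc("configError", "unknown fingerprint family; allowed: %s",
           paste(.FAMILIES, collapse = ", "))
  if (any(fam < 1L)) .stopc("configError", "family counts must be >= 1")
  nms <- .basisNames(fam)

  ## marker layout: evenly spaced across the interior of the grid, then
  ## pinned positions override their owners
  pad <- 0.03 * (grid@hi - grid@lo)
  centers <- stats::setNames(
    seq(grid@lo + pad, grid@hi - pad, length.out = length(nms)), nms)
  pins <- config$markers[names(config$markers) %in% nms]
  centers[names(pins)] <- pins
  if (any(centers <= grid@lo) || any(centers >= grid@hi))
    .stopc("configError", "marker peak center outside the grid")

  gw <- gridWavenumbers(grid)
  spectra <- .withSeed(seed, {
    lapply(nms, function(nm) {
      k <- sample(seq(config$nPeaks[1], config$nPeaks[2]), 1L)
      cen <- stats::runif(k, grid@lo + pad, grid@hi - pad)
      wid <- stats::runif(k, config$width[1], config$width[2])
      amp <- stats::runif(k, 0.1, config$minorAmplitude)
      y <- .lorentz(gw, centers[[nm]],
                    stats::runif(1, 10, 20), config$markerAmplitude)
      for (i in seq_len(k)) y <- y + .lorentz(gw, cen[i], wid[i], amp[i])
      normalizeSpectrum(RamanSpectrum(gw, y, nm))
    })
  })
  names(spectra) <- nms
  new("FingerprintLibrary", grid = grid, moleculeA = spectra[["A"]],
      moleculeB = spectra[["B"]],
      fingerprints = spectra[!(nms %in% c("A", "B"))],
      seed = as.integer(seed))
}

#' @rdname accessors
#' @export
setMethod("fingerprintNames", "FingerprintLibrary",
          function(object) names(object@fingerprints))

#' @describeIn accessors all basis spectra as a named list, molecules
#'   "A" and "B" first.
#' @export
setMethod("basisSpectra", "FingerprintLibrary", function(object) {
  c(list(A = object@moleculeA, B = object@moleculeB), object@fingerprints)
})

setMethod("show", "FingerprintLibrary", function(object) {
  nm <- fingerprintNames(object)
  cat(sprintf(paste0("FingerprintLibrary: molecules A, B + %d fingerprints",
                     " on %d-point grid [%.0f, %.0f] cm-1 (seed %s)\n"),
              length(nm), object@grid@nPoints, object@grid@lo,
              object@grid@hi, object@seed))
  cat(" ", paste(nm, collapse = " "), "\n")
})

#' Keep a subset of a library's fingerprints
#'
#' @param library a [FingerprintLibrary-class].
#' @param names fingerprint names to keep.
#' @export
subsetFingerprintLibrary <- function(library, names) {
  missing <- setdiff(names, fingerprintNames(library))
  if (length(missing))
    .stopc("unknownFingerprint", "unknown fingerprint(s): %s",
           paste(missing, collapse = ", "))
  new("FingerprintLibrary", grid = library@grid,
      moleculeA = library@moleculeA, moleculeB = library@moleculeB,
      fingerprints = library@fingerprints[names], seed = library@seed)
}

#' Synthesize a mixture spectrum from the polynomial forward model
#'
#' Evaluates the truncated Volterra combination of basis spectra -
#' constant + linear + pairwise + triple terms, plus any caller-supplied
#' fourth-order contamination terms in the coefficient set - adds
#' Gaussian intensity noise, and min-max normalizes the result.
#'
#' @param library a [FingerprintLibrary-class].
#' @param coefficients a [CoefficientSet-class]; names must be library
#'   fingerprints or "A"/"B".
#' @param noiseSd standard deviation of additive Gaussian noise on the
#'   (pre-normalization) intensities.  Basis spectra are in `[0, 1]`, so
#'   for weights summing to 1 a value of 0.01 is about 1% of full scale.
#' @param seed RNG seed; NULL draws from the current RNG stream.
#' @param label label for the returned spectrum.
#' @return a normalized [RamanSpectrum-class].
#' @export
synthesizeMixture <- function(library, coefficients, noiseSd = 0,
                              seed = 1L, label = "mixture") {
  stopifnot(noiseSd >= 0)
  basis <- basisSpectra(library)
  known <- names(basis)
  keyParts <- function(v) if (length(v))
    unlist(strsplit(names(v), "|", fixed = TRUE)) else character(0)
  allKeys <- c(names(coefficients@linear), keyParts(coefficients@pairwise),
               keyParts(coefficients@triple), keyParts(coefficients@quartic))
  bad <- setdiff(unique(allKeys), known)
  if (length(bad))
    .stopc("nameError", "unknown coefficient name(s): %s",
           paste(bad, collapse = ", "))

  n <- library@grid@nPoints
  y <- rep(coefficients@constant, n)
  for (nm in names(coefficients@linear))
    y <- y + coefficients@linear[[nm]] * basis[[nm]]@intensities
  prodTerm <- function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    Reduce(`*`, lapply(parts, function(p) basis[[p]]@intensities))
  }
  for (slotnm in c("pairwise", "triple", "quartic")) {
    v <- slot(coefficients, slotnm)
    for (key in names(v)) y <- y + v[[key]] * prodTerm(key)
  }
  y <- .withSeed(seed, y + stats::rnorm(n, 0, noiseSd))
  normalizeSpectrum(RamanSpectrum(gridWavenumbers(library@grid), y, label))
}

## ---------------------------------------------------------------------------
## Library bundle I/O: a directory with one CSV per basis spectrum and a
## JSON manifest recording names, families, the grid and the seed.
## ---------------------------------------------------------------------------

#' Write / read a fingerprint library as a directory bundle
#'
#' One CSV per basis spectrum (format of [writeSpectrumCSV()]) plus a
#' `manifest.json` naming the spectra and the grid.
#'
#' @param library a [FingerprintLibrary-class].
#' @param dir directory path (created if needed).
#' @return `writeFingerprintLibrary` returns `dir` invisibly;
#'   `readFingerprintLibrary` returns a [FingerprintLibrary-class].
#' @export
writeFingerprintLibrary <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  basis <- basisSpectra(library)
  files <- stats::setNames(paste0(names(basis), ".csv"), names(basis))
  for (nm in names(basis))
    writeSpectrumCSV(basis[[nm]], file.path(dir, files[[nm]]))
  manifest <- list(
    grid = list(lo = library@grid@lo, hi = library@grid@hi,
                nPoints = library@grid@nPoints),
    molecules = list(A = files[["A"]], B = files[["B"]]),
    fingerprints = as.list(files[fingerprintNames(library)]),
    seed = library@seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeFingerprintLibrary
#' @export
readFingerprintLibrary <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  grid <- SpectralGrid(mf$grid$lo, mf$grid$hi, mf$grid$nPoints)
  readOne <- function(f, nm) {
    s <- readSpectrumCSV(file.path(dir, f), label = nm)
    s  # spectra are stored normalized on the grid
  }
  fps <- mf$fingerprints
  new("FingerprintLibrary", grid = grid,
      moleculeA = readOne(mf$molecules$A, "A"),
      moleculeB = readOne(mf$molecules$B, "B"),
      fingerprints = stats::setNames(
        lapply(names(fps), function(nm) readOne(fps[[nm]], nm)), names(fps)),
      seed = if (is.null(mf$seed)) NA_integer_ else as.integer(mf$seed))
}
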