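#' @include AllGenerics.R
NULL

#' Wavenumber axis of a grid
#'
#' @param grid a [SpectralGrid-class].
#' @return numeric vector of length `nPoints`, uniformly spaced on
#'   `[lo, hi]`.
#' @export
gridWavenumbers <- function(grid) {
  seq(grid@lo, grid@hi, length.out = grid@nPoints)
}

#' @rdname accessors
#' @export
setMethod("wavenumbers", "RamanSpectrum", function(object) object@wavenumbers)

#' @rdname accessors
#' @export
setMethod("intensities", "RamanSpectrum", function(object) object@intensities)

#' @rdname accessors
#' @export
setMethod("spectrumLabel", "RamanSpectrum", function(object) object@label)

setMethod("show", "RamanSpectrum", function(object) {
  cat(sprintf("RamanSpectrum '%s': %d points, %.1f-%.1f cm-1, intensity [%.3g, %.3g]%s\n",
              object@label, length(object@wavenumbers),
              min(object@wavenumbers), max(object@wavenumbers),
              min(object@intensities), max(object@intensities),
              if (isNormalized(object)) " (normalized)" else ""))
})

setMethod("show", "SpectralGrid", function(object) {
  cat(sprintf("SpectralGrid: %d points on [%.1f, %.1f] cm-1 (spacing %.3f)\n",
              object@nPoints, object@lo, object@hi,
              (object@hi - object@lo) / (object@nPoints - 1L)))
})

#' Is a spectrum min-max normalized?
#'
#' TRUE when min(intensities) == 0 and max(intensities) == 1 exactly.
#' @param spectrum a [RamanSpectrum-class].
#' @export
isNormalized <- function(spectrum) {
  min(spectrum@intensities) == 0 && max(spectrum@intensities) == 1
}

#' @describeIn normalizeSpectrum Min-max normalization
#'   x-bar = (x - min) / (max - min), so intensities land in `[0, 1]`
#'   with the minimum at 0 and the maximum at 1.  Idempotent.  A constant
#'   spectrum has no defined normalization and raises a
#'   `degenerateSpectrum` error.
#' @export
setMethod("normalizeSpectrum", "RamanSpectrum", function(spectrum) {
  y <- spectrum@intensities
  r <- range(y)
  if (r[1] == r[2])
    .stopc("degenerateSpectrum",
           "cannot normalize a constant spectrum (max == min)")
  RamanSpectrum(spectrum@wavenumbers, (y - r[1]) / (r[2] - r[1]),
                spectrum@label)
})

#' @describeIn resampleSpectrum Linear interpolation onto the uniform
#'   grid.  The input must cover the full grid span; extrapolation is
#'   never performed (a `coverageError` is raised instead), so no
#'   intensity is ever fabricated outside the measured range.
#' @export
setMethod("resampleSpectrum", c("RamanSpectrum", "SpectralGrid"),
          function(spectrum, grid) {
  w <- spectrum@wavenumbers
  if (min(w) > grid@lo || max(w) < grid@hi)
    .stopc("coverageError",
           "input span [%.1f, %.1f] does not cover grid [%.1f, %.1f]",
           min(w), max(w), grid@lo, grid@hi)
  gw <- gridWavenumbers(grid)
  yi <- stats::approx(w, spectrum@intensities, xout = gw, method = "linear",
                      ties = "ordered")$y
  RamanSpectrum(gw, yi, spectrum@label)
})

#' @describeIn restrictRange Keep exactly the points with
#'   lo <= wavenumber <= hi, preserving order.  Raises `emptyRange` when
#'   fewer than 2 points survive.
#' @export
setMethod("restrictRange", "RamanSpectrum", function(spectrum, lo, hi) {
  if (!(lo < hi)) .stopc("domainError", "lo must be < hi")
  keep <- spectrum@wavenumbers >= lo & spectrum@wavenumbers <= hi
  if (sum(keep) < 2L)
    .stopc("emptyRange", "fewer than 2 grid points in [%g, %g]", lo, hi)
  RamanSpectrum(spectrum@wavenumbers[keep], spectrum@intensities[keep],
                spectrum@label)
})

## ---------------------------------------------------------------------------
## Spectrum CSV I/O: two columns `wavenumber_cm-1,intensity`, header row
## required, UTF-8.
## ---------------------------------------------------------------------------

#' Read / write a spectrum as CSV
#'
#' The on-disk format is two columns `wavenumber_cm-1,intensity` with a
#' header row.
#'
#' @param path file path.
#' @param label label for the returned spectrum (defaults to the file
#'   name without extension).
#' @return `readSpectrumCSV` returns a [RamanSpectrum-class];
#'   `writeSpectrumCSV` returns `path` invisibly.
#' @export
readSpectrumCSV <- function(path, label = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("wavenumber_cm-1", "intensity")
  if (!all(need %in% names(df)))
    .stopc("formatError", "expected columns %s in %s",
           paste(need, collapse = ","), path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  RamanSpectrum(df[["wavenumber_cm-1"]], df[["intensity"]], label)
}

#' @param spectrum a [RamanSpectrum-class] to write.
#' @rdname readSpectrumCSV
#' @export
writeSpectrumCSV <- function(spectrum, path) {
  df <- data.frame(a = spectrum@wavenumbers, b = spectrum@intensities)
  names(df) <- c("wavenumber_cm-1", "intensity")
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
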