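#' @include AllClasses.R
NULL

#' Accessors for spectral objects
#'
#' @param object a package object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("spectrumLabel", function(object) standardGeneric("spectrumLabel"))

#' @rdname accessors
#' @export
setGeneric("fingerprintNames", function(object) standardGeneric("fingerprintNames"))

#' @rdname accessors
#' @export
setGeneric("basisSpectra", function(object) standardGeneric("basisSpectra"))

#' @rdname accessors
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))

#' Min-max normalize a spectrum
#'
#' @param spectrum a [RamanSpectrum-class].
#' @return a normalized [RamanSpectrum-class].
#' @export
setGeneric("normalizeSpectrum", function(spectrum) standardGeneric("normalizeSpectrum"))

#' Resample a spectrum onto a uniform grid
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param grid a [SpectralGrid-class].
#' @export
setGeneric("resampleSpectrum",
           function(spectrum, grid) standardGeneric("resampleSpectrum"))

#' Restrict a spectrum to a wavenumber band
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param lo,hi band limits, cm^-1.
#' @export
setGeneric("restrictRange",
           function(spectrum, lo, hi) standardGeneric("restrictRange"))
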