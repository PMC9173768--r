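#' @include unmix.R
NULL

#' Construct a FractionField fixture
#'
#' @param components data.frame with columns name, baseline, height,
#'   TCenter, MCenter, TSigma, MSigma.  Each component's unnormalized
#'   intensity at (T, M) is
#'   baseline + height * exp(-(T-TCenter)^2/(2 TSigma^2)
#'                           - (M-MCenter)^2/(2 MSigma^2));
#'   normalizing across components gives the true weights.
#' @param optimum numeric c(TLo, THi, MLo, MHi): the window where the
#'   summed target fraction is maximal (recorded for recovery tests).
#' @param targets names of the target fingerprints.
#' @return a [FractionField-class].
#' @export
FractionField <- function(components, optimum, targets) {
  new("FractionField", components = components,
      optimum = as.numeric(optimum), targets = as.character(targets))
}

#' Default fraction-field fixture
#'
#' Emulates, qualitatively, the behaviours seen in computed fraction
#' maps: the two target cocrystal fingerprints (CO-2, CO-5) share a
#' unimodal maximum centered at 345 K and M = 0.475 (so the encoded
#' optimum window is 340-350 K, 0.4-0.55 M); one fingerprint peaks at
#' low T and M and decays (kinetically favoured early product); one
#' grows monotonically toward high T and M; the remainder stay
#' near-zero.
#'
#' @return a [FractionField-class] over fingerprints CO-1..CO-5, DI-1,
#'   DN-1.
#' @export
defaultFractionField <- function() {
  comp <- data.frame(
    name    = c("CO-2", "CO-5", "CO-1", "CO-3", "CO-4", "DI-1", "DN-1"),
    baseline = c(0.01, 0.01, 0.01, 0.02, 0.02, 0.02, 0.02),
    height  = c(0.45, 0.55, 0.40, 0.00, 0.00, 0.35, 0.00),
    TCenter = c(345, 345, 298, 350, 350, 400, 350),
    MCenter = c(0.475, 0.475, 0.0, 0.5, 0.5, 1.0, 0.5),
    TSigma  = c(18, 18, 30, 50, 50, 35, 50),
    MSigma  = c(0.13, 0.13, 0.18, 1, 1, 0.30, 1),
    stringsAsFactors = FALSE)
  FractionField(comp, optimum = c(340, 350, 0.40, 0.55),
                targets = c("CO-5", "CO-2"))
}

#' True fingerprint weights of a field at a condition
#'
#' @param field a [FractionField-class].
#' @param temperature K.
#' @param M gauge parameter in `[0, 1]`.
#' @return named numeric weights summing to 1.
#' @export
fieldWeights <- function(field, temperature, M) {
  cp <- field@components
  h <- cp$baseline + cp$height *
    exp(-(temperature - cp$TCenter)^2 / (2 * cp$TSigma^2)
        - (M - cp$MCenter)^2 / (2 * cp$MSigma^2))
  stats::setNames(h / sum(h), cp$name)
}

setMethod("show", "FractionField", function(object) {
  cat(sprintf("FractionField: %d components; encoded optimum %s at %g-%g K, %g-%g M\n",
              nrow(object@components), paste(object@targets, collapse = "+"),
              object@optimum[1], object@optimum[2], object@optimum[3],
              object@optimum[4]))
})
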