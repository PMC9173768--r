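#' @include design-space.R
NULL

## Flory-Huggins screening of fingerprint pairs.  The lattice-theory
## interaction parameter chi decides mixing tendency: chi below the
## critical value (2 for equal unit segment counts) favours
## coexistence/mixing of the pair, large positive chi favours demixing
## into separate phases.  Two standard routes to chi are provided:
## Hildebrand solubility parameters (always nonnegative) and lattice
## exchange energies (may be negative, i.e. favourable mixing).

.newChi <- function(names, chi, temperature) {
  dimnames(chi) <- list(names, names)
  new("ChiMatrix", names = names, chi = chi, temperature = temperature)
}

#' Chi from Hildebrand solubility parameters
#'
#' chi_ij = Vref * (delta_i - delta_j)^2 / (R * T), with delta in
#' MPa^0.5 and Vref the reference (lattice site) molar volume.  This
#' regular-solution route yields nonnegative chi only.
#'
#' @param delta named numeric solubility parameters, MPa^0.5.
#' @param temperature K.
#' @param Vref reference molar volume, m^3/mol (default 1e-4, a typical
#'   small-molecule molar volume).
#' @return a [ChiMatrix-class].
#' @examples
#' chiFromSolubility(c(F1 = 20.3, F2 = 22.1), temperature = 298)
#' @export
chiFromSolubility <- function(delta, temperature = 298, Vref = 1e-4) {
  if (is.null(names(delta)) || anyNA(delta))
    .stopc("missingDescriptor", "every component needs a named, non-NA delta")
  stopifnot(temperature > 0, Vref > 0)
  dPa <- delta * 1e3                     # MPa^0.5 -> Pa^0.5
  chi <- Vref * outer(dPa, dPa, function(a, b) (a - b)^2) /
    (.RGAS * temperature)
  .newChi(names(delta), chi, temperature)
}

#' Chi from pairwise lattice exchange energies
#'
#' chi_ij = z * (w_ij - (w_ii + w_jj) / 2) / (R * T) with contact
#' energies w in kJ/mol and lattice coordination number z.  Negative
#' chi (cross contacts more favourable than the self average) indicates
#' a mixing tendency.
#'
#' @param energies symmetric named matrix of contact energies w_ij,
#'   kJ/mol, including the self energies on the diagonal.
#' @param temperature K.
#' @param z lattice coordination number (default 6).
#' @return a [ChiMatrix-class].
#' @export
chiFromEnergies <- function(energies, temperature = 298, z = 6L) {
  if (is.null(rownames(energies)) || anyNA(energies))
    .stopc("missingDescriptor",
           "energies must be a fully specified named matrix (incl. diagonal)")
  if (max(abs(energies - t(energies))) > 1e-9)
    .stopc("missingDescriptor", "energies must be symmetric")
  stopifnot(temperature > 0, z >= 1)
  w <- energies * 1e3                    # kJ/mol -> J/mol
  self <- diag(w)
  exch <- w - outer(self, self, `+`) / 2
  chi <- z * exch / (.RGAS * temperature)
  diag(chi) <- 0
  .newChi(rownames(energies), chi, temperature)
}

#' Classify pairs as miscible or demixing
#'
#' A pair is "miscible" (can coexist mixed) when chi_ij is at or below
#' the Flory-Huggins critical value
#' chi_crit = (1/sqrt(m_i) + 1/sqrt(m_j))^2 / 2, which equals 2 for two
#' unit-segment components; otherwise "demixing".
#'
#' @param chi a [ChiMatrix-class].
#' @param segments named integer lattice segment counts (default 1 for
#'   every component).
#' @return data.frame with one row per unordered pair: i, j, chi,
#'   chiCrit, class.
#' @export
classifyMiscibility <- function(chi, segments = NULL) {
  nm <- chi@names
  m <- stats::setNames(rep(1, length(nm)), nm)
  if (!is.null(segments)) m[names(segments)] <- segments
  pairs <- utils::combn(nm, 2L)
  out <- data.frame(
    i = pairs[1, ], j = pairs[2, ],
    chi = chi@chi[cbind(pairs[1, ], pairs[2, ])],
    stringsAsFactors = FALSE)
  out$chiCrit <- 0.5 * (1 / sqrt(m[out$i]) + 1 / sqrt(m[out$j]))^2
  out$class <- ifelse(out$chi <= out$chiCrit, "miscible", "demixing")
  rownames(out) <- NULL
  out
}

setMethod("show", "ChiMatrix", function(object) {
  cat(sprintf("ChiMatrix: %d components at %g K; chi in [%.3g, %.3g]\n",
              length(object@names), object@temperature,
              min(object@chi[upper.tri(object@chi)]),
              max(object@chi[upper.tri(object@chi)])))
})
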