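#' @importFrom methods new validObject is slot show setClass setGeneric
#'   setMethod setValidity
NULL

## ---------------------------------------------------------------------------
## Spectral containers
## ---------------------------------------------------------------------------

#' RamanSpectrum: a single Raman spectrum
#'
#' Wavenumber/intensity pairs on a strictly increasing wavenumber axis.
#' This is the unit of all spectral I/O in the package: computed
#' fingerprint spectra, synthetic mixtures and probe measurements are all
#' `RamanSpectrum` objects.
#'
#' @slot wavenumbers numeric, cm^-1, strictly increasing, length >= 2.
#' @slot intensities numeric, arbitrary units, same length.
#' @slot label character scalar naming the spectrum.
#' @export
setClass("RamanSpectrum",
  representation(wavenumbers = "numeric", intensities = "numeric",
                 label = "character"),
  prototype(label = ""))

setValidity("RamanSpectrum", function(object) {
  w <- object@wavenumbers; y <- object@intensities
  if (length(w) < 2L) return("need at least 2 points")
  if (length(w) != length(y)) return("wavenumbers and intensities differ in length")
  if (anyNA(w) || anyNA(y) || any(!is.finite(w)) || any(!is.finite(y)))
    return("non-finite values")
  if (any(diff(w) <= 0)) return("wavenumbers must be strictly increasing")
  if (length(object@label) != 1L) return("label must be a single string")
  TRUE
})

#' Construct a RamanSpectrum
#'
#' @param wavenumbers numeric vector, cm^-1, strictly increasing.
#' @param intensities numeric vector, same length.
#' @param label optional name.
#' @return A [RamanSpectrum-class] object.
#' @examples
#' s <- RamanSpectrum(seq(400, 3750, length.out = 10), runif(10))
#' @export
RamanSpectrum <- function(wavenumbers, intensities, label = "") {
  new("RamanSpectrum", wavenumbers = as.numeric(wavenumbers),
      intensities = as.numeric(intensities), label = as.character(label))
}

#' SpectralGrid: a uniform wavenumber grid
#'
#' The default grid matches the spectral window used for fingerprint
#' extraction: 400 to 3750 cm^-1 sampled at 1,000 points (spectra below
#' 400 cm^-1 are dominated by phonon modes and are excluded).
#'
#' @slot lo,hi numeric bounds, cm^-1.
#' @slot nPoints integer number of points, >= 2.
#' @export
setClass("SpectralGrid",
  representation(lo = "numeric", hi = "numeric", nPoints = "integer"))

setValidity("SpectralGrid", function(object) {
  if (length(object@lo) != 1L || length(object@hi) != 1L) return("scalar bounds required")
  if (!(object@lo < object@hi)) return("lo must be < hi")
  if (object@nPoints < 2L) return("nPoints must be >= 2")
  TRUE
})

#' @param lo,hi grid bounds in cm^-1.
#' @param nPoints number of uniformly spaced points.
#' @rdname SpectralGrid-class
#' @export
SpectralGrid <- function(lo = 400, hi = 3750, nPoints = 1000L) {
  new("SpectralGrid", lo = as.numeric(lo), hi = as.numeric(hi),
      nPoints = as.integer(nPoints))
}

#' FingerprintLibrary: basis spectra for unmixing
#'
#' Holds the normalized Raman spectra of the two isolated molecules
#' (A = drug, B = coformer) and of every molecular-interaction
#' fingerprint: drug dimers (DI), coformer dimers (DN) and drug-coformer
#' cocrystal pairs (CO).  All member spectra share one [SpectralGrid-class]
#' and are min-max normalized.
#'
#' @slot grid the shared [SpectralGrid-class].
#' @slot moleculeA,moleculeB normalized spectra of the isolated molecules.
#' @slot fingerprints named list of normalized [RamanSpectrum-class]
#'   objects (names like "CO-1", "DI-2", "DN-9").
#' @slot seed integer seed the library was generated from (NA for
#'   libraries read from disk).
#' @export
setClass("FingerprintLibrary",
  representation(grid = "SpectralGrid", moleculeA = "RamanSpectrum",
                 moleculeB = "RamanSpectrum", fingerprints = "list",
                 seed = "integer"))

setValidity("FingerprintLibrary", function(object) {
  gw <- gridWavenumbers(object@grid)
  sp <- c(list(A = object@moleculeA, B = object@moleculeB), object@fingerprints)
  nm <- names(object@fingerprints)
  if (length(object@fingerprints) < 1L) return("at least one fingerprint required")
  if (is.null(nm) || anyDuplicated(nm) || any(nm %in% c("A", "B")))
    return("fingerprint names must be unique and distinct from 'A'/'B'")
  for (i in seq_along(sp)) {
    s <- sp[[i]]
    if (!is(s, "RamanSpectrum")) return("all members must be RamanSpectrum")
    if (length(s@wavenumbers) != length(gw) ||
        max(abs(s@wavenumbers - gw)) > 1e-8)
      return(sprintf("spectrum '%s' is not on the library grid", names(sp)[i]))
    if (!isNormalized(s))
      return(sprintf("spectrum '%s' is not min-max normalized", names(sp)[i]))
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Volterra kernel containers
## ---------------------------------------------------------------------------

#' CoefficientSet: coefficients of the truncated Volterra kernel
#'
#' Stores the constant a, linear a_i, pairwise a_ij and triple a_ijk
#' coefficients of the polynomial mixture model.  Pair and triple keys
#' are stored canonically (name components sorted and joined with "|"),
#' so a_ij = a_ji by construction.  The `quartic` slot holds optional
#' fourth-order terms used only by the forward synthesiser to emulate
#' truncation error; the fitted kernel never estimates them.
#'
#' @slot constant numeric scalar.
#' @slot linear named numeric (names from the library plus "A"/"B").
#' @slot pairwise,triple,quartic named numeric with canonical keys.
#' @export
setClass("CoefficientSet",
  representation(constant = "numeric", linear = "numeric",
                 pairwise = "numeric", triple = "numeric",
                 quartic = "numeric"),
  prototype(constant = 0, linear = numeric(0), pairwise = numeric(0),
            triple = numeric(0), quartic = numeric(0)))

setValidity("CoefficientSet", function(object) {
  if (length(object@constant) != 1L) return("constant must be scalar")
  for (slotnm in c("linear", "pairwise", "triple", "quartic")) {
    v <- slot(object, slotnm)
    if (length(v) && (is.null(names(v)) || any(names(v) == "")))
      return(sprintf("%s coefficients must be named", slotnm))
    if (anyDuplicated(names(v))) return(sprintf("duplicate %s keys", slotnm))
  }
  ord <- c(pairwise = 2L, triple = 3L, quartic = 4L)
  for (slotnm in names(ord)) {
    v <- slot(object, slotnm)
    if (!length(v)) next
    parts <- strsplit(names(v), "|", fixed = TRUE)
    if (any(lengths(parts) != ord[[slotnm]]))
      return(sprintf("%s keys must have %d components", slotnm, ord[[slotnm]]))
    if (!all(vapply(parts, function(p) identical(p, sort(p)), logical(1))))
      return(sprintf("%s keys must be canonically sorted", slotnm))
  }
  TRUE
})

#' Canonical key for an interaction coefficient
#'
#' Sorts the member names and joins them with "|"; used for the pairwise,
#' triple and quartic slots of [CoefficientSet-class].
#' @param names character vector of basis-spectrum names.
#' @return single string key.
#' @export
coefKey <- function(names) paste(sort(as.character(names)), collapse = "|")

#' Construct a CoefficientSet
#'
#' Pair/triple/quartic names may be given in any component order; they
#' are canonicalized (sorted) on construction and duplicate canonical
#' keys are summed.
#'
#' @param constant scalar a.
#' @param linear named numeric a_i.
#' @param pairwise,triple,quartic named numeric with "n1|n2[|n3[|n4]]" keys.
#' @return A [CoefficientSet-class].
#' @export
CoefficientSet <- function(constant = 0, linear = numeric(0),
                           pairwise = numeric(0), triple = numeric(0),
                           quartic = numeric(0)) {
  canon <- function(v) {
    if (!length(v)) return(numeric(0))
    keys <- vapply(strsplit(names(v), "|", fixed = TRUE), coefKey, character(1))
    out <- tapply(v, keys, sum)
    stats::setNames(as.numeric(out), names(out))
  }
  new("CoefficientSet", constant = as.numeric(constant),
      linear = unlist(as.list(linear)) %||% numeric(0),
      pairwise = canon(pairwise), triple = canon(triple),
      quartic = canon(quartic))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' WeightSet: intuitive fingerprint fractions
#'
#' The linear Volterra coefficients of the fingerprints, normalized so
#' they sum to one after the isolated-molecule contributions (A, B) are
#' removed and treated as noise: a'_i = a_i / sum_fingerprints(a_i).
#'
#' @slot weights named numeric a'_i over fingerprints; sums to 1 unless
#'   `noiseOnly`.
#' @slot noiseShare numeric length 2 (A, B linear coefficients removed
#'   as noise).
#' @slot noiseOnly logical; TRUE when the fingerprint contribution was
#'   negligible (pure isolated-molecule signal) and weights are NA.
#' @export
setClass("WeightSet",
  representation(weights = "numeric", noiseShare = "numeric",
                 noiseOnly = "logical"),
  prototype(noiseShare = c(A = 0, B = 0), noiseOnly = FALSE))

setValidity("WeightSet", function(object) {
  w <- object@weights
  if (is.null(names(w)) && length(w)) return("weights must be named")
  if (object@noiseOnly) return(TRUE)
  if (!length(w)) return("empty weights")
  if (abs(sum(w) - 1) > 1e-9) return("weights must sum to 1 (+- 1e-9)")
  TRUE
})

#' @param weights named numeric fractions.
#' @param noiseShare numeric length-2 c(A=, B=).
#' @param noiseOnly logical flag for the all-noise case.
#' @rdname WeightSet-class
#' @export
WeightSet <- function(weights, noiseShare = c(A = 0, B = 0),
                      noiseOnly = FALSE) {
  new("WeightSet", weights = weights,
      noiseShare = stats::setNames(as.numeric(noiseShare), c("A", "B")),
      noiseOnly = noiseOnly)
}

#' FitResult: outcome of a kernel fit
#'
#' @slot coefficients the fitted [CoefficientSet-class].
#' @slot weights the derived [WeightSet-class].
#' @slot reconstruction the reproduced spectrum R-bar on the fitted grid.
#' @slot relativeError norm-relative reconstruction error, percent.
#' @slot rank numerical rank of the design matrix.
#' @slot conditionEstimate ratio of largest to smallest retained singular
#'   value.
#' @export
setClass("FitResult",
  representation(coefficients = "CoefficientSet", weights = "WeightSet",
                 reconstruction = "RamanSpectrum", relativeError = "numeric",
                 rank = "integer", conditionEstimate = "numeric"))

setValidity("FitResult", function(object) {
  if (object@relativeError < 0) return("relativeError must be >= 0")
  TRUE
})

## ---------------------------------------------------------------------------
## Process / design-space containers
## ---------------------------------------------------------------------------

#' GranulatorSpec: twin-screw granulator geometry
#'
#' @slot L barrel length, m.
#' @slot f screw lead (forward carrying of material per rotation), m.
#' @slot psi dimensionless correction factor (default 1).
#' @export
setClass("GranulatorSpec",
  representation(L = "numeric", f = "numeric", psi = "numeric"))

setValidity("GranulatorSpec", function(object) {
  if (object@L <= 0) return("L must be > 0")
  if (object@f <= 0) return("f must be > 0")
  if (object@psi <= 0) return("psi must be > 0")
  TRUE
})

#' @param L barrel length, m.
#' @param f screw lead, m per rotation.
#' @param psi correction factor.
#' @rdname GranulatorSpec-class
#' @export
GranulatorSpec <- function(L = 1, f = 0.01, psi = 1) {
  new("GranulatorSpec", L = as.numeric(L), f = as.numeric(f),
      psi = as.numeric(psi))
}

#' ProcessCondition: one (T, shear, time) operating point
#'
#' @slot temperature K.
#' @slot shear shear rate (s^-1; molecular-simulation values in ps^-1 are
#'   accepted with `shearUnit = "ps-1"` as a tag, the numbers are used
#'   as given).
#' @slot time residence / trajectory time, s.
#' @slot shearUnit unit tag, "s-1" or "ps-1".
#' @export
setClass("ProcessCondition",
  representation(temperature = "numeric", shear = "numeric",
                 time = "numeric", shearUnit = "character"),
  prototype(shearUnit = "s-1"))

setValidity("ProcessCondition", function(object) {
  if (object@shear <= 0) return("shear must be > 0")
  if (object@time < 0) return("time must be >= 0")
  if (!object@shearUnit %in% c("s-1", "ps-1")) return("unknown shear unit")
  TRUE
})

#' @param temperature K.
#' @param shear shear rate.
#' @param time residence time, s.
#' @param shearUnit "s-1" (default) or "ps-1".
#' @rdname ProcessCondition-class
#' @export
ProcessCondition <- function(temperature, shear, time, shearUnit = "s-1") {
  new("ProcessCondition", temperature = as.numeric(temperature),
      shear = as.numeric(shear), time = as.numeric(time),
      shearUnit = shearUnit)
}

#' DesignSpace: fingerprint fractions over (T, M) cells
#'
#' A gridded map from temperature and the dimensionless gauge parameter
#' M to the mean fraction of each fingerprint.  Cells never visited are
#' NA ("not computed"), which is distinct from a true near-zero fraction
#' (< 1e-5, the "blank" rendering convention; see [blankMask()]).
#'
#' @slot TBreaks,MBreaks cell edges (length bins + 1), strictly increasing.
#' @slot TAxis,MAxis cell centers.
#' @slot fractions named list of (TBins x MBins) matrices, one per
#'   fingerprint; NA marks unvisited cells.
#' @slot counts matrix of contributing estimates per cell.
#' @slot provenance free-text id of the data source.
#' @export
setClass("DesignSpace",
  representation(TBreaks = "numeric", MBreaks = "numeric",
                 TAxis = "numeric", MAxis = "numeric",
                 fractions = "list", counts = "matrix",
                 provenance = "character"))

setValidity("DesignSpace", function(object) {
  if (any(diff(object@TBreaks) <= 0) || any(diff(object@MBreaks) <= 0))
    return("breaks must be strictly increasing")
  dims <- c(length(object@TAxis), length(object@MAxis))
  if (!all(dim(object@counts) == dims)) return("counts dimension mismatch")
  if (!length(object@fractions) || is.null(names(object@fractions)))
    return("fractions must be a named list")
  for (m in object@fractions) {
    if (!is.matrix(m) || !all(dim(m) == dims)) return("fraction matrix shape mismatch")
    if (any(m < 0, na.rm = TRUE)) return("fractions must be >= 0")
  }
  TRUE
})

#' FractionField: parametric ground-truth fraction surfaces
#'
#' A synthetic stand-in for the fingerprint-fraction surfaces that a full
#' molecular-simulation campaign would produce.  Each component is a
#' baseline plus a Gaussian bump in (T, M); evaluating the field at a
#' condition and normalizing across components yields the "true"
#' fingerprint weights there.  The encoded optimum window is stored so
#' recovery tests can check the pipeline end to end.
#'
#' @slot components data.frame with columns name, baseline, height,
#'   TCenter, MCenter, TSigma, MSigma.
#' @slot optimum numeric length 4: c(TLo, THi, MLo, MHi) of the encoded
#'   maximum-target window.
#' @slot targets character names of the target fingerprints the optimum
#'   refers to.
#' @export
setClass("FractionField",
  representation(components = "data.frame", optimum = "numeric",
                 targets = "character"))

setValidity("FractionField", function(object) {
  need <- c("name", "baseline", "height", "TCenter", "MCenter",
            "TSigma", "MSigma")
  if (!all(need %in% names(object@components))) return("missing component columns")
  if (any(object@components$height < 0) || any(object@components$height > 1))
    return("heights must lie in [0, 1]")
  if (length(object@optimum) != 4L) return("optimum must be c(TLo,THi,MLo,MHi)")
  TRUE
})

## ---------------------------------------------------------------------------
## Coexistence / rheology containers
## ---------------------------------------------------------------------------

#' ChiMatrix: pairwise Flory-Huggins interaction parameters
#'
#' @slot names component names.
#' @slot chi symmetric matrix of dimensionless interaction parameters,
#'   zero diagonal.
#' @slot temperature K the parameters refer to.
#' @export
setClass("ChiMatrix",
  representation(names = "character", chi = "matrix",
                 temperature = "numeric"))

setValidity("ChiMatrix", function(object) {
  n <- length(object@names)
  if (!all(dim(object@chi) == n)) return("chi must be n x n")
  if (max(abs(object@chi - t(object@chi))) > 1e-12) return("chi must be symmetric")
  if (max(abs(diag(object@chi))) > 1e-12) return("chi diagonal must be zero")
  TRUE
})

#' CarreauParams: shear-thinning viscosity model parameters
#'
#' mu(gamma) = mu_inf + (mu0 - mu_inf) * [1 + (lambda*gamma)^alpha]^((n-1)/alpha).
#' `mu0` may be a named vector (one zero-shear viscosity per temperature)
#' when lambda and n are shared across temperatures.
#'
#' @slot mu0 zero-shear viscosity, cP (possibly per-temperature, named).
#' @slot muInf infinite-shear viscosity, cP.
#' @slot lam time constant lambda, s.
#' @slot n power index (dimensionless; n < 1 is pseudoplastic).
#' @slot alpha transition sharpness, conventionally 2.
#' @export
setClass("CarreauParams",
  representation(mu0 = "numeric", muInf = "numeric", lam = "numeric",
                 n = "numeric", alpha = "numeric"),
  prototype(muInf = 0, alpha = 2))

setValidity("CarreauParams", function(object) {
  if (object@lam <= 0) return("lam must be > 0")
  if (object@muInf < 0) return("muInf must be >= 0")
  if (any(object@mu0 <= object@muInf)) return("mu0 must exceed muInf")
  TRUE
})

#' @param mu0 zero-shear viscosity, cP.
#' @param muInf infinite-shear viscosity, cP.
#' @param lam time constant, s.
#' @param n power index.
#' @param alpha transition exponent, default 2.
#' @rdname CarreauParams-class
#' @export
CarreauParams <- function(mu0, lam, n, muInf = 0, alpha = 2) {
  new("CarreauParams", mu0 = mu0, muInf = as.numeric(muInf),
      lam = as.numeric(lam), n = as.numeric(n), alpha = as.numeric(alpha))
}

#' ArrheniusParams: temperature dependence of viscosity
#'
#' mu(T) = A * exp(EoverR / T); the refined form relative to a reference
#' temperature T0 is mu/mu0 = exp(EoverR * (1/T - 1/T0)).
#'
#' @slot A pre-exponential constant, cP.
#' @slot EoverR activation term E/R, K (may be negative as fitted).
#' @slot T0 optional reference temperature, K (NA when unset).
#' @export
setClass("ArrheniusParams",
  representation(A = "numeric", EoverR = "numeric", T0 = "numeric"),
  prototype(T0 = NA_real_))

setValidity("ArrheniusParams", function(object) {
  if (object@A <= 0) return("A must be > 0")
  TRUE
})

#' @param A pre-exponential constant, cP.
#' @param EoverR activation term E/R, K.
#' @param T0 optional reference temperature, K.
#' @rdname ArrheniusParams-class
#' @export
ArrheniusParams <- function(A, EoverR, T0 = NA_real_) {
  new("ArrheniusParams", A = as.numeric(A), EoverR = as.numeric(EoverR),
      T0 = as.numeric(T0))
}

## ---------------------------------------------------------------------------
## Controller containers
## ---------------------------------------------------------------------------

#' ControllerState: current operating point of the granulator
#'
#' The state carries the characteristic process shear rate `shear`
#' (s^-1) delivered by the screws; together with the residence-time
#' proxy t = L / (f * speed) this fixes the gauge parameter
#' M = psi * shear / speed, which the controller steers via the screw
#' speed.
#'
#' @slot temperature barrel temperature, K.
#' @slot speed screw speed, rotations s^-1.
#' @slot shear characteristic shear rate, s^-1.
#' @slot spec the [GranulatorSpec-class].
#' @slot target fingerprint names to maximize.
#' @slot bounds named numeric c(TMin, TMax, speedMin, speedMax).
#' @export
setClass("ControllerState",
  representation(temperature = "numeric", speed = "numeric",
                 shear = "numeric", spec = "GranulatorSpec",
                 target = "character", bounds = "numeric"))

setValidity("ControllerState", function(object) {
  b <- object@bounds
  need <- c("TMin", "TMax", "speedMin", "speedMax")
  if (!all(need %in% names(b))) return("bounds must name TMin,TMax,speedMin,speedMax")
  if (object@temperature < b["TMin"] || object@temperature > b["TMax"])
    return("temperature outside bounds")
  if (object@speed < b["speedMin"] || object@speed > b["speedMax"])
    return("speed outside bounds")
  if (object@shear <= 0) return("shear must be > 0")
  if (!length(object@target)) return("at least one target fingerprint")
  TRUE
})

#' @param temperature K.
#' @param speed rotations per second.
#' @param shear characteristic shear rate, s^-1.
#' @param spec a [GranulatorSpec-class].
#' @param target character vector of target fingerprints.
#' @param bounds named numeric c(TMin, TMax, speedMin, speedMax).
#' @rdname ControllerState-class
#' @export
ControllerState <- function(temperature, speed, shear, spec = GranulatorSpec(),
                            target = c("CO-5", "CO-2"),
                            bounds = c(TMin = 298, TMax = 400,
                                       speedMin = 0.1, speedMax = 100)) {
  new("ControllerState", temperature = as.numeric(temperature),
      speed = as.numeric(speed), shear = as.numeric(shear), spec = spec,
      target = target, bounds = bounds)
}

#' Recommendation: one controller decision
#'
#' @slot action "hold" or "adjust".
#' @slot deltaT temperature move, K (0 for hold).
#' @slot deltaSpeed screw-speed move, rotations s^-1 (0 for hold).
#' @slot estimatedFractions the [WeightSet-class] the decision was based on.
#' @slot rationale human-readable explanation.
#' @export
setClass("Recommendation",
  representation(action = "character", deltaT = "numeric",
                 deltaSpeed = "numeric", estimatedFractions = "WeightSet",
                 rationale = "character"))

setValidity("Recommendation", function(object) {
  if (!object@action %in% c("hold", "adjust")) return("action must be hold/adjust")
  if (object@action == "hold" && (object@deltaT != 0 || object@deltaSpeed != 0))
    return("hold implies zero deltas")
  TRUE
})
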