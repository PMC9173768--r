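#' @include rheology.R
NULL

#' Gauge parameter implied by a controller state
#'
#' Uses the residence-time proxy t = L / (f * speed) together with the
#' state's characteristic shear rate tau, so
#' M = psi * t * tau * f / L = psi * tau / speed.  Slowing the screws
#' (longer residence at the same characteristic shear) raises M;
#' speeding them up lowers it, which is the handle the controller uses.
#'
#' @param state a [ControllerState-class].
#' @return numeric M.
#' @export
stateM <- function(state) {
  t <- state@spec@L / (state@spec@f * state@speed)
  computeM(ProcessCondition(state@temperature, state@shear, t), state@spec)
}

#' Estimate fingerprint fractions from a probe spectrum
#'
#' Resamples the measured spectrum onto the library grid if necessary,
#' then unmixes at order 3 with negative-weight clipping on (the robust
#' setting for control use).  The pseudoinverse truncation is set to
#' `rtol = 1e-2` by default: probe spectra carry measurement noise, and
#' cutting singular directions below about the noise scale (truncated-SVD
#' regularization) stops the near-collinear product columns of the
#' order-3 kernel from amplifying that noise into the linear weights,
#' at the cost of a small (<1%) bias on clean signals.  A spectrum
#' carrying essentially no fingerprint signal (pure isolated-molecule
#' contamination) cannot be normalized over fingerprints; it is
#' returned as a noise-only [WeightSet-class] instead of an error.
#'
#' @param R a [RamanSpectrum-class].
#' @param library a [FingerprintLibrary-class].
#' @param order polynomial order (default 3).
#' @param rtol pseudoinverse truncation, see [solveCoefficients()].
#' @return a [WeightSet-class].
#' @export
estimateFractions <- function(R, library, order = 3L, rtol = 1e-2) {
  gw <- gridWavenumbers(library@grid)
  if (length(R@wavenumbers) != length(gw) ||
      max(abs(R@wavenumbers - gw)) > 1e-6)
    R <- resampleSpectrum(R, library@grid)
  noiseOnly <- function() {
    nm <- fingerprintNames(library)
    WeightSet(stats::setNames(rep(NA_real_, length(nm)), nm),
              noiseOnly = TRUE)
  }
  fit <- tryCatch(
    unmix(library, R, order = order, clip = TRUE, rtol = rtol),
    zeroDenominator = function(e) NULL)
  if (is.null(fit)) return(noiseOnly())
  ## the signal is effectively pure isolated-molecule contamination when
  ## the fingerprint linear mass is negligible next to the A/B terms
  lin <- fit@coefficients@linear
  den <- sum(lin[setdiff(names(lin), c("A", "B"))])
  mol <- sum(abs(fit@weights@noiseShare))
  if (abs(den) < 0.02 * (abs(den) + mol)) return(noiseOnly())
  fit@weights
}

.clamp <- function(x, lo, hi) min(max(x, lo), hi)

#' Recommend a temperature / screw-speed move
#'
#' Compares the current state against the optimal operating window of
#' the design space (via [findOptimum()] for the state's targets).
#' Inside the window: hold.  Outside: a bounded step toward it -
#' temperature by at most `stepT` kelvin when T is outside the window's
#' temperature band, and screw speed by at most a `stepSpeedFrac`
#' relative move to steer M toward the window center (M = psi *
#' shear / speed, so lowering speed raises M).  Once the temperature is
#' inside its band only the speed moves, reflecting that screw speed is
#' the practical real-time control handle while barrel temperature is
#' slow and loss-prone.  Moves never leave the configured bounds.
#'
#' @param state a [ControllerState-class].
#' @param fractionsEstimate the current [WeightSet-class] estimate
#'   (recorded in the recommendation).
#' @param space a [DesignSpace-class] containing the state's targets.
#' @param stepT maximum temperature step, K (default 5).
#' @param stepSpeedFrac maximum relative speed step (default 0.1).
#' @return a [Recommendation-class].
#' @export
recommendMove <- function(state, fractionsEstimate, space,
                          stepT = 5, stepSpeedFrac = 0.1) {
  win <- findOptimum(space, state@target)
  b <- state@bounds
  Tnow <- state@temperature
  Mnow <- stateM(state)
  inT <- Tnow >= win$TLo && Tnow <= win$THi
  inM <- Mnow >= win$MLo && Mnow <= win$MHi
  if (inT && inM)
    return(new("Recommendation", action = "hold", deltaT = 0, deltaSpeed = 0,
               estimatedFractions = fractionsEstimate,
               rationale = sprintf(
                 "inside optimum window (%.0f-%.0f K, M %.2f-%.2f); hold",
                 win$TLo, win$THi, win$MLo, win$MHi)))

  deltaT <- 0
  if (!inT) {
    Tmid <- (win$TLo + win$THi) / 2
    move <- sign(Tmid - Tnow) * min(stepT, abs(Tmid - Tnow))
    deltaT <- .clamp(Tnow + move, b[["TMin"]], b[["TMax"]]) - Tnow
  }
  deltaSpeed <- 0
  if (!inM) {
    Mmid <- (win$MLo + win$MHi) / 2
    speedTarget <- state@spec@psi * state@shear / Mmid
    ## step-limited multiplicative move toward the target speed
    ratio <- speedTarget / state@speed
    ratio <- .clamp(ratio, 1 - stepSpeedFrac, 1 + stepSpeedFrac)
    newSpeed <- .clamp(state@speed * ratio, b[["speedMin"]], b[["speedMax"]])
    deltaSpeed <- newSpeed - state@speed
  }
  new("Recommendation", action = "adjust", deltaT = deltaT,
      deltaSpeed = deltaSpeed, estimatedFractions = fractionsEstimate,
      rationale = sprintf(
        "T %.0f K, M %.3f -> window %.0f-%.0f K, M %.2f-%.2f: dT %+.1f K, dspeed %+.3g",
        Tnow, Mnow, win$TLo, win$THi, win$MLo, win$MHi, deltaT, deltaSpeed))
}

#' Apply a recommendation to a state
#'
#' @param state a [ControllerState-class].
#' @param rec a [Recommendation-class].
#' @return the updated state (a hold is a fixed point).
#' @export
applyRecommendation <- function(state, rec) {
  if (rec@action == "hold") return(state)
  new("ControllerState", temperature = state@temperature + rec@deltaT,
      speed = state@speed + rec@deltaSpeed, shear = state@shear,
      spec = state@spec, target = state@target, bounds = state@bounds)
}

#' Simulate the closed control loop on a synthetic plant
#'
#' At each step the plant's true fingerprint weights at the current
#' (T, M) are read from the fraction field; a mixture spectrum with
#' those linear weights (plus isolated-molecule contamination and
#' Gaussian noise) is synthesized as the "probe measurement"; the
#' fractions are re-estimated by unmixing; and the controller moves the
#' state.  Deterministic given the seed.
#'
#' @param field a [FractionField-class] (its component names must be
#'   fingerprints of `library`).
#' @param library the [FingerprintLibrary-class] used for unmixing.
#' @param space the [DesignSpace-class] acting as the decision tree.
#' @param state the initial [ControllerState-class].
#' @param steps number of controller iterations (>= 1).
#' @param noiseSd spectral noise level (see [synthesizeMixture()]).
#' @param moleculeShare linear coefficient given to each isolated
#'   molecule in the synthetic probe signal.
#' @param seed RNG seed for the whole trajectory.
#' @param stepT,stepSpeedFrac controller step sizes.
#' @return data.frame log with one row per step: step, T, speed, M,
#'   action, the estimated target fractions and the true target sum.
#' @export
runClosedLoop <- function(field, library, space, state, steps = 50L,
                          noiseSd = 0.01, moleculeShare = 0.05, seed = 1L,
                          stepT = 5, stepSpeedFrac = 0.1) {
  stopifnot(steps >= 1L)
  .withSeed(seed, {
    rows <- vector("list", steps)
    for (k in seq_len(steps)) {
      M <- stateM(state)
      trueW <- fieldWeights(field, state@temperature, min(max(M, 0), 1))
      coef <- CoefficientSet(linear = c(trueW,
                                        A = moleculeShare, B = moleculeShare))
      R <- synthesizeMixture(library, coef, noiseSd = noiseSd, seed = NULL,
                             label = sprintf("probe-%d", k))
      est <- estimateFractions(R, library)
      rec <- recommendMove(state, est, space, stepT = stepT,
                           stepSpeedFrac = stepSpeedFrac)
      targetEst <- if (est@noiseOnly) NA_real_ else
        sum(est@weights[state@target])
      rows[[k]] <- data.frame(step = k, T = state@temperature,
                              speed = state@speed, M = M,
                              action = rec@action,
                              targetEstimate = targetEst,
                              targetTrue = sum(trueW[state@target]))
      state <- applyRecommendation(state, rec)
    }
    do.call(rbind, rows)
  })
}

setMethod("show", "ControllerState", function(object) {
  cat(sprintf("ControllerState: T = %.1f K, speed = %.3g rot/s, shear = %.3g 1/s, M = %.3f; targets %s\n",
              object@temperature, object@speed, object@shear, stateM(object),
              paste(object@target, collapse = "+")))
})

setMethod("show", "Recommendation", function(object) {
  cat(sprintf("Recommendation[%s]: dT = %+.1f K, dspeed = %+.3g (%s)\n",
              object@action, object@deltaT, object@deltaSpeed,
              object@rationale))
})
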