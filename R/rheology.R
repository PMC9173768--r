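#' @include coexistence.R
NULL

#' Carreau shear-thinning viscosity
#'
#' mu(gamma) = mu_inf + (mu0 - mu_inf) * [1 + (lambda*gamma)^alpha]^((n-1)/alpha).
#' For n < 1 viscosity decreases monotonically with shear
#' (pseudoplastic); the low-shear limit is the Newtonian plateau mu0 and
#' at intermediate/high shear it reduces to the power law
#' mu = mu0 * (lambda*gamma)^(n-1) (for mu_inf = 0).
#'
#' @param gammaDot shear rate(s), s^-1, >= 0.
#' @param p a [CarreauParams-class] with scalar `mu0`.
#' @return viscosity(ies), cP.
#' @export
carreauViscosity <- function(gammaDot, p) {
  stopifnot(all(gammaDot >= 0), length(p@mu0) == 1L)
  p@muInf + (p@mu0 - p@muInf) *
    (1 + (p@lam * gammaDot)^p@alpha)^((p@n - 1) / p@alpha)
}

#' Shear rate at the plateau / power-law intersection
#'
#' The low-shear plateau mu = mu0 and the high-shear power law
#' mu = mu0*(lambda*gamma)^(n-1) intersect at gamma = 1/lambda.
#'
#' @param p a [CarreauParams-class].
#' @return shear rate, s^-1.
#' @export
asymptoteIntersection <- function(p) 1 / p@lam

#' Synthesize a seeded viscosity table
#'
#' Emulates shear- and temperature-resolved viscosity data: Carreau
#' curves whose zero-shear viscosity follows the Arrhenius law
#' mu0(T) = A * exp(EoverR / T), with multiplicative lognormal noise.
#' Before noise, viscosity is strictly decreasing in shear at fixed T
#' (for n < 1).
#'
#' @param carreau a [CarreauParams-class] (its `mu0` is replaced by the
#'   Arrhenius value per temperature).
#' @param arrhenius an [ArrheniusParams-class].
#' @param shearRates shear rates, s^-1 (> 0).  Default: the six decades
#'   1 down to 1e-5 used in the shear simulations (given there in
#'   ps^-1).
#' @param temperatures K, within the 298-400 K operating range.
#' @param noiseRel sdlog of the multiplicative lognormal noise.
#' @param seed RNG seed; NULL uses the current stream.
#' @return data.frame(T_K, shear, viscosity_cP).
#' @export
makeViscosityTable <- function(carreau = CarreauParams(mu0 = 1, lam = 1e4,
                                                       n = -0.35),
                               arrhenius = ArrheniusParams(A = 610.75,
                                                           EoverR = -736.64),
                               shearRates = 10^(0:-5),
                               temperatures = c(298, 325, 350, 375, 400),
                               noiseRel = 0, seed = 1L) {
  if (any(shearRates <= 0)) .stopc("domainError", "shear rates must be > 0")
  if (any(temperatures < 298 | temperatures > 400))
    .stopc("domainError", "temperatures must lie within [298, 400] K")
  stopifnot(noiseRel >= 0)
  tab <- expand.grid(shear = sort(shearRates, decreasing = TRUE),
                     T_K = temperatures)[, 2:1]
  mu0T <- arrhenius@A * exp(arrhenius@EoverR / tab$T_K)
  pT <- function(m0) CarreauParams(mu0 = m0, lam = carreau@lam,
                                   n = carreau@n, muInf = carreau@muInf,
                                   alpha = carreau@alpha)
  mu <- vapply(seq_len(nrow(tab)), function(i)
    carreauViscosity(tab$shear[i], pT(mu0T[i])), numeric(1))
  mu <- .withSeed(seed, mu * exp(stats::rnorm(length(mu), 0, noiseRel)))
  data.frame(T_K = tab$T_K, shear = tab$shear, viscosity_cP = mu)
}

#' Fit the Carreau model to a viscosity table
#'
#' Nonlinear least squares in log-viscosity space (decades of shear are
#' weighted evenly, matching the log-scale convention for such data)
#' with alpha fixed.  lambda and n are shared across all temperatures
#' while a separate zero-shear viscosity mu0 is profiled per
#' temperature; mu_inf is fixed (default 0, appropriate when the data
#' do not reach an upper-shear plateau).  Deterministic: a fixed
#' multi-start grid over (lambda, n) feeds Levenberg-Marquardt and the
#' best converged start wins.
#'
#' @param data data.frame with columns `shear`, `viscosity_cP` and
#'   optionally `T_K` (absent = single temperature).
#' @param fixAlpha fixed transition exponent (default 2).
#' @param muInf fixed infinite-shear viscosity (default 0).
#' @return list(params = [CarreauParams-class] with per-temperature
#'   named `mu0`, rSquared on the log scale, converged flag).
#' @export
fitCarreau <- function(data, fixAlpha = 2, muInf = 0) {
  need <- c("shear", "viscosity_cP")
  stopifnot(all(need %in% names(data)))
  if (nrow(data) < 5L)
    .stopc("insufficientData", "need at least 5 data points")
  if (diff(log10(range(data$shear))) < 2)
    .stopc("insufficientData", "shear rates must span at least 2 decades")
  if (any(data$viscosity_cP <= muInf))
    .stopc("domainError", "viscosities must exceed muInf")
  Tg <- if ("T_K" %in% names(data)) factor(data$T_K) else
    factor(rep(1, nrow(data)))
  ly <- log(data$viscosity_cP - muInf)
  g <- data$shear

  shape <- function(theta)   # log of [1+(lam g)^alpha]^((n-1)/alpha)
    ((theta[2] - 1) / fixAlpha) * log1p((exp(theta[1]) * g)^fixAlpha)
  resid <- function(theta) {
    s <- shape(theta)
    r <- ly - s
    mu0log <- tapply(r, Tg, mean)        # profiled per-temperature log mu0
    r - mu0log[Tg]
  }

  starts <- expand.grid(loglam = log(1 / stats::quantile(g, c(.05, .5, .95))),
                        n = c(-0.5, 0, 0.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = as.numeric(starts[i, ]), fn = resid,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    .stopc("nonConvergence", "no Levenberg-Marquardt start converged")
  theta <- best$par
  r <- ly - shape(theta)
  mu0 <- exp(tapply(r, Tg, mean)) + muInf
  sse <- best$deviance
  sst <- sum((ly - mean(ly))^2)
  params <- CarreauParams(mu0 = stats::setNames(as.numeric(mu0), levels(Tg)),
                          lam = exp(theta[1]), n = theta[2],
                          muInf = muInf, alpha = fixAlpha)
  list(params = params, rSquared = 1 - sse / sst,
       converged = best$info %in% 1:4)
}

#' Fit the Arrhenius temperature law to low-shear viscosities
#'
#' Linear regression of ln(mu) on 1/T: mu = A * exp(EoverR / T), so
#' A = exp(intercept) and EoverR = slope.  Exact on model-generated
#' data.
#'
#' @param data data.frame with columns `T_K`, `viscosity_cP` (mu > 0),
#'   >= 2 distinct temperatures.
#' @return list(params = [ArrheniusParams-class], rSquared).
#' @export
fitArrhenius <- function(data) {
  stopifnot(all(c("T_K", "viscosity_cP") %in% names(data)))
  if (length(unique(data$T_K)) < 2L)
    .stopc("insufficientData", "need at least 2 distinct temperatures")
  if (any(data$viscosity_cP <= 0))
    .stopc("domainError", "viscosities must be > 0")
  fit <- stats::lm(log(viscosity_cP) ~ I(1 / T_K), data = data)
  co <- stats::coef(fit)
  ly <- log(data$viscosity_cP)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  list(params = ArrheniusParams(A = exp(co[[1]]), EoverR = co[[2]]),
       rSquared = r2)
}

#' Refined Arrhenius form relative to a reference temperature
#'
#' mu(T) = mu0 * exp(EoverR * (1/T - 1/T0)); the form recommended where
#' viscosity is most temperature-sensitive.  Requires `T0` to be set in
#' the parameters.
#'
#' @param temperature K (> 0).
#' @param p an [ArrheniusParams-class] with `T0` set.
#' @param mu0 viscosity at the reference temperature, cP.
#' @return viscosity, cP.
#' @export
refinedArrhenius <- function(temperature, p, mu0) {
  if (is.na(p@T0))
    .stopc("missingReference", "reference temperature T0 is unset")
  stopifnot(all(temperature > 0))
  mu0 * exp(p@EoverR * (1 / temperature - 1 / p@T0))
}

setMethod("show", "CarreauParams", function(object) {
  cat(sprintf("CarreauParams: lam = %.4g s, n = %.4g, alpha = %g, muInf = %g cP\n",
              object@lam, object@n, object@alpha, object@muInf))
  m0 <- object@mu0
  cat("  mu0 (cP):", paste(sprintf("%s%.4g",
      if (is.null(names(m0))) "" else paste0(names(m0), "="), m0),
      collapse = " "), "\n")
})

setMethod("show", "ArrheniusParams", function(object) {
  cat(sprintf("ArrheniusParams: A = %.4g cP, E/R = %.4g K%s\n",
              object@A, object@EoverR,
              if (is.na(object@T0)) "" else sprintf(", T0 = %g K", object@T0)))
})
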