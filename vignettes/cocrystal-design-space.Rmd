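---
title: "Targeting cocrystals from in-line Raman signals: methods and design choices"
author: "cocrystalDS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeting cocrystals from in-line Raman signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocrystalDS)
```

## The problem

A twin-screw granulator running continuous solid-state
cocrystallization converts a drug (molecule A, e.g. ibuprofen) and a
coformer (molecule B, e.g. nicotinamide) into granules whose quality
depends on *which* molecular interactions dominate: drug–drug dimers
(DI), coformer–coformer dimers (DN), or the desired drug–coformer
cocrystal pairs (CO).  Each interaction has a distinct Raman
signature — its *fingerprint*.  An in-line Raman probe therefore sees a
mixture spectrum that is, to good approximation, a composition of
fingerprint spectra, and decomposing it in real time tells the process
which species it is actually making.  This package implements that
decomposition and the control layer built on it.

## The unmixing kernel

All spectra are min–max normalized, $\bar{x} = (x - \min)/(\max -
\min) \in [0, 1]$, each dataset on the shared uniform grid of 1,000
points over 400–3750 cm$^{-1}$ (`SpectralGrid()`).  The band below
400 cm$^{-1}$ is excluded as phonon-dominated.

The mixture spectrum $R$ is expanded in the normalized basis spectra
$r_i$ (the two isolated molecules plus $N$ fingerprints) as a Volterra
polynomial truncated after the third-order term:

$$\bar{R} = a + \sum_i a_i r_i + \sum_{i \le j} a_{ij} r_i r_j +
\sum_{i \le j \le k} a_{ijk}\, r_i r_j r_k, \qquad
i, j, k \in \{A, B, 1 \dots N\}.$$

Products are elementwise over wavenumbers.  Because $r_i r_j = r_j
r_i$, only canonical (sorted) index combinations enter the design
matrix $\rho$; duplicated orderings span no additional model space and
only worsen conditioning.  For $P$ basis spectra at order 3 this gives
$1 + P + \binom{P+1}{2} + \binom{P+2}{3}$ columns.

The coefficient vector solves $R = \rho A$ in the least-squares sense
via the Moore–Penrose pseudoinverse, computed by SVD with a *relative*
small-singular-value cutoff `rtol`.  The solver never fails on
singular or underdetermined systems — it returns the minimum-norm
solution and reports the numerical rank.  With the full 21-fingerprint
library at order 3 the system has 2,600 columns against 1,000 rows;
the fit is then exact by construction and weight identifiability rests
entirely on the spectral distinctness of the basis, which is why the
synthetic generator guarantees distinct marker bands (below).

The *intuitive weights* remove the isolated-molecule contributions as
noise and renormalize over fingerprints only:

$$a'_i = \frac{a_i}{\sum_{\text{fingerprints}} a_i}, \qquad \sum_i a'_i = 1.$$

Weights may legitimately come out negative on noisy data; they are
reported as-is by default, with an opt-in `clip` that zeroes negatives
and renormalizes for control use.  When the fingerprint linear mass is
negligible (a probe seeing essentially pure molecule signal) the
denominator is near zero; `unmix()` raises a `zeroDenominator` error,
while the controller-facing `estimateFractions()` converts both that
case and the relative criterion $|\sum a_i| < 0.02\,(|\sum a_i| +
|a_A| + |a_B|)$ into a flagged *noise-only* result rather than an
error.

### Choosing the truncation `rtol`

Two regimes call for different cutoffs, and both are exposed:

* `rtol = 1e-10` (default in `solveCoefficients()`/`unmix()`): a pure
  numerical-noise threshold.  Noiseless consistent systems are then
  solved essentially exactly — linear-only mixtures of up to six
  fingerprints are recovered to $10^{-6}$ and better in the tests.
* `rtol = 1e-2` (default in `estimateFractions()`): truncated-SVD
  regularization for measured (noisy) spectra.  The high-order product
  columns of $\rho$ are nearly collinear; with a tight cutoff, noise of
  ~1% of full scale is amplified through singular values far below the
  noise floor and scrambles the linear coefficients.  Cutting singular
  directions below roughly the noise scale stabilizes the weights at
  the cost of a small (sub-percent in the tests) bias on clean
  signals.  The reported `relativeError` then honestly includes the
  unfit noise.

### The reconstruction error

The fit quality is summarized as the norm-relative error
$100\,\lVert R - \bar{R}\rVert_2 / \lVert R \rVert_2$ (percent).
Whether such a figure should instead be a per-wavelength maximum is a
genuine ambiguity for this family of methods; the norm-relative form
was chosen because it is the quantity least-squares actually
controls.  By least-squares nesting it is monotone nonincreasing in
the kernel order, which the tests assert.

## The synthetic data layer

No quantum-chemistry or molecular-dynamics inputs ship with the
package; a seeded generator stands in for them.

* `makeFingerprintLibrary()` emulates computed fingerprint spectra as
  sums of Lorentzian lines (the natural Raman line shape): per
  spectrum, one strong *marker* line (amplitude 3) at a
  spectrum-specific position plus 3–6 minor lines (amplitude ≤ 0.4,
  HWHM 8–30 cm$^{-1}$) at seeded random positions.  Marker positions
  are laid out evenly over the grid so all 23 basis spectra are
  mutually distinct; CO-5 is pinned to 2250 cm$^{-1}$ (its
  distinguishing band between 2000 and 2500 cm$^{-1}$) and CO-2 to
  950 cm$^{-1}$ (inside the 700–1200 cm$^{-1}$ band conventionally
  used for cocrystal monitoring).  The minor-line amplitude budget
  guarantees the marker is each spectrum's global maximum.  The
  default family counts are 9 CO, 3 DI, 9 DN.
* `synthesizeMixture()` evaluates the polynomial forward model —
  including optional fourth-order contamination terms, which the
  fitted kernel deliberately does not estimate — adds additive
  Gaussian intensity noise (basis spectra live in $[0,1]$, so
  `noiseSd = 0.01` is 1% of full scale), and normalizes.
* `makeViscosityTable()` emulates shear- and temperature-resolved
  viscosity data from a Carreau model whose zero-shear viscosity
  follows the Arrhenius law, with multiplicative lognormal noise.
  Defaults follow the study conditions: temperatures
  {298, 325, 350, 375, 400} K, six shear decades from 1 down to
  $10^{-5}$, $\lambda = 10^4$, $n = -0.35$, $\alpha = 2$,
  $A = 610.75$, $E/R = -736.64$.
* `defaultFractionField()` encodes parametric ground-truth fraction
  surfaces over (T, M): the targets CO-2 and CO-5 share a unimodal
  maximum at 345 K, $M = 0.475$ (so the encoded optimum window is
  340–350 K, 0.4–0.55); CO-1 peaks at low T and M and decays; DI-1
  grows toward high T and M; the rest stay near zero.  These shapes
  mimic the qualitative kinetic behaviours expected of early-forming,
  decomposing and slowly-growing species.

What this layer does *not* emulate: instrument line-shape and baseline
effects, cosmic-ray spikes, fluorescence background, wavenumber
miscalibration, or any real relationship between process conditions
and spectra.  Passing tests therefore demonstrate the correctness and
noise behaviour of the algorithms, not chemical validity on a real
granulator; with real DFT/MD fingerprints or measured spectra the same
entry points apply unchanged.

One printed-source discrepancy is worth recording: the grid is stated
both as "20 cm$^{-1}$ intervals" and as 1,000 points over
400–3750 cm$^{-1}$, which are mutually inconsistent (20 cm$^{-1}$
spacing would give about 168 points).  The 1,000-point contract is
honored, giving ≈ 3.35 cm$^{-1}$ spacing, and the grid is fully
configurable.

## The design space and the gauge parameter M

The printed form of the gauge parameter is typeset without a fraction
bar; the only grouping of $\psi, t, \tau, f, L$ that is dimensionless
when $\tau$ carries inverse time is

$$M = \frac{\psi\, t\, \tau\, f}{L},$$

which is what `computeM()` implements ($\psi = 1$ by default; the
alternative reading $\psi t f/(\tau L)$ carries time² and is
rejected).  M is linear and increasing in $t$, $\tau$ and $f$ and
decreasing in $L$.

`buildDesignSpace()` bins (condition, weights) estimates into a
$T \times M$ grid — by default 5 temperature bins over 298–400 K
(matching the five simulated temperatures) and 20 M bins on $[0,1]$ —
and stores the *arithmetic mean* of the contributing weight sets per
cell (the aggregation over trajectory time stamps is not otherwise
specified, and the mean preserves the unit mass of the weights, which
the tests assert).  Three cell states are kept distinct: never visited
(NA, "not computed"), near-zero (occupied with fraction < $10^{-5}$,
the "blank" rendering convention, see `blankMask()`), and genuinely
occupied.  Missing cells are never imputed.  A `binningError` is
raised for degenerate axes (fewer than 2 bins or zero-width ranges);
multiple estimates legitimately landing in one cell are averaged, not
rejected.

`findOptimum()` returns the bounds of the occupied cell maximizing the
summed target fraction, with ties broken toward the lowest
temperature, then the lowest M.  A single cell was chosen as the
window definition (rather than a grown region) because any
tolerance-based growth rule turns a perfectly flat field into an
everything-window, defeating the documented tie-break; at the default
resolution one cell spans 20.4 K × 0.05 M, a practical set-point
granularity.  `lookupFractions()` interpolates bilinearly between cell
centers, excluding unvisited neighbours and flagging the result
`incomplete`.

`screwSpeedForM()` inverts M for the shear rate at fixed residence
time and converts to screw speed through a user-supplied
proportionality `tauPerSpeed` — user-supplied because whether the
shear rate entering M is the molecular-scale shear or the screw
rotation speed itself is left open by the source method, and the
mapping is machine-specific.

## Coexistence screening

The Flory–Huggins interaction parameter $\chi$ decides whether two
fingerprints tend to mix (coexist) or demix.  The defining formula and
the underlying descriptors are not fixed by the source method, so both
standard routes are provided:

* solubility parameters (Hildebrand / regular solution):
  $\chi_{ij} = V_{\mathrm{ref}} (\delta_i - \delta_j)^2 / (R T)$,
  nonnegative by construction; $V_{\mathrm{ref}} = 10^{-4}$ m³/mol by
  default (a typical small-molecule molar volume);
* lattice exchange energies:
  $\chi_{ij} = z \left(w_{ij} - \tfrac{w_{ii}+w_{jj}}{2}\right) / (R T)$
  with coordination number $z = 6$ by default — this route can produce
  the negative (mixing-favourable) values that a coexistence map
  requires, and is the one to use when pair interaction energies are
  available.

`classifyMiscibility()` applies the critical value $\chi_c =
\tfrac12 (m_i^{-1/2} + m_j^{-1/2})^2$ (= 2 for unit segment counts):
$\chi \le \chi_c$ is labelled miscible.  The classification is
monotone in $\chi$.  No binodal/spinodal construction is attempted.

## Rheology

`carreauViscosity()` implements
$\mu = \mu_\infty + (\mu_0 - \mu_\infty)\,[1 + (\lambda
\dot\gamma)^\alpha]^{(n-1)/\alpha}$ with $\alpha = 2$ by convention:
a Newtonian plateau $\mu_0$ at low shear, a power law
$\mu_0 (\lambda\dot\gamma)^{n-1}$ at high shear, asymptotes
intersecting at $\dot\gamma = 1/\lambda$
(`asymptoteIntersection()`; the statement sometimes attached to that
point — that viscosity and shear rate are "the same" there — is
dimensionally ill-posed, and the standard asymptote-intersection
meaning is implemented instead).

`fitCarreau()` fits in *log-viscosity* space so that every decade of
shear carries equal weight, matching how such data are plotted and
preventing the low-shear plateau from dominating the loss.  $\lambda$
and $n$ are shared across all temperatures while $\mu_0$ is profiled
per temperature (a closed-form inner step), mirroring the convention
of correlating all data points at all temperatures with one
$(\lambda, n)$ pair; the temperature dependence enters through
$\mu_0(T)$, for which `fitArrhenius()` does the exact log-linear
regression $\ln\mu = \ln A + (E/R)/T$.  $\mu_\infty$ is fixed at 0 by
default: the data ranges of interest never reach an upper-shear
plateau, so $\mu_\infty$ is not identifiable and the power-law
reduction implicitly drops it.  Optimization is deterministic: a fixed
3×3 multi-start grid over $(\log\lambda, n)$ feeds
Levenberg–Marquardt (`minpack.lm`), tight tolerances ($10^{-15}$), and
the best final deviance wins; on noiseless model data the recovery is
exact to machine precision.  `refinedArrhenius()` provides the
reference-temperature form $\mu/\mu_0 = \exp[E/R\,(1/T - 1/T_0)]$,
recommended where viscosity is most temperature-sensitive; the
switching threshold is a user decision, not hard-coded.

## The controller

`ControllerState` carries the barrel temperature, screw speed, the
granulator geometry and a *characteristic process shear rate* `shear`.
With the residence-time proxy $t = L/(f \cdot \text{speed})$, the
state's gauge parameter is $M = \psi \cdot \text{shear}/\text{speed}$:
slowing the screws raises M, speeding up lowers it.  (Treating the
shear in M as itself proportional to screw speed would make M constant
in speed — the product $t\tau$ then cancels — and uncontrollable; the
characteristic-shear reading keeps the stated residence proxy *and* a
monotone speed→M handle.  The mapping is deliberately config-level:
real machines will calibrate it.)

`recommendMove()` compares the state against the optimum window: hold
inside; otherwise a *step-limited* move toward it — at most `stepT`
(default 5 K) in temperature when T is outside the window's band, and
at most a `stepSpeedFrac` (default 10%) relative speed change steering
M toward the window center.  Once the temperature is inside its band
only the speed moves: screw speed is the practical real-time handle,
while barrel temperature is slow and subject to ambient thermal loss.
Steps never overshoot the target value and never leave the configured
bounds; a hold is a fixed point of `applyRecommendation()`.  The step
policy, gains and stopping rule are this package's minimal documented
choices, not an inferred intent of the source method.

`runClosedLoop()` wires the pieces into a synthetic plant: true
weights from the fraction field at the current (T, M) → probe spectrum
via `synthesizeMixture()` (with isolated-molecule contamination and
noise) → `estimateFractions()` → `recommendMove()` → apply.  The
trajectory log is deterministic given the seed.

## Problem sizes and runtimes

The shipped tests run the kernel on libraries of 4–9 fingerprints
(order-3 design matrices of 84–220 columns × 1,000 rows), the
full-pipeline recovery on a 5 × 20 cell design space built from 100
synthetic probe spectra at 1% noise, and closed loops of 40–50 steps
over 5 seeds; the acceptance script fits 50 contaminated mixtures from
a 6-fingerprint library.  These sizes keep a full run in the
tens-of-seconds range on one core while exercising every code path at
the documented tolerances.

## Known limitations

* With the full 21-fingerprint library at order 3 the system is
  underdetermined; weights are then minimum-norm artifacts unless the
  basis is spectrally distinct.  Restrict the library to the
  fingerprints actually expected, or check the reported rank.
* The synthetic fingerprints are idealized Lorentzian sums; no claim
  is made that unmixing performance on them transfers quantitatively
  to instrument spectra with baseline drift and fluorescence.
* The Flory–Huggins screen gives pair *tendencies* only — no phase
  diagram, no kinetics.
* The controller assumes the design space is trustworthy where
  occupied and makes no attempt at exploration or re-estimation.
* JCAMP-DX input is not implemented; the CSV spectrum format and the
  library/design-space directory bundles are the supported interfaces.
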