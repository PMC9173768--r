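Package: cocrystalDS
Title: Raman Fingerprint Unmixing and Process Design Spaces for
    Continuous Twin-Screw Cocrystallization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes in-line Raman spectra of twin-screw granulation
    mixtures into fractions of molecular-interaction fingerprints
    (drug dimers, coformer dimers, and cocrystal pairs) using a
    truncated Volterra polynomial kernel solved by Moore-Penrose
    pseudoinverse least squares.  Builds a process design space over
    temperature and the dimensionless gauge parameter M that collapses
    shear rate and residence time through the granulator geometry,
    locates operating windows that maximize target cocrystal
    fingerprints, and closes the loop with a simple set-point
    controller.  Includes Flory-Huggins miscibility screening of
    fingerprint pairs, Carreau shear-thinning and Arrhenius viscosity
    analysis, and seeded synthetic generators (Lorentzian fingerprint
    libraries, mixture spectra, viscosity tables) for end-to-end
    testing without molecular-simulation inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'spectra.R'
    'library.R'
    'unmix.R'
    'fraction-field.R'
    'design-space.R'
    'coexistence.R'
    'conditions.R'
    'rheology.R'
    'controller.R'
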