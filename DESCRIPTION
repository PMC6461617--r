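Package: bundleres
Title: Nanomechanical Analysis of Suspended DNA-Bundle Resonators
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward modelling and inference for flexural resonance of
    suspended DNA-bundle resonators. Implements clamped-clamped
    Euler-Bernoulli beam eigenfrequencies with and without axial tension,
    the taut-string limit, elliptical-cross-section mode splitting, mass
    sensitivity and limit-of-detection estimates, synthesis and fitting of
    vibrometer-style amplitude spectra (damped-oscillator lineshape,
    3 dB-bandwidth quality factors, vacuum doublet resolution), extraction
    of the effective Young's modulus from frequency-geometry regression,
    per-condition and titration summaries, and post-processing of
    constant-force steered-molecular-dynamics pulling records into
    stress-strain curves and elastic moduli. A seedable synthetic-data
    generator emulates the vibrometer and pulling inputs so every stage of
    the pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
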