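Package: edisim
Title: Electrodiffusive Simulation of Beta-Dispersion in Impedance Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the polarization of a single biological cell under a
    harmonic external field with a non-stationary electrodiffusive model: a
    two-dimensional nonlinear partial differential equation combining
    diffusion, a hyperbolic-sine ionic screening term controlled by an
    inverse-Debye-length parameter, and a spatially weighted harmonic drive,
    integrated by an explicit Euler scheme with zero-flux boundaries. Sweep
    drivers extract steady-state response amplitudes at the far edge of the
    domain to build simulated impedance spectra over frequency, screening
    strength and domain length, with a linearized frequency-domain solver as
    an independent cross-check. Companion utilities cover electric impedance
    spectroscopy workflows: logarithmic measurement-frequency grids, Bode
    diagram assembly, detection of the dispersion (knee) frequency where a
    spectrum departs from its low-frequency plateau, synthetic
    single-relaxation test spectra, and type-B uncertainty combination.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
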