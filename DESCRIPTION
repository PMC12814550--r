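Package: molvib
Title: Analytic Molecular Hessians and Infrared Spectra from Gaussian-Integral Derivatives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale quantum-chemistry engine for molecular vibrational
    spectroscopy. Implements Obara-Saika evaluation of electron-repulsion
    integrals over contracted spherical Gaussian shells together with their
    first- and second-order geometric derivatives, restricted closed-shell
    self-consistent-field theory (Hartree-Fock and hybrid-functional ready),
    a generalized-gradient-approximation exchange-correlation layer on
    Becke-partitioned molecular grids, coupled-perturbed Hartree-Fock response
    with a shared-subspace solver for all nuclear perturbations, analytic
    gradient and Hessian assembly, harmonic normal-mode analysis with IR
    intensities in km/mol, partial-Hessian subsystem analysis, and Lorentzian
    spectrum construction. Every derivative path is validated against
    independent finite-difference and brute-force oracles bundled with the
    package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
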