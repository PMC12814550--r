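# molvib

Analytic molecular Hessians and infrared spectra in R, built on
Obara–Saika electron-repulsion integrals with first- and second-order
geometric derivatives.

## What this package does

Simulating an infrared spectrum from first principles requires three
things: the curvature of the electronic energy at a molecular geometry
(the nuclear Hessian **H**), the response of the electric dipole moment to
nuclear displacement (the dipole gradient dμ/dx), and a harmonic analysis
connecting the two. For a closed-shell molecule the chain is

1. **SCF reference state.** Restricted Hartree–Fock (hybrid-functional
   ready through an exact-exchange fraction c_x and a pluggable GGA
   functional on a Becke-partitioned molecular grid), converged on both
   the energy change and the orbital-gradient commutator ‖FDS − SDF‖.
2. **Integral derivatives.** Two-electron repulsion integrals (ij|kl) over
   contracted spherical Gaussian shells are evaluated by vertical
   Obara–Saika recursions on primitives, *early contraction*, and
   horizontal transfer recursions in a mixed Cartesian/spherical
   representation. Geometric derivatives follow from the primitive
   differentiation rule d/dA_i χ(l) = 2α χ(l+1_i) − N_i(l) χ(l−1_i);
   because contraction weights are geometry independent, exponent-weighted
   contraction vectors let one set of recursion tables serve the plain
   integrals and every derivative order. A differentiated transfer
   recursion (GHRR) provides an independent route that the test suite
   checks against the direct one.
3. **Coupled-perturbed Hartree–Fock.** The occupied–virtual response
   U_ai^ξ of the MO coefficients to each of the 3N nuclear perturbations
   solves (ε_i − ε_a) U_ai − G_ai[U] = R_ai with
   R_ai = F_ai^(ξ) − ε_i S_ai^(ξ) − G_ai[S^(ξ)], handled for all
   right-hand sides at once by a preconditioned shared-subspace solver.
4. **Hessian and intensities.** H combines nuclear-repulsion, one- and
   two-electron second-derivative contractions, energy-weighted overlap
   terms and the orbital-response term; IR intensities are Napierian
   integrated attenuation coefficients
   A_k = (1/4πε₀)(N_A π/3c²) |dμ/dQ_k|², i.e. 974.88 km/mol·amu/e² times
   |dμ/dQ_k|² in e²/amu.
5. **Spectrum.** Sticks (ω_k, A_k), an optional common frequency scaling
   factor, and Lorentzian broadening
   σ(ω) = Σ_k A_k (γ/π)/((ω_k − ω)² + γ²) with HWHM γ.

Partial-Hessian analysis (diagonalizing the subblock of H belonging to a
subset of atoms with the matching dipole-gradient rows) and per-mode
localization fractions support subsystem studies of large molecules.

Every derivative path is validated against bundled brute-force oracles:
central finite differences over displaced geometries, a late-contraction
scalar ERI reference, 3-D quadrature, and a dense coupled-perturbed solve.

## Worked example

```r
library(molvib)

mol   <- fixture_molecule("h2o")          # r(OH) = 0.9572 A, HOH = 104.52 deg
basis <- load_basis("sto-3g", mol)
scf   <- run_scf(mol, basis, conv = 1e-9)
scf$E_total
#> [1] -74.96302

hess <- analytic_hessian(scf)
dmu  <- dipole_gradient(scf, response = list(rhs = hess$rhs,
                                             cphf = hess$response))
vib  <- vibrational_analysis(hess$H, dmu, mol$coords, mol$masses)
round(vib$frequencies, 1)
#> [1] 2043.3 4488.4 4790.7
round(vib$intensities, 2)
#> [1] 11.37 37.43 20.01

sticks <- apply_scaling(stick_spectrum(vib$frequencies, vib$intensities), 0.957)
spec   <- broaden(sticks, gamma = 10)     # Lorentzian, HWHM in cm^-1
write_spectrum(spec, "h2o-ir.csv")
```

The three harmonic wavenumbers are the bend and the symmetric/asymmetric
stretches of water in this minimal basis at the experimental geometry (not
a stationary point of the model, so they should not be read as predictions);
intensities are in km/mol. A command-line front end wrapping the same
functions ships in `inst/cli/molvib` (`scf`, `gradient`, `hessian`, `ir`,
`partial-hessian`, `make-fixture` subcommands).

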