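---
title: "Analytic Hessians and IR spectra: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic Hessians and IR spectra: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the conventions that were fixed once and
used everywhere, the numerical choices behind the defaults, and what the
bundled tests do and do not establish.

## The model

The target quantity is the harmonic infrared spectrum of a closed-shell
molecule: harmonic wavenumbers from the mass-weighted nuclear Hessian and
band intensities from the dipole-moment gradient. The electronic model is
restricted self-consistent field theory — Hartree–Fock by default, with a
hybrid-functional path through an exact-exchange fraction $c_x$ and a GGA
exchange–correlation functional integrated on a molecular grid. Everything
is derived for a single determinant with doubly occupied orbitals; open
shells, effective core potentials, general contractions and angular
momenta above $\ell = 4$ are out of scope by design.

Internal units are Hartree atomic units throughout; Ångström appears only
when reading or writing XYZ files, and cm$^{-1}$/(km/mol) only at the
spectroscopy boundary.

### Density and Fock conventions

The package fixes one set of closed-shell conventions (`R/scf.R`) and uses
it in every module:

* $P = C_\mathrm{occ} C_\mathrm{occ}^T$ is the contraction density; the
  physical AO density is $D = 2P$.
* $G[X] = 2J[X] - c_x K[X]$ is the Coulomb/exchange contraction; the Fock
  matrix is $F = h + G[P] + V^{xc}$ and the energy
  $E = E_{nn} + 2\,\mathrm{tr}(Ph) + \mathrm{tr}(P\,G[P]) + E_{xc}$.
* $W = C_\mathrm{occ}\,\mathrm{diag}(\varepsilon_\mathrm{occ})\,C_\mathrm{occ}^T$
  is the energy-weighted density (stored as $W_\mathrm{energy} = 2W$).

These choices propagate into the coupled-perturbed equations and the
Hessian assembly; their mutual consistency is what the finite-difference
oracles certify.

## Integral evaluation

Two-electron repulsion integrals are computed per shell quartet in nine
stages: Boys-function auxiliaries, vertical recursions raising angular
momentum on the second ket and second bra centers (vectorized over all
primitive quartets of the contracted shells), early contraction, a
horizontal ket transfer, the ket Cartesian→spherical transformation, a
horizontal bra transfer in the resulting mixed representation, the bra
spherical transformation, and distribution into Fock/gradient/Hessian
accumulators. Two transcription details deserve a note because both were
fixed by derivation rather than convention:

* The ket transfer coefficient follows from
  $(x'-C) = (x'-D) + (D-C)$, i.e. the transfer that raises angular
  momentum on the first ket center multiplies the lower block by
  $(D-C)_i$; with the opposite sign the engine loses the bra↔ket
  permutational symmetry of $(ij|kl)$, which the property tests would
  catch immediately.
* The one-center second-derivative rule is obtained by composing the
  primitive shift rule
  $\partial/\partial B_i\,\chi_b = 2\zeta\,\chi_{b+1_i} - N_i(b)\,\chi_{b-1_i}$
  with itself, which produces $\delta_{ij}$ cross terms:
  $$\partial^2_{B_iB_j}\chi_b = 4\zeta^2 \chi_{b+1_i+1_j}
    - 2\zeta\left[(N_i(b)+\delta_{ij})\chi_{b+1_j-1_i} + N_j(b)\chi_{b+1_i-1_j}\right]
    + N_j(b)(N_i(b)-\delta_{ij})\chi_{b-1_i-1_j}.$$
  A transcription that drops the $\delta_{ij}$ terms fails the
  finite-difference oracle; the oracle is the arbiter.

The Boys function is evaluated by an ascending series for the highest
order followed by stable downward recursion for $T < 35$, and the
closed-form $F_0 = \tfrac12\sqrt{\pi/T}$ with upward recursion (keeping
the $e^{-T}$ term) above; absolute accuracy is at the $10^{-13}$ level
over $T \in [0, 10^6]$. Coincident centers need no special casing — the
$T \to 0$ limit of the recursions is regular.

### Geometric derivatives by weighted early contraction

Because segmented contraction coefficients do not depend on geometry,
differentiating a contracted quartet reduces to contracting the same
primitive recursion tables with *exponent-weighted* vectors
($c \cdot (2\alpha)^k$ per differentiated slot) and assembling
raised/lowered angular targets. One quartet environment therefore serves
the plain integrals, all twelve first derivatives and all 78 second
derivatives. An alternative route — differentiating the horizontal
transfer itself, which picks up Kronecker-δ couplings to lower-derivative
blocks because the transfer distance depends on the differentiated
center — is implemented in `ghrr_transfer()` and kept in agreement with
the direct route to machine precision by the test suite. Gradient and
Hessian contributions are accumulated quartet-by-quartet by double
contraction with density matrices (no derivative integral is ever stored
globally), with the 8-fold permutational symmetry handled through a
symmetrized density weight per canonical quartet.

One-electron integrals use the Hermite (McMurchie–Davidson) expansion — a
deliberately different formulation, so the one- and two-electron codes do
not share recursion kernels. Their derivatives use the same shift rule,
and the nuclear-attraction operator-center derivative is closed by
translational invariance, which makes the per-atom derivative matrices sum
exactly to zero.

## Response and Hessian assembly

With $C^\xi = C U^\xi$ and the orthonormality-fixed occupied–occupied
block $U^\xi_{ij} = -\tfrac12 \tilde S^\xi_{ij}$, the occupied–virtual
response solves
$$(\varepsilon_a - \varepsilon_i)\,U^\xi_{ai} + G_{ai}[\Delta P_U] = -R^\xi_{ai},
\qquad R^\xi_{ai} = \tilde F^{(\xi)}_{ai} - \varepsilon_i \tilde S^{(\xi)}_{ai}
+ G_{ai}[\Delta P_S],$$
where $\Delta P_U$ and $\Delta P_S$ are the AO back-transformations of the
$U$ and overlap pieces of the density response. All $3N$ systems are
solved in one shared subspace: preconditioned residuals
($1/(\varepsilon_a-\varepsilon_i)$ diagonal) are orthonormalized into a
common trial space, the projected equations are solved exactly, converged
right-hand sides are frozen, and the default max-norm tolerance is
$10^{-8}$ (tight enough that the response term of the Hessian is symmetric
to $10^{-9}$ without relying on the final symmetrization). A dense direct
solve of the explicit singlet orbital-Hessian matrix serves as the oracle
at desk scale.

The Hessian is assembled as the exact geometric derivative of the analytic
gradient: skeleton second derivatives (nuclear repulsion, one-electron,
two-electron double contraction, energy-weighted overlap) plus the
response term $2\,\mathrm{tr}(P^\xi F^{(\zeta)}) - 2\,\mathrm{tr}(W^\xi S^{(\zeta)})$,
with $P^\xi$ and $W^\xi$ built from $U^\xi$ and the total derivative Fock.
Correctness is defined by the finite-difference-of-gradient oracle, not by
formula transcription. The dipole gradient combines the nuclear charges,
the perturbed density against the dipole integrals, and the
dipole-integral derivatives at a **fixed origin** (center of nuclear
charge of the reference geometry); for neutral molecules intensities are
origin independent, and for ions the choice is recorded with the result.
Under rigid translation the rows of $d\mu/dx$ per component sum to the
total charge — the sum rule the tests assert for both neutral water and an
oxonium cation.

## Exchange–correlation layer

The XC machinery exists to exercise the full GGA chain rule needed by
Hessians: the frozen-density second-derivative assembly, the perturbed XC
matrix entering the coupled-perturbed right-hand sides, and the kernel
contraction entering the iterations. Functionals are a provider interface
returning spin-resolved derivative fields; built-ins are Slater exchange
and two analytic toy functionals ($c\rho^2$ and $c\sigma$) whose closed
forms make every chain-rule term testable in isolation. Production hybrid
functionals can be supplied through the same interface; none is required
by the test surface.

Two deliberate approximations:

* **Fixed-weight convention.** Grid points and weights are frozen at the
  reference geometry in all geometric XC derivatives; the
  finite-difference oracles use the same convention, so the comparison is
  exact rather than grid-limited. A numerical strict mode that adds the
  weight response is available for the gradient
  (`xc_gradient(weight_derivatives = TRUE)`); the Hessian-level weight
  response is not implemented. Consequences are visible where expected:
  the self-consistent LDA gradient test against full finite differences
  (which *do* rebuild the grid) is asserted at $10^{-5}$ rather than
  $10^{-8}$, the size of the neglected weight response on the medium grid.
* **Product angular grid.** The molecular grid is Gauss–Chebyshev radial
  (rational map, element-dependent scale) × Gauss–Legendre-in-$\cos\theta$
  × uniform-$\phi$ angular, with three-iteration fuzzy-cell Becke
  partitioning. Tabulated octahedral angular grids are the more common
  choice at production scale because they need fewer points per spherical
  harmonic order; the product rule was chosen because it is generated
  entirely by code (no large coefficient tables to transcribe) and meets
  the package's accuracy contracts — the `medium` preset integrates a
  converged water density to $10^{-6}$ electrons and `fine` to
  $10^{-7}$. Preset sizes (radial × θ × φ): coarse 30×8×16, medium
  70×16×32, fine 75×18×36, veryfine 99×26×52; `fine` is the default and
  plays the role of a production-quality setting.

## Vibrational analysis and spectra

The mass-weighted Hessian is diagonalized in the orthogonal complement of
the Eckart translation/rotation space, so projection returns *exactly*
$3N-6$ modes ($3N-5$ for linear molecules, detected by moment-of-inertia
degeneracy); without projection all $3N$ eigenvalues are reported and
imaginary modes appear as negative wavenumbers (never complex types).
Atomic masses default to the most-abundant-isotope table — the common
quantum-chemistry convention — and can be overridden per atom.
Intensities use the CODATA-derived prefactor
$\frac{1}{4\pi\varepsilon_0}\frac{N_A\pi}{3c^2} \approx 974.88$
km/mol·amu/e². The partial-Hessian path extracts the Hessian subblock and
the matching rows of the *full-system* dipole gradient — no re-derivation
for the fragment — which is the established way to isolate the effect of
neglecting inter-subsystem coupling from any fragment-capping scheme.
Spectra are Lorentzian by default (HWHM $\gamma$, each line integrating to
$A_k$), with a Gaussian shape behind a flag; the default grid spacing of
1 cm$^{-1}$ over [min − 10γ, max + 10γ] resolves the γ = 7.5–10 cm$^{-1}$
settings typical of protein amide-band work, and an optional common
scaling factor (e.g. 0.957 in that context) multiplies frequencies only.

## The synthetic large-system generator

`synthetic_hessian_system()` emulates the *shape* of a protein-sized
normal-mode problem: ~1150 atoms with a protein-like H/C/N/O/S
composition, a symmetric positive-definite mass-weighted Hessian with the
six rigid-body directions projected into its exact null space, mid-IR
frequency coverage (~150–3300 cm$^{-1}$), and a dipole-gradient matrix
obeying the total-charge sum rule. It is first-class, seeded, and
deterministic. What it does **not** emulate: any electronic-structure
origin of the couplings, band structure (amide clustering), or realistic
intensity distributions. Tests built on it therefore establish the
*bookkeeping* of large-system mode counting and subsystem extraction
(3450 modes for 1152 atoms; 1464- and 1992-dimensional subblocks for
488/664-atom subsets), not spectroscopic realism.

## Numerical choices and degenerate inputs

* Finite-difference oracle steps: $10^{-4}$ bohr for first derivatives of
  integrals, $10^{-3}$ bohr for energies and all second differences
  (two-step central; Richardson extrapolation where $10^{-7}$ agreement is
  asserted on second derivatives). These balance truncation against
  round-off at double precision.
* SCF: symmetric orthogonalization with canonical fallback below an
  overlap eigenvalue of $10^{-8}$; Pulay DIIS on the commutator with a
  subspace of ≤ 10; core-Hamiltonian guess; convergence is demanded on
  both the energy change and the commutator max-norm (the production-style
  default of $10^{-6}$ is deliberately applied to *both* quantities).
* Screening: Cauchy–Schwarz bounds per shell pair, default threshold
  $10^{-12}$, applied identically in Fock builds and all derivative
  passes; a zero threshold disables screening exactly.
* Ties and degeneracies: the coupled-perturbed solver refuses
  occupied–virtual gaps below $10^{-8}$ (ill-conditioned response), and
  the vibrational module refuses non-symmetric Hessians and non-positive
  masses outright rather than repairing them.
* Determinism: fixed summation order per quartet; identical inputs give
  bit-identical Fock matrices and Hessian archives. Random seeds appear
  only in the synthetic generator and test-case sampling, never in the
  scientific pipeline.

## Problem sizes used by the shipped tests

The suite runs entirely on desk-scale fixtures chosen so every oracle is
exact or FD-limited: H₂, H₂O, NH₃ in STO-3G for SCF/gradient/Hessian
checks, H₂O in def2-SV(P) for the full-quartet engine comparison (1540
canonical shell quartets), formamide/STO-3G for the analytic-vs-FD
intensity comparison (36 displaced SCF solutions), random s/p/d shell sets
for property-style quartet tests, and the seeded 1152-atom synthetic
system for large-system bookkeeping. The command-line layer is exercised
on water end to end.

## Known limitations

Open-shell states, ECPs, $\ell > 4$, meta-GGA/range-separated functionals,
Raman intensities, anharmonic corrections and thermochemistry are not
implemented. The Hessian-level grid-weight response is approximated as
described above. The pure-R engine favors transparency over speed: it is
intended for method study and desk-scale molecules, not production runs on
hundreds of atoms — although the algorithms (early contraction, shared
recursion tables for all derivative orders, subspace response solver) are
the ones that scale.
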