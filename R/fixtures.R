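# Bundled fixture molecules and the synthetic large-system Hessian
# generator used for desk-scale analyses of protein-sized mode counting
# and partial-Hessian subsystem behavior.

.fixture_geometries <- list(
  h2 = list(
    elements = c("H", "H"),
    # R = 1.4 bohr, the classic minimal-basis test separation
    ang = matrix(c(0, 0, 0, 0, 0, 0.740848095288), 2, 3, byrow = TRUE)),
  h2o = list(
    elements = c("O", "H", "H"),
    # r(OH) = 0.9572 A, HOH = 104.52 deg
    ang = matrix(c(0, 0, 0.1173,
                   0, 0.7572, -0.4692,
                   0, -0.7572, -0.4692), 3, 3, byrow = TRUE)),
  nh3 = list(
    elements = c("N", "H", "H", "H"),
    # r(NH) = 1.0116 A, HNH = 106.7 deg
    ang = matrix(c(0, 0, 0,
                   0.9372, 0, -0.3809,
                   -0.4686, 0.8116, -0.3809,
                   -0.4686, -0.8116, -0.3809), 4, 3, byrow = TRUE)),
  formamide = list(
    elements = c("C", "O", "N", "H", "H", "H"),
    # planar HCONH2 near the experimental structure
    ang = matrix(c(0.0000, 0.0000, 0.0000,
                   1.2190, 0.0000, 0.0000,
                   -0.7700, 1.1120, 0.0000,
                   -0.5150, -0.9700, 0.0000,
                   -1.7680, 1.1040, 0.0000,
                   -0.3280, 2.0120, 0.0000), 6, 3, byrow = TRUE)),
  water_dimer = list(
    elements = c("O", "H", "H", "O", "H", "H"),
    ang = matrix(c(-1.551007, -0.114520, 0.000000,
                   -1.934259, 0.762503, 0.000000,
                   -0.599677, 0.040712, 0.000000,
                   1.350625, 0.111469, 0.000000,
                   1.680398, -0.373741, -0.758561,
                   1.680398, -0.373741, 0.758561), 6, 3, byrow = TRUE))
)

#' Bundled fixture molecules
#'
#' @param name one of `"h2"`, `"h2o"`, `"nh3"`, `"formamide"`,
#'   `"water_dimer"`.
#' @return a `molvib_molecule` (coordinates converted to bohr).
#' @export
fixture_molecule <- function(name) {
  g <- .fixture_geometries[[name]]
  if (is.null(g)) {
    stop("unknown fixture: ", name, " (available: ",
         paste(names(.fixture_geometries), collapse = ", "), ")",
         call. = FALSE)
  }
  molecule(g$elements, g$ang / physical_constants()$bohr_angstrom)
}

#' Synthetic protein-scale Hessian system
#'
#' Generates a reproducible stand-in for a large-molecule normal-mode
#' problem: a nonlinear random geometry with protein-like elemental
#' composition, a symmetric positive-definite mass-weighted Hessian with
#' the six rigid-body directions projected into its exact null space, and
#' a dipole-gradient matrix obeying the total-charge translational sum
#' rule. Frequencies span the mid-infrared range typical of organic
#' molecules. Synthetic: not derived from an electronic-structure
#' calculation.
#'
#' @param n_atoms number of atoms (default 1152, a ubiquitin-sized system).
#' @param seed integer seed for reproducibility.
#' @param total_charge charge entering the dipole-gradient sum rule.
#' @return list with `elements`, `coords` (bohr), `masses` (amu),
#'   `H` (3N x 3N Cartesian Hessian, hartree/bohr^2), `dmu` (3N x 3, e),
#'   `seed`.
#' @export
synthetic_hessian_system <- function(n_atoms = 1152L, seed = 7L,
                                     total_charge = 0) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  els <- sample(c("H", "C", "N", "O", "S"), n_atoms, replace = TRUE,
                prob = c(0.50, 0.32, 0.09, 0.085, 0.005))
  info <- element_info(els)
  # random globular geometry, ~ 2 bohr mean spacing
  coords <- matrix(rnorm(3 * n_atoms), n_atoms, 3) *
    (2.0 * n_atoms^(1 / 3) / 2)
  n3 <- 3L * n_atoms
  # SPD mass-weighted Hessian: low-rank random part plus a positive shift,
  # scaled so mode frequencies land in the mid-IR range
  k <- min(n3, 200L)
  Xr <- matrix(rnorm(k * n3), k, n3)
  conv <- freq_conversion_factor()
  lam_hi <- (3300 / conv)^2   # ~3300 cm^-1
  lam_lo <- (150 / conv)^2    # ~150 cm^-1 floor
  B <- crossprod(Xr) * (lam_hi / (4 * k))
  Vr <- rigid_body_space(coords, info$mass)
  Pr <- diag(n3) - tcrossprod(Vr)
  Hmw <- Pr %*% (B + lam_lo * diag(n3)) %*% Pr
  Hmw <- (Hmw + t(Hmw)) / 2
  sq <- sqrt(rep(info$mass, each = 3))
  H <- Hmw * tcrossprod(sq)
  dmu <- matrix(rnorm(n3 * 3, sd = 0.3), n3, 3)
  # enforce the translational sum rule per dipole component
  for (d in 1:3) {
    rows <- seq(d, n3, by = 3)
    dmu[rows, d] <- dmu[rows, d] - (sum(dmu[rows, d]) - total_charge) / n_atoms
  }
  list(elements = els, coords = coords, masses = info$mass, H = H,
       dmu = dmu, seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a fixture with an expected-value manifest
#'
#' Writes the fixture geometry as XYZ together with a JSON manifest of
#' oracle-derived reference values (minimal-basis SCF energy, gradient
#' checks against the finite-difference oracle). For
#' `"synthetic_hessian_1152"` the manifest records the generator seed and
#' summary invariants (mode count, frequency range) instead of the dense
#' matrix, which is regenerated deterministically from the seed.
#'
#' @param name fixture name (see [fixture_molecule()]) or
#'   `"synthetic_hessian_1152"`.
#' @param dir output directory.
#' @param seed seed for the synthetic system.
#' @return paths of the written files, invisibly.
#' @export
make_fixture <- function(name, dir = ".", seed = 7L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (name == "synthetic_hessian_1152") {
    sys <- synthetic_hessian_system(1152L, seed = seed)
    vib <- vibrational_analysis(sys$H, sys$dmu, sys$coords, sys$masses)
    man <- list(name = name, seed = seed, n_atoms = 1152L,
                n_modes = vib$n_modes,
                freq_range_cm1 = range(vib$frequencies),
                generator = "synthetic_hessian_system")
    mpath <- file.path(dir, paste0(name, ".manifest.json"))
    jsonlite::write_json(man, mpath, auto_unbox = TRUE, digits = NA)
    return(invisible(mpath))
  }
  mol <- fixture_molecule(name)
  xpath <- file.path(dir, paste0(name, ".xyz"))
  write_xyz(mol, xpath, comment = paste("molvib fixture:", name))
  basis <- load_basis("sto-3g", mol)
  scf <- run_scf(mol, basis, conv = 1e-9)
  gr <- analytic_gradient(scf)
  fd1 <- fd_derivative(function(m) {
    run_scf(m, load_basis("sto-3g", m), conv = 1e-10)$E_total
  }, mol, 1, 3, step = 1e-3, stencil = 4)
  man <- list(name = name, n_atoms = length(mol$elements),
              total_charge = mol$total_charge,
              scf_energy_sto3g = scf$E_total,
              grad_max_abs = max(abs(gr$g)),
              grad_translation_norm = max(abs(colSums(gr$by_atom))),
              fd_check_coordinate = "atom 1, z",
              fd_gradient_value = fd1,
              analytic_gradient_value = gr$g[3],
              fd_abs_deviation = abs(fd1 - gr$g[3]))
  mpath <- file.path(dir, paste0(name, ".manifest.json"))
  jsonlite::write_json(man, mpath, auto_unbox = TRUE, digits = NA)
  invisible(c(xpath, mpath))
}
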