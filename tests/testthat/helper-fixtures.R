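# Shared cached fixtures: expensive reference states computed once per
# test run. Oracle tolerances are collected here so every file asserts
# against the same constants.

.molvib_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.molvib_test_cache[[key]])) {
    .molvib_test_cache[[key]] <- force(expr)
  }
  .molvib_test_cache[[key]]
}

TOL <- list(
  fd_first = 1e-8,        # first derivatives of integrals vs FD (step 1e-4)
  fd_second = 1e-6,       # second derivatives vs two-step FD (step 1e-3)
  fd_energy_grad = 1e-6,  # analytic gradient vs FD of the SCF energy
  fd_grad_hess = 1e-5,    # analytic Hessian vs FD of the analytic gradient
  engine_ref = 1e-10,     # early- vs late-contraction ERI paths
  perm = 1e-12,           # permutational symmetry of ERI quartets
  cphf_dense = 1e-8,      # subspace vs dense coupled-perturbed solve
  boys = 1e-13
)

scf_h2 <- function() cached("scf_h2", {
  mol <- fixture_molecule("h2")
  run_scf(mol, load_basis("sto-3g", mol), conv = 1e-10)
})

scf_h2o <- function() cached("scf_h2o", {
  mol <- fixture_molecule("h2o")
  run_scf(mol, load_basis("sto-3g", mol), conv = 1e-10)
})

scf_nh3 <- function() cached("scf_nh3", {
  mol <- fixture_molecule("nh3")
  run_scf(mol, load_basis("sto-3g", mol), conv = 1e-10)
})

hessian_h2o <- function() cached("hessian_h2o", {
  analytic_hessian(scf_h2o(), cphf_tol = 1e-10)
})

dipgrad_h2o <- function() cached("dipgrad_h2o", {
  hh <- hessian_h2o()
  dipole_gradient(scf_h2o(), response = list(rhs = hh$rhs, cphf = hh$response))
})

# random small shell set (s, p, d mixtures on four centers) for
# property-style quartet tests
random_shell_basis <- function(seed = 42, lmax = 2) {
  set.seed(seed)
  mol <- molecule(c("O", "C", "O", "C"),
                  matrix(rnorm(12, sd = 1.3), 4, 3), total_charge = 0)
  mk <- function(l, atom) {
    np <- sample(1:3, 1)
    s <- molvib:::normalize_shell(l, sort(runif(np, 0.2, 4), decreasing = TRUE),
                                  runif(np, -0.5, 1))
    s$atom <- atom
    s
  }
  shells <- list(mk(0L, 1L), mk(1L, 2L), mk(min(2L, lmax), 3L),
                 mk(1L, 4L), mk(min(2L, lmax), 1L), mk(0L, 3L))
  nsph <- vapply(shells, function(s) 2L * s$l + 1L, 0L)
  basis <- structure(list(
    shells = shells, ao_offsets = cumsum(c(1L, nsph))[seq_along(shells)],
    cart_offsets = seq_along(shells), n_ao = sum(nsph), n_cart = 0L,
    name = "random"), class = "molvib_basis")
  list(mol = mol, basis = basis)
}

# rigid rotation helper
rotate_molecule <- function(mol, axis = c(0, 0, 1), angle = 0.3) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  mol$coords <- mol$coords %*% t(R)
  list(mol = mol, R = R)
}
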