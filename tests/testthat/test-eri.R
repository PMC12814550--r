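# Boys function and the shell-quartet ERI engine against closed forms,
# quadrature, the late-contraction reference path, and its permutational
# symmetries.

test_that("Boys function matches limits, quadrature and asymptotics", {
  expect_equal(drop(boys(4, 0)), 1 / (2 * (0:4) + 1), tolerance = 1e-15)
  q <- integrate(function(t) exp(-t^2), 0, 1, rel.tol = 1e-14)$value
  expect_equal(boys(0, 1)[1, 1], q, tolerance = TOL$boys)
  expect_equal(boys(0, 1e4)[1, 1], 0.5 * sqrt(pi / 1e4), tolerance = 1e-12)
  expect_error(boys(2, -1), "nonnegative")
  # quadrature across orders and the small/large-T switchover
  for (T in c(0.1, 5, 20, 34.9, 35.1, 80)) {
    for (m in c(0, 3, 8)) {
      ref <- integrate(function(t) t^(2 * m) * exp(-T * t^2), 0, 1,
                       rel.tol = 1e-13, abs.tol = 1e-15)$value
      expect_lt(abs(boys(8, T)[1, m + 1] - ref), TOL$boys)
    }
  }
})

test_that("downward recursion is stable: F_0 rebuilt from F_mmax", {
  for (T in c(0.5, 5, 20, 50)) {
    mmax <- 16
    F <- drop(boys(mmax, T))
    f0 <- F[mmax + 1]
    for (m in mmax:1) f0 <- (2 * T * f0 + exp(-T)) / (2 * m - 1)
    expect_equal(f0, F[1], tolerance = 1e-12)
  }
})

test_that("concentric s-primitive quartet matches the closed form", {
  alpha <- 0.7
  mol <- molecule("H", matrix(0, 1, 3), total_charge = 1L)
  sh <- list(l = 0L, exponents = alpha, coefficients = 1, coef = 1, atom = 1L)
  basis <- structure(list(shells = list(sh, sh, sh, sh),
                          ao_offsets = 1:4, cart_offsets = 1:4,
                          n_ao = 4L, n_cart = 4L, name = "manual"),
                     class = "molvib_basis")
  v <- eri_quartet(mol, basis, 1, 2, 3, 4)[1, 1, 1, 1]
  ref <- 2 * pi^2.5 / ((2 * alpha)^2 * sqrt(4 * alpha)) * 1  # F_0(0) = 1
  expect_equal(v, ref, tolerance = 1e-13)
})

test_that("early-contraction engine equals the late-contraction reference", {
  rb <- random_shell_basis(seed = 42)
  set.seed(7)
  for (t in 1:10) {
    q <- sample(seq_along(rb$basis$shells), 4, replace = TRUE)
    v <- eri_quartet(rb$mol, rb$basis, q[1], q[2], q[3], q[4])
    r <- eri_quartet_ref(rb$mol, rb$basis, q[1], q[2], q[3], q[4])
    expect_lt(max(abs(v - r)), TOL$engine_ref)
  }
})

test_that("quartets carry the full 8-fold permutational symmetry", {
  rb <- random_shell_basis(seed = 11)
  perms <- list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(2, 1, 4, 3), c(3, 4, 1, 2),
                c(4, 3, 1, 2), c(3, 4, 2, 1), c(4, 3, 2, 1))
  set.seed(8)
  for (t in 1:8) {
    q <- sample(seq_along(rb$basis$shells), 4, replace = TRUE)
    v <- eri_quartet(rb$mol, rb$basis, q[1], q[2], q[3], q[4])
    for (p in perms) {
      img <- eri_quartet(rb$mol, rb$basis, q[p[1]], q[p[2]], q[p[3]], q[p[4]])
      expect_lt(max(abs(aperm(v, p) - img)), TOL$perm)
    }
  }
})

test_that("Schwarz bounds are conservative and decay with distance", {
  mol <- fixture_molecule("h2o")
  basis <- load_basis("sto-3g", mol)
  scr <- schwarz_bounds(mol, basis, threshold = 1e-12)
  ns <- length(basis$shells)
  set.seed(3)
  for (t in 1:12) {
    q <- sample(ns, 4, replace = TRUE)
    v <- max(abs(eri_quartet(mol, basis, q[1], q[2], q[3], q[4])))
    expect_lte(v, scr$Q[q[1], q[2]] * scr$Q[q[3], q[4]] + 1e-12)
  }
  far <- molecule(c("H", "H"), matrix(c(0, 0, 0, 0, 0, 50), 2, 3, byrow = TRUE))
  sf <- schwarz_bounds(far, load_basis("sto-3g", far))
  expect_lt(sf$Q[1, 2], 1e-12)
})

test_that("screened and unscreened Fock builds agree", {
  s <- scf_h2o()
  mol <- s$mol; basis <- s$basis
  scr0 <- schwarz_bounds(mol, basis, threshold = 0)
  scr <- schwarz_bounds(mol, basis, threshold = 1e-12)
  F0 <- build_fock_2e(s$P, mol, basis, c_x = 1, screen = scr0)
  F1 <- build_fock_2e(s$P, mol, basis, c_x = 1, screen = scr)
  expect_lt(max(abs(F0 - F1)), 1e-10)
  # zero density gives a zero Fock
  Z <- build_fock_2e(matrix(0, basis$n_ao, basis$n_ao), mol, basis, 1, scr)
  expect_equal(Z, matrix(0, basis$n_ao, basis$n_ao))
  expect_error(build_fock_2e(matrix(0, 2, 2), mol, basis, 1, scr), "must be")
})

test_that("Fock exchange and 2e energy agree with the explicit tensor", {
  s <- scf_h2()
  G <- s$eri
  mol <- s$mol; basis <- s$basis
  scr <- schwarz_bounds(mol, basis, threshold = 0)
  F0 <- build_fock_2e(s$P, mol, basis, c_x = 0, screen = scr)
  F1 <- build_fock_2e(s$P, mol, basis, c_x = 1, screen = scr)
  n <- basis$n_ao
  K <- matrix(matrix(aperm(G, c(1, 4, 3, 2)), n * n, n * n) %*%
                as.vector(s$P), n, n)
  expect_equal(F0 - F1, K, tolerance = 1e-12)
  # tr(P G[P]) is the two-electron energy
  s3 <- scf_h2o()
  e2 <- sum(s3$P * fock_from_tensor(s3$eri, s3$P, 1))
  Fd <- build_fock_2e(s3$P, s3$mol, s3$basis, 1,
                      schwarz_bounds(s3$mol, s3$basis, 0))
  expect_equal(sum(s3$P * Fd), e2, tolerance = 1e-10)
})

test_that("rigid rotation leaves the SCF energy invariant", {
  s <- scf_h2o()
  rot <- rotate_molecule(s$mol, axis = c(1, 2, 0.5), angle = 0.7)
  s2 <- run_scf(rot$mol, load_basis("sto-3g", rot$mol), conv = 1e-10)
  expect_equal(s2$E_total, s$E_total, tolerance = 1e-10)
})
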