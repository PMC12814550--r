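# Coupled-perturbed equations, analytic gradient/Hessian assembly, and
# dipole-moment gradients against FD and dense oracles.

test_that("auxiliary Fock map is zero at U = 0 and linear", {
  s <- scf_h2o()
  nv <- length(s$eps) - s$n_occ
  U0 <- matrix(0, nv, s$n_occ)
  expect_equal(auxiliary_fock(U0, s), U0)
  set.seed(4)
  X <- matrix(rnorm(nv * s$n_occ), nv)
  Y <- matrix(rnorm(nv * s$n_occ), nv)
  lhs <- auxiliary_fock(2.5 * X - 0.7 * Y, s)
  rhs <- 2.5 * auxiliary_fock(X, s) - 0.7 * auxiliary_fock(Y, s)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("auxiliary Fock matches the dense orbital-Hessian action (H2)", {
  s <- scf_h2()
  no <- s$n_occ; n <- length(s$eps); nv <- n - no
  Gm <- s$eri
  for (mode in 1:4) Gm <- molvib:::mode_mult(Gm, t(s$C), mode)
  set.seed(2)
  U <- matrix(rnorm(nv * no), nv, no)
  ref <- matrix(0, nv, no)
  for (a in seq_len(nv)) for (i in seq_len(no)) {
    for (b in seq_len(nv)) for (j in seq_len(no)) {
      av <- no + a; bv <- no + b
      ref[a, i] <- ref[a, i] +
        (4 * Gm[av, i, bv, j] - Gm[av, j, bv, i] - Gm[av, bv, i, j]) * U[b, j]
    }
  }
  expect_lt(max(abs(auxiliary_fock(U, s) - ref)), 1e-10)
})

test_that("zero right-hand sides give zero response immediately", {
  s <- scf_h2o()
  nv <- length(s$eps) - s$n_occ
  z <- lapply(1:3, function(k) matrix(0, nv, s$n_occ))
  sol <- solve_cphf(z, s)
  expect_identical(sol$iterations, 1L)
  expect_equal(sol$U[[1]], z[[1]])
})

test_that("subspace solutions equal the dense direct solve and scale
          linearly with the right-hand side", {
  s <- scf_h2o()
  rhs <- build_rhs(s)
  sol <- solve_cphf(rhs, s, tol = 1e-10)
  dn <- dense_cphf_solve(rhs, s)
  for (k in seq_along(sol$U)) {
    expect_lt(max(abs(sol$U[[k]] - dn[[k]])), TOL$cphf_dense)
  }
  # scaling c R -> c U
  sc <- solve_cphf(lapply(rhs$R, function(R) 10 * R), s, tol = 1e-9)
  expect_lt(max(abs(sc$U[[1]] - 10 * sol$U[[1]])), 1e-7)
  # solving subsets of right-hand sides reproduces the batch solution
  one <- solve_cphf(rhs$R[3], s, tol = 1e-10)
  expect_lt(max(abs(one$U[[1]] - sol$U[[3]])), 1e-9)
})

test_that("homonuclear symmetry and zero-input contracts of the RHS", {
  s <- scf_h2()
  rhs <- build_rhs(s)
  expect_lt(max(abs(rhs$R[[3]] + rhs$R[[6]])), 1e-9)  # z of A vs z of B
  # all derivative inputs zeroed -> R = 0
  skel <- molvib:::skeleton_derivatives(s, order = 1L)
  skel$Fd[] <- 0; skel$Sd[] <- 0
  rz <- build_rhs(s, skel = skel)
  expect_equal(max(abs(rz$R[[1]])), 0)
})

test_that("analytic gradient matches 4-point FD of the SCF energy", {
  s <- scf_h2o()
  gr <- analytic_gradient(s)
  for (k in c(2L, 3L, 5L, 9L)) {
    at <- (k - 1L) %/% 3L + 1L; ax <- (k - 1L) %% 3L + 1L
    fd <- fd_derivative(function(m) {
      run_scf(m, load_basis("sto-3g", m), conv = 1e-11)$E_total
    }, s$mol, at, ax, step = 1e-3, stencil = 4)
    expect_lt(abs(fd - gr$g[k]), TOL$fd_energy_grad)
  }
  expect_lt(max(abs(colSums(gr$by_atom))), 1e-9)
  expect_error(analytic_gradient(structure(list(converged = FALSE),
                                           class = "molvib_scf")),
               "not converged")
})

test_that("homonuclear diatomic gradient is purely axial and antisymmetric", {
  s <- scf_h2()
  gr <- analytic_gradient(s)
  expect_equal(gr$by_atom[1, ], -gr$by_atom[2, ], tolerance = 1e-10)
  expect_lt(max(abs(gr$by_atom[, 1:2])), 1e-10)
})

test_that("analytic Hessian agrees with FD of the analytic gradient (H2)", {
  s <- scf_h2()
  hh <- analytic_hessian(s, cphf_tol = 1e-10)
  expect_lt(max(abs(hh$H - t(hh$H))), 1e-9)
  for (k in c(3L, 6L)) {
    at <- (k - 1L) %/% 3L + 1L; ax <- (k - 1L) %% 3L + 1L
    fd <- fd_derivative(function(m) {
      analytic_gradient(run_scf(m, load_basis("sto-3g", m), conv = 1e-11))$g
    }, s$mol, at, ax, step = 1e-3)
    expect_lt(max(abs(fd - hh$H[, k])), TOL$fd_grad_hess)
  }
})

test_that("H2 at its equilibrium distance has one positive stretch mode and
          clean rigid-body structure", {
  # locate the minimal-basis equilibrium along the bond by Newton steps on
  # the analytic gradient
  R <- 1.4
  for (it in 1:12) {
    m <- molecule(c("H", "H"), matrix(c(0, 0, 0, 0, 0, R), 2, 3, byrow = TRUE))
    s <- run_scf(m, load_basis("sto-3g", m), conv = 1e-11)
    g <- analytic_gradient(s)$g[6]
    h <- fd_derivative(function(mm) {
      analytic_gradient(run_scf(mm, load_basis("sto-3g", mm), conv = 1e-11))$g[6]
    }, m, 2, 3, step = 1e-3)
    R <- R - g / h
    if (abs(g) < 1e-10) break
  }
  m <- molecule(c("H", "H"), matrix(c(0, 0, 0, 0, 0, R), 2, 3, byrow = TRUE))
  s <- run_scf(m, load_basis("sto-3g", m), conv = 1e-11)
  hh <- analytic_hessian(s, cphf_tol = 1e-10)
  vib <- vibrational_analysis(hh$H, coords = m$coords, masses = m$masses)
  expect_identical(vib$n_modes, 1L)  # linear molecule: 3N - 5
  expect_gt(vib$frequencies, 0)
  # without projection the five rigid-body eigenvalues are tiny
  vib2 <- vibrational_analysis(hh$H, coords = m$coords, masses = m$masses,
                               project = FALSE)
  expect_lt(max(abs(sort(abs(vib2$frequencies))[1:5])), 1)  # < 1 cm^-1
})

test_that("dipole gradient matches the FD dipole oracle and the charge sum
          rule", {
  s <- scf_h2o()
  dg <- dipgrad_h2o()
  org <- s$oe$origin
  for (k in c(3L, 5L)) {
    at <- (k - 1L) %/% 3L + 1L; ax <- (k - 1L) %% 3L + 1L
    fd <- fd_derivative(function(m) {
      b2 <- load_basis("sto-3g", m)
      s2 <- run_scf(m, b2, conv = 1e-11)
      el <- -vapply(1:3, function(d) {
        sum(s2$D * one_electron_matrices(m, b2, origin = org)$D_dip[[d]])
      }, 0)
      nuclear_dipole(m, origin = org) + el
    }, s$mol, at, ax, step = 1e-3)
    expect_lt(max(abs(fd - dg$dmu[k, ])), 1e-5)
  }
  for (d in 1:3) {
    expect_lt(abs(sum(dg$dmu[seq(d, 9, by = 3), d]) - s$mol$total_charge),
              1e-6)
  }
})

test_that("frequencies and intensities are invariant under rigid rotation", {
  s <- scf_h2o()
  hh <- hessian_h2o()
  dg <- dipgrad_h2o()
  vib <- vibrational_analysis(hh$H, dg$dmu, s$mol$coords, s$mol$masses)
  rot <- rotate_molecule(s$mol, axis = c(0.3, 1, 0.2), angle = 0.8)
  s2 <- run_scf(rot$mol, load_basis("sto-3g", rot$mol), conv = 1e-10)
  hh2 <- analytic_hessian(s2, cphf_tol = 1e-10)
  dg2 <- dipole_gradient(s2, response = list(rhs = hh2$rhs,
                                             cphf = hh2$response))
  vib2 <- vibrational_analysis(hh2$H, dg2$dmu, rot$mol$coords, rot$mol$masses)
  expect_lt(max(abs(vib$frequencies - vib2$frequencies)), 1e-6)
  expect_lt(max(abs(vib$intensities - vib2$intensities)), 1e-8)
})
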