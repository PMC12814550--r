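# One-electron matrices and their geometric derivatives against the
# finite-difference and quadrature oracles.

test_that("one-electron matrices are symmetric with correct structure", {
  s <- scf_h2o()
  oe <- s$oe
  expect_equal(oe$S, t(oe$S))
  expect_equal(oe$T_kin, t(oe$T_kin))
  expect_equal(oe$V_nuc, t(oe$V_nuc))
  expect_true(min(eigen(oe$S, symmetric = TRUE, only.values = TRUE)$values) > 0)
  # single normalized s shell: S = [1]
  he <- molecule("He", matrix(0, 1, 3))
  bhe <- load_basis("sto-3g", he)
  expect_equal(one_electron_matrices(he, bhe)$S, matrix(1, 1, 1),
               tolerance = 1e-14)
})

test_that("off-diagonal overlap matches explicit 3-D quadrature", {
  h2 <- fixture_molecule("h2")
  b <- load_basis("sto-3g", h2)
  oe <- one_electron_matrices(h2, b)
  sh <- b$shells[[1]]
  q <- molvib:::overlap_quadrature(sh$exponents, sh$coef, h2$coords[1, ],
                                   sh$exponents, sh$coef, h2$coords[2, ],
                                   n = 161, half = 10)
  expect_equal(oe$S[1, 2], q, tolerance = 1e-10)
})

test_that("dipole matrices obey the origin-shift identity", {
  s <- scf_h2o()
  mol <- s$mol
  d <- c(0.3, -0.2, 0.5)
  oeB <- one_electron_matrices(mol, s$basis, origin = s$oe$origin + d)
  for (k in 1:3) {
    expect_equal(oeB$D_dip[[k]], s$oe$D_dip[[k]] - d[k] * s$oe$S,
                 tolerance = 1e-12)
  }
})

test_that("first derivatives match central finite differences", {
  mol <- fixture_molecule("h2o")
  basis <- load_basis("sto-3g", mol)
  org <- center_of_charge(mol)
  der <- one_electron_derivatives(mol, basis, order = 1L, origin = org)
  get1 <- function(m, what) {
    o <- one_electron_matrices(m, load_basis("sto-3g", m), origin = org)
    switch(what, S = o$S, T = o$T_kin, V = o$V_nuc, D = o$D_dip[[2]])
  }
  for (k in c(1L, 3L, 5L, 8L)) {
    at <- (k - 1L) %/% 3L + 1L
    cmp <- (k - 1L) %% 3L + 1L
    expect_lt(max(abs(fd_derivative(function(m) get1(m, "S"), mol, at, cmp) -
                        der$dS[, , k])), TOL$fd_first)
    expect_lt(max(abs(fd_derivative(function(m) get1(m, "T"), mol, at, cmp) -
                        der$dT[, , k])), TOL$fd_first)
    expect_lt(max(abs(fd_derivative(function(m) get1(m, "V"), mol, at, cmp) -
                        der$dV[, , k])), TOL$fd_first)
    expect_lt(max(abs(fd_derivative(function(m) get1(m, "D"), mol, at, cmp) -
                        der$dDip[, , 2, k])), TOL$fd_first)
  }
  # translational sum rules
  for (cmp in 1:3) {
    expect_lt(max(abs(der$dS[, , cmp] + der$dS[, , 3 + cmp] +
                        der$dS[, , 6 + cmp])), 1e-10)
    expect_lt(max(abs(der$dT[, , cmp] + der$dT[, , 3 + cmp] +
                        der$dT[, , 6 + cmp])), 1e-10)
    expect_lt(max(abs(der$dV[, , cmp] + der$dV[, , 3 + cmp] +
                        der$dV[, , 6 + cmp])), 1e-10)
    # fixed-origin moment operator: the translational sum of the dipole
    # integral derivatives is delta_(i,component) * S
    oe <- one_electron_matrices(mol, basis, origin = org)
    for (d in 1:3) {
      tot <- der$dDip[, , d, cmp] + der$dDip[, , d, 3 + cmp] +
        der$dDip[, , d, 6 + cmp]
      ref <- if (d == cmp) oe$S else 0 * oe$S
      expect_lt(max(abs(tot - ref)), 1e-10)
    }
  }
  expect_error(one_electron_derivatives(mol, basis, order = 3L),
               "unsupported derivative order")
})

test_that("homonuclear diatomic first derivatives are antisymmetric", {
  h2 <- fixture_molecule("h2")
  der <- one_electron_derivatives(h2, load_basis("sto-3g", h2), order = 1L)
  expect_equal(der$dS[, , 3], -der$dS[, , 6], tolerance = 1e-12)
})

test_that("second derivatives match FD of first derivatives and are
          exchange symmetric", {
  mol <- fixture_molecule("h2o")
  basis <- load_basis("sto-3g", mol)
  org <- center_of_charge(mol)
  der <- one_electron_derivatives(mol, basis, order = 2L, origin = org)
  getd <- function(m, what) {
    d <- one_electron_derivatives(m, load_basis("sto-3g", m), order = 1L,
                                  origin = org)
    switch(what, S = d$dS, T = d$dT, V = d$dV)
  }
  for (k in c(2L, 5L, 9L)) {
    at <- (k - 1L) %/% 3L + 1L
    cmp <- (k - 1L) %% 3L + 1L
    for (what in c("S", "T", "V")) {
      fd2 <- fd_derivative(function(m) getd(m, what), mol, at, cmp,
                           step = 1e-4)
      expect_lt(max(abs(fd2 - der[[paste0("d2", what)]][, , , k])),
                TOL$fd_second)
    }
  }
  expect_equal(der$d2S, aperm(der$d2S, c(1, 2, 4, 3)), tolerance = 1e-12)
  expect_equal(der$d2V, aperm(der$d2V, c(1, 2, 4, 3)), tolerance = 1e-12)
  # contraction with a symmetric density stays (xi, zeta) symmetric
  set.seed(1)
  Dm <- crossprod(matrix(rnorm(basis$n_ao^2), basis$n_ao))
  M <- apply(der$d2S, c(3, 4), function(blk) sum(Dm * blk))
  expect_equal(M, t(M), tolerance = 1e-10)
})
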