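# Molecular grid and the exchange-correlation chain-rule machinery with
# analytic toy functionals (frozen-weight convention throughout).

grid_h2 <- function() cached("grid_h2", build_grid(fixture_molecule("h2"), "coarse"))

test_that("grid weights are positive and integrate Gaussian densities", {
  h <- molecule("H", matrix(0, 1, 3), total_charge = 1L)
  gr <- build_grid(h, "fine")
  expect_true(all(gr$weights > 0))
  # unit-normalized Gaussian density integrates to one
  alpha <- 0.8
  r2 <- rowSums(gr$points^2)
  rho <- (2 * alpha / pi)^1.5 * exp(-2 * alpha * r2)
  expect_equal(sum(gr$weights * rho), 1, tolerance = 1e-8)
  expect_error(build_grid(h, "ultra"), "unknown grid level")
})

test_that("grid integrates the converged density to the electron count", {
  s <- scf_h2o()
  for (lev in c("medium", "fine")) {
    gr <- build_grid(s$mol, lev)
    ao <- eval_ao_grid(s$mol, s$basis, gr$points, max_order = 0L)
    ne <- sum(gr$weights * rowSums((ao[["000"]] %*% s$D) * ao[["000"]]))
    expect_equal(ne, 10, tolerance = 1e-6)
  }
})

test_that("XC potential is the density derivative of the XC energy", {
  s <- scf_h2()
  gr <- grid_h2()
  for (fn in c("toy_rho2", "toy_sigma", "slater")) {
    f <- xc_functional(fn, c = 0.05)
    V <- xc_energy_potential(s$D, s$mol, s$basis, gr, f)$V
    h <- 1e-6
    for (u in 1:2) for (v in u:2) {
      Dp <- s$D; Dp[u, v] <- Dp[u, v] + h
      Dm <- s$D; Dm[u, v] <- Dm[u, v] - h
      fdv <- (xc_energy_potential(Dp, s$mol, s$basis, gr, f)$energy -
                xc_energy_potential(Dm, s$mol, s$basis, gr, f)$energy) / (2 * h)
      expect_lt(abs(fdv - V[u, v]), 1e-9)
    }
  }
})

test_that("Slater energy matches the closed-form Gaussian integral", {
  # single normalized Gaussian density rho = (2a/pi)^(3/2) exp(-2a r^2)
  h <- molecule("H", matrix(0, 1, 3), total_charge = 1L)
  gr <- build_grid(h, "fine")
  alpha <- 0.8
  r2 <- rowSums(gr$points^2)
  rho <- (2 * alpha / pi)^1.5 * exp(-2 * alpha * r2)
  Cx <- 0.75 * (6 / pi)^(1 / 3)
  # E = -2 Cx int (rho/2)^(4/3): closed form for a Gaussian
  closed <- (2 * alpha / pi)^2 / 2^(4 / 3) * (3 * pi / (8 * alpha))^1.5
  e_quad <- sum(gr$weights * (-2 * Cx * (rho / 2)^(4 / 3)))
  expect_equal(e_quad, -2 * Cx * closed, tolerance = 1e-7)
})

test_that("frozen-density XC geometric derivatives match FD oracles", {
  s <- scf_h2()
  gr <- grid_h2()
  for (fn in c("toy_rho2", "toy_sigma", "slater")) {
    f <- xc_functional(fn, c = 0.05)
    exc <- function(m) xc_energy_potential(s$D, m, s$basis, gr, f)$energy
    g <- xc_gradient(s$D, s$mol, s$basis, gr, f)
    for (k in c(3L, 4L)) {
      at <- (k - 1L) %/% 3L + 1L; ax <- (k - 1L) %% 3L + 1L
      expect_lt(abs(fd_derivative(exc, s$mol, at, ax, step = 1e-4) - g[k]),
                1e-8)
    }
    # second-derivative assembly vs FD of the analytic gradient
    H <- xc_hessian_terms(s$D, s$mol, s$basis, gr, f)
    expect_equal(H, t(H), tolerance = 1e-8)
    for (k in c(3L, 4L)) {
      at <- (k - 1L) %/% 3L + 1L; ax <- (k - 1L) %% 3L + 1L
      fdg <- fd_derivative(function(m) xc_gradient(s$D, m, s$basis, gr, f),
                           s$mol, at, ax, step = 1e-4)
      expect_lt(max(abs(fdg - H[, k])), 1e-6)
    }
    # perturbed XC matrix vs frozen-orbital FD
    Fd <- xc_fock_derivative(s$D, s$mol, s$basis, gr, f)
    for (k in c(2L, 6L)) {
      at <- (k - 1L) %/% 3L + 1L; ax <- (k - 1L) %% 3L + 1L
      fdV <- fd_derivative(function(m) {
        xc_energy_potential(s$D, m, s$basis, gr, f)$V
      }, s$mol, at, ax, step = 1e-4)
      expect_lt(max(abs(fdV - Fd[, , k])), 1e-7)
    }
  }
})

test_that("term groups are individually necessary (term-completeness)", {
  s <- scf_h2()
  gr <- grid_h2()
  f <- xc_functional("slater")
  full <- xc_hessian_terms(s$D, s$mol, s$basis, gr, f)
  # dropping the second-perturbed-density group breaks FD agreement
  part <- xc_hessian_terms(s$D, s$mol, s$basis, gr, f,
                           terms = c("rr", "rs", "ss", "gg"))
  fdg <- fd_derivative(function(m) xc_gradient(s$D, m, s$basis, gr, f),
                       s$mol, 1, 3, step = 1e-4)
  expect_lt(max(abs(fdg - full[, 3])), 1e-6)
  expect_gt(max(abs(fdg - part[, 3])), 1e-4)
  fs <- xc_functional("toy_sigma", c = 0.05)
  partb <- xc_fock_derivative(s$D, s$mol, s$basis, gr, fs, terms = "response")
  fullb <- xc_fock_derivative(s$D, s$mol, s$basis, gr, fs)
  expect_gt(max(abs(fullb - partb)), 1e-6)
})

test_that("density-only functionals have no gradient-term contributions", {
  # LDA-limit: no sigma dependence, so every grad(chi) coupling vanishes
  s <- scf_h2()
  gr <- grid_h2()
  f <- xc_functional("toy_rho2", c = 0.05)
  fe <- f$eval(c(0.1, 0.4), c(0.2, 0.1), c(0.2, 0.1))
  expect_identical(fe$f_saa, c(0, 0))
  expect_identical(fe$f_sabsab, c(0, 0))
  # the potential then has no dependence on the density gradient: adding a
  # gradient-only trial perturbation leaves the kernel density term intact
  V <- xc_energy_potential(s$D, s$mol, s$basis, gr, f)$V
  ao <- eval_ao_grid(s$mol, s$basis, gr$points, max_order = 0L)
  rho <- rowSums((ao[["000"]] %*% s$D) * ao[["000"]])
  Vref <- crossprod(ao[["000"]] * (gr$weights * 0.05 * rho), ao[["000"]])
  expect_equal(V, (Vref + t(Vref)) / 2, tolerance = 1e-12)
})

test_that("kernel contraction is linear and matches the analytic toy form", {
  s <- scf_h2()
  gr <- grid_h2()
  f <- xc_functional("toy_rho2", c = 0.05)
  z <- xc_kernel_contraction(matrix(0, 2, 2), s$mol, s$basis, gr, f, D = s$D)
  expect_equal(max(abs(z)), 0)
  set.seed(6)
  X <- crossprod(matrix(rnorm(4), 2)); Y <- crossprod(matrix(rnorm(4), 2))
  lhs <- xc_kernel_contraction(1.3 * X + 0.4 * Y, s$mol, s$basis, gr, f,
                               D = s$D)
  rhs <- 1.3 * xc_kernel_contraction(X, s$mol, s$basis, gr, f, D = s$D) +
    0.4 * xc_kernel_contraction(Y, s$mol, s$basis, gr, f, D = s$D)
  expect_lt(max(abs(lhs - rhs)), 1e-10)
  # for e = c (ra^2 + rb^2): f^xc[X] = c int w (Delta rho) chi chi
  ao <- eval_ao_grid(s$mol, s$basis, gr$points, max_order = 0L)
  drho <- rowSums((ao[["000"]] %*% X) * ao[["000"]])
  ref <- crossprod(ao[["000"]] * (gr$weights * 0.05 * drho), ao[["000"]])
  kk <- xc_kernel_contraction(X, s$mol, s$basis, gr, f, D = s$D)
  expect_equal(kk, (ref + t(ref)) / 2, tolerance = 1e-8)
  # directional FD of the potential
  h <- 1e-5
  fs <- xc_functional("toy_sigma", c = 0.05)
  kfd <- (xc_energy_potential(s$D + h * X, s$mol, s$basis, gr, fs)$V -
            xc_energy_potential(s$D - h * X, s$mol, s$basis, gr, fs)$V) / (2 * h)
  expect_lt(max(abs(xc_kernel_contraction(X, s$mol, s$basis, gr, fs,
                                          D = s$D) - kfd)), 1e-9)
})

test_that("spin-resolved functional fields obey closed-shell symmetry", {
  f <- xc_functional("slater")
  fe <- f$eval(c(0.2, 0.5), c(0.1, 0.3), c(0.1, 0.3))
  # f_rasaa = f_rbsbb etc. reduce to equal alpha/beta fields here
  expect_identical(fe$f_rasaa, fe$f_rasbb)
  expect_true(all(is.finite(unlist(fe))))
})

test_that("LDA-exchange SCF and gradient behave like the HF machinery", {
  m <- fixture_molecule("h2")
  b <- load_basis("sto-3g", m)
  s <- run_scf(m, b, method = list(c_x = 0, functional = xc_functional("slater"),
                                   grid_level = "medium"), conv = 1e-9)
  expect_true(s$converged)
  gr <- analytic_gradient(s)
  for (k in c(3L, 6L)) {
    at <- (k - 1L) %/% 3L + 1L; ax <- (k - 1L) %% 3L + 1L
    fd <- fd_derivative(function(mm) {
      run_scf(mm, load_basis("sto-3g", mm),
              method = list(c_x = 0, functional = xc_functional("slater"),
                            grid_level = "medium"), conv = 1e-11)$E_total
    }, m, at, ax, step = 1e-3, stencil = 4)
    expect_lt(abs(fd - gr$g[k]), 1e-5)
  }
})
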