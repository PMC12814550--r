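# Normal-mode analysis, IR intensities, partial Hessians, mode
# localization, and spectrum construction.

test_that("IR intensity prefactor follows from CODATA constants", {
  expect_equal(ir_intensity_prefactor(), 974.88, tolerance = 0.01 / 974.88)
})

test_that("a diatomic with known force constant gives the closed-form
          frequency and unit dipole-derivative intensity", {
  k <- 0.37  # hartree/bohr^2
  m1 <- 1.00782503207; m2 <- 18.99840322
  mu_r <- m1 * m2 / (m1 + m2)
  coords <- matrix(c(0, 0, 0, 0, 0, 1.7), 2, 3, byrow = TRUE)
  u <- c(0, 0, -1, 0, 0, 1)
  H <- k * tcrossprod(u)
  vib <- vibrational_analysis(H, coords = coords, masses = c(m1, m2))
  ref <- sqrt(k / mu_r) * molvib:::freq_conversion_factor()
  expect_identical(vib$n_modes, 1L)
  expect_equal(vib$frequencies[1], ref, tolerance = 1e-8)

  # |d mu / d Q|^2 = 1 e^2/amu -> A = prefactor
  mode <- vib$cart_modes[, 1]
  dmu <- cbind(mode / sum(mode^2) * 1, 0, 0)  # makes (dmu . dx/dQ) = 1
  vib2 <- vibrational_analysis(H, dmu, coords, c(m1, m2))
  expect_equal(vib2$intensities[1], ir_intensity_prefactor(),
               tolerance = 1e-8)
})

test_that("projection removes exactly six rigid-body modes for nonlinear
          systems of any size", {
  for (n in c(5L, 40L)) {
    sys <- synthetic_hessian_system(n, seed = 11)
    vib <- vibrational_analysis(sys$H, sys$dmu, sys$coords, sys$masses)
    expect_identical(vib$n_modes, 3L * n - 6L)
    expect_true(all(vib$frequencies > 0))
    expect_true(all(vib$intensities >= 0))
    # modes orthonormal in the mass-weighted metric
    expect_lt(max(abs(crossprod(vib$modes) - diag(vib$n_modes))), 1e-8)
  }
})

test_that("synthetic generator is reproducible and seed-sensitive", {
  a <- synthetic_hessian_system(12, seed = 5)
  b <- synthetic_hessian_system(12, seed = 5)
  c2 <- synthetic_hessian_system(12, seed = 6)
  expect_identical(a$H, b$H)
  expect_false(isTRUE(all.equal(a$H, c2$H)))
  # dipole-gradient sum rule built in
  for (d in 1:3) {
    expect_equal(sum(a$dmu[seq(d, 36, by = 3), d]), 0, tolerance = 1e-10)
  }
})

test_that("vibrational analysis rejects malformed input", {
  H <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 10), 3)  # not symmetric
  expect_error(vibrational_analysis(H + 1, coords = matrix(0, 1, 3),
                                    masses = 1), "symmetric")
  Hs <- diag(6)
  expect_error(vibrational_analysis(Hs, coords = matrix(0, 2, 3),
                                    masses = c(1, -1)), "positive")
})

test_that("partial Hessian on the full subset is the identity operation", {
  s <- scf_h2o()
  hh <- hessian_h2o(); dg <- dipgrad_h2o()
  vib <- vibrational_analysis(hh$H, dg$dmu, s$mol$coords, s$mol$masses)
  pv <- partial_hessian(hh$H, dg$dmu, s$mol$coords, s$mol$masses, 1:3)
  expect_equal(pv$frequencies, vib$frequencies, tolerance = 1e-12)
  expect_equal(pv$intensities, vib$intensities, tolerance = 1e-12)
  expect_error(partial_hessian(hh$H, dg$dmu, s$mol$coords, s$mol$masses,
                               integer(0)), "nonempty")
  expect_error(partial_hessian(hh$H, dg$dmu, s$mol$coords, s$mol$masses,
                               c(1, 1)), "unique")
  expect_error(partial_hessian(hh$H, dg$dmu, s$mol$coords, s$mol$masses,
                               c(1, 7)), "range")
})

test_that("decoupled block-diagonal Hessians reproduce fragment spectra
          exactly", {
  sysA <- synthetic_hessian_system(6, seed = 2)
  sysB <- synthetic_hessian_system(7, seed = 3)
  nA <- 18L; nB <- 21L
  H <- matrix(0, nA + nB, nA + nB)
  H[1:nA, 1:nA] <- sysA$H
  H[nA + 1:nB, nA + 1:nB] <- sysB$H
  coords <- rbind(sysA$coords, sysB$coords + 60)
  masses <- c(sysA$masses, sysB$masses)
  dmu <- rbind(sysA$dmu, sysB$dmu)
  pA <- partial_hessian(H, dmu, coords, masses, 1:6)
  refA <- vibrational_analysis(sysA$H, sysA$dmu, sysA$coords, sysA$masses)
  expect_equal(pA$frequencies, refA$frequencies, tolerance = 1e-10)
  expect_equal(pA$intensities, refA$intensities, tolerance = 1e-10)
})

test_that("mode localization fractions account for the displacement norm", {
  sys <- synthetic_hessian_system(9, seed = 4)
  vib <- vibrational_analysis(sys$H, sys$dmu, sys$coords, sys$masses)
  part <- list(a = 1:4, b = 5:9)
  loc <- mode_localization(vib, part)
  expect_equal(rowSums(loc), rep(1, vib$n_modes), tolerance = 1e-12)
  # direct norm accounting oracle
  idx <- c(vapply(1:4, function(a) 3L * (a - 1L) + 1:3, integer(3)))
  ref <- colSums(vib$modes[idx, ]^2) / colSums(vib$modes^2)
  expect_equal(unname(loc[, 1]), ref, tolerance = 1e-12)
  # a mode living on one subset only
  modes <- matrix(0, 27, 2)
  modes[1:12, 1] <- rnorm(12)
  modes[13:27, 2] <- rnorm(15)
  l2 <- mode_localization(modes, part)
  expect_equal(unname(l2[1, ]), c(1, 0))
  expect_equal(unname(l2[2, ]), c(0, 1))
  expect_error(mode_localization(vib, list(1:3, 3:5)), "overlap")
})

test_that("frequency scaling acts on frequencies only and composes", {
  st <- stick_spectrum(c(1000, 1600), c(5, 20))
  expect_equal(apply_scaling(st, 1)$frequencies, st$frequencies)
  expect_equal(apply_scaling(st, 0.957)$frequencies[1], 957)
  expect_equal(apply_scaling(st, 0.957)$intensities, st$intensities)
  twice <- apply_scaling(apply_scaling(st, sqrt(0.9)), sqrt(0.9))
  expect_equal(twice$frequencies, apply_scaling(st, 0.9)$frequencies,
               tolerance = 1e-12)
  expect_error(apply_scaling(st, -1), "positive")
})

test_that("Lorentzian broadening has the documented peak, normalization,
          linearity and width", {
  g <- 10
  st <- stick_spectrum(2000, 1)
  grid <- seq(2000 - 500 * g, 2000 + 500 * g, by = 0.5)
  sp <- broaden(st, gamma = g, grid = grid)
  expect_equal(max(sp$sigma), 1 / (pi * g), tolerance = 1e-6)
  expect_equal(sum(sp$sigma) * 0.5, 1, tolerance = 5e-3)  # 0.5% window truncation
  # FWHM = 2 gamma within a grid step
  half <- max(sp$sigma) / 2
  above <- range(sp$omega[sp$sigma >= half])
  expect_lt(abs(diff(above) - 2 * g), 1)
  # linearity: two sticks = sum of singles
  st2 <- stick_spectrum(c(1800, 2100), c(2, 3))
  sp2 <- broaden(st2, gamma = g, grid = grid)
  spa <- broaden(stick_spectrum(1800, 2), gamma = g, grid = grid)
  spb <- broaden(stick_spectrum(2100, 3), gamma = g, grid = grid)
  expect_equal(sp2$sigma, spa$sigma + spb$sigma, tolerance = 1e-14)
  expect_error(broaden(st, gamma = 0), "positive")
  expect_warning(broaden(stick_spectrum(numeric(0), numeric(0)), gamma = g),
                 "empty")
})

test_that("spectrum writers round-trip through both formats", {
  st <- stick_spectrum(c(500, 1500, 2900), c(10, 120, 45))
  sp <- broaden(st, gamma = 7.5)
  for (fmt in c("csv", "jcamp")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_spectrum(sp, path, format = fmt)
    rd <- read_spectrum(path, format = fmt)
    expect_equal(rd$omega, sp$omega, tolerance = 1e-10)
    expect_equal(rd$sigma, sp$sigma, tolerance = 1e-10)
  }
  # a strict reader parses the CSV (header plus numeric columns)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(sp, path, format = "csv")
  d <- utils::read.csv(path, check.names = FALSE, colClasses = "numeric")
  expect_identical(names(d), c("wavenumber_cm-1", "sigma"))
  expect_identical(nrow(d), length(sp$omega))
})
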