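# Exchange-correlation layer: pluggable functional providers, XC energy
# and potential on the molecular grid, geometric gradients, the
# Hessian-specific frozen-density second-derivative assembly, the perturbed
# XC matrix, and the kernel contraction entering the coupled-perturbed
# equations.
#
# All geometric XC derivatives are evaluated in the fixed-weight
# approximation: quadrature points and weights are frozen at the reference
# geometry and only the basis functions move. The finite-difference oracles
# in the test suite use the same convention. A numerical strict mode that
# includes weight derivatives is available for the gradient.
#
# Spin bookkeeping: functionals are spin-resolved (closed shell evaluated
# with rho_alpha = rho_beta); the assembly works with the closed-shell
# combinations
#   fr       = f_ra                      (= f_rb)
#   fs_eff   = 2 f_saa + f_sab
#   frr_sum  = f_rara + f_rarb
#   frs_sum  = f_rasaa + f_rasab + f_rasbb
#   fss_sum  = 2 f_saasaa + f_saasab + 2 f_saasab + f_sabsab
#              + 2 f_saasbb + f_sabsbb

#' Built-in exchange-correlation functionals
#'
#' Returns a functional provider: a list with `name` and `eval(ra, saa,
#' sab)` returning per-point derivative arrays (closed shell, so only the
#' alpha quantities are passed; beta equals alpha). Built-ins:
#' * `"slater"`: Dirac/Slater LDA exchange,
#'   e = -(3/4)(6/pi)^(1/3) (ra^(4/3) + rb^(4/3)).
#' * `"toy_rho2"`: analytic test functional e = c (ra^2 + rb^2).
#' * `"toy_sigma"`: analytic test functional e = c (saa + sbb).
#'
#' @param name functional name.
#' @param c coefficient for the toy functionals (default 0.01).
#' @return object of class `molvib_functional` with fields `name`,
#'   `needs_sigma`, `has_second`, and `eval`.
#' @export
xc_functional <- function(name = c("slater", "toy_rho2", "toy_sigma"),
                          c = 0.01) {
  name <- match.arg(name)
  zero <- function(x) rep(0, length(x))
  ev <- switch(name,
    slater = function(ra, saa, sab) {
      Cx <- 0.75 * (6 / pi)^(1 / 3)
      ras <- pmax(ra, 1e-250)
      list(e = -2 * Cx * ras^(4 / 3),
           f_ra = -(4 / 3) * Cx * ras^(1 / 3),
           f_saa = zero(ra), f_sab = zero(ra),
           f_rara = -(4 / 9) * Cx * ras^(-2 / 3),
           f_rarb = zero(ra),
           f_rasaa = zero(ra), f_rasab = zero(ra), f_rasbb = zero(ra),
           f_saasaa = zero(ra), f_saasab = zero(ra), f_saasbb = zero(ra),
           f_sabsab = zero(ra), f_sabsbb = zero(ra))
    },
    toy_rho2 = function(ra, saa, sab) {
      list(e = 2 * c * ra^2, f_ra = 2 * c * ra,
           f_saa = zero(ra), f_sab = zero(ra),
           f_rara = rep(2 * c, length(ra)), f_rarb = zero(ra),
           f_rasaa = zero(ra), f_rasab = zero(ra), f_rasbb = zero(ra),
           f_saasaa = zero(ra), f_saasab = zero(ra), f_saasbb = zero(ra),
           f_sabsab = zero(ra), f_sabsbb = zero(ra))
    },
    toy_sigma = function(ra, saa, sab) {
      list(e = 2 * c * saa, f_ra = zero(ra),
           f_saa = rep(c, length(ra)), f_sab = zero(ra),
           f_rara = zero(ra), f_rarb = zero(ra),
           f_rasaa = zero(ra), f_rasab = zero(ra), f_rasbb = zero(ra),
           f_saasaa = zero(ra), f_saasab = zero(ra), f_saasbb = zero(ra),
           f_sabsab = zero(ra), f_sabsbb = zero(ra))
    })
  structure(list(name = name, needs_sigma = (name != "toy_rho2"),
                 has_second = TRUE, eval = ev),
            class = "molvib_functional")
}

# closed-shell derivative combinations at the grid points
functional_combos <- function(func, ra, saa) {
  fe <- func$eval(ra, saa, saa)
  list(e = fe$e, fr = fe$f_ra,
       fs_eff = 2 * fe$f_saa + fe$f_sab,
       frr_sum = fe$f_rara + fe$f_rarb,
       frs_sum = fe$f_rasaa + fe$f_rasab + fe$f_rasbb,
       fss_sum = 2 * fe$f_saasaa + 3 * fe$f_saasab + fe$f_sabsab +
         2 * fe$f_saasbb + fe$f_sabsbb,
       raw = fe)
}

# density and gradient on the grid from the physical density D = 2P
grid_density <- function(D, ao) {
  DAO <- ao[["000"]] %*% D
  rho <- rowSums(DAO * ao[["000"]])
  grho <- vapply(c("100", "010", "001"), function(k) {
    2 * rowSums(DAO * ao[[k]])
  }, numeric(nrow(DAO)))
  list(rho = rho, grho = grho)
}

#' XC energy and potential matrix
#'
#' E_xc = sum_g w_g e(rho_g, sigma_g) and the matching potential
#' V_mu.nu = d E_xc / d D_mu.nu (GGA form with density-gradient terms).
#'
#' @param D physical AO density (2P convention).
#' @param mol,basis molecule and basis.
#' @param grid a `molvib_grid`.
#' @param func a `molvib_functional`.
#' @return list with `energy` (hartree) and `V` (n_ao x n_ao).
#' @export
xc_energy_potential <- function(D, mol, basis, grid, func) {
  ao <- eval_ao_grid(mol, basis, grid$points, max_order = 1L)
  dg <- grid_density(D, ao)
  ra <- dg$rho / 2
  gra <- dg$grho / 2
  saa <- rowSums(gra^2)
  fc <- functional_combos(func, ra, saa)
  w <- grid$weights
  energy <- sum(w * fc$e)
  # V = sum_g w [ fr chi_mu chi_nu + fs_eff grad(rho_a) . grad(chi_mu chi_nu) ]
  A0 <- ao[["000"]]
  V <- crossprod(A0 * (w * fc$fr), A0)
  Bv <- w * fc$fs_eff * gra
  for (dd in 1:3) {
    k <- c("100", "010", "001")[dd]
    M <- crossprod(A0 * Bv[, dd], ao[[k]])
    V <- V + M + t(M)
  }
  list(energy = energy, V = (V + t(V)) / 2)
}

# basis-derivative perturbed densities for all 3N perturbations
# (fixed weights, frozen D); order 2 adds the (xi, zeta) second perturbed
# densities for the requested pairs
xc_perturbed_densities <- function(D, mol, basis, grid, ao = NULL,
                                   max_order = 1L) {
  nat <- nrow(mol$coords)
  n3 <- 3L * nat
  if (is.null(ao)) {
    ao <- eval_ao_grid(mol, basis, grid$points, max_order = 1L + max_order)
  }
  npts <- nrow(grid$points)
  aomask <- lapply(seq_len(nat), function(a) {
    unlist(lapply(which(vapply(basis$shells, `[[`, 0L, "atom") == a),
                  function(s) shell_ao_range(basis, s)))
  })
  d1keys <- c("100", "010", "001")
  addk <- function(k1, k2) {
    paste(sprintf("%d", as.integer(strsplit(k1, "")[[1]]) +
                    as.integer(strsplit(k2, "")[[1]])), collapse = "")
  }
  A0 <- ao[["000"]]
  DAO <- A0 %*% D
  dDAO <- lapply(d1keys, function(k) ao[[k]] %*% D)
  rho_xi <- matrix(0, npts, n3)
  grho_xi <- array(0, dim = c(npts, 3, n3))
  for (a in seq_len(nat)) for (i in 1:3) {
    k <- 3L * (a - 1L) + i
    m <- aomask[[a]]
    if (length(m) == 0) next
    ki <- d1keys[i]
    # rho^(xi) = -2 sum_{mu on a} D_mu.nu (d_i chi_mu) chi_nu
    rho_xi[, k] <- -2 * rowSums(ao[[ki]][, m, drop = FALSE] *
                                  DAO[, m, drop = FALSE])
    for (dd in 1:3) {
      kd <- d1keys[dd]
      grho_xi[, dd, k] <- -2 * (
        rowSums(ao[[addk(ki, kd)]][, m, drop = FALSE] * DAO[, m, drop = FALSE]) +
          rowSums(ao[[ki]][, m, drop = FALSE] * dDAO[[dd]][, m, drop = FALSE]))
    }
  }
  out <- list(ao = ao, rho_xi = rho_xi, grho_xi = grho_xi, aomask = aomask)
  out
}

#' Geometric gradient of the XC energy (frozen density)
#'
#' The skeleton XC term of the nuclear gradient:
#' dE_xc/dxi = 2 int w [ f_ra rho_a^(xi) + fs_eff/2 * ... ] evaluated with
#' fixed grid weights; `weight_derivatives = TRUE` adds the weight-response
#' numerically (rebuilding the grid at displaced geometries).
#'
#' @inheritParams xc_energy_potential
#' @param weight_derivatives include grid-weight derivatives numerically.
#' @param step finite-difference step for the weight term (bohr).
#' @return numeric 3N vector (hartree/bohr).
#' @export
xc_gradient <- function(D, mol, basis, grid, func,
                        weight_derivatives = FALSE, step = 1e-4) {
  ao <- eval_ao_grid(mol, basis, grid$points, max_order = 2L)
  dg <- grid_density(D, ao)
  ra <- dg$rho / 2
  gra <- dg$grho / 2
  saa <- rowSums(gra^2)
  fc <- functional_combos(func, ra, saa)
  pd <- xc_perturbed_densities(D, mol, basis, grid, ao = ao, max_order = 1L)
  n3 <- ncol(pd$rho_xi)
  w <- grid$weights
  g <- vapply(seq_len(n3), function(k) {
    ra_x <- pd$rho_xi[, k] / 2
    gra_x <- pd$grho_xi[, , k] / 2
    2 * sum(w * (fc$fr * ra_x + fc$fs_eff * rowSums(gra * gra_x)))
  }, 0)
  if (weight_derivatives) {
    exc_at <- function(m, gr, wts) {
      ao2 <- eval_ao_grid(m, basis, gr, max_order = 1L)
      dg2 <- grid_density(D, ao2)
      ra2 <- dg2$rho / 2
      saa2 <- rowSums((dg2$grho / 2)^2)
      sum(wts * functional_combos(func, ra2, saa2)$e)
    }
    for (a in seq_len(nrow(mol$coords))) for (i in 1:3) {
      k <- 3L * (a - 1L) + i
      full <- fd_derivative(function(m) {
        gr2 <- build_grid(m, grid$level)
        exc_at(m, gr2$points, gr2$weights)
      }, mol, a, i, step = step)
      frozen <- fd_derivative(function(m) {
        exc_at(m, grid$points, grid$weights)
      }, mol, a, i, step = step)
      g[k] <- g[k] + (full - frozen)
    }
  }
  g
}

#' Frozen-density XC second-derivative assembly
#'
#' The explicit XC contribution to the molecular Hessian for a GGA
#' functional, assembled term by term from the chain rule (density-density,
#' density-sigma, sigma-sigma, gradient-overlap, and second perturbed
#' density terms), with frozen density matrix and fixed grid weights.
#'
#' @inheritParams xc_energy_potential
#' @param terms character vector selecting term groups (default all):
#'   `"rr"`, `"rs"`, `"ss"`, `"gg"`, `"second"`.
#' @return (3N x 3N) matrix (hartree/bohr^2).
#' @export
xc_hessian_terms <- function(D, mol, basis, grid, func,
                             terms = c("rr", "rs", "ss", "gg", "second")) {
  nat <- nrow(mol$coords)
  n3 <- 3L * nat
  ao <- eval_ao_grid(mol, basis, grid$points, max_order = 3L)
  dg <- grid_density(D, ao)
  ra <- dg$rho / 2
  gra <- dg$grho / 2
  saa <- rowSums(gra^2)
  fc <- functional_combos(func, ra, saa)
  if (any(!is.finite(fc$frr_sum))) {
    stop("functional does not supply finite second derivatives", call. = FALSE)
  }
  pd <- xc_perturbed_densities(D, mol, basis, grid, ao = ao, max_order = 2L)
  w <- grid$weights
  H <- matrix(0, n3, n3)
  d1keys <- c("100", "010", "001")
  # per-xi scalar fields
  ra_x <- pd$rho_xi / 2                      # npts x n3
  sa_x <- matrix(0, length(w), n3)           # sigma_aa^(xi) = 2 grad.ra . (grad ra)^(xi)
  for (k in seq_len(n3)) {
    sa_x[, k] <- 2 * rowSums(gra * (pd$grho_xi[, , k] / 2))
  }
  for (k1 in seq_len(n3)) for (k2 in k1:n3) {
    acc <- 0
    if ("rr" %in% terms) {
      acc <- acc + sum(w * fc$frr_sum * ra_x[, k1] * ra_x[, k2])
    }
    if ("rs" %in% terms) {
      acc <- acc + sum(w * fc$frs_sum * (ra_x[, k1] * sa_x[, k2] +
                                           sa_x[, k1] * ra_x[, k2]))
    }
    if ("ss" %in% terms) {
      acc <- acc + 0.5 * sum(w * fc$fss_sum * sa_x[, k1] * sa_x[, k2])
    }
    if ("gg" %in% terms) {
      acc <- acc + sum(w * fc$fs_eff *
                         rowSums((pd$grho_xi[, , k1] / 2) *
                                   (pd$grho_xi[, , k2] / 2)))
    }
    H[k1, k2] <- H[k2, k1] <- 2 * acc
  }
  if ("second" %in% terms) {
    # rho^(xi,zeta) and (grad rho)^(xi,zeta) basis terms
    A0 <- ao[["000"]]
    DAO <- A0 %*% D
    dDAO <- lapply(d1keys, function(k) ao[[k]] %*% D)
    addk <- function(k1, k2) {
      paste(sprintf("%d", as.integer(strsplit(k1, "")[[1]]) +
                      as.integer(strsplit(k2, "")[[1]])), collapse = "")
    }
    for (a1 in seq_len(nat)) for (i in 1:3) {
      k1 <- 3L * (a1 - 1L) + i
      m1 <- pd$aomask[[a1]]
      if (length(m1) == 0) next
      for (a2 in seq_len(nat)) for (j in 1:3) {
        k2 <- 3L * (a2 - 1L) + j
        if (k2 < k1) next
        m2 <- pd$aomask[[a2]]
        if (length(m2) == 0) next
        ki <- d1keys[i]; kj <- d1keys[j]
        rho_xz <- numeric(length(w))
        grho_xz <- matrix(0, length(w), 3)
        if (a1 == a2) {
          kk <- addk(ki, kj)
          rho_xz <- rho_xz + 2 * rowSums(ao[[kk]][, m1, drop = FALSE] *
                                           DAO[, m1, drop = FALSE])
          for (dd in 1:3) {
            kd <- d1keys[dd]
            grho_xz[, dd] <- grho_xz[, dd] +
              2 * rowSums(ao[[addk(kk, kd)]][, m1, drop = FALSE] *
                            DAO[, m1, drop = FALSE]) +
              2 * rowSums(ao[[kk]][, m1, drop = FALSE] *
                            dDAO[[dd]][, m1, drop = FALSE])
          }
        }
        Dsub <- D[m1, m2, drop = FALSE]
        Xi <- ao[[ki]][, m1, drop = FALSE]
        Xj <- ao[[kj]][, m2, drop = FALSE]
        rho_xz <- rho_xz + 2 * rowSums((Xi %*% Dsub) * Xj)
        for (dd in 1:3) {
          kd <- d1keys[dd]
          grho_xz[, dd] <- grho_xz[, dd] +
            2 * rowSums((ao[[addk(ki, kd)]][, m1, drop = FALSE] %*% Dsub) * Xj) +
            2 * rowSums((Xi %*% Dsub) * ao[[addk(kj, kd)]][, m2, drop = FALSE])
        }
        v <- 2 * sum(w * (fc$fr * rho_xz / 2 +
                            fc$fs_eff * rowSums(gra * grho_xz / 2)))
        H[k1, k2] <- H[k1, k2] + v
        if (k1 != k2) H[k2, k1] <- H[k2, k1] + v
      }
    }
  }
  H
}

#' Geometric derivative of the XC potential matrix
#'
#' d v^xc_mu.nu / d xi at frozen density and fixed grid weights, including
#' both the density-response terms (functional second derivatives times the
#' basis-motion perturbed densities) and the explicit basis-function
#' derivative terms.
#'
#' @inheritParams xc_energy_potential
#' @param terms term groups: `"response"` (functional-derivative response)
#'   and `"basis"` (chi^(xi) terms); default both.
#' @return array n_ao x n_ao x 3N.
#' @export
xc_fock_derivative <- function(D, mol, basis, grid, func,
                               terms = c("response", "basis")) {
  nat <- nrow(mol$coords)
  n3 <- 3L * nat
  n <- basis$n_ao
  ao <- eval_ao_grid(mol, basis, grid$points, max_order = 2L)
  dg <- grid_density(D, ao)
  ra <- dg$rho / 2
  gra <- dg$grho / 2
  saa <- rowSums(gra^2)
  fc <- functional_combos(func, ra, saa)
  pd <- xc_perturbed_densities(D, mol, basis, grid, ao = ao, max_order = 1L)
  w <- grid$weights
  d1keys <- c("100", "010", "001")
  A0 <- ao[["000"]]
  out <- array(0, dim = c(n, n, n3))
  addk <- function(k1, k2) {
    paste(sprintf("%d", as.integer(strsplit(k1, "")[[1]]) +
                    as.integer(strsplit(k2, "")[[1]])), collapse = "")
  }
  for (k in seq_len(n3)) {
    a <- (k - 1L) %/% 3L + 1L
    i <- (k - 1L) %% 3L + 1L
    ki <- d1keys[i]
    m <- pd$aomask[[a]]
    V <- matrix(0, n, n)
    if ("response" %in% terms) {
      ra_x <- pd$rho_xi[, k] / 2
      gra_x <- pd$grho_xi[, , k] / 2
      sa_x <- 2 * rowSums(gra * gra_x)
      dA <- fc$frr_sum * ra_x + fc$frs_sum * sa_x
      V <- V + crossprod(A0 * (w * dA), A0)
      # dB = (2 frs_sum ra_x + fss_sum sa_x) grad.ra + fs_eff (grad ra)^(xi)
      coefB <- 2 * fc$frs_sum * ra_x + fc$fss_sum * sa_x
      for (dd in 1:3) {
        kd <- d1keys[dd]
        Bd <- w * (coefB * gra[, dd] + fc$fs_eff * gra_x[, dd])
        M <- crossprod(A0 * Bd, ao[[kd]])
        V <- V + M + t(M)
      }
    }
    if ("basis" %in% terms && length(m) > 0) {
      # chi^(xi) = -d_i chi for chi on atom a
      Ax <- matrix(0, length(w), n)
      Ax[, m] <- -ao[[ki]][, m, drop = FALSE]
      M <- crossprod(Ax * (w * fc$fr), A0)
      V <- V + M + t(M)
      for (dd in 1:3) {
        kd <- d1keys[dd]
        Bd <- w * fc$fs_eff * gra[, dd]
        dAx <- matrix(0, length(w), n)
        dAx[, m] <- -ao[[addk(ki, kd)]][, m, drop = FALSE]
        M <- crossprod(dAx * Bd, A0) + crossprod(Ax * Bd, ao[[kd]])
        V <- V + M + t(M)
      }
    }
    out[, , k] <- (V + t(V)) / 2
  }
  out
}

#' XC kernel contraction f^xc[X]
#'
#' Second functional derivative contracted with a trial density
#' perturbation X (physical 2P-convention density units), as it enters the
#' auxiliary Fock matrix of the coupled-perturbed equations. Linear in X.
#'
#' @param X symmetric trial AO density perturbation (n_ao x n_ao).
#' @inheritParams xc_energy_potential
#' @param D reference physical density.
#' @return symmetric n_ao x n_ao matrix.
#' @export
xc_kernel_contraction <- function(X, mol, basis, grid, func, D = NULL,
                                  scf = NULL) {
  if (is.null(D)) {
    if (is.null(scf)) stop("reference density D required", call. = FALSE)
    D <- scf$D
  }
  n <- basis$n_ao
  ao <- eval_ao_grid(mol, basis, grid$points, max_order = 1L)
  dg <- grid_density(D, ao)
  ra <- dg$rho / 2
  gra <- dg$grho / 2
  saa <- rowSums(gra^2)
  fc <- functional_combos(func, ra, saa)
  dgx <- grid_density(X, ao)
  ra_t <- dgx$rho / 2
  gra_t <- dgx$grho / 2
  sa_t <- 2 * rowSums(gra * gra_t)
  w <- grid$weights
  A0 <- ao[["000"]]
  dA <- fc$frr_sum * ra_t + fc$frs_sum * sa_t
  V <- crossprod(A0 * (w * dA), A0)
  coefB <- 2 * fc$frs_sum * ra_t + fc$fss_sum * sa_t
  for (dd in 1:3) {
    kd <- c("100", "010", "001")[dd]
    Bd <- w * (coefB * gra[, dd] + fc$fs_eff * gra_t[, dd])
    M <- crossprod(A0 * Bd, ao[[kd]])
    V <- V + M + t(M)
  }
  (V + t(V)) / 2
}
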