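# Analytic nuclear gradient and Hessian assembly, dipole-moment gradients,
# and the orbital-response quantities connecting them.
#
# Gradient (converged closed-shell state, P = C_occ C_occ^T, W = C_occ E C_occ^T):
#   g_xi = E_nn^xi + 2 tr(P h^(xi)) + Gamma : ERI^(xi) - 2 tr(W S^(xi)) [+ XC]
# Hessian, by differentiating the gradient with the orbital response from
# the coupled-perturbed equations:
#   H_xi.zeta = [skeleton second derivatives] + 2 tr(P^xi F^(zeta),skel)
#               - 2 tr(W^xi S^(zeta))
# with P^xi from U^xi (occupied-virtual from the solver, occupied-occupied
# = -1/2 S~^xi) and W^xi assembled from U^xi and the total derivative Fock.

#' Analytic nuclear gradient
#'
#' @param scf a converged `molvib_scf`.
#' @param skel optional precomputed [skeleton_derivatives()] result.
#' @return object of class `molvib_gradient`: `g` (3N vector, hartree/bohr),
#'   `by_atom` (N x 3), and `decomposition` (per-term 3N vectors: nuclear,
#'   one-electron, two-electron, overlap, xc).
#' @export
analytic_gradient <- function(scf, skel = NULL) {
  if (!isTRUE(scf$converged)) stop("SCF state is not converged", call. = FALSE)
  mol <- scf$mol; basis <- scf$basis
  nat <- nrow(mol$coords)
  n3 <- 3L * nat
  if (is.null(skel)) {
    oed <- one_electron_derivatives(mol, basis, order = 1L,
                                    origin = scf$oe$origin)
  } else oed <- skel$oed
  g_nuc <- nuclear_repulsion(mol, order = 1L)$gradient
  g_1e <- vapply(seq_len(n3), function(k) {
    2 * sum(scf$P * (oed$dT[, , k] + oed$dV[, , k]))
  }, 0)
  g_2e <- eri_gradient_contraction(scf$P, scf$P, mol, basis,
                                   screen = scf$schwarz, c_x = scf$c_x)$g
  g_ovl <- vapply(seq_len(n3), function(k) {
    -sum(scf$W_energy * oed$dS[, , k])
  }, 0)
  g_xc <- numeric(n3)
  if (!is.null(scf$functional)) {
    g_xc <- xc_gradient(scf$D, mol, basis, scf$grid, scf$functional)
  }
  g <- g_nuc + g_1e + g_2e + g_ovl + g_xc
  structure(list(
    g = g, by_atom = matrix(g, nat, 3, byrow = TRUE),
    decomposition = list(nuclear = g_nuc, one_electron = g_1e,
                         two_electron = g_2e, overlap = g_ovl, xc = g_xc)
  ), class = "molvib_gradient")
}

# orbital-response quantities P^xi and W^xi for every perturbation
response_densities <- function(scf, rhs, cphf) {
  no <- scf$n_occ
  C <- scf$C
  Co <- C[, seq_len(no), drop = FALSE]
  eo <- scf$eps[seq_len(no)]
  n3 <- length(rhs$R)
  Pd <- vector("list", n3)
  Wd <- vector("list", n3)
  for (k in seq_len(n3)) {
    Stil <- rhs$Stilde[[k]]
    Ufull <- matrix(0, ncol(C), no)
    Ufull[seq_len(no), ] <- -0.5 * Stil[seq_len(no), seq_len(no)]
    Ufull[-seq_len(no), ] <- cphf$U[[k]]
    Cxi <- C %*% Ufull
    Pk <- Cxi %*% t(Co)
    Pk <- Pk + t(Pk)
    Pd[[k]] <- Pk
    Ftot <- rhs$skel$Fd[, , k] + response_G(scf, Pk)
    Foo <- crossprod(Co, Ftot %*% Co)
    Uoo <- Ufull[seq_len(no), , drop = FALSE]
    M <- t(Uoo) %*% diag(eo, no) + diag(eo, no) %*% Uoo + Foo
    Wk <- Cxi %*% (eo * t(Co))
    Wk <- Wk + t(Wk) + Co %*% M %*% t(Co)
    Wd[[k]] <- Wk
  }
  list(Pd = Pd, Wd = Wd)
}

#' Analytic nuclear Hessian
#'
#' Assembles the full (3N x 3N) second-derivative matrix: nuclear-repulsion
#' second derivatives, one-electron second-derivative contractions, the
#' two-electron second-derivative double contraction, the energy-weighted
#' overlap second-derivative term, XC terms under a functional, and the
#' orbital-response term built from the coupled-perturbed solutions.
#'
#' @param scf a converged `molvib_scf`.
#' @param cphf_tol residual tolerance for the response equations.
#' @return object of class `molvib_hessian`: `H` (3N x 3N, hartree/bohr^2),
#'   `decomposition`, `response` (the `molvib_cphf` object), `rhs`,
#'   and `metadata`.
#' @export
analytic_hessian <- function(scf, cphf_tol = 1e-8) {
  if (!isTRUE(scf$converged)) stop("SCF state is not converged", call. = FALSE)
  mol <- scf$mol; basis <- scf$basis
  nat <- nrow(mol$coords)
  n3 <- 3L * nat
  skel2 <- skeleton_derivatives(scf, order = 2L)
  oed <- skel2$oed
  H_nuc <- nuclear_repulsion(mol, order = 2L)$hessian
  H_1e <- matrix(0, n3, n3)
  H_ovl <- matrix(0, n3, n3)
  for (k1 in seq_len(n3)) for (k2 in k1:n3) {
    v1 <- 2 * sum(scf$P * (oed$d2T[, , k1, k2] + oed$d2V[, , k1, k2]))
    v2 <- -sum(scf$W_energy * oed$d2S[, , k1, k2])
    H_1e[k1, k2] <- H_1e[k2, k1] <- v1
    H_ovl[k1, k2] <- H_ovl[k2, k1] <- v2
  }
  H_2e <- eri_hessian_contraction(scf$P, scf$P, mol, basis,
                                  screen = scf$schwarz, c_x = scf$c_x)
  H_xc <- matrix(0, n3, n3)
  if (!is.null(scf$functional)) {
    H_xc <- xc_hessian_terms(scf$D, mol, basis, scf$grid, scf$functional)
  }
  rhs <- build_rhs(scf, skel = skel2)
  cphf <- solve_cphf(rhs, scf, tol = cphf_tol)
  rd <- response_densities(scf, rhs, cphf)
  H_resp <- matrix(0, n3, n3)
  for (k1 in seq_len(n3)) for (k2 in seq_len(n3)) {
    H_resp[k1, k2] <- 2 * sum(rd$Pd[[k1]] * rhs$skel$Fd[, , k2]) -
      2 * sum(rd$Wd[[k1]] * rhs$skel$Sd[, , k2])
  }
  H <- H_nuc + H_1e + H_2e + H_ovl + H_xc + H_resp
  H <- (H + t(H)) / 2
  structure(list(
    H = H,
    decomposition = list(nuclear = H_nuc, one_electron = H_1e,
                         two_electron = H_2e, overlap = H_ovl, xc = H_xc,
                         response = (H_resp + t(H_resp)) / 2),
    response = cphf, rhs = rhs,
    metadata = list(method = if (is.null(scf$functional)) "hf" else "hybrid",
                    c_x = scf$c_x, basis = basis$name, cphf_tol = cphf_tol)
  ), class = "molvib_hessian")
}

#' SCF electric dipole moment
#'
#' mu = sum_A Z_A (R_A - origin) - tr(D Dip), in e bohr.
#' @param scf a converged `molvib_scf`.
#' @return length-3 numeric vector.
#' @export
scf_dipole <- function(scf) {
  el <- -vapply(1:3, function(d) sum(scf$D * scf$oe$D_dip[[d]]), 0)
  nuclear_dipole(scf$mol, origin = scf$oe$origin) + el
}

#' Analytic dipole-moment gradient
#'
#' d mu / d x as a (3N x 3) matrix (units e): nuclear term Z_A on the
#' diagonal components plus the electronic term from the perturbed density
#' (coupled-perturbed solutions) and the dipole-integral derivatives. The
#' dipole origin is held fixed at the reference geometry's center of
#' nuclear charge, so the translational row sum per component equals the
#' total charge.
#'
#' @param scf a converged `molvib_scf`.
#' @param response optional list with `rhs` and `cphf` (reused from a
#'   Hessian run); computed on demand otherwise.
#' @param cphf_tol solver tolerance when computed on demand.
#' @return object of class `molvib_dipgrad`: `dmu` (3N x 3 matrix),
#'   `nuclear`, `electronic`.
#' @export
dipole_gradient <- function(scf, response = NULL, cphf_tol = 1e-8) {
  mol <- scf$mol; basis <- scf$basis
  nat <- nrow(mol$coords)
  n3 <- 3L * nat
  if (is.null(response)) {
    rhs <- build_rhs(scf)
    cphf <- solve_cphf(rhs, scf, tol = cphf_tol)
  } else {
    rhs <- response$rhs; cphf <- response$cphf
  }
  rd <- response_densities(scf, rhs, cphf)
  oed <- rhs$skel$oed
  dmu_n <- matrix(0, n3, 3)
  for (a in seq_len(nat)) for (i in 1:3) {
    dmu_n[3 * (a - 1) + i, i] <- mol$charges[a]
  }
  dmu_e <- matrix(0, n3, 3)
  for (k in seq_len(n3)) for (d in 1:3) {
    dmu_e[k, d] <- -2 * sum(rd$Pd[[k]] * scf$oe$D_dip[[d]]) -
      sum(scf$D * oed$dDip[, , d, k])
  }
  structure(list(dmu = dmu_n + dmu_e, nuclear = dmu_n, electronic = dmu_e),
            class = "molvib_dipgrad")
}
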