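# Coupled-perturbed Hartree-Fock/Kohn-Sham equations for all 3N nuclear
# perturbations, solved in one shared subspace.
#
# With U collecting the occupied-column response of the MO coefficients
# (C^xi = C U^xi), orthonormality fixes the occupied-occupied block
# U_oo = -1/2 S~^xi_oo, and the occupied-virtual block solves
#   (eps_a - eps_i) U_ai + G~[dP_U]_ai = -R_ai,
#   R_ai = F~^(xi)_ai - eps_i S~^(xi)_ai + G~[dP_S]_ai,
# where dP_U = sum_bj U_bj (C_b C_j^T + c.c.), dP_S = -sum_kl S~_kl C_k C_l^T,
# G[X] = 2J[X] - c_x K[X] + f^xc[X], and ~ denotes the MO basis. The sign
# conventions are fixed by self-consistency with the closed-shell Fock
# convention and validated against a dense direct solve and the
# finite-difference Hessian oracle.

# skeleton derivative Fock and overlap matrices for all perturbations
skeleton_derivatives <- function(scf, order = 1L) {
  mol <- scf$mol; basis <- scf$basis
  oed <- one_electron_derivatives(mol, basis, order = order,
                                  origin = scf$oe$origin)
  n3 <- dim(oed$dS)[3]
  Fd <- oed$dT + oed$dV +
    fock_derivative_2e(scf$P, mol, basis, screen = scf$schwarz, c_x = scf$c_x)
  if (!is.null(scf$functional)) {
    Fd <- Fd + xc_fock_derivative(scf$D, mol, basis, scf$grid, scf$functional)
  }
  list(Fd = Fd, Sd = oed$dS, oed = oed)
}

# auxiliary-Fock response map in the AO basis: G[X] for a symmetric AO
# perturbation density X (P convention)
response_G <- function(scf, X) {
  if (!is.null(scf$eri)) {
    Gm <- fock_from_tensor(scf$eri, X, c_x = scf$c_x)
  } else {
    Gm <- build_fock_2e(X, scf$mol, scf$basis, c_x = scf$c_x,
                        screen = scf$schwarz)
  }
  if (!is.null(scf$functional)) {
    Gm <- Gm + xc_kernel_contraction(2 * X, scf$mol, scf$basis, scf$grid,
                                     scf$functional, D = scf$D)
  }
  Gm
}

#' Auxiliary Fock matrix G_ai[U]
#'
#' The action of the orbital-Hessian coupling on a trial occupied-virtual
#' response matrix: the trial U is back-transformed to an AO perturbation
#' density, contracted with [2(mu nu|theta phi) - c_x (mu phi|theta nu)]
#' (plus the XC kernel under a functional), and projected to the
#' virtual-occupied block. Linear in U.
#'
#' @param U matrix (n_virt x n_occ) or a list of such matrices.
#' @param scf a converged `molvib_scf`.
#' @return matrix (or list) matching `U`.
#' @export
auxiliary_fock <- function(U, scf) {
  if (is.list(U)) return(lapply(U, auxiliary_fock, scf = scf))
  no <- scf$n_occ
  Co <- scf$C[, seq_len(no), drop = FALSE]
  Cv <- scf$C[, -seq_len(no), drop = FALSE]
  if (!all(dim(U) == c(ncol(Cv), no))) {
    stop("U must be n_virt x n_occ", call. = FALSE)
  }
  X <- Cv %*% U %*% t(Co)
  X <- X + t(X)
  crossprod(Cv, response_G(scf, X) %*% Co)
}

#' Right-hand sides of the coupled-perturbed equations
#'
#' R_ai^xi = F_ai^(xi) - eps_i S_ai^(xi) - G_ai[S^(xi)] for every nuclear
#' perturbation, with the G term evaluated by the same auxiliary-Fock
#' routine used in the iterations.
#'
#' @param scf a converged `molvib_scf`.
#' @param skel optional precomputed [skeleton_derivatives()] result.
#' @return object of class `molvib_cphf_rhs`: list with `R` (list of
#'   n_virt x n_occ matrices), `Stilde` (list of full MO overlap-derivative
#'   matrices), `skel`.
#' @export
build_rhs <- function(scf, skel = NULL) {
  if (is.null(skel)) skel <- skeleton_derivatives(scf, order = 1L)
  no <- scf$n_occ
  C <- scf$C
  Co <- C[, seq_len(no), drop = FALSE]
  Cv <- C[, -seq_len(no), drop = FALSE]
  n3 <- dim(skel$Sd)[3]
  R <- vector("list", n3)
  St <- vector("list", n3)
  for (k in seq_len(n3)) {
    Stil <- crossprod(C, skel$Sd[, , k] %*% C)
    St[[k]] <- Stil
    Soo <- Stil[seq_len(no), seq_len(no), drop = FALSE]
    dP_S <- -Co %*% Soo %*% t(Co)
    Fai <- crossprod(Cv, skel$Fd[, , k] %*% Co)
    Sai <- Stil[-seq_len(no), seq_len(no), drop = FALSE]
    Gai <- crossprod(Cv, response_G(scf, dP_S) %*% Co)
    R[[k]] <- Fai - sweep(Sai, 2, scf$eps[seq_len(no)], `*`) + Gai
  }
  structure(list(R = R, Stilde = St, skel = skel), class = "molvib_cphf_rhs")
}

#' Solve the coupled-perturbed equations in a shared subspace
#'
#' Preconditioned subspace iteration over all right-hand sides at once:
#' trial vectors are orthonormalized preconditioned residuals, the
#' projected equations are solved in the subspace, and per-perturbation
#' convergence is monitored on the max-norm residual.
#'
#' @param rhs a `molvib_cphf_rhs` (or list of n_virt x n_occ matrices).
#' @param scf a converged `molvib_scf`.
#' @param tol max-norm residual tolerance (default 1e-8).
#' @param max_iter maximum subspace expansions.
#' @return object of class `molvib_cphf`: `U` (list of n_virt x n_occ
#'   solutions), `residuals` (final max-norms), `iterations`,
#'   `trace` (per-iteration max residual).
#' @export
solve_cphf <- function(rhs, scf, tol = 1e-8, max_iter = 60L) {
  Rl <- if (inherits(rhs, "molvib_cphf_rhs")) rhs$R else rhs
  no <- scf$n_occ
  nv <- length(scf$eps) - no
  if (nv == 0) stop("no virtual orbitals: response undefined", call. = FALSE)
  eo <- scf$eps[seq_len(no)]
  ev <- scf$eps[-seq_len(no)]
  gap <- outer(ev, eo, `-`)
  if (min(gap) < 1e-8) {
    stop("near-degenerate occupied-virtual gap (", format(min(gap)),
         "): coupled-perturbed equations ill-conditioned", call. = FALSE)
  }
  nrhs <- length(Rl)
  ndim <- nv * no
  b <- -vapply(Rl, as.vector, numeric(ndim))  # solve A u = -R
  dim(b) <- c(ndim, nrhs)
  if (max(abs(b)) < tol) {
    return(structure(list(U = lapply(seq_len(nrhs), function(k) matrix(0, nv, no)),
                          residuals = rep(0, nrhs), iterations = 1L,
                          trace = 0), class = "molvib_cphf"))
  }
  prec <- as.vector(1 / gap)
  Amul <- function(v) {
    U <- matrix(v, nv, no)
    as.vector(gap * U + auxiliary_fock(U, scf))
  }
  # subspace loop
  V <- NULL; AV <- NULL
  X <- prec * b  # preconditioned initial guess
  addvecs <- function(V, W) {
    for (c in seq_len(ncol(W))) {
      w <- W[, c]
      for (rep in 1:2) if (!is.null(V)) w <- w - V %*% crossprod(V, w)
      nw <- sqrt(sum(w * w))
      if (nw > 1e-10) V <- cbind(V, w / nw)
    }
    V
  }
  trace <- numeric(0)
  res_norm <- rep(Inf, nrhs)
  for (it in seq_len(max_iter)) {
    Vnew <- addvecs(V, X)
    if (is.null(Vnew) || (!is.null(V) && ncol(Vnew) == ncol(V))) break
    newcols <- if (is.null(V)) seq_len(ncol(Vnew)) else (ncol(V) + 1):ncol(Vnew)
    for (c in newcols) AV <- cbind(AV, Amul(Vnew[, c]))
    V <- Vnew
    Ared <- crossprod(V, AV)
    bred <- crossprod(V, b)
    y <- solve(Ared, bred)
    U <- V %*% y
    Res <- AV %*% y - b
    res_norm <- apply(abs(Res), 2, max)
    trace <- c(trace, max(res_norm))
    if (max(res_norm) <= tol) break
    live <- res_norm > tol
    X <- (prec * Res)[, live, drop = FALSE]
  }
  if (max(res_norm) > tol) {
    stop("coupled-perturbed solver stagnated: max residual ",
         format(max(res_norm)), " after ", it, " iterations (trace: ",
         paste(format(trace, digits = 3), collapse = " "), ")", call. = FALSE)
  }
  Ul <- lapply(seq_len(nrhs), function(k) matrix(U[, k], nv, no))
  structure(list(U = Ul, residuals = res_norm, iterations = it,
                 trace = trace), class = "molvib_cphf")
}

#' Dense direct solve of the coupled-perturbed equations (oracle)
#'
#' Builds the explicit singlet orbital-Hessian matrix
#' A_(ai),(bj) = delta (eps_a - eps_i) + 4(ai|bj) - c_x (aj|bi) - c_x (ab|ij)
#' from the MO-transformed ERI tensor and solves directly. Intended as an
#' independent reference for [solve_cphf()] at desk scale.
#'
#' @inheritParams solve_cphf
#' @return list of n_virt x n_occ solution matrices.
#' @export
dense_cphf_solve <- function(rhs, scf) {
  Rl <- if (inherits(rhs, "molvib_cphf_rhs")) rhs$R else rhs
  if (is.null(scf$eri)) stop("dense solve requires the stored ERI tensor",
                             call. = FALSE)
  if (!is.null(scf$functional)) {
    stop("dense oracle implemented for the Hartree-Fock coupling only",
         call. = FALSE)
  }
  no <- scf$n_occ
  n <- length(scf$eps)
  nv <- n - no
  if (nv * no > 2000) stop("dense solve limited to n_occ*n_virt <= 2000",
                           call. = FALSE)
  # MO transformation of the tensor
  Gm <- scf$eri
  C <- scf$C
  for (mode in 1:4) Gm <- mode_mult(Gm, t(C), mode)
  occ <- seq_len(no); vir <- no + seq_len(nv)
  A <- matrix(0, nv * no, nv * no)
  for (i in occ) for (a in seq_len(nv)) {
    ia <- (i - 1) * nv + a
    for (j in occ) for (bb in seq_len(nv)) {
      jb <- (j - 1) * nv + bb
      av <- vir[a]; bv <- vir[bb]
      A[ia, jb] <- 4 * Gm[av, i, bv, j] -
        scf$c_x * (Gm[av, j, bv, i] + Gm[av, bv, i, j])
      if (ia == jb) A[ia, jb] <- A[ia, jb] + (scf$eps[av] - scf$eps[i])
    }
  }
  lapply(Rl, function(R) matrix(solve(A, -as.vector(R)), nv, no))
}
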