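# Restricted closed-shell self-consistent field with DIIS acceleration.
#
# Density conventions used package-wide (fixed here once):
#   P = C_occ C_occ^T            ("P convention", used in all contractions)
#   D = 2 P                      (physical closed-shell AO density)
#   G[X] = 2 J[X] - c_x K[X]     (Coulomb/exchange contraction of X)
#   F = h + G[P] + V_xc          (Fock matrix)
#   E = E_nn + 2 tr(P h) + tr(P G[P]) + E_xc
#   W = C_occ diag(eps_occ) C_occ^T;  W_energy = 2 W

#' Run a closed-shell SCF calculation
#'
#' Hartree-Fock by default; hybrid-density-functional ready through the
#' exact-exchange fraction `c_x` and a pluggable functional evaluated on a
#' Becke-partitioned molecular grid.
#'
#' @param mol a `molvib_molecule` (even electron count).
#' @param basis a `molvib_basis`.
#' @param method `"hf"`, or a list with fields `c_x` (exact-exchange
#'   fraction) and optionally `functional` (a `molvib_functional`) and
#'   `grid_level` (see [build_grid()]).
#' @param conv convergence threshold applied to both the energy change and
#'   the max-norm of the orbital-gradient commutator FDS - SDF (default
#'   1e-6).
#' @param screen Cauchy-Schwarz screening threshold for direct Fock builds
#'   (default 1e-12); dense-tensor builds are used automatically for small
#'   systems unless `force_direct = TRUE`.
#' @param max_iter maximum number of SCF iterations.
#' @param diis logical; Pulay DIIS on the commutator (default TRUE).
#' @param force_direct force the screened direct Fock path.
#' @param verbose print per-iteration energy and commutator norm.
#' @return An object of class `molvib_scf`: MO coefficients `C`, orbital
#'   energies `eps`, densities `P` and `D = 2P`, `E_total`, `n_occ`,
#'   `converged`, energy-weighted density `W_energy`, Fock matrix `F`,
#'   core Hamiltonian `h`, overlap `S`, the one-electron set `oe`, the ERI
#'   tensor `eri` when the dense path was used, `c_x`, `functional`,
#'   `grid`, `E_xc`, and the iteration `trace`.
#' @export
run_scf <- function(mol, basis, method = "hf", conv = 1e-6, screen = 1e-12,
                    max_iter = 100L, diis = TRUE, force_direct = FALSE,
                    verbose = FALSE) {
  nel <- n_electrons(mol)
  if (nel %% 2 != 0) stop("closed-shell SCF requires an even electron count",
                          call. = FALSE)
  n_occ <- nel %/% 2L
  n <- basis$n_ao
  if (n_occ > n) stop("basis too small for electron count", call. = FALSE)

  if (identical(method, "hf")) {
    c_x <- 1; functional <- NULL; grid_level <- "fine"
  } else if (is.list(method)) {
    c_x <- method$c_x %||% 1
    functional <- method$functional
    grid_level <- method$grid_level %||% "fine"
  } else stop("unknown method: ", method, call. = FALSE)

  oe <- one_electron_matrices(mol, basis)
  S <- oe$S
  h <- oe$T_kin + oe$V_nuc
  Enn <- nuclear_repulsion(mol)$energy

  # symmetric orthogonalization, canonical fallback for near-dependence
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-8) {
    keep <- es$values > 1e-8
    X <- es$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(es$values[keep]), sum(keep))
  } else {
    X <- es$vectors %*% diag(1 / sqrt(es$values), n) %*% t(es$vectors)
  }

  use_tensor <- !force_direct && n <= 64
  G <- NULL; scr <- NULL
  if (use_tensor) {
    scr <- schwarz_bounds(mol, basis, threshold = screen)
    G <- eri_tensor(mol, basis, screen = scr)
    gmat <- function(P) fock_from_tensor(G, P, c_x = c_x)
  } else {
    scr <- schwarz_bounds(mol, basis, threshold = screen)
    gmat <- function(P) build_fock_2e(P, mol, basis, c_x = c_x, screen = scr)
  }

  grid <- NULL
  if (!is.null(functional)) grid <- build_grid(mol, grid_level)

  # core-Hamiltonian initial guess
  mo_from_fock <- function(Fm) {
    Fo <- t(X) %*% Fm %*% X
    ef <- eigen((Fo + t(Fo)) / 2, symmetric = TRUE)
    ord <- order(ef$values)  # eigen() sorts decreasing; want ascending
    C <- X %*% ef$vectors[, ord, drop = FALSE]
    list(C = C, eps = ef$values[ord])
  }
  mo <- mo_from_fock(h)
  P <- tcrossprod(mo$C[, seq_len(n_occ), drop = FALSE])

  E_old <- Inf; converged <- FALSE
  err_list <- list(); fock_list <- list()
  trace <- data.frame(iter = integer(0), energy = numeric(0),
                      comm_norm = numeric(0))
  E_xc <- 0
  Fm <- NULL
  for (it in seq_len(max_iter)) {
    Gp <- gmat(P)
    Vxc <- NULL
    if (!is.null(functional)) {
      xc <- xc_energy_potential(2 * P, mol, basis, grid, functional)
      E_xc <- xc$energy
      Vxc <- xc$V
    }
    Fm <- h + Gp
    if (!is.null(Vxc)) Fm <- Fm + Vxc
    E <- Enn + 2 * sum(P * h) + sum(P * Gp) + E_xc
    err <- Fm %*% P %*% S - S %*% P %*% Fm
    cn <- max(abs(err))
    trace <- rbind(trace, data.frame(iter = it, energy = E, comm_norm = cn))
    if (verbose) message(sprintf("iter %3d  E = %.12f  |FDS-SDF| = %.3e", it, E, cn))
    if (abs(E - E_old) <= conv && cn <= conv && it > 1) {
      converged <- TRUE
      break
    }
    E_old <- E
    Fuse <- Fm
    if (diis) {
      err_list[[length(err_list) + 1L]] <- t(X) %*% err %*% X
      fock_list[[length(fock_list) + 1L]] <- Fm
      if (length(err_list) > 10) {
        err_list <- err_list[-1]; fock_list <- fock_list[-1]
      }
      m <- length(err_list)
      if (m >= 2) {
        B <- matrix(0, m + 1, m + 1)
        for (a in 1:m) for (b in 1:m) B[a, b] <- sum(err_list[[a]] * err_list[[b]])
        B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
        rhs <- c(rep(0, m), -1)
        cf <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
        if (!is.null(cf) && all(is.finite(cf))) {
          Fuse <- Reduce(`+`, Map(`*`, fock_list, cf))
        }
      }
    }
    mo <- mo_from_fock(Fuse)
    P <- tcrossprod(mo$C[, seq_len(n_occ), drop = FALSE])
  }
  if (!converged) {
    stop("SCF failed to converge in ", max_iter, " iterations (last |dE| = ",
         format(abs(E - E_old)), ", |FDS-SDF| = ", format(cn), ")",
         call. = FALSE)
  }
  mo <- mo_from_fock(Fm)
  P <- tcrossprod(mo$C[, seq_len(n_occ), drop = FALSE])
  Cocc <- mo$C[, seq_len(n_occ), drop = FALSE]
  W <- Cocc %*% (mo$eps[seq_len(n_occ)] * t(Cocc))
  structure(list(
    C = mo$C, eps = mo$eps, P = P, D = 2 * P, E_total = E,
    n_occ = n_occ, converged = converged, W_energy = 2 * W,
    F = Fm, h = h, S = S, oe = oe, eri = G, schwarz = scr,
    c_x = c_x, functional = functional, grid = grid, E_xc = E_xc,
    mol = mol, basis = basis, trace = trace
  ), class = "molvib_scf")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.molvib_scf <- function(x, ...) {
  cat(sprintf("<molvib_scf: E_total = %.10f hartree, %d iterations, %s>\n",
              x$E_total, nrow(x$trace),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# minimal independent SCF reference: dense diagonalization, no DIIS, no
# screening, late-contraction ERIs; used as an oracle at tiny scale
scf_reference <- function(mol, basis, conv = 1e-10, max_iter = 200L) {
  n <- basis$n_ao
  n_occ <- n_electrons(mol) %/% 2L
  oe <- one_electron_matrices(mol, basis)
  h <- oe$T_kin + oe$V_nuc
  S <- oe$S
  ns <- length(basis$shells)
  G <- array(0, dim = rep(n, 4))
  for (i in seq_len(ns)) for (j in seq_len(ns)) for (k in seq_len(ns))
    for (l in seq_len(ns)) {
      G[shell_ao_range(basis, i), shell_ao_range(basis, j),
        shell_ao_range(basis, k), shell_ao_range(basis, l)] <-
        eri_quartet_ref(mol, basis, i, j, k, l)
    }
  Enn <- nuclear_repulsion(mol)$energy
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), n) %*% t(es$vectors)
  Fm <- h
  E_old <- Inf
  for (it in seq_len(max_iter)) {
    Fo <- t(X) %*% Fm %*% X
    ef <- eigen((Fo + t(Fo)) / 2, symmetric = TRUE)
    ord <- order(ef$values)
    C <- X %*% ef$vectors[, ord, drop = FALSE]
    P <- tcrossprod(C[, seq_len(n_occ), drop = FALSE])
    Gp <- fock_from_tensor(G, P, c_x = 1)
    Fm <- h + Gp
    E <- Enn + 2 * sum(P * h) + sum(P * Gp)
    if (abs(E - E_old) < conv) return(list(energy = E, iter = it))
    E_old <- E
  }
  list(energy = E, iter = max_iter)
}
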