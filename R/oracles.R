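# Independent brute-force references used by the test suite: central finite
# differences over displaced geometries, a late-contraction scalar ERI path,
# 3-D quadrature for one-electron integrals, and a dense coupled-perturbed
# solver. These deliberately avoid the production recursion kernels; they
# share only elementary conventions (component ordering, spherical
# transformation matrices) so that comparisons are meaningful.

#' Central finite-difference geometric derivative
#'
#' Displaces one nuclear Cartesian coordinate of a molecule and applies a
#' central-difference stencil to an arbitrary function of the geometry.
#'
#' @param f function(molecule) returning a numeric scalar/vector/matrix.
#' @param mol a `molvib_molecule`.
#' @param atom atom index.
#' @param comp Cartesian component (1..3).
#' @param order derivative order, 1 or 2 (second along the same coordinate).
#' @param step step size in bohr.
#' @param stencil 2 or 4 point central stencil (order 1 only).
#' @return same shape as `f(mol)`.
#' @export
fd_derivative <- function(f, mol, atom, comp, order = 1L, step = 1e-4,
                          stencil = 2L) {
  disp <- function(h) {
    m <- mol
    m$coords[atom, comp] <- m$coords[atom, comp] + h
    f(m)
  }
  if (order == 1) {
    if (stencil == 4) {
      (8 * (disp(step) - disp(-step)) - (disp(2 * step) - disp(-2 * step))) /
        (12 * step)
    } else {
      (disp(step) - disp(-step)) / (2 * step)
    }
  } else if (order == 2) {
    (disp(step) - 2 * f(mol) + disp(-step)) / step^2
  } else {
    stop("unsupported derivative order: ", order, call. = FALSE)
  }
}

#' Mixed second finite difference over two coordinates
#' @inheritParams fd_derivative
#' @param atom2,comp2 second displacement coordinate.
#' @export
fd_derivative2 <- function(f, mol, atom, comp, atom2, comp2, step = 1e-3) {
  disp <- function(h1, h2) {
    m <- mol
    m$coords[atom, comp] <- m$coords[atom, comp] + h1
    m$coords[atom2, comp2] <- m$coords[atom2, comp2] + h2
    f(m)
  }
  (disp(step, step) - disp(step, -step) - disp(-step, step) +
     disp(-step, -step)) / (4 * step^2)
}

# ---- late-contraction scalar ERI reference --------------------------------

# primitive Cartesian [0b|0d] tables for one primitive quartet, scalar code
ref_prim_tables <- function(A, B, C, D, a, b, g, d, Lb, Ld) {
  zeta <- a + b; eta <- g + d
  P <- (a * A + b * B) / zeta
  Q <- (g * C + d * D) / eta
  rho <- zeta * eta / (zeta + eta)
  W <- (zeta * P + eta * Q) / (zeta + eta)
  Sab <- (pi / zeta)^1.5 * exp(-a * b / zeta * sum((A - B)^2))
  Scd <- (pi / eta)^1.5 * exp(-g * d / eta * sum((C - D)^2))
  Tv <- rho * sum((P - Q)^2)
  mmax <- Lb + Ld
  base <- 2 * sqrt(rho / pi) * Sab * Scd * drop(boys(mmax, Tv))
  PB <- P - B; QD <- Q - D; WP <- W - P; WQ <- W - Q
  V <- vector("list", Lb + 1)
  for (bb in 0:Lb) V[[bb + 1]] <- vector("list", Ld + 1)
  V[[1]][[1]] <- lapply(0:mmax, function(m) matrix(base[m + 1], 1, 1))
  if (Ld > 0) for (dd in 0:(Ld - 1)) {
    ct1 <- comp_table(dd + 1)$comps
    out <- vector("list", mmax - dd)
    for (m in 0:(mmax - dd - 1)) {
      v <- numeric(nrow(ct1))
      for (t in seq_len(nrow(ct1))) {
        i <- vrr_axis(ct1[t, ]); s <- map_shift_cached(dd + 1, i, -1L)[t]
        v[t] <- QD[i] * V[[1]][[dd + 1]][[m + 1]][1, s] +
          WQ[i] * V[[1]][[dd + 1]][[m + 2]][1, s]
        Ni <- comp_table(dd)$comps[s, i]
        if (Ni > 0) {
          s2 <- map_shift_cached(dd, i, -1L)[s]
          v[t] <- v[t] + Ni / (2 * eta) *
            (V[[1]][[dd]][[m + 1]][1, s2] - rho / eta * V[[1]][[dd]][[m + 2]][1, s2])
        }
      }
      out[[m + 1]] <- matrix(v, 1)
    }
    V[[1]][[dd + 2]] <- out
  }
  if (Lb > 0) for (bb in 0:(Lb - 1)) {
    ctb1 <- comp_table(bb + 1)$comps
    for (dd in 0:Ld) {
      ncd <- n_cart_comp(dd)
      nm <- mmax - (bb + 1) - dd
      if (nm < 0) next
      out <- vector("list", nm + 1)
      for (m in 0:nm) {
        M <- matrix(0, nrow(ctb1), ncd)
        for (t in seq_len(nrow(ctb1))) {
          i <- vrr_axis(ctb1[t, ]); s <- map_shift_cached(bb + 1, i, -1L)[t]
          M[t, ] <- PB[i] * V[[bb + 1]][[dd + 1]][[m + 1]][s, ] +
            WP[i] * V[[bb + 1]][[dd + 1]][[m + 2]][s, ]
          Ni <- comp_table(bb)$comps[s, i]
          if (Ni > 0) {
            s2 <- map_shift_cached(bb, i, -1L)[s]
            M[t, ] <- M[t, ] + Ni / (2 * zeta) *
              (V[[bb]][[dd + 1]][[m + 1]][s2, ] -
                 rho / zeta * V[[bb]][[dd + 1]][[m + 2]][s2, ])
          }
          if (dd >= 1) {
            dmm <- map_shift_cached(dd, i, -1L)
            for (u in seq_len(ncd)) {
              Nd <- comp_table(dd)$comps[u, i]
              if (Nd > 0) {
                M[t, u] <- M[t, u] + Nd / (2 * (zeta + eta)) *
                  V[[bb + 1]][[dd]][[m + 2]][s, dmm[u]]
              }
            }
          }
        }
        out[[m + 1]] <- M
      }
      V[[bb + 2]][[dd + 1]] <- out
    }
  }
  V
}

# primitive Cartesian (ab|cd) for one primitive quartet by all-Cartesian HRRs
ref_prim_quartet <- function(A, B, C, D, a, b, g, d, la, lb, lc, ld) {
  V <- ref_prim_tables(A, B, C, D, a, b, g, d, la + lb, lc + ld)
  DC <- D - C; BA <- B - A
  # ket transfer: X[[c+1]][[d+1]] over composite bra e (rows = comp(e))
  ketfor <- function(e) {
    X <- vector("list", lc + 1)
    for (cc in 0:lc) X[[cc + 1]] <- vector("list", lc + ld + 1)
    for (dd in ld:(lc + ld)) {
      X[[1]][[dd + 1]] <- array(V[[e + 1]][[dd + 1]][[1]],
                                dim = c(n_cart_comp(e), 1, n_cart_comp(dd)))
    }
    if (lc > 0) for (cc in 1:lc) {
      ctc <- comp_table(cc)$comps
      for (dd in ld:(lc + ld - cc)) {
        B1 <- X[[cc]][[dd + 1]]; B2 <- X[[cc]][[dd + 2]]
        R <- array(0, dim = c(n_cart_comp(e), nrow(ctc), n_cart_comp(dd)))
        for (t in seq_len(nrow(ctc))) {
          i <- vrr_axis(ctc[t, ]); s <- map_shift_cached(cc, i, -1L)[t]
          up <- map_shift_cached(dd, i, 1L)
          R[, t, ] <- DC[i] * B1[, s, ] + B2[, s, up]
        }
        X[[cc + 1]][[dd + 1]] <- R
      }
    }
    X[[lc + 1]][[ld + 1]]
  }
  K <- n_cart_comp(lc) * n_cart_comp(ld)
  kets <- lapply(lb:(la + lb), function(e) {
    matrix(ketfor(e), nrow = n_cart_comp(e), ncol = K)
  })
  # bra transfer
  Y <- vector("list", la + 1)
  for (aa in 0:la) Y[[aa + 1]] <- vector("list", la + lb + 1)
  for (bb in lb:(la + lb)) {
    Y[[1]][[bb + 1]] <- array(kets[[bb - lb + 1]], dim = c(1, n_cart_comp(bb), K))
  }
  if (la > 0) for (aa in 1:la) {
    cta <- comp_table(aa)$comps
    for (bb in lb:(la + lb - aa)) {
      B1 <- Y[[aa]][[bb + 1]]; B2 <- Y[[aa]][[bb + 2]]
      R <- array(0, dim = c(nrow(cta), n_cart_comp(bb), K))
      for (t in seq_len(nrow(cta))) {
        i <- vrr_axis(cta[t, ]); s <- map_shift_cached(aa, i, -1L)[t]
        up <- map_shift_cached(bb, i, 1L)
        R[t, , ] <- BA[i] * B1[s, , ] + B2[s, up, ]
      }
      Y[[aa + 1]][[bb + 1]] <- R
    }
  }
  array(Y[[la + 1]][[lb + 1]],
        dim = c(n_cart_comp(la), n_cart_comp(lb), n_cart_comp(lc), n_cart_comp(ld)))
}

#' Late-contraction reference ERI quartet
#'
#' Slow reference path: every primitive quartet is evaluated fully in the
#' Cartesian representation, contraction over primitives happens only at the
#' very end, and the spherical transformation is applied last. Used as the
#' independent check of the early-contraction mixed-representation engine.
#'
#' @inheritParams eri_quartet
#' @return 4D array matching [eri_quartet()].
#' @export
eri_quartet_ref <- function(mol, basis, i, j, k, l) {
  sh <- basis$shells[c(i, j, k, l)]
  ctr <- lapply(sh, function(s) mol$coords[s$atom, ])
  ls <- vapply(sh, `[[`, 0L, "l")
  acc <- array(0, dim = vapply(ls, n_cart_comp, 0L))
  for (pa in seq_along(sh[[1]]$coef)) for (pb in seq_along(sh[[2]]$coef))
    for (pc in seq_along(sh[[3]]$coef)) for (pd in seq_along(sh[[4]]$coef)) {
      w <- sh[[1]]$coef[pa] * sh[[2]]$coef[pb] * sh[[3]]$coef[pc] * sh[[4]]$coef[pd]
      acc <- acc + w * ref_prim_quartet(
        ctr[[1]], ctr[[2]], ctr[[3]], ctr[[4]],
        sh[[1]]$exponents[pa], sh[[2]]$exponents[pb],
        sh[[3]]$exponents[pc], sh[[4]]$exponents[pd],
        ls[1], ls[2], ls[3], ls[4])
    }
  sph_transform4(acc, ls)
}

# ---- quadrature overlap oracle --------------------------------------------

# numeric 3-D quadrature of the overlap of two contracted s-type AOs on a
# Gauss-Hermite-like product grid (used for a single cross-check)
overlap_quadrature <- function(exp1, coef1, A, exp2, coef2, B, n = 60, half = 8) {
  g <- seq(-half, half, length.out = n)
  h <- g[2] - g[1]
  pts <- as.matrix(expand.grid(x = g + (A[1] + B[1]) / 2,
                               y = g + (A[2] + B[2]) / 2,
                               z = g + (A[3] + B[3]) / 2))
  r1 <- rowSums((pts - matrix(A, nrow(pts), 3, byrow = TRUE))^2)
  r2 <- rowSums((pts - matrix(B, nrow(pts), 3, byrow = TRUE))^2)
  f1 <- rowSums(vapply(seq_along(exp1),
                       function(p) coef1[p] * exp(-exp1[p] * r1), numeric(length(r1))))
  f2 <- rowSums(vapply(seq_along(exp2),
                       function(p) coef2[p] * exp(-exp2[p] * r2), numeric(length(r2))))
  sum(f1 * f2) * h^3
}
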