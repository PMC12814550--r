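# One-electron integrals (overlap, kinetic, nuclear attraction, dipole
# moments) and their first and second geometric derivatives.
#
# Evaluated with the McMurchie-Davidson Hermite-Gaussian expansion, a
# different formulation from the Obara-Saika two-electron path, which keeps
# the one- and two-electron codes independent. Geometric derivatives are
# assembled from the primitive angular-momentum shift rule
#   d/dA_i chi(l) = 2*alpha*chi(l+1_i) - N_i(l)*chi(l-1_i)
# applied per shell slot, with the nuclear-attraction operator-center
# derivative closed by translational invariance.

# Hermite expansion coefficients E_t^{ij} for one dimension.
# Returns array E[i+1, j+1, t+1] for i<=imax, j<=jmax, t<=i+j.
hermite_E <- function(imax, jmax, p, PA, PB, Kab) {
  E <- array(0, dim = c(imax + 1, jmax + 1, imax + jmax + 1))
  E[1, 1, 1] <- Kab
  i2p <- 1 / (2 * p)
  if (imax > 0) for (i in 1:imax) {
    for (t in 0:(i + 0)) {
      v <- PA * E[i, 1, t + 1]
      if (t > 0) v <- v + i2p * E[i, 1, t]
      if (t + 2 <= i) v <- v + (t + 1) * E[i, 1, t + 2]
      E[i + 1, 1, t + 1] <- v
    }
  }
  if (jmax > 0) for (j in 1:jmax) {
    for (i in 0:imax) {
      for (t in 0:(i + j)) {
        v <- PB * E[i + 1, j, t + 1]
        if (t > 0) v <- v + i2p * E[i + 1, j, t]
        if (t + 2 <= i + j) v <- v + (t + 1) * E[i + 1, j, t + 2]
        E[i + 1, j + 1, t + 1] <- v
      }
    }
  }
  E
}

# Hermite Coulomb integrals R_{tuv} (n = 0) for argument center PC
hermite_R <- function(tmax, umax, vmax, p, PC) {
  nmax <- tmax + umax + vmax
  Fm <- drop(boys(nmax, p * sum(PC * PC)))
  base <- (-2 * p)^(0:nmax) * Fm
  R <- array(0, dim = c(nmax + 1, tmax + 1, umax + 1, vmax + 1))
  R[, 1, 1, 1] <- base
  if (tmax > 0) for (t in 1:tmax) for (n in 0:(nmax - t)) {
    v <- PC[1] * R[n + 2, t, 1, 1]
    if (t > 1) v <- v + (t - 1) * R[n + 2, t - 1, 1, 1]
    R[n + 1, t + 1, 1, 1] <- v
  }
  if (umax > 0) for (u in 1:umax) for (t in 0:tmax) for (n in 0:(nmax - t - u)) {
    v <- PC[2] * R[n + 2, t + 1, u, 1]
    if (u > 1) v <- v + (u - 1) * R[n + 2, t + 1, u - 1, 1]
    R[n + 1, t + 1, u + 1, 1] <- v
  }
  if (vmax > 0) for (w in 1:vmax) for (u in 0:umax) for (t in 0:tmax)
    for (n in 0:(nmax - t - u - w)) {
      v <- PC[3] * R[n + 2, t + 1, u + 1, w]
      if (w > 1) v <- v + (w - 1) * R[n + 2, t + 1, u + 1, w - 1]
      R[n + 1, t + 1, u + 1, w + 1] <- v
    }
  R[1, , , , drop = FALSE]
}

# per-pair environment with primitive data; extra angular headroom for
# derivatives (da on slot a, db on slot b)
pair_env <- function(sh1, sh2, A, B, da = 0L, db = 0L) {
  imax <- sh1$l + da
  jmax <- sh2$l + db + 2L  # +2 headroom for the kinetic-energy form
  prims <- list()
  k <- 1L
  for (p1 in seq_along(sh1$coef)) for (p2 in seq_along(sh2$coef)) {
    a <- sh1$exponents[p1]; b <- sh2$exponents[p2]
    p <- a + b
    P <- (a * A + b * B) / p
    Kd <- exp(-a * b / p * (A - B)^2)
    E <- lapply(1:3, function(d) {
      hermite_E(imax, jmax, p, P[d] - A[d], P[d] - B[d], Kd[d])
    })
    prims[[k]] <- list(a = a, b = b, p = p, P = P, E = E,
                       w = sh1$coef[p1] * sh2$coef[p2])
    k <- k + 1L
  }
  list(prims = prims, la = sh1$l, lb = sh2$l, A = A, B = B,
       imax = imax, jmax = jmax)
}

# Cartesian operator block for angular momenta (la2, lb2) with exponent
# weights (2a)^wa (2b)^wb.  op: "S", "T", "Dx", "Dy", "Dz", or "V" (with C).
pair_block <- function(pe, la2, lb2, wa = 0L, wb = 0L, op = "S",
                       C = NULL, origin = c(0, 0, 0)) {
  if (la2 < 0 || lb2 < 0) return(NULL)
  ca <- comp_table(la2)$comps; cb <- comp_table(lb2)$comps
  na <- nrow(ca); nb <- nrow(cb)
  out <- matrix(0, na, nb)
  dipd <- match(op, c("Dx", "Dy", "Dz"))
  for (pr in pe$prims) {
    w <- pr$w * (2 * pr$a)^wa * (2 * pr$b)^wb
    sq <- sqrt(pi / pr$p)
    E <- pr$E
    S1 <- function(d, i, j) E[[d]][i + 1, j + 1, 1] * sq
    blk <- matrix(0, na, nb)
    if (op == "S") {
      for (u in seq_len(na)) for (v in seq_len(nb)) {
        blk[u, v] <- S1(1, ca[u, 1], cb[v, 1]) * S1(2, ca[u, 2], cb[v, 2]) *
          S1(3, ca[u, 3], cb[v, 3])
      }
    } else if (op == "T") {
      b <- pr$b
      T1 <- function(d, i, j) {
        v <- b * (2 * j + 1) * S1(d, i, j) - 2 * b^2 * S1(d, i, j + 2)
        if (j >= 2) v <- v - 0.5 * j * (j - 1) * S1(d, i, j - 2)
        v
      }
      for (u in seq_len(na)) for (v in seq_len(nb)) {
        i <- ca[u, ]; j <- cb[v, ]
        blk[u, v] <- T1(1, i[1], j[1]) * S1(2, i[2], j[2]) * S1(3, i[3], j[3]) +
          S1(1, i[1], j[1]) * T1(2, i[2], j[2]) * S1(3, i[3], j[3]) +
          S1(1, i[1], j[1]) * S1(2, i[2], j[2]) * T1(3, i[3], j[3])
      }
    } else if (!is.na(dipd)) {
      M1 <- function(d, i, j) {
        v <- (pr$P[d] - origin[d]) * E[[d]][i + 1, j + 1, 1]
        if (i + j >= 1) v <- v + E[[d]][i + 1, j + 1, 2]
        v * sq
      }
      for (u in seq_len(na)) for (v in seq_len(nb)) {
        i <- ca[u, ]; j <- cb[v, ]
        f <- 1
        for (d in 1:3) f <- f * (if (d == dipd) M1(d, i[d], j[d]) else S1(d, i[d], j[d]))
        blk[u, v] <- f
      }
    } else if (op == "V") {
      PC <- pr$P - C
      lt <- la2 + lb2
      R <- hermite_R(lt, lt, lt, pr$p, PC)
      pref <- 2 * pi / pr$p
      for (u in seq_len(na)) for (v in seq_len(nb)) {
        i <- ca[u, ]; j <- cb[v, ]
        acc <- 0
        for (t in 0:(i[1] + j[1])) for (s in 0:(i[2] + j[2])) for (r in 0:(i[3] + j[3])) {
          acc <- acc + E[[1]][i[1] + 1, j[1] + 1, t + 1] *
            E[[2]][i[2] + 1, j[2] + 1, s + 1] *
            E[[3]][i[3] + 1, j[3] + 1, r + 1] * R[1, t + 1, s + 1, r + 1]
        }
        blk[u, v] <- pref * acc
      }
    } else stop("unknown one-electron operator: ", op, call. = FALSE)
    out <- out + w * blk
  }
  out
}

# first derivative of a pair block with respect to slot 1 (A) or 2 (B)
pair_block_d1 <- function(pe, slot, axis, op, C = NULL, origin = c(0, 0, 0)) {
  la <- pe$la; lb <- pe$lb
  if (slot == 1) {
    up <- pair_block(pe, la + 1, lb, wa = 1L, op = op, C = C, origin = origin)
    dn <- pair_block(pe, la - 1, lb, op = op, C = C, origin = origin)
    shift_assemble(up, dn, la, lb, 1L, axis)
  } else {
    up <- pair_block(pe, la, lb + 1, wb = 1L, op = op, C = C, origin = origin)
    dn <- pair_block(pe, la, lb - 1, op = op, C = C, origin = origin)
    shift_assemble(up, dn, la, lb, 2L, axis)
  }
}

# assemble 2*exp-raised and N-lowered blocks into a derivative block
shift_assemble <- function(up, dn, la, lb, slot, axis) {
  if (slot == 1L) {
    ct <- comp_table(la)$comps
    mp_up <- map_shift_cached(la, axis, 1L)
    mp_dn <- if (la > 0) map_shift_cached(la, axis, -1L) else NULL
    out <- up[mp_up, , drop = FALSE]
    for (u in seq_len(nrow(ct))) {
      if (ct[u, axis] > 0) out[u, ] <- out[u, ] - ct[u, axis] * dn[mp_dn[u], ]
    }
  } else {
    ct <- comp_table(lb)$comps
    mp_up <- map_shift_cached(lb, axis, 1L)
    mp_dn <- if (lb > 0) map_shift_cached(lb, axis, -1L) else NULL
    out <- up[, mp_up, drop = FALSE]
    for (v in seq_len(nrow(ct))) {
      if (ct[v, axis] > 0) out[, v] <- out[, v] - ct[v, axis] * dn[, mp_dn[v]]
    }
  }
  out
}

# second derivative w.r.t. (slot1, axis i) and (slot2, axis j)
pair_block_d2 <- function(pe, slot1, i, slot2, j, op, C = NULL,
                          origin = c(0, 0, 0)) {
  la <- pe$la; lb <- pe$lb
  if (slot1 != slot2) {
    # independent operators on different slots
    g <- function(dla, dlb, wa, wb) pair_block(pe, la + dla, lb + dlb,
                                               wa = wa, wb = wb, op = op,
                                               C = C, origin = origin)
    if (slot1 == 2L) { tmp <- i; i <- j; j <- tmp }  # slot1 -> A, slot2 -> B
    pp <- g(1L, 1L, 1L, 1L); pm <- g(1L, -1L, 1L, 0L)
    mp <- g(-1L, 1L, 0L, 1L); mm <- g(-1L, -1L, 0L, 0L)
    cta <- comp_table(la)$comps; ctb <- comp_table(lb)$comps
    ua <- map_shift_cached(la, i, 1L)
    da <- if (la > 0) map_shift_cached(la, i, -1L) else NULL
    ub <- map_shift_cached(lb, j, 1L)
    db <- if (lb > 0) map_shift_cached(lb, j, -1L) else NULL
    out <- matrix(0, nrow(cta), nrow(ctb))
    for (u in seq_len(nrow(cta))) for (v in seq_len(nrow(ctb))) {
      acc <- pp[ua[u], ub[v]]
      if (ctb[v, j] > 0) acc <- acc - ctb[v, j] * pm[ua[u], db[v]]
      if (cta[u, i] > 0) acc <- acc - cta[u, i] * mp[da[u], ub[v]]
      if (cta[u, i] > 0 && ctb[v, j] > 0) {
        acc <- acc + cta[u, i] * ctb[v, j] * mm[da[u], db[v]]
      }
      out[u, v] <- acc
    }
    out
  } else {
    # same slot: apply the one-center second-derivative shift rule
    slot <- slot1
    l0 <- if (slot == 1L) la else lb
    g <- function(dl, wp) {
      if (slot == 1L) pair_block(pe, la + dl, lb, wa = wp, op = op, C = C,
                                 origin = origin)
      else pair_block(pe, la, lb + dl, wb = wp, op = op, C = C, origin = origin)
    }
    b2 <- g(2L, 2L); b0 <- g(0L, 1L); bm <- g(-2L, 0L)
    ct <- comp_table(l0)$comps
    idx2 <- comp_table(l0 + 2)$index
    idx0 <- comp_table(l0)$index
    idxm <- if (l0 >= 2) comp_table(l0 - 2)$index else NULL
    nc0 <- nrow(ct)
    pick <- function(mat, row_idx, slot) {
      if (slot == 1L) mat[row_idx, , drop = FALSE] else t(mat[, row_idx, drop = FALSE])
    }
    nother <- if (slot == 1L) ncol(b0) else nrow(b0)
    out <- matrix(0, nc0, nother)
    dij <- as.integer(i == j)
    for (u in seq_len(nc0)) {
      t <- ct[u, ]
      tp <- t; tp[i] <- tp[i] + 1L; tp[j] <- tp[j] + 1L
      acc <- pick(b2, idx2[tp[1] + 1, tp[2] + 1, tp[3] + 1], slot)
      # - (N_i + delta_ij) [t +1_j -1_i] - N_j [t +1_i -1_j]
      if (t[i] + dij > 0 && (t[i] > 0 || i == j)) {
        tm <- t; tm[j] <- tm[j] + 1L; tm[i] <- tm[i] - 1L
        if (all(tm >= 0)) {
          acc <- acc - (t[i] + dij) * pick(b0, idx0[tm[1] + 1, tm[2] + 1, tm[3] + 1], slot)
        }
      }
      if (t[j] > 0) {
        tm <- t; tm[i] <- tm[i] + 1L; tm[j] <- tm[j] - 1L
        if (all(tm >= 0)) {
          acc <- acc - t[j] * pick(b0, idx0[tm[1] + 1, tm[2] + 1, tm[3] + 1], slot)
        }
      }
      if (t[j] > 0 && t[i] - dij > 0) {
        tm <- t; tm[i] <- tm[i] - 1L; tm[j] <- tm[j] - 1L
        if (all(tm >= 0)) {
          acc <- acc + t[j] * (t[i] - dij) *
            pick(bm, idxm[tm[1] + 1, tm[2] + 1, tm[3] + 1], slot)
        }
      }
      out[u, ] <- acc
    }
    if (slot == 1L) out else t(out)
  }
}

sph_pair <- function(blk, la, lb) {
  cart_to_spherical(la) %*% blk %*% t(cart_to_spherical(lb))
}

#' One-electron integral matrices
#'
#' Overlap, kinetic energy, nuclear attraction and the three electric
#' dipole-moment matrices over spherical AOs.
#'
#' @param mol a `molvib_molecule`.
#' @param basis a `molvib_basis`.
#' @param origin dipole origin (bohr); default center of nuclear charge.
#' @param strict if `TRUE`, near-linear dependence of the overlap
#'   (smallest eigenvalue < 1e-10) is an error instead of a warning.
#' @return list with `S`, `T_kin`, `V_nuc` (hartree), `D_dip` (list of 3
#'   moment matrices, e bohr), and `origin`.
#' @export
one_electron_matrices <- function(mol, basis, origin = center_of_charge(mol),
                                  strict = FALSE) {
  n <- basis$n_ao
  ns <- length(basis$shells)
  S <- Tk <- V <- matrix(0, n, n)
  Dip <- lapply(1:3, function(d) matrix(0, n, n))
  for (ii in seq_len(ns)) for (jj in 1:ii) {
    s1 <- basis$shells[[ii]]; s2 <- basis$shells[[jj]]
    pe <- pair_env(s1, s2, mol$coords[s1$atom, ], mol$coords[s2$atom, ])
    ri <- shell_ao_range(basis, ii); rj <- shell_ao_range(basis, jj)
    put <- function(M, blk) {
      M[ri, rj] <- sph_pair(blk, s1$l, s2$l)
      if (ii != jj) M[rj, ri] <- t(M[ri, rj])
      M
    }
    S <- put(S, pair_block(pe, s1$l, s2$l, op = "S"))
    Tk <- put(Tk, pair_block(pe, s1$l, s2$l, op = "T"))
    vblk <- 0
    for (at in seq_along(mol$charges)) {
      vblk <- vblk - mol$charges[at] *
        pair_block(pe, s1$l, s2$l, op = "V", C = mol$coords[at, ])
    }
    V <- put(V, vblk)
    for (d in 1:3) {
      Dip[[d]] <- put(Dip[[d]], pair_block(pe, s1$l, s2$l,
                                           op = c("Dx", "Dy", "Dz")[d],
                                           origin = origin))
    }
  }
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-10) {
    msg <- paste0("near-linear dependence in basis: smallest overlap eigenvalue ",
                  format(ev_min))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  list(S = S, T_kin = Tk, V_nuc = V, D_dip = Dip, origin = origin)
}

#' Geometric derivatives of one-electron matrices
#'
#' First (and optionally second) derivatives of the overlap, kinetic,
#' nuclear-attraction and dipole matrices with respect to nuclear Cartesian
#' displacements. The nuclear-attraction derivative includes the
#' operator-center term, so the translational sum over atoms vanishes for
#' every matrix.
#'
#' @inheritParams one_electron_matrices
#' @param order 1 or 2.
#' @return list with `dS`, `dT`, `dV` (arrays n_ao x n_ao x 3N),
#'   `dDip` (array n_ao x n_ao x 3 x 3N, moment component first), and for
#'   `order = 2` also `d2S`, `d2T`, `d2V` (arrays n_ao x n_ao x 3N x 3N).
#' @export
one_electron_derivatives <- function(mol, basis, order = 1L,
                                     origin = center_of_charge(mol)) {
  if (!order %in% c(1L, 2L)) {
    stop("unsupported derivative order: ", order, call. = FALSE)
  }
  n <- basis$n_ao
  nat <- nrow(mol$coords)
  n3 <- 3L * nat
  ns <- length(basis$shells)
  dS <- dT <- dV <- array(0, dim = c(n, n, n3))
  dDip <- array(0, dim = c(n, n, 3, n3))
  if (order >= 2) d2S <- d2T <- d2V <- array(0, dim = c(n, n, n3, n3))

  xi <- function(atom, comp) 3L * (atom - 1L) + comp

  for (ii in seq_len(ns)) for (jj in 1:ii) {
    s1 <- basis$shells[[ii]]; s2 <- basis$shells[[jj]]
    atA <- s1$atom; atB <- s2$atom
    pe <- pair_env(s1, s2, mol$coords[atA, ], mol$coords[atB, ],
                   da = order, db = order)
    ri <- shell_ao_range(basis, ii); rj <- shell_ao_range(basis, jj)
    la <- s1$l; lb <- s2$l
    sym_add <- function(A3, blk, k) {
      A3[ri, rj, k] <- A3[ri, rj, k] + blk
      if (ii != jj) A3[rj, ri, k] <- A3[rj, ri, k] + t(blk)
      else if (!identical(ri, rj)) NULL
      A3
    }
    # first derivatives, slots A and B, operators S/T/dipole
    for (slot in 1:2) {
      at <- if (slot == 1) atA else atB
      for (ax in 1:3) {
        k <- xi(at, ax)
        for (opn in c("S", "T")) {
          blk <- sph_pair(pair_block_d1(pe, slot, ax, opn), la, lb)
          if (opn == "S") dS <- sym_add(dS, blk, k) else dT <- sym_add(dT, blk, k)
        }
        for (d in 1:3) {
          blk <- sph_pair(pair_block_d1(pe, slot, ax, c("Dx", "Dy", "Dz")[d],
                                        origin = origin), la, lb)
          dDip[ri, rj, d, k] <- dDip[ri, rj, d, k] + blk
          if (ii != jj) dDip[rj, ri, d, k] <- dDip[rj, ri, d, k] + t(blk)
        }
      }
    }
    # nuclear attraction: slots A, B and operator centers C
    for (at in seq_len(nat)) {
      Z <- mol$charges[at]; C <- mol$coords[at, ]
      dA <- lapply(1:3, function(ax) {
        -Z * sph_pair(pair_block_d1(pe, 1L, ax, "V", C = C), la, lb)
      })
      dB <- lapply(1:3, function(ax) {
        -Z * sph_pair(pair_block_d1(pe, 2L, ax, "V", C = C), la, lb)
      })
      for (ax in 1:3) {
        dV <- sym_add(dV, dA[[ax]], xi(atA, ax))
        dV <- sym_add(dV, dB[[ax]], xi(atB, ax))
        dV <- sym_add(dV, -(dA[[ax]] + dB[[ax]]), xi(at, ax))  # operator center
      }
    }
    if (order >= 2) {
      # ordered (xi, zeta) accumulation: cross-slot contributions (A_i, B_j)
      # and (B_j, A_i) are distinct derivative pairs and are both added,
      # also when they fall on the same entry (shells sharing an atom)
      sym_add2 <- function(A4, blk, k1, k2, mirror) {
        A4[ri, rj, k1, k2] <- A4[ri, rj, k1, k2] + blk
        if (ii != jj) A4[rj, ri, k1, k2] <- A4[rj, ri, k1, k2] + t(blk)
        if (mirror) {
          A4[ri, rj, k2, k1] <- A4[ri, rj, k2, k1] + blk
          if (ii != jj) A4[rj, ri, k2, k1] <- A4[rj, ri, k2, k1] + t(blk)
        }
        A4
      }
      slotpairs <- list(c(1L, 1L), c(1L, 2L), c(2L, 2L))
      for (sp in slotpairs) {
        at1 <- if (sp[1] == 1) atA else atB
        at2 <- if (sp[2] == 1) atA else atB
        cross <- sp[1] != sp[2]
        for (i in 1:3) for (j in 1:3) {
          if (!cross && j < i) next
          k1 <- xi(at1, i); k2 <- xi(at2, j)
          mirror <- if (cross) TRUE else (k1 != k2)
          for (opn in c("S", "T")) {
            blk <- sph_pair(pair_block_d2(pe, sp[1], i, sp[2], j, opn), la, lb)
            if (opn == "S") d2S <- sym_add2(d2S, blk, k1, k2, mirror)
            else d2T <- sym_add2(d2T, blk, k1, k2, mirror)
          }
        }
      }
      # nuclear attraction second derivatives: the slot partials AA, AB, BB
      # are evaluated directly; partials involving the operator center C
      # follow from translational invariance d/dC = -(d/dA + d/dB).
      acc <- function(A4, blk, k1, k2) {
        A4[ri, rj, k1, k2] <- A4[ri, rj, k1, k2] + blk
        if (ii != jj) A4[rj, ri, k1, k2] <- A4[rj, ri, k1, k2] + t(blk)
        A4
      }
      for (at in seq_len(nat)) {
        Z <- mol$charges[at]; C <- mol$coords[at, ]
        AA <- BB <- AB <- array(list(), dim = c(3, 3))
        for (i in 1:3) for (j in 1:3) {
          AB[[i, j]] <- -Z * sph_pair(pair_block_d2(pe, 1L, i, 2L, j, "V", C = C), la, lb)
          if (j >= i) {
            AA[[i, j]] <- -Z * sph_pair(pair_block_d2(pe, 1L, i, 1L, j, "V", C = C), la, lb)
            BB[[i, j]] <- -Z * sph_pair(pair_block_d2(pe, 2L, i, 2L, j, "V", C = C), la, lb)
          } else {
            AA[[i, j]] <- AA[[j, i]]; BB[[i, j]] <- BB[[j, i]]
          }
        }
        for (i in 1:3) for (j in 1:3) {
          aa <- AA[[i, j]]; bb <- BB[[i, j]]
          ab <- AB[[i, j]]; ba <- AB[[j, i]]  # d2/dB_i dA_j = d2/dA_j dB_i
          d2V <- acc(d2V, aa, xi(atA, i), xi(atA, j))
          d2V <- acc(d2V, bb, xi(atB, i), xi(atB, j))
          d2V <- acc(d2V, ab, xi(atA, i), xi(atB, j))
          d2V <- acc(d2V, ba, xi(atB, i), xi(atA, j))
          d2V <- acc(d2V, -(aa + ab), xi(atA, i), xi(at, j))
          d2V <- acc(d2V, -(aa + ba), xi(at, i), xi(atA, j))
          d2V <- acc(d2V, -(ba + bb), xi(atB, i), xi(at, j))
          d2V <- acc(d2V, -(ab + bb), xi(at, i), xi(atB, j))
          d2V <- acc(d2V, aa + ab + ba + bb, xi(at, i), xi(at, j))
        }
      }
    }
  }
  out <- list(dS = dS, dT = dT, dV = dV, dDip = dDip)
  if (order >= 2) out <- c(out, list(d2S = d2S, d2T = d2T, d2V = d2V))
  out
}
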