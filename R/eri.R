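# Shell-quartet electron-repulsion integrals by the Obara-Saika scheme:
#
#   1. auxiliary integrals [00|00]^(m) from pair overlaps and the Boys function
#   2. vertical recursion raising angular momentum on the second ket center
#   3. vertical recursion raising angular momentum on the second bra center
#      (both carried out in the primitive Cartesian basis, vectorized over
#      all primitive quartets of the contracted shells)
#   4. early contraction of the primitive [0b|0d] tables, optionally with
#      several exponent-weighted contraction vectors at once -- the hook
#      used by the geometric-derivative module
#   5. horizontal recursion transferring ket angular momentum
#   6. ket Cartesian -> spherical transformation
#   7. horizontal recursion transferring bra angular momentum in the mixed
#      Cartesian/spherical representation
#   8. bra Cartesian -> spherical transformation
#   9. distribution into Fock/gradient/Hessian accumulators (callers)
#
# A fully Cartesian target path (spherical transformation deferred to the
# very end) is also provided; the derivative module uses it because angular
# raising/lowering must act on Cartesian components.

# index maps between component sets of l and l+1 / l-1 along an axis
map_shift <- function(l, axis, dir) {
  ct <- comp_table(l)$comps
  tgt <- comp_table(l + dir)
  out <- integer(nrow(ct))
  for (r in seq_len(nrow(ct))) {
    p <- ct[r, ]
    p[axis] <- p[axis] + dir
    out[r] <- if (p[axis] < 0) NA_integer_ else tgt$index[p[1] + 1, p[2] + 1, p[3] + 1]
  }
  out
}

.map_cache <- local({
  # dense lookup table: [[l+1]][[axis]][[dir_index]] (dir_index: 1 = -1, 2 = +1)
  tab <- vector("list", .MAX_COMPOSITE_L + 1L)
  for (l in 0:.MAX_COMPOSITE_L) {
    tab[[l + 1L]] <- lapply(1:3, function(axis) {
      list(if (l > 0) map_shift(l, axis, -1L) else NULL,
           map_shift(l, axis, 1L))
    })
  }
  tab
})
map_shift_cached <- function(l, axis, dir) {
  .map_cache[[l + 1L]][[axis]][[if (dir < 0) 1L else 2L]]
}

# first axis with nonzero power, and the reduced component index
vrr_axis <- function(comp) which(comp > 0)[1]

#' @keywords internal
quartet_env <- function(mol, basis, si, sj, sk, sl,
                        bra_extra = 0L, ket_extra = 0L) {
  sh <- basis$shells[c(si, sj, sk, sl)]
  ctr <- lapply(sh, function(s) mol$coords[s$atom, ])
  ls <- vapply(sh, `[[`, 0L, "l")
  Lb <- ls[1] + ls[2] + bra_extra
  Ld <- ls[3] + ls[4] + ket_extra
  mmax <- Lb + Ld

  A <- ctr[[1]]; B <- ctr[[2]]; C <- ctr[[3]]; D <- ctr[[4]]
  ea <- sh[[1]]$exponents; eb <- sh[[2]]$exponents
  ec <- sh[[3]]$exponents; ed <- sh[[4]]$exponents
  ca <- sh[[1]]$coef; cb <- sh[[2]]$coef
  cc <- sh[[3]]$coef; cd <- sh[[4]]$coef
  na <- length(ea); nb <- length(eb); nc <- length(ec); nd <- length(ed)

  # bra pair data (pa fastest)
  al <- rep(ea, times = nb); be <- rep(eb, each = na)
  zeta <- al + be
  AB <- A - B
  P <- (outer(al, A) + outer(be, B)) / zeta
  PB <- P - matrix(B, length(al), 3, byrow = TRUE)
  Sab <- (pi / zeta)^1.5 * exp(-al * be / zeta * sum(AB * AB))
  wbra <- rep(ca, times = nb) * rep(cb, each = na)

  # ket pair data (pc fastest)
  ga <- rep(ec, times = nd); de <- rep(ed, each = nc)
  eta <- ga + de
  CD <- C - D
  Q <- (outer(ga, C) + outer(de, D)) / eta
  QD <- Q - matrix(D, length(ga), 3, byrow = TRUE)
  Scd <- (pi / eta)^1.5 * exp(-ga * de / eta * sum(CD * CD))
  wket <- rep(cc, times = nd) * rep(cd, each = nc)

  nbp <- length(al); nkp <- length(ga)
  ib <- rep(seq_len(nbp), times = nkp)
  ik <- rep(seq_len(nkp), each = nbp)
  zq <- zeta[ib]; eq <- eta[ik]
  rho <- zq * eq / (zq + eq)
  Wc <- (zq * P[ib, , drop = FALSE] + eq * Q[ik, , drop = FALSE]) / (zq + eq)
  WP <- Wc - P[ib, , drop = FALSE]
  WQ <- Wc - Q[ik, , drop = FALSE]
  PQ <- P[ib, , drop = FALSE] - Q[ik, , drop = FALSE]
  Tb <- rho * rowSums(PQ * PQ)
  Fm <- boys(mmax, Tb)
  base <- 2 * sqrt(rho / pi) * Sab[ib] * Scd[ik] * Fm  # nw x (mmax+1)

  env <- new.env(parent = emptyenv())
  env$ls <- ls; env$Lb <- Lb; env$Ld <- Ld; env$mmax <- mmax
  env$atoms <- vapply(sh, `[[`, 0L, "atom")
  env$BA <- B - A; env$DC <- -CD
  env$nw <- nbp * nkp
  env$alpha_w <- al[ib]; env$beta_w <- be[ib]
  env$gamma_w <- ga[ik]; env$delta_w <- de[ik]
  env$wplain <- wbra[ib] * wket[ik]
  env$PBw <- PB[ib, , drop = FALSE]; env$QDw <- QD[ik, , drop = FALSE]
  env$WP <- WP; env$WQ <- WQ
  env$i2z <- 1 / (2 * zq); env$i2e <- 1 / (2 * eq)
  env$roz <- rho / zq; env$roe <- rho / eq
  env$i2ze <- 1 / (2 * (zq + eq))
  env$V <- build_vrr_tables(env, base)
  env$ctab <- list(); env$ket <- list(); env$bra <- list(); env$cart <- list()
  env
}

# primitive [0b|0d]^(m) tables: V[[b+1]][[d+1]][[m+1]] is nw x (cb*cd)
build_vrr_tables <- function(env, base) {
  Lb <- env$Lb; Ld <- env$Ld; mmax <- env$mmax
  V <- vector("list", Lb + 1)
  for (b in 0:Lb) V[[b + 1]] <- vector("list", Ld + 1)
  V[[1]][[1]] <- lapply(0:mmax, function(m) base[, m + 1, drop = FALSE])

  # ket ladder at b = 0
  if (Ld > 0) for (d in 0:(Ld - 1)) {
    ctd <- comp_table(d)$comps; ncd1 <- n_cart_comp(d + 1)
    mp <- lapply(1:3, function(i) map_shift_cached(d, i, 1L))
    ctd1 <- comp_table(d + 1)$comps
    src <- V[[1]][[d + 1]]
    low <- if (d >= 1) V[[1]][[d]] else NULL
    nm <- mmax - (d + 1)
    out <- vector("list", nm + 1)
    for (m in 0:nm) {
      M <- matrix(0, env$nw, ncd1)
      for (t in seq_len(ncd1)) {
        i <- vrr_axis(ctd1[t, ])
        s <- map_shift_cached(d + 1, i, -1L)[t]
        M[, t] <- env$QDw[, i] * src[[m + 1]][, s] + env$WQ[, i] * src[[m + 2]][, s]
        Ni <- ctd[s, i]
        if (Ni > 0) {
          s2 <- map_shift_cached(d, i, -1L)[s]
          M[, t] <- M[, t] + Ni * env$i2e *
            (low[[m + 1]][, s2] - env$roe * low[[m + 2]][, s2])
        }
      }
      out[[m + 1]] <- M
    }
    V[[1]][[d + 2]] <- out
  }

  # bra ladder over all d
  if (Lb > 0) for (b in 0:(Lb - 1)) {
    ctb <- comp_table(b)$comps; ncb1 <- n_cart_comp(b + 1)
    ctb1 <- comp_table(b + 1)$comps
    for (d in 0:Ld) {
      ncd <- n_cart_comp(d); ctd <- comp_table(d)$comps
      src <- V[[b + 1]][[d + 1]]
      low <- if (b >= 1) V[[b]][[d + 1]] else NULL
      dket <- if (d >= 1) V[[b + 1]][[d]] else NULL
      nm <- mmax - (b + 1) - d
      if (nm < 0) next
      out <- vector("list", nm + 1)
      for (m in 0:nm) {
        M <- matrix(0, env$nw, ncb1 * ncd)
        for (t in seq_len(ncb1)) {
          i <- vrr_axis(ctb1[t, ])
          s <- map_shift_cached(b + 1, i, -1L)[t]
          colsT <- (t - 1L) * ncd + seq_len(ncd)
          colsS <- (s - 1L) * ncd + seq_len(ncd)
          M[, colsT] <- env$PBw[, i] * src[[m + 1]][, colsS, drop = FALSE] +
            env$WP[, i] * src[[m + 2]][, colsS, drop = FALSE]
          Ni <- ctb[s, i]
          if (Ni > 0) {
            s2 <- map_shift_cached(b, i, -1L)[s]
            colsS2 <- (s2 - 1L) * ncd + seq_len(ncd)
            M[, colsT] <- M[, colsT] + Ni * env$i2z *
              (low[[m + 1]][, colsS2, drop = FALSE] -
                 env$roz * low[[m + 2]][, colsS2, drop = FALSE])
          }
          if (d >= 1) {
            dm <- map_shift_cached(d, i, -1L)
            for (cd_i in seq_len(ncd)) {
              Nd <- ctd[cd_i, i]
              if (Nd > 0) {
                ncdm <- n_cart_comp(d - 1)
                M[, (t - 1L) * ncd + cd_i] <- M[, (t - 1L) * ncd + cd_i] +
                  Nd * env$i2ze * dket[[m + 2]][, (s - 1L) * ncdm + dm[cd_i]]
              }
            }
          }
        }
        out[[m + 1]] <- M
      }
      V[[b + 2]][[d + 1]] <- out
    }
  }
  V
}

# contracted [0b|0d] tables for contraction weights w = plain * prod (2 exp)^pow
# wpow is an integer vector over slots (A, B, C, D)
get_ctab <- function(env, wpow = c(0L, 0L, 0L, 0L)) {
  key <- paste(wpow, collapse = "")
  ct <- env$ctab[[key]]
  if (!is.null(ct)) return(ct)
  w <- env$wplain
  if (wpow[1] > 0) w <- w * (2 * env$alpha_w)^wpow[1]
  if (wpow[2] > 0) w <- w * (2 * env$beta_w)^wpow[2]
  if (wpow[3] > 0) w <- w * (2 * env$gamma_w)^wpow[3]
  if (wpow[4] > 0) w <- w * (2 * env$delta_w)^wpow[4]
  ct <- lapply(0:env$Lb, function(b) {
    lapply(0:env$Ld, function(d) {
      if (is.null(env$V[[b + 1]][[d + 1]])) return(NULL)
      drop(w %*% env$V[[b + 1]][[d + 1]][[1]])  # length cb*cd, d fastest
    })
  })
  env$ctab[[key]] <- ct
  ct
}

# contracted (0b|cd) block, dims (ncomp(b), ncomp(c), ncomp(d))
ket_block <- function(env, wkey, wpow, b, c, d) {
  key <- paste(wkey, b, c, d)
  blk <- env$ket[[key]]
  if (!is.null(blk)) return(blk)
  ncb <- n_cart_comp(b)
  if (c == 0) {
    v <- get_ctab(env, wpow)[[b + 1]][[d + 1]]
    blk <- array(0, dim = c(ncb, 1, n_cart_comp(d)))
    blk[, 1, ] <- matrix(v, nrow = ncb, byrow = TRUE)
  } else {
    B1 <- ket_block(env, wkey, wpow, b, c - 1, d)
    B2 <- ket_block(env, wkey, wpow, b, c - 1, d + 1)
    ctc <- comp_table(c)$comps
    ncc <- nrow(ctc)
    blk <- array(0, dim = c(ncb, ncc, n_cart_comp(d)))
    for (t in seq_len(ncc)) {
      i <- vrr_axis(ctc[t, ])
      s <- map_shift_cached(c, i, -1L)[t]
      up <- map_shift_cached(d, i, 1L)
      blk[, t, ] <- env$DC[i] * B1[, s, ] + B2[, s, up]
    }
  }
  env$ket[[key]] <- blk
  blk
}

# bra transfer over a list of (0,e|ket) blocks with flattened ket dimension:
# kets[[e - b0 + 1]] is matrix (ncomp(e), K); returns (ncomp(a), ncomp(b), K)
bra_block <- function(kets, a, b, BA, b0 = 0L) {
  if (a == 0) {
    m <- kets[[b - b0 + 1L]]
    K <- ncol(m)
    return(array(m, dim = c(1, n_cart_comp(b), K)))
  }
  B1 <- bra_block(kets, a - 1, b, BA, b0)
  B2 <- bra_block(kets, a - 1, b + 1, BA, b0)
  cta <- comp_table(a)$comps
  nca <- nrow(cta)
  K <- dim(B1)[3]
  out <- array(0, dim = c(nca, n_cart_comp(b), K))
  for (t in seq_len(nca)) {
    i <- vrr_axis(cta[t, ])
    s <- map_shift_cached(a, i, -1L)[t]
    up <- map_shift_cached(b, i, 1L)
    out[t, , ] <- BA[i] * B1[s, , ] + B2[s, up, ]
  }
  out
}

# fully Cartesian contracted quartet (la2 lb2 | lc2 ld2), optionally with
# exponent-weighted contraction; returns 4D array or NULL for negative l
cart_quartet <- function(env, la2, lb2, lc2, ld2, wpow = c(0L, 0L, 0L, 0L)) {
  if (min(la2, lb2, lc2, ld2) < 0) return(NULL)
  wkey <- paste(wpow, collapse = "")
  key <- paste(wkey, la2, lb2, lc2, ld2)
  out <- env$cart[[key]]
  if (!is.null(out)) return(out)
  stopifnot(la2 + lb2 <= env$Lb, lc2 + ld2 <= env$Ld)
  ncc <- n_cart_comp(lc2); ncd <- n_cart_comp(ld2)
  K <- ncc * ncd
  kets <- lapply(lb2:(la2 + lb2), function(e) {
    blk <- ket_block(env, wkey, wpow, e, lc2, ld2)
    matrix(blk, nrow = n_cart_comp(e), ncol = K)  # (c,d) flattened, c fastest
  })
  arr <- bra_block(kets, la2, lb2, env$BA, b0 = lb2)
  out <- array(arr, dim = c(n_cart_comp(la2), n_cart_comp(lb2), ncc, ncd))
  env$cart[[key]] <- out
  out
}

# multiply 4D array along one mode by a transformation matrix
mode_mult <- function(arr, M, mode) {
  d <- dim(arr)
  perm <- c(mode, setdiff(1:4, mode))
  a <- aperm(arr, perm)
  dim(a) <- c(d[mode], prod(d[-mode]))
  a <- M %*% a
  dim(a) <- c(nrow(M), d[perm[-1]])
  aperm(a, order(perm))
}

# the l = 1 spherical transform is the (y, z, x) component permutation
.p1perm <- c(2L, 3L, 1L)

sph_transform4 <- function(arr, ls) {
  if (all(ls <= 1L)) {
    idx <- lapply(ls, function(l) if (l == 1L) .p1perm else 1L)
    return(arr[idx[[1]], idx[[2]], idx[[3]], idx[[4]], drop = FALSE])
  }
  for (mode in 1:4) {
    l <- ls[mode]
    if (l >= 2) arr <- mode_mult(arr, cart_to_spherical(l), mode)
    else if (l == 1) {
      d <- dim(arr)
      perm <- c(mode, setdiff(1:4, mode))
      a <- aperm(arr, perm)
      dim(a) <- c(3L, prod(d[-mode]))
      a <- a[.p1perm, , drop = FALSE]
      dim(a) <- c(3L, d[perm[-1]])
      arr <- aperm(a, order(perm))
    }
  }
  arr
}

#' Contracted spherical ERI shell quartet
#'
#' Evaluates the block of electron-repulsion integrals (ij|kl) over four
#' contracted shells by the early-contraction mixed Cartesian/spherical
#' scheme (vertical recursions on primitives, contraction, ket transfer,
#' ket spherical transformation, bra transfer in mixed representation,
#' bra spherical transformation).
#'
#' @param mol a `molvib_molecule`.
#' @param basis a `molvib_basis` loaded for `mol`.
#' @param i,j,k,l shell indices into `basis$shells`.
#' @return 4D array of spherical integrals,
#'   dim (2li+1) x (2lj+1) x (2lk+1) x (2ll+1), in hartree.
#' @export
eri_quartet <- function(mol, basis, i, j, k, l) {
  env <- quartet_env(mol, basis, i, j, k, l)
  eri_quartet_from_env(env)
}

eri_quartet_from_env <- function(env) {
  ls <- env$ls
  la <- ls[1]; lb <- ls[2]; lc <- ls[3]; ld <- ls[4]
  nsc <- n_sph_comp(lc); nsd <- n_sph_comp(ld)
  Tc <- cart_to_spherical(lc); Td <- cart_to_spherical(ld)
  fastket <- lc <= 1L && ld <= 1L
  pc <- if (lc == 1L) .p1perm else 1L
  pd <- if (ld == 1L) .p1perm else 1L
  kets <- lapply(lb:(la + lb), function(e) {
    blk <- ket_block(env, "0000", c(0L, 0L, 0L, 0L), e, lc, ld)
    ne <- n_cart_comp(e)
    a <- array(blk, dim = c(ne, dim(blk)[2], dim(blk)[3]))
    # ket spherical transformation (mixed representation)
    if (fastket) {
      a <- a[, pc, pd, drop = FALSE]
    } else {
      d3 <- dim(a)
      m <- matrix(aperm(a, c(2, 1, 3)), nrow = d3[2])
      m <- Tc %*% m
      a <- aperm(array(m, dim = c(nsc, d3[1], d3[3])), c(2, 1, 3))
      m2 <- matrix(a, ncol = d3[3])
      m2 <- m2 %*% t(Td)
      a <- array(m2, dim = c(d3[1], nsc, nsd))
    }
    matrix(a, nrow = ne, ncol = nsc * nsd)
  })
  arr <- bra_block(kets, la, lb, env$BA, b0 = lb)
  arr <- array(arr, dim = c(n_cart_comp(la), n_cart_comp(lb), nsc, nsd))
  if (la <= 1L && lb <= 1L) {
    pa <- if (la == 1L) .p1perm else 1L
    pb <- if (lb == 1L) .p1perm else 1L
    arr[pa, pb, , , drop = FALSE]
  } else {
    arr <- mode_mult(arr, cart_to_spherical(la), 1)
    mode_mult(arr, cart_to_spherical(lb), 2)
  }
}

# fully Cartesian-path spherical quartet (used by the derivative module for
# its undifferentiated reference target)
eri_quartet_cartpath <- function(env) {
  ls <- env$ls
  arr <- cart_quartet(env, ls[1], ls[2], ls[3], ls[4])
  sph_transform4(arr, ls)
}

#' Cauchy-Schwarz screening bounds
#'
#' Per shell-pair bounds Q_ij = sqrt(max (mu nu|mu nu)) such that
#' |(ij|kl)| <= Q_ij Q_kl for every integral in the quartet.
#'
#' @param mol a `molvib_molecule`.
#' @param basis a `molvib_basis`.
#' @param threshold quartets with Q_ij * Q_kl below this are skipped by
#'   screened builders (default 1e-12).
#' @return object of class `molvib_schwarz`: list with `Q` (n_shell x
#'   n_shell matrix) and `threshold`.
#' @export
schwarz_bounds <- function(mol, basis, threshold = 1e-12) {
  ns <- length(basis$shells)
  Q <- matrix(0, ns, ns)
  for (i in seq_len(ns)) for (j in i:ns) {
    blk <- eri_quartet(mol, basis, i, j, i, j)
    d <- dim(blk)
    m <- matrix(blk, d[1] * d[2], d[3] * d[4])
    dg <- diag(m)
    mn <- min(dg)
    if (mn < -1e-14) {
      stop("negative Schwarz diagonal (", mn, ") in shell pair (", i, ",", j,
           "): numerical integrity violation", call. = FALSE)
    }
    Q[i, j] <- Q[j, i] <- sqrt(max(dg, 0))
  }
  structure(list(Q = Q, threshold = threshold), class = "molvib_schwarz")
}

# distinct permutation images of a canonical quartet (i,j,k,l) under the
# 8-fold ERI symmetry group; each entry gives the shell tuple and the axis
# permutation pulling block indices back to canonical order
quartet_images <- function(i, j, k, l) {
  perms <- list(c(1, 2, 3, 4), c(2, 1, 3, 4), c(1, 2, 4, 3), c(2, 1, 4, 3),
                c(3, 4, 1, 2), c(4, 3, 1, 2), c(3, 4, 2, 1), c(4, 3, 2, 1))
  sh <- c(i, j, k, l)
  seen <- character(0)
  out <- list()
  for (p in perms) {
    tup <- sh[p]
    key <- paste(tup, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(shells = tup, perm = p)
  }
  out
}

#' Full ERI tensor
#'
#' Dense (n_ao)^4 tensor of spherical ERIs, built from canonical shell
#' quartets with the 8-fold permutational symmetry. Intended for desk-scale
#' systems and for oracle cross-checks.
#'
#' @inheritParams schwarz_bounds
#' @param screen optional `molvib_schwarz`; quartets below its threshold are
#'   left zero.
#' @return 4D array (n_ao^4), hartree.
#' @export
eri_tensor <- function(mol, basis, screen = NULL) {
  n <- basis$n_ao
  ns <- length(basis$shells)
  G <- array(0, dim = rep(n, 4))
  rng <- lapply(seq_len(ns), function(s) shell_ao_range(basis, s))
  for (i in seq_len(ns)) for (j in 1:i) for (k in 1:i) {
    lmax <- if (k == i) j else k
    for (l in 1:lmax) {
      if (!is.null(screen) &&
          screen$Q[i, j] * screen$Q[k, l] < screen$threshold) next
      blk <- eri_quartet(mol, basis, i, j, k, l)
      for (im in quartet_images(i, j, k, l)) {
        s <- im$shells
        G[rng[[s[1]]], rng[[s[2]]], rng[[s[3]]], rng[[s[4]]]] <-
          aperm(blk, im$perm)
      }
    }
  }
  G
}

#' Two-electron Fock matrix
#'
#' F2e_mu.nu = sum_theta.phi D_theta.phi [2(mu nu|theta phi)
#'   - c_x (mu phi|theta nu)], the closed-shell Coulomb-plus-scaled-exchange
#' contraction with the density in the P = C_occ C_occ^T convention.
#' Built directly from screened shell quartets with full 8-fold symmetry.
#'
#' @param D symmetric density matrix (n_ao x n_ao), P convention.
#' @param mol,basis molecule and basis.
#' @param c_x exact-exchange fraction (1 for Hartree-Fock).
#' @param screen a `molvib_schwarz` (threshold 0 disables screening).
#' @return symmetric n_ao x n_ao matrix.
#' @export
build_fock_2e <- function(D, mol, basis, c_x = 1, screen = NULL) {
  n <- basis$n_ao
  if (!is.matrix(D) || any(dim(D) != n)) {
    stop("density matrix must be ", n, " x ", n, call. = FALSE)
  }
  if (is.null(screen)) screen <- schwarz_bounds(mol, basis, threshold = 0)
  ns <- length(basis$shells)
  rng <- lapply(seq_len(ns), function(s) shell_ao_range(basis, s))
  F2 <- matrix(0, n, n)
  for (i in seq_len(ns)) for (j in 1:i) for (k in 1:i) {
    lmax <- if (k == i) j else k
    for (l in 1:lmax) {
      if (screen$Q[i, j] * screen$Q[k, l] < screen$threshold) next
      blk <- eri_quartet(mol, basis, i, j, k, l)
      for (im in quartet_images(i, j, k, l)) {
        s <- im$shells
        B <- aperm(blk, im$perm)
        ri <- rng[[s[1]]]; rj <- rng[[s[2]]]; rk <- rng[[s[3]]]; rl <- rng[[s[4]]]
        d <- dim(B)
        Bm <- matrix(B, d[1] * d[2], d[3] * d[4])
        # Coulomb: F[mu,nu] += 2 sum (mu nu|theta phi) D[theta,phi]
        F2[ri, rj] <- F2[ri, rj] + 2 * matrix(Bm %*% as.vector(D[rk, rl]), d[1], d[2])
        if (c_x != 0) {
          # exchange: F[mu,phi] -= c_x sum (mu nu|theta phi)... via
          # F[i,l] -= c_x D[k,j] (ij|kl)
          Bk <- aperm(B, c(1, 4, 3, 2))
          Bkm <- matrix(Bk, d[1] * d[4], d[3] * d[2])
          F2[ri, rl] <- F2[ri, rl] -
            c_x * matrix(Bkm %*% as.vector(D[rk, rj]), d[1], d[4])
        }
      }
    }
  }
  (F2 + t(F2)) / 2
}

# tensor-based Fock for small systems (G is the full ERI tensor)
fock_from_tensor <- function(G, D, c_x = 1) {
  n <- dim(G)[1]
  Gm <- matrix(G, n * n, n * n)
  J <- matrix(Gm %*% as.vector(D), n, n)
  Fm <- 2 * J
  if (c_x != 0) {
    Km <- matrix(aperm(G, c(1, 4, 3, 2)), n * n, n * n)
    K <- matrix(Km %*% as.vector(D), n, n)
    Fm <- Fm - c_x * K
  }
  (Fm + t(Fm)) / 2
}
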