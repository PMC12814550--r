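# Becke-partitioned molecular quadrature grid and AO evaluation on grid
# points with derivatives up to third order.
#
# Radial: Gauss-Chebyshev (second kind) nodes mapped to (0, inf) with the
# rational map r = R (1+x)/(1-x). Angular: product quadrature,
# Gauss-Legendre in cos(theta) times uniform phi. Atomic weights by the
# smooth Becke partition of unity (three fuzzy-cell iterations).

# Bragg-Slater-like radial scale parameters (bohr) per element symbol
.radial_scale <- c(H = 0.66, He = 0.59, Li = 2.74, Be = 1.98, B = 1.60,
                   C = 1.32, N = 1.23, O = 1.13, F = 0.94, Ne = 0.71,
                   Na = 3.40, Mg = 2.83, Al = 2.36, Si = 2.08, P = 1.89,
                   S = 1.89, Cl = 1.89, Ar = 1.34)

.grid_presets <- list(
  coarse = c(nr = 30, nt = 8, np = 16),
  medium = c(nr = 70, nt = 16, np = 32),
  fine = c(nr = 75, nt = 18, np = 36),
  veryfine = c(nr = 99, nt = 26, np = 52)
)

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch
gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

#' Build a Becke-partitioned molecular quadrature grid
#'
#' @param mol a `molvib_molecule`.
#' @param level `"coarse"`, `"medium"`, `"fine"` (default; the preset used
#'   for production-style settings) or `"veryfine"`.
#' @return object of class `molvib_grid`: `points` (n x 3, bohr),
#'   `weights` (bohr^3, positive), `atom` (owning atom per point), `level`.
#' @export
build_grid <- function(mol, level = "fine") {
  if (!level %in% names(.grid_presets)) {
    stop("unknown grid level: ", level, " (use ",
         paste(names(.grid_presets), collapse = "/"), ")", call. = FALSE)
  }
  p <- .grid_presets[[level]]
  nr <- p["nr"]; nt <- p["nt"]; np <- p["np"]
  # radial nodes (Gauss-Chebyshev second kind)
  i <- seq_len(nr)
  xi <- cos(i * pi / (nr + 1))
  wch <- pi / (nr + 1) * sin(i * pi / (nr + 1))^2
  gl <- gauss_legendre(nt)
  phi <- 2 * pi * (seq_len(np) - 0.5) / np
  wphi <- 2 * pi / np
  nat <- nrow(mol$coords)
  pts_list <- list(); w_list <- list(); at_list <- list()
  for (a in seq_len(nat)) {
    R <- .radial_scale[[mol$elements[a]]] %||% 1.5
    r <- R * (1 + xi) / (1 - xi)
    jac <- 2 * R / (1 - xi)^2
    wr <- wch / sqrt(1 - xi^2) * jac * r^2
    keep <- r < 45  # discard the far tail (integrand is below precision)
    r <- r[keep]; wr <- wr[keep]
    ct <- gl$x; st <- sqrt(1 - ct^2)
    # assemble product grid for this atom
    ang <- cbind(rep(st, each = np) * cos(phi),
                 rep(st, each = np) * sin(phi),
                 rep(ct, each = np))
    wang <- rep(gl$w, each = np) * wphi
    pts <- ang[rep(seq_len(nrow(ang)), times = length(r)), ] *
      rep(r, each = nrow(ang))
    w <- rep(wr, each = nrow(ang)) * wang
    pts <- sweep(pts, 2, mol$coords[a, ], `+`)
    pts_list[[a]] <- pts; w_list[[a]] <- w
    at_list[[a]] <- rep(a, length(w))
  }
  points <- do.call(rbind, pts_list)
  w <- unlist(w_list)
  atom <- unlist(at_list)
  # Becke partition of unity
  if (nat > 1) {
    npts <- nrow(points)
    dist_at <- vapply(seq_len(nat), function(b) {
      sqrt(rowSums(sweep(points, 2, mol$coords[b, ])^2))
    }, numeric(npts))
    Rab <- as.matrix(dist(mol$coords))
    Pcell <- matrix(1, npts, nat)
    for (a in seq_len(nat)) for (b in seq_len(nat)) {
      if (a == b) next
      mu <- (dist_at[, a] - dist_at[, b]) / Rab[a, b]
      f <- mu
      for (k in 1:3) f <- 1.5 * f - 0.5 * f^3
      Pcell[, a] <- Pcell[, a] * 0.5 * (1 - f)
    }
    becke <- Pcell[cbind(seq_len(npts), atom)] / rowSums(Pcell)
    w <- w * becke
  }
  keep <- w > 1e-16
  structure(list(points = points[keep, , drop = FALSE], weights = w[keep],
                 atom = atom[keep], level = level), class = "molvib_grid")
}

#' @export
print.molvib_grid <- function(x, ...) {
  cat(sprintf("<molvib_grid '%s': %d points>\n", x$level, length(x$weights)))
  invisible(x)
}

#' Evaluate spherical AOs (and derivatives) on grid points
#'
#' Each Cartesian primitive factorizes as
#' x^i e^(-a x^2) * y^j e^(-a y^2) * z^k e^(-a z^2), so arbitrary mixed
#' derivatives follow from the 1-D shift rule
#' d/dx [x^i e^(-a x^2)] = i x^(i-1) e - 2 a x^(i+1) e.
#'
#' @param mol,basis molecule and basis.
#' @param points matrix (n x 3) of evaluation points (bohr).
#' @param max_order highest derivative order (0..3).
#' @return list keyed by derivative multi-index string (`"000"` for values,
#'   `"100"` for d/dx, `"110"` for d2/dxdy, ...) of matrices
#'   (n_points x n_ao).
#' @export
eval_ao_grid <- function(mol, basis, points, max_order = 0L) {
  stopifnot(max_order <= 3)
  npts <- nrow(points)
  n <- basis$n_ao
  midx <- list()
  for (o in 0:max_order) {
    for (a in 0:o) for (b in 0:(o - a)) {
      midx[[paste0(a, b, o - a - b)]] <- c(a, b, o - a - b)
    }
  }
  out <- lapply(midx, function(x) matrix(0, npts, n))
  for (si in seq_along(basis$shells)) {
    sh <- basis$shells[[si]]
    A <- mol$coords[sh$atom, ]
    l <- sh$l
    d <- sweep(points, 2, A)
    ct <- comp_table(l)$comps
    Tm <- cart_to_spherical(l)
    rng <- shell_ao_range(basis, si)
    cart_vals <- lapply(midx, function(x) matrix(0, npts, nrow(ct)))
    for (pidx in seq_along(sh$coef)) {
      al <- sh$exponents[pidx]
      # 1-D tables g[[dim]][[order+1]][, i+1] for i = 0..l + max_order
      imax <- l + max_order
      g <- lapply(1:3, function(dd) {
        x <- d[, dd]
        e <- exp(-al * x^2)
        G0 <- vapply(0:(imax + max_order), function(i) x^i * e,
                     numeric(npts))
        tabs <- list(G0)
        for (o in seq_len(max_order)) {
          prev <- tabs[[o]]
          ncur <- ncol(prev) - 1
          cur <- matrix(0, npts, ncur)
          for (i in 0:(ncur - 1)) {
            v <- -2 * al * prev[, i + 2]
            if (i >= 1) v <- v + i * prev[, i]
            cur[, i + 1] <- v
          }
          tabs[[o + 1]] <- cur
        }
        tabs
      })
      for (key in names(midx)) {
        ord <- midx[[key]]
        for (u in seq_len(nrow(ct))) {
          cart_vals[[key]][, u] <- cart_vals[[key]][, u] + sh$coef[pidx] *
            g[[1]][[ord[1] + 1]][, ct[u, 1] + 1] *
            g[[2]][[ord[2] + 1]][, ct[u, 2] + 1] *
            g[[3]][[ord[3] + 1]][, ct[u, 3] + 1]
        }
      }
    }
    for (key in names(midx)) {
      out[[key]][, rng] <- cart_vals[[key]] %*% t(Tm)
    }
  }
  out
}
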