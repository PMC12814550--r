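# Cartesian shell components, real solid harmonics, and the
# Cartesian->spherical transformation matrices.
#
# Conventions fixed once for the whole package:
#  * Cartesian components of a shell with angular momentum l are ordered
#    lexicographically with the x power descending: (l,0,0), (l-1,1,0),
#    (l-1,0,1), ..., (0,0,l)  (for d: xx, xy, xz, yy, yz, zz).
#  * Spherical components are ordered m = -l..+l.
#  * Engine Cartesian integrals are normalized to the (l,0,0) component;
#    the transformation rows absorb the remaining component-dependent
#    normalization so that spherical AOs have unit self-overlap.

.MAX_L <- 4L          # highest user-facing shell angular momentum
.MAX_COMPOSITE_L <- 12L  # highest composite angular momentum in recursions

double_factorial <- function(n) {
  vapply(n, function(k) {
    if (k <= 0) return(1)
    prod(seq(k, 1, by = -2))
  }, numeric(1))
}

#' Cartesian components of a shell
#' @param l angular momentum.
#' @return integer matrix (n_comp x 3) of (lx, ly, lz) powers in the
#'   package's lexicographic order.
#' @export
cart_components <- function(l) {
  if (l < 0) stop("angular momentum must be >= 0", call. = FALSE)
  out <- matrix(0L, ncol = 3, nrow = (l + 1) * (l + 2) / 2)
  r <- 1L
  for (lx in l:0) for (ly in (l - lx):0) {
    out[r, ] <- c(lx, ly, l - lx - ly)
    r <- r + 1L
  }
  out
}

n_cart_comp <- function(l) ((l + 1L) * (l + 2L)) %/% 2L
n_sph_comp <- function(l) 2L * l + 1L

# Precomputed component tables and triple->index lookups.
.comp_cache <- new.env(parent = emptyenv())

comp_table <- function(l) {
  key <- as.character(l)
  if (is.null(.comp_cache[[key]])) {
    cc <- cart_components(l)
    idx <- array(0L, dim = c(l + 1, l + 1, l + 1))
    for (r in seq_len(nrow(cc))) idx[cc[r, 1] + 1, cc[r, 2] + 1, cc[r, 3] + 1] <- r
    .comp_cache[[key]] <- list(comps = cc, index = idx)
  }
  .comp_cache[[key]]
}

comp_index <- function(l, lx, ly, lz) comp_table(l)$index[lx + 1, ly + 1, lz + 1]

# ---- real solid harmonics as monomial polynomials -------------------------

poly_new <- function() structure(list(pow = matrix(integer(0), 0, 3),
                                      coef = complex(0)), class = "mvpoly")

poly_term <- function(lx, ly, lz, c = 1 + 0i) {
  structure(list(pow = matrix(as.integer(c(lx, ly, lz)), 1, 3),
                 coef = as.complex(c)), class = "mvpoly")
}

poly_add <- function(p, q, qscale = 1 + 0i) {
  pow <- rbind(p$pow, q$pow)
  coef <- c(p$coef, q$coef * qscale)
  key <- paste(pow[, 1], pow[, 2], pow[, 3])
  agg <- rowsum(cbind(Re(coef), Im(coef)), key, reorder = FALSE)
  upow <- pow[!duplicated(key), , drop = FALSE]
  keep <- abs(agg[, 1]) + abs(agg[, 2]) > 1e-14
  structure(list(pow = upow[keep, , drop = FALSE],
                 coef = complex(real = agg[keep, 1], imaginary = agg[keep, 2])),
            class = "mvpoly")
}

poly_shift <- function(p, dx = 0L, dy = 0L, dz = 0L, scale = 1 + 0i) {
  p$pow <- p$pow + matrix(as.integer(c(dx, dy, dz)), nrow(p$pow), 3, byrow = TRUE)
  p$coef <- p$coef * scale
  p
}

# multiply by (x + i y), z, or r^2
poly_mul_xiy <- function(p) poly_add(poly_shift(p, dx = 1L),
                                     poly_shift(p, dy = 1L), qscale = 1i)
poly_mul_z <- function(p) poly_shift(p, dz = 1L)
poly_mul_r2 <- function(p) {
  poly_add(poly_add(poly_shift(p, dx = 2L), poly_shift(p, dy = 2L)),
           poly_shift(p, dz = 2L))
}

# Complex regular solid harmonics R_l^m (m >= 0) up to an overall scale,
# by the upward recursion (l-m) R_l^m = (2l-1) z R_{l-1}^m - (l-1+m) r^2 R_{l-2}^m,
# seeded with R_m^m ~ (x+iy)^m.
solid_harmonics_l <- function(l) {
  out <- vector("list", l + 1)  # index m+1
  for (m in 0:l) {
    Rmm <- poly_term(0L, 0L, 0L)
    if (m > 0) for (k in seq_len(m)) Rmm <- poly_mul_xiy(Rmm)
    if (m == l) { out[[m + 1]] <- Rmm; next }
    prev2 <- poly_new()  # R_{m-1}^m = 0
    prev1 <- Rmm
    for (ll in (m + 1):l) {
      cur <- poly_add(poly_mul_z(prev1), poly_new())
      cur$coef <- cur$coef * (2 * ll - 1)
      if (ll - 2 >= m) {
        cur <- poly_add(cur, poly_mul_r2(prev2), qscale = -(ll - 1 + m))
      }
      cur$coef <- cur$coef / (ll - m)
      prev2 <- prev1; prev1 <- cur
    }
    out[[m + 1]] <- prev1
  }
  out
}

# relative within-shell overlap of engine-convention Cartesian components
cart_overlap_rel <- function(l) {
  cc <- comp_table(l)$comps
  n <- nrow(cc)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    s <- cc[i, ] + cc[j, ]
    if (all(s %% 2 == 0)) {
      S[i, j] <- S[j, i] <- prod(double_factorial(s - 1)) /
        double_factorial(2 * l - 1)
    }
  }
  S
}

#' Cartesian-to-spherical transformation matrix
#'
#' Rows are real solid-harmonic combinations (m = -l..+l) of the package's
#' engine-normalized Cartesian components; each row is scaled so the
#' resulting spherical function has unit self-overlap when the Cartesian
#' (l,0,0) component does.
#'
#' @param l angular momentum, 0..4.
#' @return numeric matrix (2l+1) x ((l+1)(l+2)/2).
#' @export
cart_to_spherical <- function(l) {
  if (l < 0 || l > .MAX_L) {
    stop("unsupported angular momentum: l = ", l, " (supported 0..", .MAX_L, ")",
         call. = FALSE)
  }
  key <- paste0("T", l)
  if (!is.null(.comp_cache[[key]])) return(.comp_cache[[key]])
  cc <- comp_table(l)
  nc <- nrow(cc$comps)
  Tm <- matrix(0, 2 * l + 1, nc)
  Rl <- solid_harmonics_l(l)
  rowfill <- function(row, pow, coef) {
    for (t in seq_along(coef)) {
      if (abs(coef[t]) < 1e-14) next
      j <- cc$index[pow[t, 1] + 1, pow[t, 2] + 1, pow[t, 3] + 1]
      Tm[row, j] <<- Tm[row, j] + coef[t]
    }
  }
  for (m in 0:l) {
    p <- Rl[[m + 1]]
    if (m == 0) {
      rowfill(l + 1, p$pow, Re(p$coef))
    } else {
      rowfill(l + 1 + m, p$pow, Re(p$coef))   # cosine-type -> +m
      rowfill(l + 1 - m, p$pow, Im(p$coef))   # sine-type   -> -m
    }
  }
  Srel <- cart_overlap_rel(l)
  for (r in seq_len(nrow(Tm))) {
    nrm <- sqrt(drop(Tm[r, ] %*% Srel %*% Tm[r, ]))
    Tm[r, ] <- Tm[r, ] / nrm
  }
  Tm[abs(Tm) < 1e-14] <- 0
  .comp_cache[[key]] <- Tm
  Tm
}
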