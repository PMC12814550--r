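# Harmonic normal-mode analysis, IR intensities, partial-Hessian subsystem
# analysis and mode-localization accounting.

# orthonormal rigid-body (translation + rotation) vectors in the
# mass-weighted coordinate space; Eckart-frame construction
rigid_body_space <- function(coords, masses, tol = 1e-8) {
  nat <- nrow(coords)
  com <- colSums(coords * masses) / sum(masses)
  rc <- sweep(coords, 2, com)
  sq <- sqrt(masses)
  V <- matrix(0, 3 * nat, 6)
  for (i in 1:3) V[seq(i, 3 * nat, by = 3), i] <- sq
  rotpairs <- list(c(2, 3), c(3, 1), c(1, 2))
  for (r in 1:3) {
    p <- rotpairs[[r]]
    v <- numeric(3 * nat)
    v[seq(p[1], 3 * nat, by = 3)] <- -sq * rc[, p[2]]
    v[seq(p[2], 3 * nat, by = 3)] <- sq * rc[, p[1]]
    V[, 3 + r] <- v
  }
  # orthonormalize; rank drops to 5 for linear molecules (or 3 for an atom)
  qr_d <- qr(V)
  rank <- sum(abs(diag(qr.R(qr_d))) > tol * max(abs(diag(qr.R(qr_d))), 1))
  qr.Q(qr_d)[, seq_len(rank), drop = FALSE]
}

#' Harmonic vibrational analysis with IR intensities
#'
#' Mass-weights the Cartesian Hessian, optionally projects out rigid
#' translations and rotations (Eckart frame), diagonalizes, converts
#' eigenvalues to wavenumbers (imaginary modes encoded as negative cm^-1),
#' and evaluates IR intensities as Napierian integrated attenuation
#' coefficients A_k = prefactor * |d mu/d Q_k|^2 with |d mu/d Q_k|^2 in
#' e^2/amu and the prefactor (about 974.88 km/mol amu/e^2) derived from
#' CODATA constants.
#'
#' @param H Hessian matrix (3N x 3N, hartree/bohr^2) or a `molvib_hessian`.
#' @param dmu dipole gradient (3N x 3, e) or a `molvib_dipgrad`; may be
#'   NULL for frequencies only.
#' @param coords nuclear coordinates (N x 3, bohr) — required for
#'   projection.
#' @param masses atomic masses (amu).
#' @param project project out rigid-body modes (default TRUE).
#' @return object of class `molvib_vibration`: `frequencies` (cm^-1,
#'   ascending), `modes` (3N x n_modes mass-weighted normal-mode
#'   coefficients l_ik, 1/sqrt(amu) after un-weighting), `cart_modes`
#'   (Cartesian displacement vectors, 1/sqrt(amu)), `intensities` (km/mol,
#'   or NULL), `dmu_dQ` (3 x n_modes, e/sqrt(amu)), `n_modes`, `projected`.
#' @export
vibrational_analysis <- function(H, dmu = NULL, coords = NULL, masses,
                                 project = TRUE) {
  if (inherits(H, "molvib_hessian")) H <- H$H
  if (inherits(dmu, "molvib_dipgrad")) dmu <- dmu$dmu
  n3 <- nrow(H)
  if (!isTRUE(all.equal(H, t(H), tolerance = 1e-7))) {
    stop("Hessian must be symmetric", call. = FALSE)
  }
  if (any(masses <= 0)) stop("masses must be positive", call. = FALSE)
  if (length(masses) * 3 != n3) stop("length(masses)*3 must match dim(H)",
                                     call. = FALSE)
  H <- (H + t(H)) / 2
  invsq <- 1 / sqrt(rep(masses, each = 3))
  Hmw <- H * tcrossprod(invsq)
  if (project) {
    if (is.null(coords)) stop("coords required for rigid-body projection",
                              call. = FALSE)
    Vr <- rigid_body_space(coords, masses)
    # diagonalize in the orthogonal complement: exactly 3N - rank modes
    B <- qr.Q(qr(cbind(Vr, diag(n3))))[, (ncol(Vr) + 1):n3, drop = FALSE]
    Hp <- crossprod(B, Hmw %*% B)
    ee <- eigen((Hp + t(Hp)) / 2, symmetric = TRUE)
    ord <- order(ee$values)
    lam <- ee$values[ord]
    modes <- B %*% ee$vectors[, ord, drop = FALSE]
  } else {
    ee <- eigen(Hmw, symmetric = TRUE)
    ord <- order(ee$values)
    lam <- ee$values[ord]
    modes <- ee$vectors[, ord, drop = FALSE]
  }
  conv <- freq_conversion_factor()
  freqs <- sign(lam) * sqrt(abs(lam)) * conv
  cart <- modes * invsq  # d x / d Q_k, units 1/sqrt(amu)
  out <- list(frequencies = freqs, modes = modes, cart_modes = cart,
              n_modes = length(freqs), projected = project,
              masses = masses, intensities = NULL, dmu_dQ = NULL)
  if (!is.null(dmu)) {
    dQ <- crossprod(dmu, cart)  # 3 x n_modes, e / sqrt(amu)
    out$dmu_dQ <- dQ
    out$intensities <- ir_intensity_prefactor() * colSums(dQ^2)
  }
  structure(out, class = "molvib_vibration")
}

#' @export
print.molvib_vibration <- function(x, ...) {
  cat(sprintf("<molvib_vibration: %d modes, %.1f .. %.1f cm^-1%s>\n",
              x$n_modes, min(x$frequencies), max(x$frequencies),
              if (!is.null(x$intensities)) ", IR intensities available" else ""))
  invisible(x)
}

#' Partial-Hessian vibrational analysis
#'
#' Extracts the subblock of a full Hessian belonging to a subset of atoms,
#' together with the matching dipole-gradient rows and masses, and performs
#' a separate vibrational analysis, neglecting the coupling to the rest of
#' the system.
#'
#' @inheritParams vibrational_analysis
#' @param atom_subset integer vector of atom indices (unique, nonempty).
#' @return a `molvib_vibration` for the subsystem.
#' @export
partial_hessian <- function(H, dmu = NULL, coords = NULL, masses, atom_subset,
                            project = TRUE) {
  if (inherits(H, "molvib_hessian")) H <- H$H
  if (inherits(dmu, "molvib_dipgrad")) dmu <- dmu$dmu
  if (length(atom_subset) == 0) stop("atom subset must be nonempty", call. = FALSE)
  if (anyDuplicated(atom_subset)) stop("atom subset must be unique", call. = FALSE)
  nat <- length(masses)
  if (any(atom_subset < 1 | atom_subset > nat)) {
    stop("atom subset out of range", call. = FALSE)
  }
  idx <- as.vector(vapply(atom_subset, function(a) 3L * (a - 1L) + 1:3,
                          integer(3)))
  vibrational_analysis(H[idx, idx, drop = FALSE],
                       dmu = if (!is.null(dmu)) dmu[idx, , drop = FALSE],
                       coords = if (!is.null(coords)) coords[atom_subset, , drop = FALSE],
                       masses = masses[atom_subset], project = project)
}

#' Mode localization fractions over atom subsets
#'
#' For each normal mode, the fraction of its mass-weighted displacement
#' norm-squared carried by each subset of a disjoint partition. Over a
#' partition covering all atoms the fractions sum to one per mode.
#'
#' @param vib a `molvib_vibration` (or a 3N x n_modes mass-weighted mode
#'   matrix).
#' @param partition list of disjoint integer atom-index vectors.
#' @return matrix n_modes x length(partition) of fractions.
#' @export
mode_localization <- function(vib, partition) {
  modes <- if (inherits(vib, "molvib_vibration")) vib$modes else vib
  all_atoms <- unlist(partition)
  if (anyDuplicated(all_atoms)) stop("partition subsets overlap", call. = FALSE)
  tot <- colSums(modes^2)
  out <- vapply(partition, function(sub) {
    idx <- as.vector(vapply(sub, function(a) 3L * (a - 1L) + 1:3, integer(3)))
    colSums(modes[idx, , drop = FALSE]^2) / tot
  }, numeric(ncol(modes)))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(partition))
  colnames(out) <- names(partition) %||% paste0("subset", seq_along(partition))
  out
}
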