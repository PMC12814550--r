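#' Construct a molecule
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n x 3) of nuclear positions in bohr.
#' @param total_charge integer net charge.
#' @param masses optional numeric vector of atomic masses (amu); defaults to
#'   the most-abundant-isotope table.
#' @return An object of class `molvib_molecule` with fields `elements`,
#'   `charges` (nuclear charges Z), `coords` (bohr), `total_charge`, `masses`.
#' @export
molecule <- function(elements, coords, total_charge = 0L, masses = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an n x 3 matrix", call. = FALSE)
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  info <- element_info(elements)
  if (nrow(info) != nrow(coords)) {
    stop("length(elements) must equal nrow(coords)", call. = FALSE)
  }
  if (is.null(masses)) masses <- info$mass
  if (length(masses) != nrow(coords)) {
    stop("masses must have one entry per atom", call. = FALSE)
  }
  n_elec <- sum(info$Z) - total_charge
  if (n_elec %% 2 != 0) {
    stop("open-shell systems are not supported: electron count ",
         n_elec, " is odd", call. = FALSE)
  }
  structure(list(
    elements = info$symbol,
    charges = info$Z,
    coords = unname(coords),
    total_charge = as.integer(total_charge),
    masses = as.numeric(masses)
  ), class = "molvib_molecule")
}

#' @export
print.molvib_molecule <- function(x, ...) {
  cat(sprintf("<molvib_molecule: %d atoms, charge %+d, %d electrons>\n",
              length(x$elements), x$total_charge, n_electrons(x)))
  invisible(x)
}

#' Number of electrons
#' @param mol a `molvib_molecule`.
#' @return integer electron count.
#' @export
n_electrons <- function(mol) as.integer(sum(mol$charges) - mol$total_charge)

#' Read a molecule from an XYZ file
#'
#' Standard XYZ: first line atom count, second line comment, then
#' `element x y z` with coordinates in Angstrom. Coordinates are converted
#' to bohr on read.
#'
#' @param path path to the XYZ file.
#' @param total_charge net charge assigned to the molecule.
#' @return a `molvib_molecule`.
#' @export
read_xyz <- function(path, total_charge = 0L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(length(lines))]
  if (length(lines) < 2) stop("malformed XYZ file: fewer than 2 lines", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) {
    stop("malformed XYZ count line: ", sQuote(lines[1]), call. = FALSE)
  }
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n) {
    stop("XYZ atom-count mismatch: count line says ", n,
         " but found ", length(body), " atom lines", call. = FALSE)
  }
  toks <- strsplit(trimws(body), "\\s+")
  bad <- vapply(toks, length, 1L) < 4
  if (any(bad)) stop("malformed XYZ atom line: ", body[which(bad)[1]], call. = FALSE)
  elements <- vapply(toks, `[[`, "", 1L)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("non-numeric coordinate in XYZ file", call. = FALSE)
  molecule(elements, xyz / physical_constants()$bohr_angstrom,
           total_charge = total_charge)
}

#' Write a molecule to an XYZ file
#' @param mol a `molvib_molecule`.
#' @param path output path.
#' @param comment comment line.
#' @export
write_xyz <- function(mol, path, comment = "written by molvib") {
  ang <- mol$coords * physical_constants()$bohr_angstrom
  lines <- c(length(mol$elements), comment,
             sprintf("%-3s %20.12f %20.12f %20.12f",
                     mol$elements, ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Center of nuclear charge (bohr)
#' @param mol a `molvib_molecule`.
#' @return length-3 numeric vector.
#' @export
center_of_charge <- function(mol) {
  colSums(mol$coords * mol$charges) / sum(mol$charges)
}

#' Nuclear repulsion energy and its geometric derivatives
#'
#' @param mol a `molvib_molecule`.
#' @param order 0 (energy), 1 (also gradient) or 2 (also Hessian).
#' @return list with `energy` (hartree), and when requested `gradient`
#'   (3N vector, hartree/bohr) and `hessian` (3N x 3N, hartree/bohr^2).
#' @export
nuclear_repulsion <- function(mol, order = 0L) {
  R <- mol$coords; Z <- mol$charges; n <- nrow(R)
  e <- 0
  g <- if (order >= 1) numeric(3 * n) else NULL
  H <- if (order >= 2) matrix(0, 3 * n, 3 * n) else NULL
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    d <- R[a, ] - R[b, ]
    r2 <- sum(d * d); r <- sqrt(r2)
    zz <- Z[a] * Z[b]
    e <- e + zz / r
    if (order >= 1) {
      ga <- -zz * d / r^3
      ia <- 3 * (a - 1) + 1:3; ib <- 3 * (b - 1) + 1:3
      g[ia] <- g[ia] + ga
      g[ib] <- g[ib] - ga
      if (order >= 2) {
        blk <- zz * (3 * tcrossprod(d) / r^5 - diag(3) / r^3)
        H[ia, ia] <- H[ia, ia] + blk
        H[ib, ib] <- H[ib, ib] + blk
        H[ia, ib] <- H[ia, ib] - blk
        H[ib, ia] <- H[ib, ia] - blk
      }
    }
  }
  out <- list(energy = e)
  if (order >= 1) out$gradient <- g
  if (order >= 2) out$hessian <- H
  out
}

#' Nuclear contribution to the electric dipole moment (e bohr)
#' @param mol a `molvib_molecule`.
#' @param origin dipole origin (bohr); defaults to the center of nuclear charge.
#' @return length-3 numeric vector.
#' @export
nuclear_dipole <- function(mol, origin = center_of_charge(mol)) {
  colSums((mol$coords - matrix(origin, nrow(mol$coords), 3, byrow = TRUE)) *
            mol$charges)
}
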