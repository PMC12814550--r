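#' Physical constants (CODATA 2018)
#'
#' Returns the immutable table of physical constants used throughout the
#' package. All internal computation is performed in Hartree atomic units;
#' these constants appear only at unit boundaries (XYZ input in Angstrom,
#' wavenumbers in cm^-1, IR intensities in km/mol).
#'
#' @return A named list with elements `N_A` (Avogadro constant, 1/mol),
#'   `eps0` (vacuum permittivity, F/m), `c` (speed of light, m/s),
#'   `e` (elementary charge, C), `amu_kg` (atomic mass unit, kg),
#'   `bohr_m` (Bohr radius, m), `hartree_J` (Hartree energy, J),
#'   `bohr_angstrom` (Bohr radius, Angstrom), `h` (Planck constant, J s).
#' @export
#' @examples
#' physical_constants()$bohr_angstrom
physical_constants <- function() {
  list(
    N_A = 6.02214076e23,
    eps0 = 8.8541878128e-12,
    c = 2.99792458e8,
    e = 1.602176634e-19,
    amu_kg = 1.66053906660e-27,
    bohr_m = 0.529177210903e-10,
    hartree_J = 4.3597447222071e-18,
    bohr_angstrom = 0.529177210903,
    h = 6.62607015e-34
  )
}

# Element data: symbol, nuclear charge, most-abundant-isotope mass (amu).
# Masses follow the common quantum-chemistry convention of single-isotope
# values rather than standard atomic weights; they can be overridden per
# atom in vibrational_analysis().
.element_table <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar"),
  Z = 1:18,
  mass = c(1.00782503207, 4.00260325415, 7.016004548, 9.012182201,
           11.009305406, 12.0, 14.00307400478, 15.99491461956,
           18.998403224, 19.99244017542, 22.98976928087, 23.985041699,
           26.981538627, 27.976926532, 30.973761629, 31.972070999,
           34.968852682, 39.962383123),
  stringsAsFactors = FALSE
)

#' Look up element properties
#'
#' @param symbols character vector of element symbols (any case).
#' @return data.frame with columns `symbol`, `Z`, `mass` in input order.
#' @export
element_info <- function(symbols) {
  symbols <- normalize_element(symbols)
  idx <- match(symbols, .element_table$symbol)
  if (anyNA(idx)) {
    stop("unsupported element(s): ",
         paste(unique(symbols[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  .element_table[idx, , drop = FALSE]
}

normalize_element <- function(symbols) {
  s <- tolower(trimws(symbols))
  paste0(toupper(substring(s, 1, 1)), substring(s, 2))
}

#' IR intensity unit prefactor
#'
#' The conversion factor turning a squared dipole-moment gradient along a
#' normal coordinate, |d mu / d Q|^2 expressed in e^2/amu, into a Napierian
#' integrated attenuation coefficient in km/mol:
#' A_k = (1 / (4 pi eps0)) * (N_A pi / (3 c^2)) * |d mu / d Q_k|^2.
#' Evaluated from CODATA constants; approximately 974.88 km/mol amu/e^2.
#'
#' @return scalar, km/mol per (e^2/amu).
#' @export
#' @examples
#' ir_intensity_prefactor()
ir_intensity_prefactor <- function() {
  k <- physical_constants()
  si <- (1 / (4 * pi * k$eps0)) * k$N_A * pi / (3 * k$c^2) * k$e^2 / k$amu_kg
  si / 1000  # m/mol -> km/mol
}

#' Harmonic frequency conversion factor
#'
#' sqrt of a mass-weighted Hessian eigenvalue (hartree / (amu bohr^2))
#' times this factor gives the harmonic wavenumber in cm^-1.
#' @return scalar, cm^-1 per sqrt(hartree/(amu bohr^2)).
#' @keywords internal
freq_conversion_factor <- function() {
  k <- physical_constants()
  # omega [1/s] = sqrt(lambda * E_h / (amu * a0^2)); nu~ = omega / (2 pi c)
  sqrt(k$hartree_J / (k$amu_kg * k$bohr_m^2)) / (2 * pi * k$c) / 100
}
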