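# Stick spectra, frequency scaling, Lorentzian (optionally Gaussian)
# broadening, and spectrum file writers.

#' Construct a stick spectrum
#' @param frequencies wavenumbers (cm^-1).
#' @param intensities band intensities (km/mol, nonnegative).
#' @param labels optional per-mode annotations.
#' @return object of class `molvib_sticks`.
#' @export
stick_spectrum <- function(frequencies, intensities, labels = NULL) {
  if (length(frequencies) != length(intensities)) {
    stop("frequencies and intensities must have equal length", call. = FALSE)
  }
  if (any(intensities < -1e-12)) stop("intensities must be nonnegative", call. = FALSE)
  structure(list(frequencies = as.numeric(frequencies),
                 intensities = pmax(as.numeric(intensities), 0),
                 labels = labels), class = "molvib_sticks")
}

#' Apply a frequency scaling factor
#'
#' Multiplies all stick frequencies by a common empirical factor (e.g.
#' 0.957 for hybrid-functional amide-region spectra); intensities are
#' unchanged.
#'
#' @param sticks a `molvib_sticks`.
#' @param factor positive scalar.
#' @return scaled `molvib_sticks`.
#' @export
apply_scaling <- function(sticks, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    stop("scaling factor must be a positive scalar", call. = FALSE)
  }
  sticks$frequencies <- sticks$frequencies * factor
  sticks$scale_factor <- (sticks$scale_factor %||% 1) * factor
  sticks
}

#' Broaden a stick spectrum
#'
#' sigma(omega) = sum_k A_k f(omega; omega_k0, gamma) with a Lorentzian
#' line shape f = (1/pi) gamma / ((omega_k0 - omega)^2 + gamma^2) (HWHM
#' gamma) by default; each line integrates to A_k over the real line.
#'
#' @param sticks a `molvib_sticks`.
#' @param gamma half-width at half-maximum (cm^-1, positive).
#' @param grid numeric vector of wavenumbers, or NULL for the default
#'   1 cm^-1 grid over [max(0, min - 10 gamma), max + 10 gamma].
#' @param shape "lorentzian" (default) or "gaussian" (gamma read as HWHM).
#' @return object of class `molvib_spectrum`: `omega`, `sigma`
#'   (km/mol per cm^-1), `gamma`, `shape`, `scale_factor`.
#' @export
broaden <- function(sticks, gamma = 10, grid = NULL,
                    shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  if (gamma <= 0) stop("gamma (HWHM) must be positive", call. = FALSE)
  if (length(sticks$frequencies) == 0) {
    warning("empty stick spectrum: returning empty broadened spectrum")
    return(structure(list(omega = numeric(0), sigma = numeric(0),
                          gamma = gamma, shape = shape,
                          scale_factor = sticks$scale_factor %||% 1),
                     class = "molvib_spectrum"))
  }
  if (is.null(grid)) {
    lo <- max(0, floor(min(sticks$frequencies) - 10 * gamma))
    hi <- ceiling(max(sticks$frequencies) + 10 * gamma)
    grid <- seq(lo, hi, by = 1)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  sigma <- numeric(length(grid))
  for (k in seq_along(sticks$frequencies)) {
    d <- sticks$frequencies[k] - grid
    sigma <- sigma + sticks$intensities[k] *
      if (shape == "lorentzian") {
        (1 / pi) * gamma / (d^2 + gamma^2)
      } else {
        s <- gamma / sqrt(2 * log(2))
        exp(-d^2 / (2 * s^2)) / (s * sqrt(2 * pi))
      }
  }
  structure(list(omega = grid, sigma = sigma, gamma = gamma, shape = shape,
                 scale_factor = sticks$scale_factor %||% 1),
            class = "molvib_spectrum")
}

#' Write a spectrum to file
#'
#' CSV (`wavenumber_cm-1,sigma`) or a minimal JCAMP-DX XYDATA record.
#' @param spec a `molvib_spectrum`.
#' @param path output path.
#' @param format "csv" or "jcamp".
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, format = c("csv", "jcamp")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(data.frame(`wavenumber_cm-1` = spec$omega,
                                sigma = spec$sigma, check.names = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    lines <- c("##TITLE=molvib simulated IR spectrum",
               "##JCAMP-DX=4.24",
               "##DATA TYPE=INFRARED SPECTRUM",
               "##XUNITS=1/CM", "##YUNITS=ARBITRARY",
               sprintf("##FIRSTX=%.6f", spec$omega[1]),
               sprintf("##LASTX=%.6f", spec$omega[length(spec$omega)]),
               sprintf("##NPOINTS=%d", length(spec$omega)),
               "##XYDATA=(XY..XY)",
               sprintf("%.6f, %.10e", spec$omega, spec$sigma),
               "##END=")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#' @param path file path.
#' @param format "csv" or "jcamp".
#' @return list with `omega`, `sigma`.
#' @export
read_spectrum <- function(path, format = c("csv", "jcamp")) {
  format <- match.arg(format)
  if (format == "csv") {
    d <- utils::read.csv(path, check.names = FALSE)
    list(omega = d[[1]], sigma = d[[2]])
  } else {
    lines <- readLines(path)
    xy <- grep("^[0-9.+-]", lines, value = TRUE)
    parts <- do.call(rbind, strsplit(xy, ",\\s*"))
    list(omega = as.numeric(parts[, 1]), sigma = as.numeric(parts[, 2]))
  }
}

#' Write a stick table (TSV) with optional per-mode labels
#' @param sticks a `molvib_sticks`.
#' @param path output path.
#' @export
write_sticks <- function(sticks, path) {
  d <- data.frame(wavenumber_cm1 = sticks$frequencies,
                  intensity_km_mol = sticks$intensities)
  if (!is.null(sticks$labels)) d$label <- sticks$labels
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
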