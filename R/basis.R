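# Basis-set ingestion: Gaussian-94-style text files and a structured JSON
# dialect, shell bookkeeping and contraction normalization.
#
# Shells are segmented contractions of primitive Cartesian Gaussians.
# Stored contraction coefficients (`coef`) include the primitive
# normalization of the (l,0,0) component and an overall rescaling so that
# each contracted AO has unit self-overlap.

l_letters <- c(S = 0L, P = 1L, D = 2L, F = 3L, G = 4L)

prim_norm <- function(alpha, l) {
  (2 * alpha / pi)^0.75 * (4 * alpha)^(l / 2) / sqrt(double_factorial(2 * l - 1))
}

normalize_shell <- function(l, exponents, coefficients) {
  o <- order(exponents, decreasing = TRUE)
  exponents <- exponents[o]; coefficients <- coefficients[o]
  if (any(exponents <= 0)) stop("primitive exponents must be positive", call. = FALSE)
  c0 <- coefficients * prim_norm(exponents, l)
  ab <- outer(exponents, exponents, `+`)
  Spp <- (pi / ab)^1.5 * double_factorial(2 * l - 1) / (2 * ab)^l
  self <- drop(c0 %*% Spp %*% c0)
  list(l = as.integer(l), exponents = exponents,
       coefficients = coefficients, coef = c0 / sqrt(self))
}

parse_g94_basis <- function(lines) {
  lines <- sub("!.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  elements <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (lines[i] == "****") { i <- i + 1L; next }
    hdr <- strsplit(lines[i], "\\s+")[[1]]
    el <- normalize_element(hdr[1])
    i <- i + 1L
    shells <- list()
    while (i <= length(lines) && lines[i] != "****") {
      sh <- strsplit(lines[i], "\\s+")[[1]]
      type <- toupper(sh[1])
      np <- as.integer(sh[2])
      if (is.na(np) || np < 1) stop("malformed shell header: ", lines[i], call. = FALSE)
      prim <- do.call(rbind, lapply(lines[i + seq_len(np)], function(x) {
        as.numeric(strsplit(gsub("[DdEe]([+-])", "e\\1", x), "\\s+")[[1]])
      }))
      i <- i + np + 1L
      if (type == "SP") {
        shells[[length(shells) + 1L]] <- list(l = 0L, exponents = prim[, 1],
                                              coefficients = prim[, 2])
        shells[[length(shells) + 1L]] <- list(l = 1L, exponents = prim[, 1],
                                              coefficients = prim[, 3])
      } else {
        if (!type %in% names(l_letters)) {
          stop("unsupported shell type: ", type, call. = FALSE)
        }
        shells[[length(shells) + 1L]] <- list(l = l_letters[[type]],
                                              exponents = prim[, 1],
                                              coefficients = prim[, 2])
      }
    }
    elements[[el]] <- shells
    i <- i + 1L
  }
  elements
}

parse_json_basis <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$elements)) stop("structured basis file lacks 'elements'", call. = FALSE)
  lapply(obj$elements, function(el) {
    sh <- el$shells
    lapply(seq_along(sh$l), function(k) {
      list(l = as.integer(sh$l[[k]]),
           exponents = as.numeric(unlist(sh$exponents[[k]])),
           coefficients = as.numeric(unlist(sh$coefficients[[k]])))
    })
  })
}

resolve_basis_file <- function(name_or_file) {
  if (file.exists(name_or_file)) return(name_or_file)
  key <- gsub("\\(", "_", tolower(name_or_file))
  key <- gsub("\\)", "", key)
  for (ext in c(".gbs", ".json")) {
    f <- system.file("extdata", "basis", paste0(key, ext), package = "molvib")
    if (nzchar(f)) return(f)
  }
  stop("basis set not found: ", name_or_file, call. = FALSE)
}

#' Load a basis set for a molecule
#'
#' Reads a Gaussian-94-style text file (`.gbs`) or the package's structured
#' JSON dialect (`.json`), either by library name (e.g. `"sto-3g"`,
#' `"def2-sv(p)"`) or by file path, and instantiates shells on every atom.
#' Shells are ordered by atom and then by ascending angular momentum;
#' contraction coefficients are renormalized so each contracted function
#' has unit self-overlap.
#'
#' @param basis_name_or_file basis library name or path.
#' @param molecule a `molvib_molecule`.
#' @return An object of class `molvib_basis`: list with `shells` (each with
#'   `atom`, `l`, `exponents`, `coefficients`, normalized `coef`),
#'   `ao_offsets` (first spherical AO index per shell, 1-based),
#'   `cart_offsets`, `n_ao`, `n_cart`, `name`.
#' @export
load_basis <- function(basis_name_or_file, molecule) {
  file <- resolve_basis_file(basis_name_or_file)
  lib <- if (grepl("\\.json$", file)) parse_json_basis(file)
         else parse_g94_basis(readLines(file, warn = FALSE))
  names(lib) <- normalize_element(names(lib))
  shells <- list()
  for (a in seq_along(molecule$elements)) {
    el <- molecule$elements[a]
    blk <- lib[[el]]
    if (is.null(blk)) {
      stop("element ", el, " not present in basis ", basis_name_or_file,
           call. = FALSE)
    }
    ls <- vapply(blk, `[[`, 0L, "l")
    if (any(ls > .MAX_L)) {
      stop("unsupported angular momentum l = ", max(ls), " in basis for ", el,
           call. = FALSE)
    }
    for (sh in blk[order(ls)]) {
      s <- normalize_shell(sh$l, sh$exponents, sh$coefficients)
      s$atom <- a
      shells[[length(shells) + 1L]] <- s
    }
  }
  nsph <- vapply(shells, function(s) n_sph_comp(s$l), 0L)
  ncar <- vapply(shells, function(s) n_cart_comp(s$l), 0L)
  structure(list(
    shells = shells,
    ao_offsets = cumsum(c(1L, nsph))[seq_along(shells)],
    cart_offsets = cumsum(c(1L, ncar))[seq_along(shells)],
    n_ao = sum(nsph),
    n_cart = sum(ncar),
    name = basis_name_or_file
  ), class = "molvib_basis")
}

#' @export
print.molvib_basis <- function(x, ...) {
  cat(sprintf("<molvib_basis '%s': %d shells, %d spherical AOs, %d Cartesian AOs>\n",
              x$name, length(x$shells), x$n_ao, x$n_cart))
  invisible(x)
}

# spherical AO index range of a shell
shell_ao_range <- function(basis, i) {
  basis$ao_offsets[i] + seq_len(n_sph_comp(basis$shells[[i]]$l)) - 1L
}
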