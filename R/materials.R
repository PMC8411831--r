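#' Tabulated complex refractive index of a dispersive material
#'
#' Reads a whitespace-delimited table with a header row naming columns
#' `wavelength_nm`, `n` and `k` (comment lines starting with `#` are
#' skipped) and returns a `dielectric_table` used to interpolate the
#' complex refractive index at arbitrary wavelengths inside the covered
#' band.
#'
#' @param path Path to the table file. The default is the bundled
#'   Johnson--Christy table for evaporated gold films, which covers
#'   roughly 188--1937 nm.
#' @return An object of class `dielectric_table` with fields
#'   `wavelengths` (nm, strictly increasing), `n` and `k`.
#' @export
read_dielectric_table <- function(path = system.file("extdata",
                                                     "gold_johnson_christy.txt",
                                                     package = "plasmocnr")) {
  stopifnot(file.exists(path))
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  required <- c("wavelength_nm", "n", "k")
  if (!all(required %in% names(tab)))
    stop("dielectric table must have columns: ", paste(required, collapse = ", "))
  dielectric_table(tab$wavelength_nm, tab$n, tab$k)
}

#' Construct a dielectric table from vectors
#'
#' @param wavelengths Wavelengths in nm, strictly increasing.
#' @param n Real refractive index at each wavelength.
#' @param k Extinction coefficient at each wavelength, all >= 0.
#' @return A `dielectric_table` object.
#' @export
dielectric_table <- function(wavelengths, n, k) {
  stopifnot(length(wavelengths) == length(n), length(n) == length(k))
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(k < 0))
    stop("extinction coefficient k must be >= 0")
  structure(list(wavelengths = as.numeric(wavelengths),
                 n = as.numeric(n), k = as.numeric(k)),
            class = "dielectric_table")
}

#' @export
print.dielectric_table <- function(x, ...) {
  cat(sprintf("<dielectric_table> %d nodes, %.1f-%.1f nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Complex relative permittivity of a tabulated material
#'
#' Interpolates n and k linearly in wavelength between the bracketing
#' table nodes (not in permittivity) and returns (n + i k)^2.
#'
#' @param table A `dielectric_table`.
#' @param wavelength Wavelength(s) in nm; must lie inside the table band.
#' @return Complex relative permittivity, same length as `wavelength`.
#' @export
gold_permittivity <- function(table, wavelength) {
  stopifnot(inherits(table, "dielectric_table"))
  lo <- min(table$wavelengths); hi <- max(table$wavelengths)
  if (any(wavelength < lo | wavelength > hi))
    stop(sprintf("wavelength outside tabulated band [%.1f, %.1f] nm", lo, hi))
  n <- stats::approx(table$wavelengths, table$n, xout = wavelength)$y
  k <- stats::approx(table$wavelengths, table$k, xout = wavelength)$y
  (complex(real = n, imaginary = k))^2
}

#' Material set for the biosensor scene
#'
#' Bundles the constant refractive indices of the dielectric materials
#' (water ambient, glass substrate, functionalization shell, analyte
#' molecule) with the dispersive gold table. Defaults follow the
#' reference biosensor model: shell n = 1.45 (PEG), molecule n = 1.57
#' (water-free streptavidin), water 1.33, glass 1.52.
#'
#' @param n_water,n_glass,n_shell,n_molecule Constant real refractive
#'   indices, all >= 1.
#' @param gold A `dielectric_table` for gold; defaults to the bundled
#'   Johnson--Christy data.
#' @return A `material_set` object.
#' @export
material_set <- function(n_water = 1.33, n_glass = 1.52,
                         n_shell = 1.45, n_molecule = 1.57,
                         gold = read_dielectric_table()) {
  idx <- c(n_water = n_water, n_glass = n_glass,
           n_shell = n_shell, n_molecule = n_molecule)
  if (any(!is.finite(idx)) || any(idx < 1))
    stop("constant refractive indices must be real and >= 1")
  stopifnot(inherits(gold, "dielectric_table"))
  structure(list(n_water = n_water, n_glass = n_glass, n_shell = n_shell,
                 n_molecule = n_molecule, gold = gold),
            class = "material_set")
}

#' @export
print.material_set <- function(x, ...) {
  cat(sprintf("<material_set> water %.3f | glass %.3f | shell %.3f | molecule %.3f | gold: %d-node table\n",
              x$n_water, x$n_glass, x$n_shell, x$n_molecule,
              length(x$gold$wavelengths)))
  invisible(x)
}

# Relative permittivity of a material id at given wavelength(s).
# Material ids: 0 ambient/water, 1 gold, 2 shell, 3 molecule, 4 glass.
material_permittivity <- function(materials, material_id, wavelength) {
  switch(as.character(material_id),
         "0" = complex(real = rep(materials$n_water^2, length(wavelength))),
         "1" = gold_permittivity(materials$gold, wavelength),
         "2" = complex(real = rep(materials$n_shell^2, length(wavelength))),
         "3" = complex(real = rep(materials$n_molecule^2, length(wavelength))),
         "4" = complex(real = rep(materials$n_glass^2, length(wavelength))),
         stop("unknown material id: ", material_id))
}

MATERIAL_IDS <- c(ambient = 0L, gold = 1L, shell = 2L, molecule = 3L, glass = 4L)
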