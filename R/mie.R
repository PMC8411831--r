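#' Lorenz-Mie cross sections of a homogeneous sphere
#'
#' Independent validation oracle for the DDA solver: exact Mie series
#' for a sphere of complex permittivity embedded in a non-absorbing
#' ambient medium. The series is truncated by the Wiscombe size-
#' parameter rule and the truncation is checked by doubling the order;
#' the logarithmic derivative is evaluated by downward recurrence.
#'
#' @param radius Sphere radius in nm (> 0).
#' @param eps_particle Complex relative permittivity of the sphere
#'   (relative to vacuum).
#' @param ambient_index Real refractive index of the medium.
#' @param wavelength Vacuum wavelength in nm (> 0).
#' @param conv_tol Relative change in C_ext allowed when doubling the
#'   truncation order (default 1e-8); exceeded -> error.
#' @return A `cross_sections` object with fields `C_ext`, `C_abs`,
#'   `C_scat` (um2) and `wavelength` (nm).
#' @export
mie_oracle <- function(radius, eps_particle, ambient_index = 1.33,
                       wavelength, conv_tol = 1e-8) {
  stopifnot(radius > 0, wavelength > 0, ambient_index >= 1)
  k <- 2 * pi * ambient_index / wavelength         # 1/nm, in medium
  x <- k * radius                                   # size parameter
  m <- sqrt(as.complex(eps_particle)) / ambient_index
  if (Im(m) < 0) m <- -m                            # principal branch, Im >= 0
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  ce1 <- .mie_qext(x, m, nmax)
  ce2 <- .mie_qext(x, m, 2 * nmax)
  if (abs(ce2$ext - ce1$ext) > conv_tol * abs(ce2$ext))
    stop("Mie series did not converge under truncation doubling")
  geo <- pi * radius^2                              # nm2
  C_ext <- ce2$ext * geo * 1e-6                     # -> um2
  C_scat <- ce2$sca * geo * 1e-6
  cross_sections(C_ext = C_ext, C_abs = C_ext - C_scat, wavelength = wavelength)
}

# Mie efficiencies at truncation order nmax (Bohren & Huffman scheme).
.mie_qext <- function(x, m, nmax) {
  mx <- m * x
  nmx <- max(nmax, ceiling(Mod(mx))) + 16
  D <- complex(length.out = nmx + 1)                # log-derivative, downward
  for (n in seq(nmx, 1)) {
    rn <- (n + 1) / mx
    D[n] <- rn - 1 / (D[n + 1] + rn)
  }
  psi0 <- sin(x); psi_m1 <- cos(x)
  chi0 <- cos(x); chi_m1 <- -sin(x)
  qext <- 0; qsca <- 0
  psi_nm1 <- psi0; psi_nm2 <- psi_m1
  chi_nm1 <- chi0; chi_nm2 <- chi_m1
  for (n in seq_len(nmax)) {
    psi_n <- (2 * n - 1) / x * psi_nm1 - psi_nm2
    chi_n <- (2 * n - 1) / x * chi_nm1 - chi_nm2
    xi_n <- complex(real = psi_n, imaginary = -chi_n)
    xi_nm1 <- complex(real = psi_nm1, imaginary = -chi_nm1)
    da <- D[n] / m + n / x
    db <- D[n] * m + n / x
    an <- (da * psi_n - psi_nm1) / (da * xi_n - xi_nm1)
    bn <- (db * psi_n - psi_nm1) / (db * xi_n - xi_nm1)
    qext <- qext + (2 * n + 1) * Re(an + bn)
    qsca <- qsca + (2 * n + 1) * (Mod(an)^2 + Mod(bn)^2)
    psi_nm2 <- psi_nm1; psi_nm1 <- psi_n
    chi_nm2 <- chi_nm1; chi_nm1 <- chi_n
  }
  list(ext = 2 / x^2 * qext, sca = 2 / x^2 * qsca)
}

#' Cross-section container
#'
#' @param C_ext,C_abs Extinction and absorption cross sections in um2;
#'   scattering is their difference (clipped at zero with a warning if
#'   slightly negative).
#' @param wavelength Vacuum wavelength in nm.
#' @param tol Tolerance for the non-negativity check on `C_scat`,
#'   relative to `C_ext`.
#' @return A `cross_sections` object.
#' @export
cross_sections <- function(C_ext, C_abs, wavelength, tol = 1e-6) {
  C_scat <- C_ext - C_abs
  bad <- C_scat < -tol * pmax(abs(C_ext), .Machine$double.eps)
  if (any(bad))
    warning("C_scat slightly negative; clipped to 0")
  C_scat <- pmax(C_scat, 0)
  structure(list(C_ext = C_ext, C_abs = C_abs, C_scat = C_scat,
                 wavelength = wavelength),
            class = "cross_sections")
}

#' @export
print.cross_sections <- function(x, ...) {
  cat(sprintf("<cross_sections> lambda %.1f nm: C_ext %.4g, C_abs %.4g, C_scat %.4g um2\n",
              x$wavelength[1], x$C_ext[1], x$C_abs[1], x$C_scat[1]))
  invisible(x)
}
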