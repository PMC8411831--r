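#' Specification of a synthetic two-state Lorentzian count spectrum
#'
#' Describes the statistical structure the sensing pipeline assumes: a
#' Lorentzian resonance whose bound state is shifted (and optionally
#' amplified and broadened), observed as Poisson-distributed photon
#' counts.
#'
#' @param lambda_res Bare resonance position, nm.
#' @param gamma Bare resonance FWHM, nm (> 0).
#' @param peak_counts Mean photon count at the bare peak.
#' @param shift Bound-state resonance shift, nm.
#' @param amp_change Fractional bound-state amplitude change.
#' @param width_change Fractional bound-state width change.
#' @param baseline Additive baseline counts.
#' @param n_points Spectral points.
#' @param span Sampled half-window in units of gamma.
#' @return A `synthetic_spectrum_spec` object.
#' @export
synthetic_spectrum_spec <- function(lambda_res = 800, gamma = 40,
                                    peak_counts = 1e4, shift = 0.4,
                                    amp_change = 0, width_change = 0,
                                    baseline = 0, n_points = 21, span = 1.2) {
  stopifnot(gamma > 0, peak_counts >= 0, baseline >= 0, n_points >= 5,
            span > 0, width_change > -1, amp_change > -1)
  structure(list(lambda_res = lambda_res, gamma = gamma,
                 peak_counts = peak_counts, shift = shift,
                 amp_change = amp_change, width_change = width_change,
                 baseline = baseline, n_points = n_points, span = span),
            class = "synthetic_spectrum_spec")
}

#' Generate a synthetic two-state count spectrum pair
#'
#' Poisson-samples both states around their analytic Lorentzians and
#' returns the noiseless truth alongside. With `sample = FALSE` the
#' noiseless means themselves are returned as the spectra
#' (infinite-count limit).
#'
#' @param spec A `synthetic_spectrum_spec`.
#' @param seed Integer seed; the draw is reproducible given it.
#' @param sample Logical; Poisson-sample the counts (default `TRUE`).
#' @return A list with `without` and `with` (`spectrum` objects, counts),
#'   `truth_without`, `truth_with` (noiseless means), `wavelengths` and
#'   the generating `spec` and `seed`.
#' @export
make_two_state_spectra <- function(spec = synthetic_spectrum_spec(), seed = 1,
                                   sample = TRUE) {
  stopifnot(inherits(spec, "synthetic_spectrum_spec"))
  wl <- seq(spec$lambda_res - spec$span * spec$gamma,
            spec$lambda_res + spec$span * spec$gamma,
            length.out = spec$n_points)
  lor <- function(l0, g, a) a * (g / 2)^2 / ((wl - l0)^2 + (g / 2)^2)
  t1 <- spec$baseline + lor(spec$lambda_res, spec$gamma, spec$peak_counts)
  t2 <- spec$baseline + lor(spec$lambda_res + spec$shift,
                            spec$gamma * (1 + spec$width_change),
                            spec$peak_counts * (1 + spec$amp_change))
  if (sample) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    y1 <- stats::rpois(length(wl), t1)
    y2 <- stats::rpois(length(wl), t2)
  } else {
    y1 <- t1; y2 <- t2
  }
  list(without = spectrum(wl, y1, kind = "counts"),
       with = spectrum(wl, y2, kind = "counts"),
       truth_without = t1, truth_with = t2,
       wavelengths = wl, spec = spec, seed = seed)
}

#' Small dipole-grid fixtures with checkable solutions
#'
#' Named voxelized layouts small enough for brute-force validation of
#' the electromagnetic solver: a single gold sphere, two separated
#' spheres, and a coarse bare nanorod scene.
#'
#' @param layout `"sphere"` (10 nm gold sphere, 1 nm voxels),
#'   `"two_spheres"` (two 6 nm spheres 20 nm apart), or `"rod_coarse"`
#'   (16 x 32 nm shelled rod at 2 nm voxels, on glass).
#' @param materials A `material_set`.
#' @return A `dipole_grid` of fewer than 5000 voxels.
#' @export
make_toy_grid <- function(layout = c("sphere", "two_spheres", "rod_coarse"),
                          materials = material_set()) {
  layout <- match.arg(layout)
  if (layout == "sphere")
    return(sphere_grid(5, 1, materials = materials))
  if (layout == "two_spheres") {
    g1 <- sphere_grid(3, 1, materials = materials, center = c(-10, 0, 0))
    g2 <- sphere_grid(3, 1, materials = materials, center = c(10, 0, 0))
    pts <- rbind(g1$coords, g2$coords)
    h <- 1
    ix <- round(pts[, 1] / h - 0.5); iy <- round(pts[, 2] / h - 0.5)
    iz <- round(pts[, 3] / h - 0.5)
    ix <- ix - min(ix) + 1L; iy <- iy - min(iy) + 1L; iz <- iz - min(iz) + 1L
    scn <- list(materials = materials, substrate = FALSE, z_interface = -Inf)
    return(structure(list(voxel_size = h, coords = pts,
                          material = rep(MATERIAL_IDS[["gold"]], nrow(pts)),
                          index = cbind(ix = as.integer(ix),
                                        iy = as.integer(iy),
                                        iz = as.integer(iz)),
                          dims = c(max(ix), max(iy), max(iz)),
                          band = NULL, molecule_scale = 1, scene = scn),
                     class = "dipole_grid"))
  }
  scn <- build_scene(nanorod_geometry(16, 2), materials = materials)
  suppressWarnings(voxelize(scn, 2))
}
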