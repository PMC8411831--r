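#' Capped gold nanorod geometry
#'
#' The nanorod is a spherically capped cylinder (spherocylinder): a
#' cylinder of diameter `d` and length `D - d` capped by two hemispheres
#' of diameter `d`, so the total tip-to-tip length is `D = AR * d`.
#' `AR = 1` degenerates to a sphere.
#'
#' @param diameter Rod width `d` in nm (> 0).
#' @param aspect_ratio Length over width, `AR >= 1`.
#' @return A `nanorod_geometry` object with fields `d`, `ar`, `length`.
#' @export
nanorod_geometry <- function(diameter, aspect_ratio) {
  stopifnot(is.numeric(diameter), diameter > 0,
            is.numeric(aspect_ratio), aspect_ratio >= 1)
  structure(list(d = diameter, ar = aspect_ratio,
                 length = diameter * aspect_ratio),
            class = "nanorod_geometry")
}

#' Functionalization shell specification
#'
#' @param thickness Shell thickness in nm (>= 0); default 1.5 nm, the
#'   length of the PEG4-thiol linkers assumed for tip functionalization
#'   and side passivation.
#' @param refractive_index Real refractive index of the shell; default 1.45.
#' @return A `shell_spec` object.
#' @export
shell_spec <- function(thickness = 1.5, refractive_index = 1.45) {
  stopifnot(thickness >= 0, refractive_index >= 1)
  structure(list(thickness = thickness, refractive_index = refractive_index),
            class = "shell_spec")
}

#' Analyte molecule specification
#'
#' The molecule is modeled as a dielectric solid of fixed volume. All
#' shapes are constrained to the volume of the reference sphere, so a
#' `molecule_spec` can be given either an `equivalent_diameter` (diameter
#' of the equal-volume sphere) or a molecular weight, which is converted
#' assuming a closely packed protein interior.
#'
#' @param shape One of `"sphere"`, `"hemisphere"`, `"spherical_segment"`,
#'   `"concave_spherical_segment"`.
#' @param equivalent_diameter Diameter (nm) of the equal-volume sphere.
#'   Default 5 nm (approximately streptavidin, 52.8 kDa at 1.37 g/cm3).
#' @param mw_kda Molecular weight in kDa; used if
#'   `equivalent_diameter` is missing.
#' @param refractive_index Real refractive index; default 1.57
#'   (water-free streptavidin).
#' @param density Protein density in g/cm3 used for the mass-to-size
#'   conversion; default 1.37.
#' @return A `molecule_spec` object with fields `shape`, `volume` (nm3),
#'   `equivalent_diameter` (nm), `refractive_index`.
#' @export
molecule_spec <- function(shape = c("sphere", "hemisphere",
                                    "spherical_segment",
                                    "concave_spherical_segment"),
                          equivalent_diameter = NULL, mw_kda = NULL,
                          refractive_index = 1.57, density = 1.37) {
  shape <- match.arg(shape)
  if (is.null(equivalent_diameter)) {
    if (is.null(mw_kda)) equivalent_diameter <- 5
    else equivalent_diameter <- sphere_diameter_from_mass(mw_kda, density)
  }
  stopifnot(equivalent_diameter > 0, refractive_index >= 1)
  structure(list(shape = shape,
                 equivalent_diameter = equivalent_diameter,
                 volume = pi * equivalent_diameter^3 / 6,
                 refractive_index = refractive_index),
            class = "molecule_spec")
}

#' Molecular binding site on the shell surface
#'
#' Sites are indexed from the tip apex: indices 0..6 step every 15
#' degrees along the spherical cap (0 = apex on the long axis, 6 = the
#' cap--cylinder junction at 90 degrees), and indices 7..12 step every
#' 5 nm along the flat side toward the rod midpoint (index 12 is the
#' midpoint for a 20 x 80 nm rod; for other lengths the last index is
#' clamped to the midpoint). On the vertical plane, negative indices
#' mirror the site toward the substrate.
#'
#' @param plane `"horizontal_side"` (sites in the plane parallel to the
#'   substrate) or `"vertical_ridge"` (plane perpendicular to it).
#' @param index Integer site code in -12..12; negative values only on
#'   the vertical plane.
#' @return A `binding_site` object.
#' @export
binding_site <- function(plane = c("horizontal_side", "vertical_ridge"),
                         index = 0L) {
  plane <- match.arg(plane)
  stopifnot(length(index) == 1, index == round(index))
  if (abs(index) > 12)
    stop("site index beyond the rod midpoint (|index| must be <= 12)")
  if (index < 0 && plane != "vertical_ridge")
    stop("negative (substrate-facing) site indices require the vertical plane")
  structure(list(plane = plane, index = as.integer(index)),
            class = "binding_site")
}

#' Analytic volume of a capped nanorod
#'
#' Closed form: pi d^2 (D - d) / 4 + pi d^3 / 6.
#'
#' @param rod A `nanorod_geometry`.
#' @return Volume in nm3.
#' @export
rod_volume <- function(rod) {
  stopifnot(inherits(rod, "nanorod_geometry"))
  d <- rod$d; D <- rod$length
  pi * d^2 * (D - d) / 4 + pi * d^3 / 6
}

#' Volume-equivalent sphere radius of a nanorod
#'
#' Radius of the sphere with the same volume as the capped rod,
#' `(3 V / 4 pi)^(1/3)`; used in the steady-state heating formula.
#'
#' @param rod A `nanorod_geometry`.
#' @return Radius in nm.
#' @export
equivalent_radius <- function(rod) {
  (3 * rod_volume(rod) / (4 * pi))^(1 / 3)
}

DALTON_G <- 1.66053906660e-21  # grams per kilodalton

#' Equal-volume sphere diameter of a globular protein
#'
#' Converts molecular weight to the diameter of a sphere of the same
#' mass at the given density: `d = (6 m / (pi rho))^(1/3)`.
#'
#' @param mass_kda Molecular weight in kDa (> 0).
#' @param density Density in g/cm3 (> 0); default 1.37 for a closely
#'   packed protein interior.
#' @return Diameter in nm.
#' @export
sphere_diameter_from_mass <- function(mass_kda, density = 1.37) {
  stopifnot(all(mass_kda > 0), density > 0)
  v_nm3 <- mass_kda * DALTON_G / density * 1e21  # cm3 -> nm3
  (6 * v_nm3 / pi)^(1 / 3)
}

#' Inverse of [sphere_diameter_from_mass()]
#' @param diameter_nm Sphere diameter in nm.
#' @param density Density in g/cm3.
#' @return Molecular weight in kDa.
#' @export
mass_from_sphere_diameter <- function(diameter_nm, density = 1.37) {
  stopifnot(all(diameter_nm > 0), density > 0)
  v_nm3 <- pi * diameter_nm^3 / 6
  v_nm3 * 1e-21 * density / DALTON_G
}

# Distance from points (n x 3 matrix) to the rod axis segment.
# The rod axis lies along x, centered at the origin.
.axis_distance <- function(pts, half_len) {
  x <- pmin(pmax(pts[, 1], -half_len), half_len)
  sqrt((pts[, 1] - x)^2 + pts[, 2]^2 + pts[, 3]^2)
}

# Geometry of a binding site on the outer shell surface: returns the
# anchor point on the surface and the outward unit normal there.
.site_geometry <- function(rod, shell, site) {
  r_out <- rod$d / 2 + shell$thickness
  hl <- (rod$length - rod$d) / 2  # cylinder half-length
  u <- switch(site$plane,
              horizontal_side = c(0, 1, 0),
              vertical_ridge = c(0, 0, if (site$index < 0) -1 else 1))
  i <- abs(site$index)
  if (i <= 6) {  # spherical cap, 15 degree steps from the apex
    theta <- i * 15 * pi / 180
    normal <- cos(theta) * c(1, 0, 0) + sin(theta) * u
    point <- c(hl, 0, 0) + r_out * normal
  } else {       # flat side, 5 nm steps from the junction, clamped
    s <- min((i - 6) * 5, hl)
    normal <- u
    point <- c(hl - s, 0, 0) + r_out * u
  }
  list(point = point, normal = normal)
}

#' Point-membership predicate for a molecule shape
#'
#' Builds the solid region of the analyte molecule oriented along the
#' outward surface normal of its binding site, constrained to the volume
#' of the reference sphere. The concave spherical segment's inner face
#' conforms to the outer shell surface (its radius is calibrated
#' numerically so the enclosed volume matches the sphere volume to
#' better than 0.5%).
#'
#' @param spec A `molecule_spec`.
#' @param rod A `nanorod_geometry`.
#' @param site A `binding_site` (or the list returned by the internal
#'   site-geometry helper).
#' @param shell A `shell_spec`.
#' @return A list with `contains(pts)` (a vectorized membership
#'   predicate over an n x 3 coordinate matrix), `center` (a point
#'   inside the solid), `bound_radius` (radius of a bounding sphere
#'   about `center`), and shape dimensions.
#' @export
molecule_shape_solid <- function(spec, rod, site, shell = shell_spec()) {
  stopifnot(inherits(spec, "molecule_spec"))
  geom <- if (inherits(site, "binding_site"))
    .site_geometry(rod, shell, site) else site
  p <- geom$point; nrm <- geom$normal
  a <- spec$equivalent_diameter / 2
  v_ref <- spec$volume
  r_out <- rod$d / 2 + shell$thickness
  hl <- (rod$length - rod$d) / 2

  if (spec$shape == "sphere") {
    ctr <- p + a * nrm
    contains <- function(pts) {
      dd <- sweep(pts, 2, ctr)
      rowSums(dd^2) <= a^2
    }
    return(list(contains = contains, center = ctr, bound_radius = a,
                dims = list(radius = a)))
  }
  if (spec$shape == "hemisphere") {
    rh <- (2)^(1 / 3) * a  # half-ball of equal volume
    contains <- function(pts) {
      dd <- sweep(pts, 2, p)
      rowSums(dd^2) <= rh^2 & (dd %*% nrm)[, 1] >= 0
    }
    return(list(contains = contains, center = p + (rh / 2) * nrm,
                bound_radius = rh, dims = list(radius = rh, height = rh)))
  }
  if (spec$shape == "spherical_segment") {
    # cap of a sphere with height h = R/2; V = 5 pi R^3 / 24
    R <- (24 * v_ref / (5 * pi))^(1 / 3)
    h <- R / 2
    c_sph <- p + (h - R) * nrm
    contains <- function(pts) {
      dd <- sweep(pts, 2, c_sph)
      along <- (sweep(pts, 2, p) %*% nrm)[, 1]
      rowSums(dd^2) <= R^2 & along >= 0 & along <= h
    }
    return(list(contains = contains, center = p + (h / 2) * nrm,
                bound_radius = R, dims = list(radius = R, height = h)))
  }
  # concave_spherical_segment: ball centered on the anchor point minus the
  # shell solid, radius calibrated so the enclosed volume equals v_ref
  member_at <- function(R, pts) {
    dd <- sweep(pts, 2, p)
    rowSums(dd^2) <= R^2 & .axis_distance(pts, hl) > r_out
  }
  vol_at <- function(R) {
    n1 <- 36L  # quadrature points per radius
    h <- R / n1
    g <- seq(-R + h / 2, R - h / 2, by = h)
    pts <- as.matrix(expand.grid(x = p[1] + g, y = p[2] + g, z = p[3] + g))
    sum(member_at(R, pts)) * h^3
  }
  R <- stats::uniroot(function(R) vol_at(R) - v_ref,
                      lower = 0.8 * a, upper = 4 * a, tol = 1e-3 * a)$root
  achieved <- vol_at(R)
  if (abs(achieved - v_ref) / v_ref > 0.005)
    stop("could not calibrate concave segment volume to within 0.5%")
  contains <- function(pts) member_at(R, pts)
  list(contains = contains, center = p + (R / 2) * nrm, bound_radius = R,
       dims = list(radius = R))
}

#' Assemble a biosensor scene
#'
#' Validates and combines the rod, shell, molecule and environment into
#' a `scene`. The molecule rests on the outer shell surface along the
#' local outward normal of its binding site. With the substrate enabled
#' the shell rests on the glass plane (plus an optional water gap).
#'
#' @param rod A `nanorod_geometry`.
#' @param shell A `shell_spec`.
#' @param molecule A `molecule_spec`, or `NULL` for the bare sensor.
#' @param site A `binding_site`.
#' @param materials A `material_set`.
#' @param substrate Logical; include the glass half-space (via the
#'   quasi-static image correction in the solver).
#' @param gap Water gap between shell and glass in nm (default 0).
#' @return A `scene` object.
#' @export
build_scene <- function(rod, shell = shell_spec(), molecule = NULL,
                        site = binding_site(), materials = material_set(),
                        substrate = TRUE, gap = 0) {
  stopifnot(inherits(rod, "nanorod_geometry"), inherits(shell, "shell_spec"),
            inherits(site, "binding_site"), inherits(materials, "material_set"),
            gap >= 0)
  # apply the molecule's refractive index to the material set
  if (!is.null(molecule)) {
    stopifnot(inherits(molecule, "molecule_spec"))
    materials$n_molecule <- molecule$refractive_index
  }
  geom <- .site_geometry(rod, shell, site)
  solid <- if (!is.null(molecule))
    molecule_shape_solid(molecule, rod, geom, shell) else NULL
  z_interface <- -(rod$d / 2 + shell$thickness) - gap
  hl <- (rod$length - rod$d) / 2
  if (!is.null(solid)) {
    # molecule must not intersect gold: probe its solid on a coarse grid
    g <- seq(-solid$bound_radius, solid$bound_radius, length.out = 13)
    pts <- as.matrix(expand.grid(x = solid$center[1] + g,
                                 y = solid$center[2] + g,
                                 z = solid$center[3] + g))
    inside <- solid$contains(pts)
    if (any(inside & .axis_distance(pts, hl) < rod$d / 2 - 1e-9))
      stop("molecule solid intersects the gold rod")
    if (any(inside & pts[, 3] < z_interface - 1e-9))
      stop("molecule solid extends into the glass substrate")
  }
  structure(list(rod = rod, shell = shell, molecule = molecule,
                 site = site, site_geom = geom, molecule_solid = solid,
                 materials = materials, substrate = isTRUE(substrate),
                 gap = gap, z_interface = z_interface),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> rod %.3g x %.3g nm (AR %.3g), shell %.3g nm (n=%.3g)%s%s\n",
              x$rod$d, x$rod$length, x$rod$ar, x$shell$thickness,
              x$shell$refractive_index,
              if (!is.null(x$molecule))
                sprintf(", molecule %s d_eq=%.3g nm at %s site %d",
                        x$molecule$shape, x$molecule$equivalent_diameter,
                        x$site$plane, x$site$index)
              else ", bare",
              if (x$substrate) ", on glass" else ""))
  invisible(x)
}
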