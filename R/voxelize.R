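#' Voxelize a scene into a dipole grid
#'
#' Discretizes the non-ambient solids of a scene (gold rod, shell,
#' molecule) on a cubic lattice aligned with the rod axis. Each voxel's
#' material is decided by a center-in-solid test with priority
#' gold > molecule > shell. Ambient (water) voxels are not stored; the
#' surrounding water enters through the ambient index of the solver, and
#' the glass half-space through the image-interaction correction.
#'
#' Because the analyte molecule is much smaller than typical voxel sizes
#' used for whole-rod runs, molecule voxels optionally carry a
#' volume-renormalization factor that rescales their susceptibility so
#' the integrated (volume times contrast) product matches the analytic
#' molecule volume. This conserves the molecule's Rayleigh-limit
#' polarizability under coarse discretization and is exact to first
#' order in the field perturbation.
#'
#' @param scene A `scene`.
#' @param voxel_size Lattice constant in nm; must be at most `d / 8`
#'   (a warning is issued above `d / 16`).
#' @param band Wavelength grid in nm stored with the grid (used by the
#'   solver to resolve per-voxel permittivities).
#' @param molecule_volume_correction Logical; apply the molecule
#'   susceptibility renormalization described above (default `TRUE`).
#' @return A `dipole_grid` with voxel centers, integer lattice indices,
#'   material ids, lattice dimensions and the scene reference.
#' @export
voxelize <- function(scene, voxel_size, band = NULL,
                     molecule_volume_correction = TRUE) {
  stopifnot(inherits(scene, "scene"))
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  d <- scene$rod$d
  if (voxel_size > d / 8 + 1e-12)
    stop(sprintf("voxel_size %.3g nm too coarse for rod width %.3g nm (max d/8 = %.3g)",
                 voxel_size, d, d / 8))
  if (voxel_size > d / 16 + 1e-12)
    warning(sprintf("voxel_size %.3g nm above d/16; discretization error may be large",
                    voxel_size))
  h <- voxel_size
  r <- d / 2
  t <- scene$shell$thickness
  hl <- (scene$rod$length - d) / 2
  r_out <- r + t
  solid <- scene$molecule_solid

  # bounding box of all solids, in lattice units; lattice centered on rod
  ext <- c(hl + r_out, r_out, r_out)
  lo <- -ext; hi <- ext
  if (!is.null(solid)) {
    lo <- pmin(lo, solid$center - solid$bound_radius)
    hi <- pmax(hi, solid$center + solid$bound_radius)
  }
  ax <- function(l, u) {
    i0 <- floor(l / h - 0.5); i1 <- ceiling(u / h + 0.5)
    (seq.int(i0, i1) + 0.5) * h   # voxel centers symmetric about 0
  }
  gx <- ax(lo[1], hi[1]); gy <- ax(lo[2], hi[2]); gz <- ax(lo[3], hi[3])
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))

  dist_axis <- .axis_distance(pts, hl)
  mat <- integer(nrow(pts))                     # 0 = ambient
  mat[dist_axis <= r_out] <- MATERIAL_IDS[["shell"]]
  if (!is.null(solid)) {
    in_mol <- solid$contains(pts)
    mat[in_mol & mat == 0L] <- MATERIAL_IDS[["molecule"]]
  }
  mat[dist_axis <= r] <- MATERIAL_IDS[["gold"]]
  if (scene$substrate)                          # nothing below the interface
    mat[pts[, 3] < scene$z_interface] <- 0L

  # a molecule smaller than the voxel may contain no lattice center at
  # all; it must still be represented, so fall back to the free voxel
  # nearest its centroid (the volume renormalization below restores its
  # integrated polarizability)
  if (!is.null(solid) && !any(mat == MATERIAL_IDS[["molecule"]])) {
    free <- which(mat == 0L &
                    (!scene$substrate | pts[, 3] >= scene$z_interface))
    if (length(free)) {
      dd <- sweep(pts[free, , drop = FALSE], 2, solid$center)
      mat[free[which.min(rowSums(dd^2))]] <- MATERIAL_IDS[["molecule"]]
    }
  }

  keep <- mat != 0L
  if (!any(keep)) stop("voxelization produced an empty grid")
  pts <- pts[keep, , drop = FALSE]
  mat <- mat[keep]

  mol_scale <- 1
  n_mol <- sum(mat == MATERIAL_IDS[["molecule"]])
  if (!is.null(solid) && n_mol > 0 && molecule_volume_correction) {
    v_vox <- n_mol * h^3
    mol_scale <- scene$molecule$volume / v_vox
  }

  ix <- round(pts[, 1] / h - 0.5); iy <- round(pts[, 2] / h - 0.5)
  iz <- round(pts[, 3] / h - 0.5)
  ix <- ix - min(ix) + 1L; iy <- iy - min(iy) + 1L; iz <- iz - min(iz) + 1L
  structure(list(voxel_size = h,
                 coords = pts,
                 material = mat,
                 index = cbind(ix = as.integer(ix), iy = as.integer(iy),
                               iz = as.integer(iz)),
                 dims = c(max(ix), max(iy), max(iz)),
                 band = band,
                 molecule_scale = mol_scale,
                 scene = scene),
            class = "dipole_grid")
}

#' @export
print.dipole_grid <- function(x, ...) {
  tb <- table(factor(x$material, levels = MATERIAL_IDS,
                     labels = names(MATERIAL_IDS)))
  cat(sprintf("<dipole_grid> %d voxels @ %.3g nm (%s)\n", nrow(x$coords),
              x$voxel_size,
              paste(sprintf("%s %d", names(tb)[tb > 0], tb[tb > 0]),
                    collapse = ", ")))
  invisible(x)
}

#' Build a free-standing dipole grid for a homogeneous sphere
#'
#' Utility used by solver validation: a sphere of the given radius and
#' material id voxelized on a cubic lattice (no shell, no substrate).
#'
#' @param radius Sphere radius in nm.
#' @param voxel_size Lattice constant in nm.
#' @param material_id Material id (default gold).
#' @param materials A `material_set`.
#' @param center Sphere center (nm), length-3.
#' @return A `dipole_grid`.
#' @export
sphere_grid <- function(radius, voxel_size, material_id = MATERIAL_IDS[["gold"]],
                        materials = material_set(), center = c(0, 0, 0)) {
  h <- voxel_size
  g <- (seq.int(floor((-radius + center[1]) / h - 1),
                ceiling((radius + center[1]) / h + 1)) + 0.5) * h
  gy <- (seq.int(floor((-radius + center[2]) / h - 1),
                 ceiling((radius + center[2]) / h + 1)) + 0.5) * h
  gz <- (seq.int(floor((-radius + center[3]) / h - 1),
                 ceiling((radius + center[3]) / h + 1)) + 0.5) * h
  pts <- as.matrix(expand.grid(x = g, y = gy, z = gz))
  keep <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
    (pts[, 3] - center[3])^2 <= radius^2
  if (!any(keep)) stop("voxelization produced an empty grid")
  pts <- pts[keep, , drop = FALSE]
  ix <- round(pts[, 1] / h - 0.5); iy <- round(pts[, 2] / h - 0.5)
  iz <- round(pts[, 3] / h - 0.5)
  ix <- ix - min(ix) + 1L; iy <- iy - min(iy) + 1L; iz <- iz - min(iz) + 1L
  scn <- list(materials = materials, substrate = FALSE, z_interface = -Inf)
  structure(list(voxel_size = h, coords = pts,
                 material = rep(as.integer(material_id), nrow(pts)),
                 index = cbind(ix = as.integer(ix), iy = as.integer(iy),
                               iz = as.integer(iz)),
                 dims = c(max(ix), max(iy), max(iz)),
                 band = NULL, molecule_scale = 1, scene = scn),
            class = "dipole_grid")
}

#' Export a dipole grid as a voxel table
#'
#' @param grid A `dipole_grid`.
#' @param path Optional file path; when given, a whitespace-delimited
#'   table `x y z material_id` is written there.
#' @return The voxel data frame, invisibly when written to a file.
#' @export
grid_table <- function(grid, path = NULL) {
  df <- data.frame(x = grid$coords[, 1], y = grid$coords[, 2],
                   z = grid$coords[, 3], material_id = grid$material)
  if (!is.null(path)) {
    utils::write.table(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
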