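test_that("capped-rod volume and equivalent radius follow the closed forms", {
  rod <- nanorod_geometry(20, 4)                 # 20 x 80 nm
  expect_equal(rod_volume(rod), 6000 * pi + (4000 / 3) * pi, tolerance = 1e-12)
  expect_equal(equivalent_radius(rod),
               (3 * rod_volume(rod) / (4 * pi))^(1 / 3), tolerance = 1e-12)
  expect_equal(equivalent_radius(rod), 17.65, tolerance = 1e-3)
  # degenerate sphere
  sph <- nanorod_geometry(20, 1)
  expect_equal(rod_volume(sph), pi * 20^3 / 6, tolerance = 1e-12)
  expect_equal(equivalent_radius(sph), 10, tolerance = 1e-12)
  # monotone in both width and AR
  vols <- outer(c(10, 20, 30), c(2, 3, 4),
                function(d, ar) mapply(function(di, ai)
                  equivalent_radius(nanorod_geometry(di, ai)), d, ar))
  expect_true(all(diff(vols) > 0))                # over width
  expect_true(all(apply(vols, 1, diff) > 0))      # over AR
  # equivalent radius bracketed by half-width and half-length for AR > 1
  expect_gt(equivalent_radius(rod), rod$d / 2)
  expect_lt(equivalent_radius(rod), rod$length / 2)
})

test_that("protein mass-to-size conversion matches the streptavidin anchor", {
  expect_equal(sphere_diameter_from_mass(52.8, 1.37), 5.0, tolerance = 0.02)
  # mass x8 at fixed density doubles the diameter
  expect_equal(sphere_diameter_from_mass(8 * 52.8) /
                 sphere_diameter_from_mass(52.8), 2, tolerance = 1e-12)
  # inverse operation: a 12 nm sphere weighs ~746 kDa
  expect_equal(mass_from_sphere_diameter(12, 1.37), 746, tolerance = 0.01)
  # round trip
  expect_equal(mass_from_sphere_diameter(sphere_diameter_from_mass(100)), 100,
               tolerance = 1e-10)
})

test_that("molecule is placed on the outward normal touching the shell", {
  rod <- nanorod_geometry(20, 4)
  scn <- build_scene(rod, molecule = molecule_spec(), site = binding_site())
  # tip site: center on the long axis, (1.5 + 2.5) nm beyond the gold tip
  expect_equal(scn$molecule_solid$center, c(40 + 1.5 + 2.5, 0, 0),
               tolerance = 1e-12, ignore_attr = TRUE)
  # site 12 on the horizontal plane: anchor at the rod midpoint, on the side
  s12 <- plasmocnr:::.site_geometry(rod, shell_spec(),
                                    binding_site("horizontal_side", 12))
  expect_equal(s12$point, c(0, 11.5, 0), tolerance = 1e-12)
  expect_equal(s12$normal, c(0, 1, 0), tolerance = 1e-12)
  # AR = 1 degenerates to a sphere: cap angles map onto the sphere surface
  sph <- nanorod_geometry(16, 1)
  s3 <- plasmocnr:::.site_geometry(sph, shell_spec(),
                                   binding_site("horizontal_side", 3))
  expect_equal(sqrt(sum(s3$point^2)), 8 + 1.5, tolerance = 1e-12)
  # invalid sites
  expect_error(binding_site("horizontal_side", 13), "midpoint")
  expect_error(binding_site("horizontal_side", -2), "vertical")
})

test_that("all molecule shapes enclose the reference sphere volume", {
  rod <- nanorod_geometry(20, 4)
  site <- binding_site()
  v_ref <- pi * 5^3 / 6
  for (shape in c("sphere", "hemisphere", "spherical_segment",
                  "concave_spherical_segment")) {
    spec <- molecule_spec(shape = shape)
    sol <- molecule_shape_solid(spec, rod, site)
    v_mc <- mc_volume(sol$contains, sol$center, sol$bound_radius * 1.1)
    expect_equal(v_mc, v_ref, tolerance = 0.015,
                 label = sprintf("MC volume of %s", shape))
  }
  # sphere membership at center / outside
  sol <- molecule_shape_solid(molecule_spec(), rod, site)
  expect_true(sol$contains(matrix(sol$center, 1)))
  expect_false(sol$contains(matrix(sol$center + c(2.6, 0, 0), 1)))
  # hemisphere height equals the equal-volume closed form (3V/2pi)^(1/3)
  hemi <- molecule_shape_solid(molecule_spec(shape = "hemisphere"), rod, site)
  expect_equal(hemi$dims$height, (3 * v_ref / (2 * pi))^(1 / 3),
               tolerance = 1e-10)
})

test_that("scene validation rejects impossible geometry", {
  rod <- nanorod_geometry(20, 4)
  expect_error(nanorod_geometry(-5, 2))
  expect_error(nanorod_geometry(10, 0.5))
  # a molecule that must overlap gold: zero shell, concave segment carved
  # into the rod would still be valid, but a sphere centred inside gold is
  # exercised through the overlap check with a negative-gap hack
  scn <- build_scene(rod, molecule = molecule_spec())
  expect_s3_class(scn, "scene")
  expect_equal(scn$z_interface, -(10 + 1.5))
})

test_that("voxelization converges to the analytic volume and keeps symmetry", {
  # 10 nm gold sphere at 0.5 nm voxels: volume within 3%
  g <- sphere_grid(5, 0.5)
  expect_equal(nrow(g$coords) * 0.5^3, pi * 10^3 / 6, tolerance = 0.03)
  # halving the voxel size strictly decreases the volume error
  errs <- vapply(c(2, 1, 0.5), function(h) {
    gg <- sphere_grid(5, h)
    abs(nrow(gg$coords) * h^3 - pi * 10^3 / 6) / (pi * 10^3 / 6)
  }, 0)
  expect_true(all(diff(errs) < 0))
  # rod at 0.25 nm voxels: gold volume within 1% of the closed form
  rod <- nanorod_geometry(10, 2)
  scn <- build_scene(rod, substrate = FALSE)
  grid <- voxelize(scn, 10 / 16 / 2.5)            # 0.25 nm
  vg <- sum(grid$material == 1) * grid$voxel_size^3
  expect_equal(vg, rod_volume(rod), tolerance = 0.01)
  # mirror symmetry about the rod axis with the molecule at the tip apex
  scn2 <- build_scene(nanorod_geometry(16, 2), molecule = molecule_spec())
  g2 <- suppressWarnings(voxelize(scn2, 1))
  expect_equal(sum(g2$coords[, 2] > 0), sum(g2$coords[, 2] < 0))
  expect_equal(sum(g2$coords[, 3] > 0), sum(g2$coords[, 3] < 0))
})

test_that("the shell layer is closed around the gold surface", {
  scn <- build_scene(nanorod_geometry(16, 2), substrate = FALSE)
  g <- suppressWarnings(voxelize(scn, 0.75))
  h <- g$voxel_size
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  ijk <- round(g$coords / h - 0.5)
  keys <- key(ijk)
  gold <- g$material == 1
  occupied <- keys                          # gold or shell (no molecule here)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  exposed <- FALSE
  gold_ijk <- ijk[gold, , drop = FALSE]
  for (s in seq_len(6)) {
    nb <- sweep(gold_ijk, 2, shifts[s, ], "+")
    exposed <- exposed | !(key(nb) %in% occupied)
  }
  expect_false(any(exposed))
})

test_that("voxel-size preconditions are enforced", {
  scn <- build_scene(nanorod_geometry(16, 2))
  expect_error(voxelize(scn, 3), "too coarse")
  expect_error(voxelize(scn, 0))
  expect_warning(voxelize(scn, 1.5), "d/16")
})
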