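tab <- read_dielectric_table()

test_that("voxel polarizability models behave in their limits", {
  eps_amb <- 1.33^2
  # no contrast -> zero polarizability
  expect_equal(dipole_polarizability(eps_amb, eps_amb, 1, 600), 0 + 0i)
  # static limit: both corrections vanish, bare Clausius-Mossotti remains
  eps <- -10 + 1i
  a_cm <- 3 / (4 * pi) * (eps / eps_amb - 1) / (eps / eps_amb + 2)
  for (model in c("lattice_dispersion", "clausius_mossotti_rr"))
    expect_equal(dipole_polarizability(eps, eps_amb, 1, 1e9, model), a_cm,
                 tolerance = 1e-10)
  # LDR and CM+RR differ by < 5% at moderate |m| k d
  eps_g <- gold_permittivity(tab, 800)
  h <- 2                                    # |m| k d ~ 0.06 here
  a1 <- dipole_polarizability(eps_g, eps_amb, h, 800, "lattice_dispersion")
  a2 <- dipole_polarizability(eps_g, eps_amb, h, 800, "clausius_mossotti_rr")
  expect_lt(Mod(a1 - a2) / Mod(a2), 0.05)
})

test_that("single- and two-dipole systems match dense closed-form solves", {
  mats <- material_set()
  w <- plane_wave(600)
  # one voxel: P = alpha E_inc, zero-iteration residual
  g1 <- sphere_grid(0.55, 1, center = c(0.5, 0.5, 0.5))
  expect_equal(nrow(g1$coords), 1L)
  s1 <- solve_dda(g1, w)
  a <- dipole_polarizability(gold_permittivity(tab, 600), 1.33^2, 1, 600)
  expect_equal(s1$P[1, ], a * s1$Einc[1, ], tolerance = 1e-10)
  # two voxels along the polarization axis vs direct 6x6 inversion
  pts <- rbind(c(0.5, 0.5, 0.5), c(1.5, 0.5, 0.5))
  g2 <- structure(list(voxel_size = 1, coords = pts,
                       material = c(1L, 1L),
                       index = cbind(ix = c(1L, 2L), iy = c(1L, 1L),
                                     iz = c(1L, 1L)),
                       dims = c(2L, 1L, 1L), band = NULL, molecule_scale = 1,
                       scene = list(materials = mats, substrate = FALSE,
                                    z_interface = -Inf)),
                  class = "dipole_grid")
  s2 <- solve_dda(g2, w, solver_settings(tol = 1e-10))
  phase <- exp(1i * w$k * as.vector(pts %*% w$propagation))
  Einc <- outer(phase, w$polarization)
  P_ref <- dense_dda_solve(pts, rep(a, 2), w$k, Einc)
  expect_equal(s2$P, P_ref, tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("solution respects mirror symmetry of a symmetric scene", {
  scn <- build_scene(nanorod_geometry(16, 2), molecule = molecule_spec(),
                     substrate = FALSE)
  g <- suppressWarnings(voxelize(scn, 2))
  w <- plane_wave(650)
  s <- solve_dda(g, w, solver_settings(tol = 1e-6))
  # pair voxels with their y-mirror images; x-component of P must match
  key <- paste(round(g$coords[, 1], 6), round(-g$coords[, 2], 6),
               round(g$coords[, 3], 6))
  self <- paste(round(g$coords[, 1], 6), round(g$coords[, 2], 6),
                round(g$coords[, 3], 6))
  mirror <- match(key, self)
  expect_false(any(is.na(mirror)))
  expect_equal(s$P[, 1], s$P[mirror, 1], tolerance = 1e-4)
  expect_equal(s$P[, 2], -s$P[mirror, 2], tolerance = 1e-4)
})

test_that("Mie oracle reproduces the Rayleigh limit and its identities", {
  # tiny real-index sphere: Rayleigh scattering to 0.1%
  eps <- 2.25            # n = 1.5 dielectric
  k <- 2 * pi * 1.33 / 600
  mie <- mie_oracle(1, eps, 1.33, 600)
  ray <- rayleigh_cross_sections(1, eps / 1.33^2, k)
  expect_equal(mie$C_scat, ray$C_scat * 1e-6, tolerance = 1e-3)
  expect_equal(mie$C_abs, 0, tolerance = 1e-12 * mie$C_ext)
  # extinction = absorption + scattering by construction of the series
  mg <- mie_oracle(20, gold_permittivity(tab, 600), 1.33, 600)
  expect_equal(mg$C_ext, mg$C_abs + mg$C_scat, tolerance = 1e-10)
  expect_gt(mg$C_abs, 0)
})

test_that("DDA matches Mie for a 10 nm gold sphere and converges under refinement", {
  wl <- 520
  mie <- mie_oracle(5, gold_permittivity(tab, wl), 1.33, wl)
  errs <- vapply(c(2, 1, 0.5), function(h) {
    g <- sphere_grid(5, h)
    w <- plane_wave(wl)
    s <- solve_dda(g, w)
    cs <- dda_cross_sections(g, w, s)
    abs(cs$C_ext - mie$C_ext) / mie$C_ext
  }, 0)
  expect_lt(errs[3], 0.05)            # 0.5 nm voxels within 5%
  expect_true(all(diff(errs) < 0))    # error decreases monotonically
})

test_that("absorption of a voxelized tiny sphere matches the Rayleigh closed form", {
  wl <- 600
  eps_g <- gold_permittivity(tab, wl)
  g <- sphere_grid(2, 0.25)
  w <- plane_wave(wl)
  s <- solve_dda(g, w)
  cs <- dda_cross_sections(g, w, s)
  ray <- rayleigh_cross_sections(2, eps_g / 1.33^2, w$k)
  expect_equal(cs$C_abs, ray$C_abs * 1e-6, tolerance = 0.02)
  # lossless dielectric: no absorption
  gd <- sphere_grid(2, 0.25, material_id = 3)   # molecule material, real index
  sd <- solve_dda(gd, w)
  cd <- dda_cross_sections(gd, w, sd)
  expect_lt(abs(cd$C_abs), 1e-3 * cd$C_ext)
})

test_that("small-sphere scaling: C_abs ~ V and C_scat ~ V^2", {
  wl <- 550
  radii <- c(2, 2.5, 3.2, 4)
  cs <- lapply(radii, function(r) {
    g <- sphere_grid(r, r / 8)
    w <- plane_wave(wl)
    s <- solve_dda(g, w)
    dda_cross_sections(g, w, s)
  })
  v <- radii^3
  sl_abs <- stats::coef(stats::lm(log(vapply(cs, `[[`, 0, "C_abs")) ~ log(v)))[2]
  sl_sca <- stats::coef(stats::lm(log(vapply(cs, `[[`, 0, "C_scat")) ~ log(v)))[2]
  expect_equal(unname(sl_abs), 1.0, tolerance = 0.1)
  expect_equal(unname(sl_sca), 2.0, tolerance = 0.05)
})

test_that("cross sections are invariant under rigid lattice translation", {
  wl <- 600
  g1 <- sphere_grid(3, 0.75)
  g2 <- sphere_grid(3, 0.75, center = c(3, -1.5, 2.25))  # lattice-aligned
  w <- plane_wave(wl)
  c1 <- dda_cross_sections(g1, w, solve_dda(g1, w))
  c2 <- dda_cross_sections(g2, w, solve_dda(g2, w))
  expect_equal(c1$C_ext, c2$C_ext, tolerance = 1e-6)
  expect_equal(c1$C_abs, c2$C_abs, tolerance = 1e-6)
})

test_that("substrate image correction is exact for one dipole and vanishes when index-matched", {
  mats <- material_set()
  # index-matched glass: solution equals the homogeneous case
  mats_eq <- material_set(n_glass = 1.33)
  scn <- build_scene(nanorod_geometry(16, 2), materials = mats_eq,
                     substrate = TRUE)
  g <- suppressWarnings(voxelize(scn, 2))
  w <- plane_wave(650)
  s_sub <- solve_dda(g, w, solver_settings(tol = 1e-7))
  s_hom <- solve_dda(g, w, solver_settings(tol = 1e-7,
                                           substrate_model = "none"))
  expect_equal(s_sub$P, s_hom$P, tolerance = 1e-5)
  # one dipole above the interface: operator matches the textbook image field
  pts <- matrix(c(0.5, 0.5, 2.5), 1)
  z0 <- 0
  grid1 <- structure(list(voxel_size = 1, coords = pts, material = 1L,
                          index = cbind(ix = 1L, iy = 1L, iz = 1L),
                          dims = c(1L, 1L, 1L), band = NULL,
                          molecule_scale = 1,
                          scene = list(materials = mats, substrate = TRUE,
                                       z_interface = z0)),
                     class = "dipole_grid")
  st <- solver_settings()
  alpha <- plasmocnr:::.grid_alpha(grid1, w, st)
  op <- plasmocnr:::.make_dda_operator(grid1, w, st)
  refl <- (1.52^2 - 1.33^2) / (1.52^2 + 1.33^2)
  u <- matrix(c(1 + 0.5i, 0.3 - 0.2i, -0.7 + 0.1i), 1)
  got <- op$apply(u, alpha)
  P <- u * alpha
  img <- dense_green(c(0, 0, 2 * 2.5), w$k, static = TRUE) %*%
    (diag(c(-1, -1, 1)) * refl) %*% as.vector(P)
  expect_equal(as.vector(got), as.vector(u - t(img)), tolerance = 1e-10)
})

test_that("enabling the substrate red-shifts the fitted rod resonance", {
  tmpl_off <- scene_template(substrate = FALSE)
  tmpl_on <- scene_template(substrate = TRUE)
  opts <- sweep_options(fine_points = 5, settings = solver_settings(tol = 3e-4))
  rod <- nanorod_geometry(16, 2)
  b_off <- plasmocnr:::.bare_state(rod, tmpl_off, opts)
  b_on <- plasmocnr:::.bare_state(rod, tmpl_on, opts)
  f_off <- fit_lorentzian(b_off$spectra, baseline = FALSE)
  f_on <- fit_lorentzian(b_on$spectra, baseline = FALSE)
  expect_gt(f_on$lambda_res, f_off$lambda_res)
})

test_that("solver reports failure states honestly", {
  g <- sphere_grid(5, 1)
  w <- plane_wave(520)
  expect_error(solve_dda(g, w, solver_settings(tol = 1e-8, max_iter = 3)),
               "did not converge")
  expect_error(plane_wave(600, polarization = c(0, 0, 1)), "orthogonal")
})
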