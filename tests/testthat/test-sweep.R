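sw_tmpl <- coarse_template()
sw_opts <- coarse_opts()

test_that("a small size sweep produces normalized, internally consistent maps", {
  grid <- size_grid(widths = c(10, 20), aspect_ratios = c(2, 3))
  map <- run_size_sweep(grid, sw_tmpl, sw_opts)
  df <- map$cells
  expect_equal(nrow(df), 4)
  expect_false(any(df$failed))
  for (m in c("cnr_spectral_norm", "cnr_fixed_norm", "cnr_photothermal_norm")) {
    expect_equal(max(df[[m]]), 1)
    expect_true(all(df[[m]] > 0 & df[[m]] <= 1))
    expect_equal(sum(df[[m]] == 1), 1)     # exactly one cell attains 1
  }
  # the 95% region is contained in the 90% region
  s <- map_summary(map, "spectral")
  expect_true(all(!s$above_95 | s$above_90))
  # sensing wavelengths sit on the long-wavelength side of the bare peak
  # (each modality relative to the resonance of its own spectrum)
  expect_true(all(df$lambda_sens_fixed > df$lambda_res))
  expect_true(all(df$lambda_sens_pt > df$lambda_res_abs))
  # binding red-shifts the resonance everywhere
  expect_true(all(df$delta_lambda > 0))
})

test_that("constant-dT mode rescales each cell by its admissible intensity", {
  grid <- size_grid(widths = c(10, 20), aspect_ratios = c(2, 3))
  tp <- thermal_params(dT_target = 10)
  map_i <- run_size_sweep(grid, sw_tmpl, sw_opts, "constant_intensity")
  map_t <- run_size_sweep(grid, sw_tmpl, sw_opts, "constant_dT", thermal = tp)
  # the spectral sensing wavelength equals the fitted bare resonance and
  # every rescaled CNR stays positive
  expect_equal(map_t$cells$lambda_sens_spectral, map_i$cells$lambda_res,
               tolerance = 1e-9)
  expect_true(all(map_t$cells$cnr_spectral > 0))
  # direct recomputation for one cell
  ci <- map_i$cells[2, ]; ct <- map_t$cells[2, ]
  rod <- nanorod_geometry(ci$width, ci$ar)
  bare <- plasmocnr:::.cached_bare_state(rod, sw_tmpl, sw_opts)
  cs <- plasmocnr:::.cell_sensing(bare, sw_tmpl, sw_opts)
  i_sp <- intensity_for_dT(
    predict_lorentzian(cs$responses$abs$fit_without, ci$lambda_sens_spectral),
    equivalent_radius(rod), beta_coefficient(tp, ci$ar), tp$kappa_water,
    tp$dT_target)
  expect_equal(ct$cnr_spectral, ci$cnr_spectral * sqrt(i_sp),
               tolerance = 1e-9)
})

test_that("shape scan: a surface-conforming molecule outperforms the sphere", {
  # molecule shape is sub-voxel at the d/8 screening scale, so this scan
  # runs at 1 nm voxels on a smaller rod where the 5 nm molecule spans
  # dozens of voxels
  fine_opts <- sweep_options(voxel_size = 1, fine_points = 5,
                             settings = solver_settings(tol = 3e-4))
  res <- shape_scan(sw_tmpl, shapes = c("sphere", "concave_spherical_segment"),
                    opts = fine_opts, rod = nanorod_geometry(12, 2))
  df <- res$cnr
  expect_equal(df$cnr_spectral_norm[df$shape == "sphere"], 1)
  for (m in c("cnr_spectral_norm", "cnr_fixed_norm", "cnr_photothermal_norm"))
    expect_gt(df[[m]][df$shape == "concave_spherical_segment"], 1)
})

test_that("diameter scan is normalized at 5 nm and strictly increasing", {
  res <- diameter_scan(sw_tmpl, diameters = c(3, 5, 8), opts = sw_opts,
                       rod = nanorod_geometry(20, 2))
  df <- res$cnr
  expect_equal(df$cnr_spectral_norm[df$diameter == 5], 1)
  expect_true(all(diff(df$cnr_spectral) > 0))
  expect_true(all(diff(df$cnr_fixed) > 0))
  expect_gt(res$fits$exponents[["cnr_spectral"]], 1)
})

test_that("cell results are deterministic across recomputation", {
  grid <- size_grid(widths = 20, aspect_ratios = 2)
  map1 <- run_size_sweep(grid, sw_tmpl, sw_opts)   # cached from previous test
  sweep_cache_clear()
  map2 <- run_size_sweep(grid, sw_tmpl, sw_opts)
  expect_equal(map1$cells$cnr_spectral, map2$cells$cnr_spectral,
               tolerance = 1e-12)
  expect_equal(map1$cells$lambda_res, map2$cells$lambda_res,
               tolerance = 1e-12)
})
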