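#' Size grid for nanorod optimization
#'
#' @param widths Rod widths in nm (default 10-40).
#' @param aspect_ratios Aspect ratios (default 2-5).
#' @return A `size_grid` object.
#' @export
size_grid <- function(widths = seq(10, 40, by = 10),
                      aspect_ratios = seq(2, 5, by = 1)) {
  stopifnot(all(widths > 0), all(aspect_ratios >= 1))
  structure(list(widths = sort(widths), aspect_ratios = sort(aspect_ratios)),
            class = "size_grid")
}

#' Scene template: everything but the rod size
#'
#' @param shell A `shell_spec`.
#' @param molecule A `molecule_spec`.
#' @param site A `binding_site`.
#' @param materials A `material_set`.
#' @param substrate Logical; glass half-space on/off.
#' @param gap Water gap between shell and glass, nm.
#' @return A `scene_template` list.
#' @export
scene_template <- function(shell = shell_spec(), molecule = molecule_spec(),
                           site = binding_site(), materials = material_set(),
                           substrate = TRUE, gap = 0) {
  structure(list(shell = shell, molecule = molecule, site = site,
                 materials = materials, substrate = substrate, gap = gap),
            class = "scene_template")
}

#' Sweep/scan solver options
#'
#' Controls the spectral sampling and solver effort of sweep cells.
#' The fine wavelength grid spans `fine_span` estimated half-widths
#' around the coarse-scan peak with `fine_points` points (the package's
#' spectral sampling convention uses 10-21 points near the peak;
#' screening runs may go as low as 6).
#'
#' @param voxel_size Either a number (nm) or a function of the rod
#'   width returning the voxel size; default `d / 8` (the coarsest
#'   admissible discretization, appropriate for screening; production
#'   runs use 0.25-0.5 nm).
#' @param settings A `solver_settings`.
#' @param coarse_points Points of the peak-locating scan.
#' @param fine_points Points of the fitting grid.
#' @param fine_span Half-width of the fitting grid in units of the
#'   estimated resonance width.
#' @param eta Peak-fit noise factor for spectral CNR.
#' @param fit_baseline Logical; fit an additive baseline in the
#'   Lorentzian fits of solver spectra. Cross-section spectra are
#'   background-free, so the default pins it to zero, which keeps the
#'   fit well-conditioned on short fitting grids.
#' @param config A `detection_config`.
#' @param pt_params A `photothermal_params`.
#' @return A `sweep_options` list.
#' @export
sweep_options <- function(voxel_size = function(d) d / 8,
                          settings = solver_settings(tol = 1e-4),
                          coarse_points = 5, fine_points = 9,
                          fine_span = 1.2, eta = 0.21,
                          config = detection_config(),
                          pt_params = photothermal_params(),
                          fit_baseline = FALSE) {
  stopifnot(coarse_points >= 5, fine_points >= 5, fine_span > 0)
  structure(list(voxel_size = voxel_size, settings = settings,
                 coarse_points = coarse_points, fine_points = fine_points,
                 fine_span = fine_span, eta = eta, config = config,
                 pt_params = pt_params, fit_baseline = fit_baseline),
            class = "sweep_options")
}

.voxel_for <- function(opts, d) {
  v <- if (is.function(opts$voxel_size)) opts$voxel_size(d) else opts$voxel_size
  min(v, d / 8)
}

# Empirical first guess of the longitudinal resonance of a gold rod in
# water (nm); only seeds the adaptive coarse scan, which recenters
# itself if the peak falls at a window edge.
.resonance_guess <- function(d, ar) {
  list(center = 420 + 120 * ar + 1.5 * (d - 20),
       halfwidth = 100 + 25 * ar)
}

# Adaptive coarse scan: solve a short spectrum, recenter while the
# maximum sits on a window edge, then fit a Lorentzian for the peak
# position and width estimate.
.locate_resonance <- function(grid, opts, guess) {
  lo_band <- min(grid$scene$materials$gold$wavelengths) + 1
  hi_band <- max(grid$scene$materials$gold$wavelengths) - 1
  center <- guess$center; hw <- guess$halfwidth
  for (attempt in 1:6) {
    wl <- seq(max(lo_band, center - hw), min(hi_band, center + hw),
              length.out = opts$coarse_points)
    st <- opts$settings
    st$tol <- max(st$tol, 1e-3)       # screening accuracy for peak location
    sp <- spectrum_scan(grid, wl, st)
    i <- which.max(sp$C_scat_um2)
    if (i == 1 && wl[1] > lo_band + 1) { center <- center - 1.4 * hw; next }
    if (i == length(wl) && wl[length(wl)] < hi_band - 1) {
      center <- center + 1.4 * hw; next
    }
    fit <- tryCatch(fit_lorentzian(sp, baseline = FALSE),
                    error = function(e) NULL)
    if (is.null(fit))
      return(list(lambda = wl[i], gamma = 0.12 * wl[i]))
    return(list(lambda = fit$lambda_res,
                gamma = min(max(fit$gamma, 0.03 * fit$lambda_res),
                            0.3 * fit$lambda_res)))
  }
  stop("could not bracket the plasmon resonance within the gold table band")
}

# integer lattice keys for matching voxels across grids on the shared
# global lattice
.lattice_keys <- function(grid) {
  ijk <- round(grid$coords / grid$voxel_size - 0.5)
  paste(ijk[, 1], ijk[, 2], ijk[, 3], sep = ",")
}

# Build a warm-start y vector for a with-molecule grid from the bare
# solution at the same wavelength: shared voxels copy the bare field,
# new (molecule) voxels start at the incident field.
.warm_from_bare <- function(grid_mol, grid_bare, sol_bare, wave, settings) {
  n <- nrow(grid_mol$coords)
  keys_m <- .lattice_keys(grid_mol)
  keys_b <- .lattice_keys(grid_bare)
  pos <- match(keys_m, keys_b)
  alpha <- .grid_alpha(grid_mol, wave, settings)
  sa <- sqrt(alpha)
  phase <- exp(1i * wave$k * as.vector(grid_mol$coords %*% wave$propagation))
  E0 <- outer(phase, wave$polarization)
  E <- E0
  shared <- !is.na(pos)
  E[shared, ] <- sol_bare$E[pos[shared], , drop = FALSE]
  list(y = as.vector(E * sa))
}

# Compute the bare-sensor state of a cell: locate the resonance (via
# the adaptive coarse scan, or a predicted window from neighboring
# cells), record the fine-grid spectra (scattering and absorption) with
# per-wavelength solutions kept for warm starts. A predicted window is
# verified against the fitted peak and re-centered once if it misses.
.bare_state <- function(rod, template, opts, window = NULL) {
  scn <- build_scene(rod, shell = template$shell, molecule = NULL,
                     site = template$site, materials = template$materials,
                     substrate = template$substrate, gap = template$gap)
  h <- .voxel_for(opts, rod$d)
  grid <- suppressWarnings(voxelize(scn, h))
  loc <- if (is.null(window))
    .locate_resonance(grid, opts, .resonance_guess(rod$d, rod$ar))
  else window
  lo_band <- min(template$materials$gold$wavelengths) + 1
  hi_band <- max(template$materials$gold$wavelengths) - 1
  for (pass in 1:3) {
    wl <- seq(max(lo_band, loc$lambda - opts$fine_span * loc$gamma),
              min(hi_band, loc$lambda + opts$fine_span * loc$gamma),
              length.out = opts$fine_points)
    sp <- spectrum_scan(grid, wl, opts$settings, keep_solutions = TRUE)
    fit <- tryCatch(fit_lorentzian(sp, baseline = FALSE),
                    error = function(e) NULL)
    inner_lo <- wl[1] + 0.15 * (wl[length(wl)] - wl[1])
    inner_hi <- wl[length(wl)] - 0.15 * (wl[length(wl)] - wl[1])
    ok <- !is.null(fit) && fit$lambda_res >= inner_lo &&
      fit$lambda_res <= inner_hi
    if (ok || pass == 3) break
    if (is.null(fit)) {   # window missed entirely: full coarse relocation
      ctr <- wl[which.max(sp$C_scat_um2)]
      loc <- .locate_resonance(grid, opts,
                               list(center = ctr,
                                    halfwidth = 3 * opts$fine_span * loc$gamma))
    } else {
      loc <- list(lambda = fit$lambda_res, gamma = loc$gamma)
    }
  }
  sols <- attr(sp, "solutions")
  list(scene = scn, grid = grid, wavelengths = wl, spectra = sp,
       solutions = sols, peak = loc, voxel = h)
}

# Two-state binding responses (scattering and absorption) of a molecule
# variant against a precomputed bare state.
.mol_response <- function(bare, molecule, site, template, opts) {
  scn <- build_scene(bare$scene$rod, shell = template$shell,
                     molecule = molecule, site = site,
                     materials = template$materials,
                     substrate = template$substrate, gap = template$gap)
  grid <- suppressWarnings(voxelize(scn, bare$voxel))
  n_amb <- template$materials$n_water
  rows <- vector("list", length(bare$wavelengths))
  for (i in seq_along(bare$wavelengths)) {
    wl <- bare$wavelengths[i]
    wave <- plane_wave(wl, ambient_index = n_amb)
    ws <- .warm_from_bare(grid, bare$grid, bare$solutions[[i]], wave,
                          opts$settings)
    sol <- solve_dda(grid, wave, opts$settings, warm_start = ws)
    cs <- dda_cross_sections(grid, wave, sol)
    rows[[i]] <- data.frame(wavelength_nm = wl, C_ext_um2 = cs$C_ext,
                            C_abs_um2 = cs$C_abs, C_scat_um2 = cs$C_scat,
                            iterations = sol$iterations)
  }
  sp <- do.call(rbind, rows)
  scat <- binding_response(
    spectrum(bare$spectra$wavelength_nm, bare$spectra$C_scat_um2, "C_scat"),
    spectrum(sp$wavelength_nm, sp$C_scat_um2, "C_scat"),
    baseline = isTRUE(opts$fit_baseline))
  abs_ <- binding_response(
    spectrum(bare$spectra$wavelength_nm, bare$spectra$C_abs_um2, "C_abs"),
    spectrum(sp$wavelength_nm, sp$C_abs_um2, "C_abs"),
    baseline = isTRUE(opts$fit_baseline))
  list(scat = scat, abs = abs_, spectra_with = sp)
}

# All three modality results for one sensor configuration.
.cell_sensing <- function(bare, template, opts, molecule = NULL, site = NULL) {
  molecule <- if (is.null(molecule)) template$molecule else molecule
  site <- if (is.null(site)) template$site else site
  resp <- .mol_response(bare, molecule, site, template, opts)
  list(
    responses = resp,
    spectral = cnr_spectral(resp$scat, opts$config, opts$eta),
    fixed = cnr_fixed_wavelength(resp$scat, opts$config),
    photothermal = cnr_photothermal(resp$abs, opts$pt_params, opts$config))
}

# cache environment for bare states / cell results within a session
.sweep_cache <- new.env(parent = emptyenv())

#' Clear the sweep computation cache
#' @return Invisibly, the number of entries removed.
#' @export
sweep_cache_clear <- function() {
  n <- length(ls(.sweep_cache))
  rm(list = ls(.sweep_cache), envir = .sweep_cache)
  invisible(n)
}

.template_key <- function(rod, template, opts) {
  mt <- template$materials
  paste(format(c(rod$d, rod$ar, template$shell$thickness,
                 template$shell$refractive_index, mt$n_water, mt$n_glass,
                 mt$n_shell, template$gap, as.numeric(template$substrate),
                 .voxel_for(opts, rod$d), opts$settings$tol,
                 opts$coarse_points, opts$fine_points, opts$fine_span),
               digits = 10), collapse = "|")
}

.cached_bare_state <- function(rod, template, opts, window = NULL) {
  key <- .template_key(rod, template, opts)
  if (!is.null(.sweep_cache[[key]])) return(.sweep_cache[[key]])
  bs <- .bare_state(rod, template, opts, window = window)
  .sweep_cache[[key]] <- bs
  bs
}

#' Contrast-to-noise maps over a nanorod size grid
#'
#' For every (width, aspect ratio) cell: computes the bare and
#' with-molecule cross-section spectra, fits the two-state binding
#' response, and evaluates the three sensing modalities at their
#' respective sensing wavelengths. In `"constant_dT"` mode the
#' illumination (or heating-beam) intensity of each cell is rescaled to
#' produce the same steady-state surface temperature rise before the
#' CNRs are formed; scattering-modality CNRs scale with the square root
#' of the admissible intensity and the photothermal CNR linearly. Maps
#' are normalized per modality to their maximum.
#'
#' @param grid A `size_grid`.
#' @param template A `scene_template`.
#' @param opts A `sweep_options`.
#' @param mode `"constant_intensity"` or `"constant_dT"`.
#' @param thermal A `thermal_params` (used in `"constant_dT"` mode).
#' @return A `cnr_map`: data frame of cells plus normalization metadata.
#' @export
run_size_sweep <- function(grid = size_grid(), template = scene_template(),
                           opts = sweep_options(),
                           mode = c("constant_intensity", "constant_dT"),
                           thermal = thermal_params()) {
  mode <- match.arg(mode)
  cells <- expand.grid(width = grid$widths, ar = grid$aspect_ratios)
  rows <- vector("list", nrow(cells))
  done <- data.frame(width = numeric(), ar = numeric(),
                     lambda_res = numeric(), gamma = numeric())
  # once enough cells are fitted, predict the next cell's resonance
  # window by regression on (width, AR) instead of coarse-scanning
  predict_window <- function(d, ar) {
    if (nrow(done) < 4 || length(unique(done$width)) < 2 ||
        length(unique(done$ar)) < 2) return(NULL)
    fml <- if (length(unique(done$ar)) >= 3)
      lambda_res ~ width + ar + I(ar^2) else lambda_res ~ width + ar
    fl <- tryCatch(stats::lm(fml, data = done), error = function(e) NULL)
    fg <- tryCatch(stats::lm(gamma ~ width + ar, data = done),
                   error = function(e) NULL)
    if (is.null(fl) || is.null(fg)) return(NULL)
    nd <- data.frame(width = d, ar = ar)
    list(lambda = unname(stats::predict(fl, nd)),
         gamma = max(unname(stats::predict(fg, nd)), 20))
  }
  for (i in seq_len(nrow(cells))) {
    d <- cells$width[i]; ar <- cells$ar[i]
    rod <- nanorod_geometry(d, ar)
    row <- tryCatch({
      bare <- .cached_bare_state(rod, template, opts,
                                 window = predict_window(d, ar))
      cs <- .cell_sensing(bare, template, opts)
      cnr_sp <- cs$spectral$cnr
      cnr_fx <- cs$fixed$cnr
      cnr_pt <- cs$photothermal$cnr
      scale_sp <- scale_fx <- scale_pt <- 1
      if (mode == "constant_dT") {
        beta <- beta_coefficient(thermal, ar)
        req <- equivalent_radius(rod)
        i_at <- function(lam) {
          cab <- predict_lorentzian(cs$responses$abs$fit_without, lam)
          intensity_for_dT(cab, req, beta, thermal$kappa_water,
                           thermal$dT_target)
        }
        scale_sp <- sqrt(i_at(cs$spectral$sensing_wavelength))
        scale_fx <- sqrt(i_at(cs$fixed$sensing_wavelength))
        scale_pt <- i_at(cs$photothermal$sensing_wavelength)
      }
      data.frame(width = d, ar = ar,
                 lambda_res = cs$responses$scat$fit_without$lambda_res,
                 lambda_res_abs = cs$responses$abs$fit_without$lambda_res,
                 gamma = cs$responses$scat$fit_without$gamma,
                 delta_lambda = cs$responses$scat$delta_lambda,
                 lambda_sens_spectral = cs$spectral$sensing_wavelength,
                 lambda_sens_fixed = cs$fixed$sensing_wavelength,
                 lambda_sens_pt = cs$photothermal$sensing_wavelength,
                 cnr_spectral = cnr_sp * scale_sp,
                 cnr_fixed = cnr_fx * scale_fx,
                 cnr_photothermal = cnr_pt * scale_pt,
                 fom_spectral = cs$spectral$fom,
                 fom_fixed = cs$fixed$fom,
                 fom_abs = cs$photothermal$fom,
                 failed = FALSE)
    }, error = function(e) {
      warning(sprintf("cell %g x %g failed: %s", d, d * ar,
                      conditionMessage(e)))
      data.frame(width = d, ar = ar, lambda_res = NA, lambda_res_abs = NA,
                 gamma = NA,
                 delta_lambda = NA, lambda_sens_spectral = NA,
                 lambda_sens_fixed = NA, lambda_sens_pt = NA,
                 cnr_spectral = NA, cnr_fixed = NA, cnr_photothermal = NA,
                 fom_spectral = NA, fom_fixed = NA, fom_abs = NA,
                 failed = TRUE)
    })
    if (!row$failed)
      done <- rbind(done, row[, c("width", "ar", "lambda_res", "gamma")])
    rows[[i]] <- row
  }
  df <- do.call(rbind, rows)
  for (m in c("cnr_spectral", "cnr_fixed", "cnr_photothermal")) {
    mx <- max(df[[m]], na.rm = TRUE)
    df[[paste0(m, "_norm")]] <- df[[m]] / mx
  }
  structure(list(cells = df, grid = grid, mode = mode,
                 template = template, opts = opts),
            class = "cnr_map")
}

#' Normalized map values, argmax and contour masks of one modality
#'
#' @param map A `cnr_map`.
#' @param modality `"spectral"`, `"fixed"` or `"photothermal"` (or
#'   `"fom_spectral"`, `"fom_fixed"`, `"fom_abs"` for the
#'   noise-independent maps).
#' @return A list with the normalized cell data frame (`norm` column),
#'   the argmax row, and logical `above_90` / `above_95` masks.
#' @export
map_summary <- function(map, modality = c("spectral", "fixed", "photothermal",
                                          "fom_spectral", "fom_fixed",
                                          "fom_abs")) {
  modality <- match.arg(modality)
  col <- switch(modality, spectral = "cnr_spectral", fixed = "cnr_fixed",
                photothermal = "cnr_photothermal", modality)
  df <- map$cells
  v <- df[[col]]
  norm <- v / max(v, na.rm = TRUE)
  i <- which.max(norm)
  list(cells = transform(df, norm = norm),
       argmax = df[i, c("width", "ar")],
       above_90 = !is.na(norm) & norm >= 0.9,
       above_95 = !is.na(norm) & norm >= 0.95)
}

#' @export
print.cnr_map <- function(x, ...) {
  am <- map_summary(x, "spectral")$argmax
  cat(sprintf("<cnr_map> %d cells (%s); spectral argmax at %g x %g nm\n",
              nrow(x$cells), x$mode, am$width, am$width * am$ar))
  invisible(x)
}

#' Noise-independent FOM maps over the size grid
#'
#' Computes (or reuses from the session cache) the same two-state
#' responses as [run_size_sweep()] and reports the three
#' noise-independent figures of merit per cell.
#'
#' @inheritParams run_size_sweep
#' @return A `cnr_map` whose interesting columns are `fom_spectral`,
#'   `fom_fixed` (scattering intensity) and `fom_abs` (absorption
#'   intensity).
#' @export
fom_sweep <- function(grid = size_grid(), template = scene_template(),
                      opts = sweep_options()) {
  run_size_sweep(grid, template, opts, mode = "constant_intensity")
}

.scan_result <- function(variable, values, rows, fits = NULL, meta = NULL) {
  structure(list(variable = variable, values = values,
                 cnr = rows, fits = fits, meta = meta),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %s: %d points\n", x$variable, length(x$values)))
  print(x$cnr)
  invisible(x)
}

# run the three modalities for a molecule variant and return a one-row
# data frame of raw CNRs
.variant_cnrs <- function(bare, template, opts, molecule = NULL, site = NULL) {
  cs <- .cell_sensing(bare, template, opts, molecule = molecule, site = site)
  data.frame(cnr_spectral = cs$spectral$cnr,
             cnr_fixed = cs$fixed$cnr,
             cnr_photothermal = cs$photothermal$cnr)
}

.reference_rod <- function() nanorod_geometry(20, 4)

#' Binding-position scan along the nanorod surface
#'
#' CNR of the three modalities versus binding-site index (0 = tip apex
#' through 6 = cap junction in 15 degree steps, then 5 nm steps to 12 =
#' rod midpoint), normalized to the tip site, for the 20 x 80 nm
#' reference rod. Negative indices (vertical plane) probe the
#' substrate-facing ridge.
#'
#' @param template A `scene_template`.
#' @param plane `"horizontal_side"` or `"vertical_ridge"`.
#' @param indices Site indices to evaluate (must include 0).
#' @param opts A `sweep_options`.
#' @param rod The rod geometry (default 20 x 80 nm).
#' @return A `scan_result` with per-site normalized CNRs.
#' @export
position_scan <- function(template = scene_template(),
                          plane = c("horizontal_side", "vertical_ridge"),
                          indices = 0:12, opts = sweep_options(),
                          rod = .reference_rod()) {
  plane <- match.arg(plane)
  stopifnot(0 %in% indices)
  bare <- .cached_bare_state(rod, template, opts)
  rows <- lapply(indices, function(i)
    .variant_cnrs(bare, template, opts,
                  site = binding_site(plane, as.integer(i))))
  df <- do.call(rbind, rows)
  ref <- which(indices == 0)[1]
  for (m in names(df)) df[[paste0(m, "_norm")]] <- df[[m]] / df[[m]][ref]
  df <- cbind(index = indices, df)
  .scan_result("binding_position", indices, df,
               meta = list(plane = plane, rod = rod))
}

#' Molecule-size scan with power-law summary
#'
#' CNR versus equal-volume sphere diameter of the analyte, normalized at
#' 5 nm, with the least-squares log-log slope (power-law exponent) per
#' modality.
#'
#' @param template A `scene_template`.
#' @param diameters Molecule diameters in nm (should include 5).
#' @param opts A `sweep_options`.
#' @param rod The rod geometry.
#' @return A `scan_result`; `fits` holds the fitted exponents.
#' @export
diameter_scan <- function(template = scene_template(),
                          diameters = c(2, 3.5, 5, 8, 12),
                          opts = sweep_options(), rod = .reference_rod()) {
  stopifnot(all(diameters > 0))
  bare <- .cached_bare_state(rod, template, opts)
  rows <- lapply(diameters, function(dm)
    .variant_cnrs(bare, template, opts,
                  molecule = molecule_spec(
                    shape = template$molecule$shape,
                    equivalent_diameter = dm,
                    refractive_index = template$molecule$refractive_index)))
  df <- do.call(rbind, rows)
  ref <- which.min(abs(diameters - 5))
  for (m in names(df)) df[[paste0(m, "_norm")]] <- df[[m]] / df[[m]][ref]
  df <- cbind(diameter = diameters, df)
  expo <- vapply(c("cnr_spectral", "cnr_fixed", "cnr_photothermal"),
                 function(m) {
                   f <- stats::lm(log(df[[m]]) ~ log(diameters))
                   unname(stats::coef(f)[2])
                 }, 0)
  .scan_result("molecule_diameter", diameters, df,
               fits = list(exponents = expo), meta = list(rod = rod))
}

#' Refractive-index-contrast scan with linear summary
#'
#' CNR versus molecule refractive-index contrast against water,
#' normalized at contrast 0.24 (n = 1.57 in water 1.33), with an
#' ordinary least-squares linear fit per modality.
#'
#' @param template A `scene_template`.
#' @param contrasts Index contrasts `n_molecule - n_water` (> 0).
#' @param opts A `sweep_options`.
#' @param rod The rod geometry.
#' @return A `scan_result`; `fits` holds slopes and R-squared values.
#' @export
ri_scan <- function(template = scene_template(),
                    contrasts = c(0.06, 0.12, 0.18, 0.24, 0.3),
                    opts = sweep_options(), rod = .reference_rod()) {
  stopifnot(all(contrasts > 0))
  nw <- template$materials$n_water
  bare <- .cached_bare_state(rod, template, opts)
  rows <- lapply(contrasts, function(ct)
    .variant_cnrs(bare, template, opts,
                  molecule = molecule_spec(
                    shape = template$molecule$shape,
                    equivalent_diameter = template$molecule$equivalent_diameter,
                    refractive_index = nw + ct)))
  df <- do.call(rbind, rows)
  ref <- which.min(abs(contrasts - 0.24))
  for (m in names(df)) df[[paste0(m, "_norm")]] <- df[[m]] / df[[m]][ref]
  df <- cbind(contrast = contrasts, df)
  fits <- lapply(c("cnr_spectral", "cnr_fixed", "cnr_photothermal"),
                 function(m) {
                   f <- stats::lm(df[[m]] ~ contrasts)
                   list(slope = unname(stats::coef(f)[2]),
                        r_squared = summary(f)$r.squared)
                 })
  names(fits) <- c("cnr_spectral", "cnr_fixed", "cnr_photothermal")
  .scan_result("ri_contrast", contrasts, df, fits = fits,
               meta = list(rod = rod))
}

#' Molecule-shape scan at constant volume
#'
#' CNR for each molecule shape of the equal-volume menu (sphere,
#' hemisphere, spherical segment, concave spherical segment conforming
#' to the shell), normalized to the sphere.
#'
#' @param template A `scene_template`.
#' @param shapes Shapes to evaluate.
#' @param opts A `sweep_options`.
#' @param rod The rod geometry.
#' @return A `scan_result`.
#' @export
shape_scan <- function(template = scene_template(),
                       shapes = c("sphere", "hemisphere", "spherical_segment",
                                  "concave_spherical_segment"),
                       opts = sweep_options(), rod = .reference_rod()) {
  shapes <- match.arg(shapes, several.ok = TRUE)
  stopifnot("sphere" %in% shapes)
  bare <- .cached_bare_state(rod, template, opts)
  rows <- lapply(shapes, function(sh)
    .variant_cnrs(bare, template, opts,
                  molecule = molecule_spec(
                    shape = sh,
                    equivalent_diameter = template$molecule$equivalent_diameter,
                    refractive_index = template$molecule$refractive_index)))
  df <- do.call(rbind, rows)
  ref <- which(shapes == "sphere")[1]
  for (m in names(df)) df[[paste0(m, "_norm")]] <- df[[m]] / df[[m]][ref]
  df <- cbind(shape = shapes, df)
  .scan_result("molecule_shape", shapes, df, meta = list(rod = rod))
}

#' Shell-thickness and shell-index scans
#'
#' CNR versus functionalization-shell thickness (normalized at 1.5 nm)
#' with exponential-decay and linear summaries, and versus shell
#' refractive index (normalized at 1.45).
#'
#' @param template A `scene_template`.
#' @param thicknesses Shell thicknesses in nm (>= 0; should include 1.5).
#' @param shell_indices Shell refractive indices (should include 1.45).
#' @param opts A `sweep_options`.
#' @param rod The rod geometry.
#' @return A list of two `scan_result`s: `thickness` (with `fits` per
#'   modality holding the exponential decay constant and the residual
#'   sums of squares of the exponential and linear fits on the
#'   normalized values) and `index`.
#' @export
shell_scan <- function(template = scene_template(),
                       thicknesses = c(0.5, 1.5, 3, 4.5),
                       shell_indices = c(1.40, 1.45, 1.50),
                       opts = sweep_options(), rod = .reference_rod()) {
  stopifnot(all(thicknesses >= 0))
  run_at <- function(shell) {
    tmpl <- template
    tmpl$shell <- shell
    bare <- .cached_bare_state(rod, tmpl, opts)
    .variant_cnrs(bare, tmpl, opts)
  }
  # thickness scan
  rows <- lapply(thicknesses, function(th)
    run_at(shell_spec(th, template$shell$refractive_index)))
  df <- do.call(rbind, rows)
  ref <- which.min(abs(thicknesses - 1.5))
  for (m in names(df)) df[[paste0(m, "_norm")]] <- df[[m]] / df[[m]][ref]
  dft <- cbind(thickness = thicknesses, df)
  fits <- lapply(c("cnr_spectral", "cnr_fixed", "cnr_photothermal"),
                 function(m) {
                   y <- dft[[paste0(m, "_norm")]]
                   fe <- stats::lm(log(y) ~ thicknesses)
                   rss_exp <- sum((y - exp(stats::fitted(fe)))^2)
                   fl <- stats::lm(y ~ thicknesses)
                   list(decay_per_nm = -unname(stats::coef(fe)[2]),
                        rss_exponential = rss_exp,
                        rss_linear = sum(stats::resid(fl)^2))
                 })
  names(fits) <- c("cnr_spectral", "cnr_fixed", "cnr_photothermal")
  thick <- .scan_result("shell_thickness", thicknesses, dft, fits = fits,
                        meta = list(rod = rod))
  # shell index scan
  rows <- lapply(shell_indices, function(ns)
    run_at(shell_spec(template$shell$thickness, ns)))
  df <- do.call(rbind, rows)
  ref <- which.min(abs(shell_indices - 1.45))
  for (m in names(df)) df[[paste0(m, "_norm")]] <- df[[m]] / df[[m]][ref]
  dfn <- cbind(shell_index = shell_indices, df)
  index <- .scan_result("shell_index", shell_indices, dfn,
                        meta = list(rod = rod))
  list(thickness = thick, index = index)
}
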