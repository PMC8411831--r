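# Configuration schema: known keys per block. Unknown keys are
# rejected so typos cannot silently fall back to defaults.
.CONFIG_SCHEMA <- list(
  schema_version = NULL,
  seed = NULL,
  materials = c("n_water", "n_glass", "n_shell", "n_molecule", "gold_table"),
  scene = c("rod.diameter_nm", "rod.aspect_ratio", "shell.thickness_nm",
            "shell.n", "molecule.shape", "molecule.mw_kda",
            "molecule.diameter_nm", "molecule.n", "site.plane", "site.index",
            "substrate.enabled", "substrate.gap_nm"),
  solver = c("polarizability_model", "tol", "max_iter", "substrate_model",
             "voxel_size_nm"),
  detection = c("phi", "intensity_W_m2", "bandwidth_nm", "dt_s", "a_sys",
                "a_det", "area_um2", "dark_current", "read_noise",
                "sigma_sys"),
  photothermal = c("c_th", "i_heat", "phi_probe"),
  thermal = c("kappa_w_mk", "dt_target_k", "beta_table"),
  sweep = c("widths_nm", "aspect_ratios", "coarse_points", "fine_points",
            "fine_span", "eta", "mode"),
  output = c("dir", "formats"))

# flatten nested yaml lists to dotted keys one level deep (rod: {...})
.flatten1 <- function(x) {
  out <- list()
  for (nm in names(x)) {
    if (is.list(x[[nm]]) && !is.null(names(x[[nm]]))) {
      for (sub in names(x[[nm]]))
        out[[paste(nm, sub, sep = ".")]] <- x[[nm]][[sub]]
    } else out[[nm]] <- x[[nm]]
  }
  out
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration with blocks `materials`,
#' `scene`, `solver`, `detection`, `photothermal`, `thermal`, `sweep`,
#' `output` plus `seed` and `schema_version`, validates every key
#' against the schema (unknown keys are an error naming the offenders),
#' applies the package defaults for everything omitted, and returns the
#' resolved configuration together with ready-made parameter objects.
#'
#' @param path Path to the configuration file; an empty or absent block
#'   resolves to all defaults.
#' @return A `run_config` list with elements `raw` (resolved key-value
#'   configuration), `objects` (constructed parameter objects:
#'   `materials`, `template`, `rod`, `opts`, `thermal`, `grid`, `mode`),
#'   `seed`, and `hash` (content hash of the resolved configuration).
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown_blocks <- setdiff(names(raw), names(.CONFIG_SCHEMA))
  if (length(unknown_blocks))
    stop("unknown configuration block(s): ",
         paste(unknown_blocks, collapse = ", "))
  flat <- list()
  for (blk in setdiff(names(raw), c("seed", "schema_version"))) {
    keys <- .flatten1(raw[[blk]])
    bad <- setdiff(names(keys), .CONFIG_SCHEMA[[blk]])
    if (length(bad))
      stop(sprintf("unknown key(s) in block '%s': %s", blk,
                   paste(bad, collapse = ", ")))
    flat[[blk]] <- keys
  }
  gv <- function(blk, key, default = NULL) {
    v <- flat[[blk]][[key]]
    if (is.null(v)) default else v
  }
  neg_check <- function(x, key) {
    if (!is.null(x) && (!is.numeric(x) || x <= 0))
      stop(sprintf("configuration key %s must be a positive number", key))
    x
  }
  neg_check(gv("scene", "rod.diameter_nm"), "scene.rod.diameter_nm")
  neg_check(gv("scene", "molecule.diameter_nm"), "scene.molecule.diameter_nm")
  neg_check(gv("detection", "dt_s"), "detection.dt_s")

  gold <- if (!is.null(gv("materials", "gold_table")))
    read_dielectric_table(gv("materials", "gold_table"))
  else read_dielectric_table()
  mats <- material_set(n_water = gv("materials", "n_water", 1.33),
                       n_glass = gv("materials", "n_glass", 1.52),
                       n_shell = gv("materials", "n_shell", 1.45),
                       n_molecule = gv("materials", "n_molecule", 1.57),
                       gold = gold)
  shell <- shell_spec(thickness = gv("scene", "shell.thickness_nm", 1.5),
                      refractive_index = gv("scene", "shell.n", 1.45))
  mol <- molecule_spec(shape = gv("scene", "molecule.shape", "sphere"),
                       equivalent_diameter = gv("scene", "molecule.diameter_nm"),
                       mw_kda = gv("scene", "molecule.mw_kda"),
                       refractive_index = gv("scene", "molecule.n", 1.57))
  site <- binding_site(plane = gv("scene", "site.plane", "horizontal_side"),
                       index = gv("scene", "site.index", 0L))
  rod <- nanorod_geometry(gv("scene", "rod.diameter_nm", 20),
                          gv("scene", "rod.aspect_ratio", 4))
  template <- scene_template(shell = shell, molecule = mol, site = site,
                             materials = mats,
                             substrate = isTRUE(gv("scene", "substrate.enabled",
                                                   TRUE)),
                             gap = gv("scene", "substrate.gap_nm", 0))
  settings <- solver_settings(
    polarizability_model = gv("solver", "polarizability_model",
                              "lattice_dispersion"),
    tol = gv("solver", "tol", 1e-5),
    max_iter = gv("solver", "max_iter", 4000),
    substrate_model = gv("solver", "substrate_model"))
  phi <- gv("detection", "phi")
  if (is.null(phi)) {
    inten <- gv("detection", "intensity_W_m2")
    phi <- if (is.null(inten)) 1e21 else photon_flux_density(inten, 800)
  }
  config <- detection_config(phi = phi,
                             bandwidth = gv("detection", "bandwidth_nm", 1),
                             dt = gv("detection", "dt_s", 1e-3),
                             a_sys = gv("detection", "a_sys", 1),
                             a_det = gv("detection", "a_det", 1),
                             area_um2 = gv("detection", "area_um2", 1),
                             dark_current = gv("detection", "dark_current", 0),
                             read_noise = gv("detection", "read_noise", 0),
                             sigma_sys = gv("detection", "sigma_sys", 0))
  pt <- photothermal_params(c_th = gv("photothermal", "c_th", 1),
                            i_heat = gv("photothermal", "i_heat", 1e9),
                            phi_probe = gv("photothermal", "phi_probe", 1e21))
  bt <- gv("thermal", "beta_table")
  therm <- thermal_params(kappa_water = gv("thermal", "kappa_w_mk", 0.6),
                          beta_table = if (is.null(bt))
                            c("1" = 1.00, "2" = 1.08, "3" = 1.18,
                              "4" = 1.28, "5" = 1.37)
                          else unlist(bt),
                          dT_target = gv("thermal", "dt_target_k", 10))
  vox <- gv("solver", "voxel_size_nm")
  opts <- sweep_options(
    voxel_size = if (is.null(vox)) function(d) d / 8 else vox,
    settings = settings,
    coarse_points = gv("sweep", "coarse_points", 5),
    fine_points = gv("sweep", "fine_points", 9),
    fine_span = gv("sweep", "fine_span", 1.2),
    eta = gv("sweep", "eta", 0.21),
    config = config, pt_params = pt)
  sg <- size_grid(widths = unlist(gv("sweep", "widths_nm",
                                     seq(10, 40, by = 10))),
                  aspect_ratios = unlist(gv("sweep", "aspect_ratios",
                                            seq(2, 5, by = 1))))
  resolved <- list(schema_version = gv0 <- if (is.null(raw$schema_version)) 1
                   else raw$schema_version,
                   seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
                   blocks = flat)
  structure(list(raw = resolved,
                 objects = list(materials = mats, template = template,
                                rod = rod, opts = opts, thermal = therm,
                                grid = sg,
                                mode = gv("sweep", "mode",
                                          "constant_intensity")),
                 seed = resolved$seed,
                 hash = config_hash(resolved)),
            class = "run_config")
}

#' Content hash of a configuration
#'
#' MD5 of the deparsed, resolved configuration; identical
#' configurations hash identically and any change to a value changes
#' the hash.
#'
#' @param x Any R object (typically a resolved configuration list).
#' @return A hex string.
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Write sweep/scan results with a run manifest
#'
#' Writes each tabular result as CSV and a `manifest.json` recording the
#' configuration hash, package version, seed and timing. Deterministic
#' stages reproduce identical CSV bytes for identical configurations.
#'
#' @param results Named list of results (`cnr_map`, `scan_result` or
#'   data frames).
#' @param out_dir Output directory (created if absent).
#' @param config Optional `run_config` whose hash and seed enter the
#'   manifest.
#' @return Invisibly, the manifest list.
#' @export
write_outputs <- function(results, out_dir, config = NULL) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  files <- character()
  for (nm in names(results)) {
    x <- results[[nm]]
    df <- if (inherits(x, "cnr_map")) x$cells
          else if (inherits(x, "scan_result")) x$cnr
          else if (is.data.frame(x)) x
          else next
    path <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files <- c(files, basename(path))
  }
  manifest <- list(
    package = "plasmocnr",
    version = as.character(utils::packageVersion("plasmocnr")),
    config_hash = if (!is.null(config)) config$hash else NA,
    seed = if (!is.null(config)) config$seed else NA,
    files = files,
    written_at = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
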