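# plasmocnr

Contrast-to-noise optimization of gold nanorod single-molecule
plasmonic biosensors.

A single gold nanorod on a glass coverslip reports the binding of one
protein molecule through a sub-nanometre red shift of its longitudinal
localized surface plasmon resonance (LSPR) and a sub-percent change of
its scattering and absorption cross sections. Whether that event is
*detectable* depends on the competition between this contrast and the
measurement noise. `plasmocnr` is for researchers designing such
sensors: it models the full chain from electromagnetics to photon
statistics and answers which nanorod size — and which detection
modality — resolves a single binding event best.

## What it computes

- **Scene**: a spherically capped gold nanorod (width *d*, aspect
  ratio *AR*), a 1.5 nm functionalization shell (*n* = 1.45), water
  (*n* = 1.33) over glass (*n* = 1.52), and a protein-sized dielectric
  molecule (*n* = 1.57; 52.8 kDa ↔ 5 nm equal-volume sphere at
  1.37 g/cm³) bound anywhere on the shell surface.
- **Electromagnetics**: discrete dipole approximation (DDA) with
  FFT-accelerated matrix-free COCG iterations, lattice-dispersion
  polarizabilities, Johnson–Christy gold optical constants (bundled),
  a quasi-static image treatment of the substrate, and an internal
  Lorenz–Mie series as an independent oracle.
- **Observables**: Lorentzian fits of *C*<sub>scat</sub>(λ) and
  *C*<sub>abs</sub>(λ) in both states give λ<sub>res</sub>, Γ (FWHM),
  the binding shift Δλ, and the wavelength of maximal intensity change
  λ<sub>max</sub> on the long-wavelength flank.
- **Sensing metrics**: for a shot-noise-limited photon budget, the
  contrast-to-noise ratio

  CNR = |s₂ − s₁| / √(σ₁² + σ₂²)

  for three modalities — spectral (signal = fitted peak position, noise
  = η Γ / SNR with η = 0.21), fixed-wavelength scattering (signal =
  counts at λ<sub>max</sub>, noise = shot noise), and photothermal
  (signal ∝ ΔC<sub>abs</sub> · I<sub>heat</sub>, noise from the probe
  beam only) — plus the noise-independent figures of merit
  FOM<sub>λ</sub> = Δλ/Γ and FOM<sub>I</sub> = max |ΔC(λ)|/C(λ).
- **Optimization**: CNR maps over a (width, AR) grid at constant
  illumination intensity or at constant steady-state temperature rise
  ΔT = C<sub>abs</sub> I / (4π κ R<sub>eq</sub> β), and sensitivity
  scans over binding position, molecule size/shape/index and shell
  thickness/index.

## Worked example

Spectra of a 20 × 80 nm rod with and without a 52.8 kDa protein at the
tip, at screening resolution (2.5 nm voxels, homogeneous water host):

```r
library(plasmocnr)

rod   <- nanorod_geometry(20, 4)                     # 20 x 80 nm
bare  <- build_scene(rod, substrate = FALSE)
bound <- build_scene(rod, molecule = molecule_spec(mw_kda = 52.8),
                     substrate = FALSE)
g0 <- voxelize(bare,  2.5)
g1 <- voxelize(bound, 2.5)

wl <- seq(814, 934, by = 15)                         # around the resonance
st <- solver_settings(tol = 1e-4)
s0 <- spectrum_scan(g0, wl, st)
s1 <- spectrum_scan(g1, wl, st)

(resp <- binding_response(s0, s1))
#> <binding_response> delta_lambda 0.1572 nm, lambda_max 890.3 nm, |dC|max 4.496e-05

cnr_spectral(resp)
#> <sensing_result> spectral @ 874.8 nm: CNR 0.9563 (FOM 0.002852)
cnr_fixed_wavelength(resp)
#> <sensing_result> fixed_wavelength @ 890.3 nm: CNR 0.366 (FOM 0.00707)
```

Reading: at this rod size the bare resonance sits at 874.8 nm; one
bound protein shifts it by 0.157 nm, and the largest cross-section
change (4.5 × 10⁻⁵ µm²) appears at 890.3 nm on the red flank. With the
default photon budget (Φ = 10²¹ photons s⁻¹ m⁻² nm⁻¹, 1 nm bandwidth,
1 ms integration), the binding step stands at 0.96 combined noise
standard deviations in spectral detection and 0.37 in fixed-wavelength
detection — detectable after modest averaging. Absolute values scale
as √(Φ Δt); the package's size sweeps compare them across rod
geometries:

```r
map <- run_size_sweep(size_grid(), scene_template(substrate = FALSE),
                      sweep_options(fine_points = 5,
                                    settings = solver_settings(tol = 3e-4)))
map_summary(map, "spectral")$argmax     # -> width 20, AR 4 (20 x 80 nm)
```

A thin command-line front end lives in `inst/cli/plasmocnr.R`
(`sweep`, `fom`, `scan`, `eta`, `spectra` subcommands over a YAML
configuration; see `load_config()`).

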