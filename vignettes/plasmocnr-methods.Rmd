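---
title: "Modelling single-molecule plasmonic sensing with plasmocnr"
author: "plasmocnr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling single-molecule plasmonic sensing with plasmocnr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The sensing problem

A single gold nanorod supports a longitudinal localized surface plasmon
resonance (LSPR) whose wavelength, width and amplitude respond to the
refractive index of its immediate surroundings. When a single protein
binds at the rod tip, the resonance red-shifts by a fraction of a
nanometre and the scattering and absorption cross sections change by a
fraction of a percent. Whether that binding event is detectable is not a
property of the shift alone: it is a competition between the
*contrast* (how much the observable changes) and the *noise* of the
measurement. `plasmocnr` models this end to end:

1. an electromagnetic scene — a spherically capped gold nanorod
   (width $d$, aspect ratio $AR$, length $D = AR\,d$) wrapped in a
   1.5 nm functionalization shell ($n = 1.45$), resting on glass
   ($n = 1.52$) in water ($n = 1.33$), with a protein modelled as a
   dielectric solid ($n = 1.57$) bound on the outer shell surface;
2. a discrete dipole approximation (DDA) solver producing far-field
   scattering and absorption cross-section spectra with and without the
   molecule;
3. Lorentzian resonance fits turning spectra into the sensing
   observables $\lambda_\mathrm{res}$, $\Gamma$ (FWHM), $C_\mathrm{max}$,
   the binding shift $\Delta\lambda$ and the wavelength of maximal
   intensity change $\lambda_\mathrm{max}$;
4. a shot-noise-limited photon-budget model that converts those
   observables into contrast-to-noise ratios (CNR) for three detection
   modalities — spectral, fixed-wavelength scattering, and
   photothermal — plus the noise-independent figures of merit
   $\mathrm{FOM}_\lambda = \Delta\lambda/\Gamma$ and
   $\mathrm{FOM}_I = \max_\lambda |\Delta C(\lambda)|/C(\lambda)$;
5. orchestration: size-grid optimization maps (at constant illumination
   intensity or constant steady-state temperature rise) and
   parameter-sensitivity scans over binding position, molecule size,
   shape and index contrast, and shell properties.

## Electromagnetic model

### Geometry and voxelization

The rod is a spherocylinder: all points within $d/2$ of an axial segment
of length $D - d$. The shell is the parallel surface at distance $t$
(default 1.5 nm). Binding sites are indexed 0–6 along the spherical cap
in 15° steps from the apex and 7–12 along the flat side in 5 nm steps;
index 12 is the rod midpoint of the 20 × 80 nm reference rod, and for
other lengths the last step is clamped to the midpoint. The molecule
menu holds four equal-volume solids — sphere, hemisphere, spherical
segment (height $R/2$), and a concave spherical segment whose inner
face conforms to the shell — all calibrated to the volume of the
reference sphere (closed forms where available, deterministic grid
quadrature with a root solve for the concave shape, required to agree
within 0.5%). Protein mass maps to size through a closely packed
interior at 1.37 g/cm³, which sends 52.8 kDa (streptavidin) to a 5.0 nm
sphere.

Voxelization uses cubic voxels on a lattice aligned with the rod axis
and a center-in-solid material test with priority
gold > molecule > shell. Two deliberate deviations from plain
center-testing exist, both for the *analyte only*:

* **molecule volume renormalization** — the 5 nm molecule is comparable
  to (or smaller than) the voxel at screening resolutions, so molecule
  voxels carry a susceptibility factor that restores the analytic
  molecule volume. In the Rayleigh limit the molecule acts through its
  integrated polarizability $\propto V \Delta\varepsilon$, so this
  correction is exact to first order and removes the dominant
  discretization artifact from the differential signal;
* **nearest-voxel fallback** — if no lattice center falls inside the
  molecule at all, the free voxel nearest its centroid becomes the
  molecule voxel (again volume-renormalized). Without it the binding
  signal silently vanishes at coarse voxel sizes.

The gold table is the Johnson–Christy dataset for evaporated films,
bundled as plain text (188–1937 nm) and interpolated linearly in $n$
and $k$ versus wavelength (not in permittivity): monotone-safe on a
sparse table and standard DDA practice.

### Solver

Each voxel is a point dipole with a Clausius–Mossotti polarizability
corrected either by the Draine–Goodman lattice dispersion relation
(default) or by radiative reaction. The coupled-dipole equations are
solved matrix-free: the interaction sum is a discrete convolution on
the padded lattice evaluated with FFTs, and the linear system is solved
with COCG (conjugate orthogonal conjugate gradient) on the
diagonally-symmetrized complex-symmetric form — one operator
application per iteration, the method of choice for DDA-type systems.
A true-residual check guards the recursive residual at convergence.
Warm starts come from the neighbouring wavelength of a spectrum and,
for the with-molecule state, from the bare-state field on the shared
lattice, which both roughly halves iteration counts and correlates the
residual error of the two states entering the differential signal.

The glass half-space enters through quasi-static image dipoles with the
static reflection factor
$(\varepsilon_g - \varepsilon_w)/(\varepsilon_g + \varepsilon_w)$, a
documented approximation to the rigorous half-space Green function
(Sommerfeld integrals are out of scope). The image term is a
correlation in $z$; its Fourier transform is obtained from the direct
transforms by a frequency mirror and phase twist, so the substrate adds
no extra forward FFTs. Quantities that depend on the substrate
therefore carry a model error; the image operator itself is validated
to machine precision against a dense evaluation, and index-matched
glass reproduces the homogeneous solution exactly.

Cross sections follow the standard DDA estimators: extinction from the
optical theorem (work of the incident field on the dipoles), absorption
from the per-dipole dissipation sum (which cancels the radiative-
reaction term exactly, so lossless materials absorb nothing), and
scattering as the difference. An internal Lorenz–Mie series (with a
truncation-doubling convergence check) is the independent oracle: at
0.5 nm voxels a 10 nm gold sphere in water agrees in $C_\mathrm{ext}$
to better than 1%, with monotone improvement under refinement.

### Numerical choices

* iterative tolerance: 1e-5 relative residual by default (cross-section
  changes below plotting precision); screening runs use 1e-4–3e-4;
* spectra are fitted near the peak: a short adaptive coarse scan (or,
  inside a size sweep, a window predicted by regression on already
  computed cells, verified and re-centred if the fitted peak lands near
  a window edge) followed by a fine grid spanning ±1.2 estimated
  half-widths. Production sampling uses 10–21 points; the screening
  scale used in the test suite uses 5-point grids, which for noiseless
  solver spectra is an interpolation rather than a statistical fit;
* Lorentzian fits run Levenberg–Marquardt on
  $L(\lambda) = b + C_\mathrm{max}(\Gamma/2)^2 /
  ((\lambda-\lambda_\mathrm{res})^2 + (\Gamma/2)^2)$, initialized from
  the discrete peak and half-maximum crossings. The baseline $b$ is
  fitted by default in `fit_lorentzian()` but pinned to zero throughout
  the sweep pipeline: cross-section spectra are background-free, and on
  short fitting grids the four-parameter fit is nearly underdetermined
  (on a five-point grid it leaves a single degree of freedom, and the
  fitted width becomes unstable);
* $\lambda_\mathrm{max}$ is the argmax of the fitted difference curve
  on a 0.1 nm grid restricted to the long-wavelength side of the bare
  resonance, ties broken toward shorter wavelength.

## Sensing model

With photon flux density $\Phi$ (photons s⁻¹ m⁻² nm⁻¹), detection
bandwidth, integration time $\Delta t$ and ideal optics, the registered
signal from a scattering factor $A_\mathrm{NP}$ is
$s = \Phi\,bw\,A_\mathrm{NP}\,A_\mathrm{SYS}\,A_\mathrm{DET}\,\Delta t$
and the shot-noise-limited SNR is $\sqrt{s}$. The universal figure of
merit is the contrast-to-noise ratio
$\mathrm{CNR} = |s_2 - s_1| / \sqrt{\sigma_1^2 + \sigma_2^2}$ — the
binding step over the combined root-mean-square noise of the two
states; the quadrature combination is the standard choice for the
difference of two independently noisy signals.

* **Spectral sensing**: the signal is the fitted peak position. Its
  noise is $\sigma_\mathrm{fit} = \eta\,\Gamma/\mathrm{SNR}$ with
  state-specific $\Gamma_i$ and resonance cross sections; a simplified
  form $\Delta\lambda\,\mathrm{SNR}_1/(\eta\,\Gamma_1\sqrt{2})$ is
  reported alongside and agrees when binding barely perturbs $\Gamma$
  and $C$.
* **Fixed-wavelength scattering**: counts at $\lambda_\mathrm{max}$;
  $\mathrm{CNR}_I = |\Delta C|\sqrt{\Phi\,bw\,\Delta t}/\sqrt{C_1+C_2}$.
* **Photothermal**: the heating beam at the $\lambda_\mathrm{max}$ of
  the absorption difference dissipates $P = C_\mathrm{abs} I_\mathrm{heat}$;
  a thermal-lens factor $C_\mathrm{th}$ (scattering cross section per
  watt dissipated, an opaque parameter defaulting to 1 — only relative
  photothermal maps are meaningful) converts it into probe-beam
  scattering, while the noise comes from the probe reference field only
  and is independent of the heating intensity.

### The peak-fit noise constant η

The constant linking peak-position noise to $\Gamma/\mathrm{SNR}$ is
commonly taken as 0.21. For an unweighted least-squares Lorentzian fit
of Poisson-noised counts sampled at $n$ points across ±1.2 Γ, the
sandwich (heteroscedasticity-corrected) variance of the fitted center
gives $\eta = 0.264, 0.247, 0.227, 0.221$ for $n = 15, 17, 20, 21$:
the constant is a property of the sampling design, falling like
$\approx 1/\sqrt{n}$, and 21 points across ±1.2 Γ is the sampling at
which the canonical 0.21 is recovered. The package therefore uses a
21-point window as its default spectral sampling convention for count
spectra, ships η = 0.21 as the default constant, and provides
`estimate_eta_monte_carlo()` to re-estimate it by simulation for any
other design (the estimate is independent of Γ and of SNR, as the
scaling form requires).

## Thermal limits

Steady-state surface heating of an illuminated particle is
$\Delta T = C_\mathrm{abs} I / (4\pi\kappa R_\mathrm{eq}\beta)$ with
$R_\mathrm{eq}$ the volume-equivalent sphere radius recomputed from the
exact capped-cylinder volume, $\kappa = 0.6$ W m⁻¹ K⁻¹ for water, and
β a dimensionless thermal capacitance (1 for a sphere, larger for
elongated shapes). Published boundary-element tabulations of β for
capped rods are not bundled; the shipped default table
(AR 1→1.00 … 5→1.37) is a clearly marked placeholder consistent with
the qualitative behaviour and fully replaceable via configuration —
all constant-temperature results should be read with that caveat. In
constant-ΔT sweeps each cell's illumination is rescaled to the
intensity that produces the target rise given its own absorption at the
sensing wavelength; scattering-modality CNRs scale as $\sqrt{I}$ and
the photothermal CNR linearly in the heating intensity.

## Synthetic fixtures

`make_two_state_spectra()` generates the statistical structure the
metrics pipeline assumes — two Lorentzian states (shift, optional
amplitude and width changes) observed as Poisson counts — with the
noiseless truth returned alongside and full seed determinism. It
emulates shot-noise-limited spectroscopy only: no correlated system
noise, no detector fixed-pattern noise, no baseline drift. Tests built
on it therefore validate the estimator chain, not camera physics.
`make_toy_grid()` provides solver fixtures small enough for dense
brute-force checks.

## Problem sizes and what the tests show

The paper-scale experiment (0.25–0.5 nm voxels, 1 nm width steps,
rigorous substrate treatment) is a cluster-scale computation. The test
suite instead runs a screening scale chosen to finish on a single CPU:
$d/8$ voxels (the coarsest the voxelizer admits), 5-point fitting
grids, relative residual 3e-4, the homogeneous water host (the
substrate model is validated separately against its closed forms), and
a 4 × 4 size grid over widths 10–40 nm and AR 2–5. At this scale the
structural results are reproduced — the constant-intensity CNR optimum
sits at interior widths near 20 nm for all three modalities while the
noise-independent FOMs peak at the smallest width; binding sites lose
sensitivity monotonically along the cap with a steep drop by mid-rod;
CNR is linear in the index contrast and decays exponentially with
shell thickness — but absolute cross sections at this resolution carry
several-percent discretization errors, and a sub-voxel molecule is
represented by few (volume-renormalized) voxels, so per-cell values
are semiquantitative. Production runs should use 0.25–0.5 nm voxels,
10–21-point spectra, tolerance 1e-5 and the image-substrate model.

## Known limitations

* The substrate is quasi-static images, not the retarded half-space
  Green function: substrate-induced shifts are qualitatively right
  (index-matching limit exact, red shift reproduced) but not
  quantitative.
* The optical theorem is evaluated with the incident field only, which
  with the image term active makes extinction approximate to the same
  order as the substrate model itself.
* β values for capped rods are placeholders (see above).
* $A_\mathrm{SYS} = 1$: angular redistribution of scattering and
  finite numerical aperture are not modelled; a user-supplied detector
  QE curve is supported through `apply_qe()`.
* Single molecule per rod; no mass transport, surface chemistry or
  transient heating.
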