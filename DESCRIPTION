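Package: plasmocnr
Title: Contrast-to-Noise Optimization of Gold Nanorod Single-Molecule Plasmonic Biosensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a single-molecule plasmonic biosensor built from a
    spherically capped gold nanorod with a thin functionalization shell,
    resting on a glass substrate in water, with a protein-sized dielectric
    molecule bound at a configurable surface site. Scattering and absorption
    cross-section spectra are computed with an FFT-accelerated discrete
    dipole approximation (DDA) solver, validated against an internal
    Lorenz-Mie series oracle. Lorentzian resonance fits feed a
    contrast-to-noise-ratio (CNR) framework for three shot-noise-limited
    sensing modalities (spectral, fixed-wavelength scattering, and
    photothermal), including steady-state heating limits that normalize
    illumination intensity to a constant temperature rise, size-grid
    optimization maps, and parameter-sensitivity scans over binding
    position, molecule size, shape and refractive index, and shell
    properties.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
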