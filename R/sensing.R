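PLANCK_J_S <- 6.62607015e-34
LIGHT_SPEED_M_S <- 2.99792458e8

#' Spectral photon flux density of an illumination intensity
#'
#' `Phi = I0 / (h nu)` per nm of bandwidth, with the photon energy taken
#' at the given wavelength.
#'
#' @param intensity Spectral illumination intensity in W/m2 per nm.
#' @param wavelength Wavelength in nm.
#' @return Photon flux density in photons s-1 m-2 nm-1.
#' @export
photon_flux_density <- function(intensity, wavelength) {
  stopifnot(all(intensity >= 0), all(wavelength > 0))
  intensity * (wavelength * 1e-9) / (PLANCK_J_S * LIGHT_SPEED_M_S)
}

#' Detection configuration
#'
#' Photon-budget and noise parameters of the measurement. The defaults
#' describe the idealized reference setup: perfect optics and detector
#' (`a_sys = a_det = 1`), no system or detector noise (shot-noise
#' limited), 1 nm detection bandwidth.
#'
#' @param phi Illumination photon flux density, photons s-1 m-2 nm-1.
#' @param bandwidth Detection bandwidth in nm.
#' @param dt Integration time in s.
#' @param a_sys Dimensionless optical system factor in (0, 1].
#' @param a_det Detector quantum efficiency: a scalar in (0, 1] or a
#'   function of wavelength (nm).
#' @param area_um2 Detector area in um2 (photothermal noise term).
#' @param dark_current Dark current in counts/s.
#' @param read_noise Read noise in counts.
#' @param sigma_sys Optical system noise in counts.
#' @return A `detection_config` object.
#' @export
detection_config <- function(phi = 1e21, bandwidth = 1, dt = 1e-3,
                             a_sys = 1, a_det = 1, area_um2 = 1,
                             dark_current = 0, read_noise = 0,
                             sigma_sys = 0) {
  stopifnot(phi > 0, bandwidth > 0, dt > 0, a_sys > 0, a_sys <= 1,
            area_um2 > 0, dark_current >= 0, read_noise >= 0, sigma_sys >= 0)
  if (!is.function(a_det)) stopifnot(a_det > 0, a_det <= 1)
  structure(list(phi = phi, bandwidth = bandwidth, dt = dt, a_sys = a_sys,
                 a_det = a_det, area_um2 = area_um2,
                 dark_current = dark_current, read_noise = read_noise,
                 sigma_sys = sigma_sys),
            class = "detection_config")
}

.qe_at <- function(config, wavelength) {
  q <- if (is.function(config$a_det)) config$a_det(wavelength) else config$a_det
  if (any(q <= 0))
    stop("detector quantum efficiency is zero at the sensing wavelength")
  q
}

.is_shot_limited <- function(config) {
  config$sigma_sys == 0 && config$dark_current == 0 && config$read_noise == 0
}

#' Registered photon counts from a scattering factor
#'
#' `s = Phi * bandwidth * A_NP * A_SYS * A_DET(lambda) * dt`; for
#' background-free scattering detection `A_NP` is the scattering cross
#' section.
#'
#' @param config A `detection_config`.
#' @param a_np Wavelength-dependent scattering factor in um2 (>= 0).
#' @param wavelength Sensing wavelength in nm (for the QE curve).
#' @return Expected photon counts.
#' @export
registered_signal <- function(config, a_np, wavelength = NULL) {
  stopifnot(inherits(config, "detection_config"), all(a_np >= 0))
  q <- if (is.null(wavelength)) {
    if (is.function(config$a_det))
      stop("wavelength required for a wavelength-dependent QE curve")
    config$a_det
  } else .qe_at(config, wavelength)
  config$phi * config$bandwidth * (a_np * 1e-12) * config$a_sys * q * config$dt
}

#' Shot noise of a photon count
#'
#' Poisson statistics: standard deviation `sqrt(s)`.
#'
#' @param s Expected counts (>= 0).
#' @return Counts.
#' @export
shot_noise <- function(s) {
  stopifnot(all(s >= 0))
  sqrt(s)
}

#' Total measurement noise
#'
#' Quadrature sum of the optical system noise, the detector noise
#' `sigma_det = sqrt(I_D dt + sigma_R^2)` and the shot noise `sqrt(s)`.
#'
#' @param config A `detection_config`.
#' @param s Registered counts (>= 0).
#' @return A `noise_model` list with `sigma_sys`, `sigma_det`,
#'   `sigma_shot`, `total`.
#' @export
total_noise <- function(config, s) {
  stopifnot(inherits(config, "detection_config"), all(s >= 0))
  sigma_det <- sqrt(config$dark_current * config$dt + config$read_noise^2)
  sigma_shot <- sqrt(s)
  structure(list(sigma_sys = config$sigma_sys, sigma_det = sigma_det,
                 sigma_shot = sigma_shot,
                 total = sqrt(config$sigma_sys^2 + sigma_det^2 + sigma_shot^2)),
            class = "noise_model")
}

#' Signal-to-noise ratio of single-particle detection
#'
#' Shot-noise-limited SNR: `sqrt(s)` with `s` the registered counts.
#'
#' @param config A shot-noise-limited `detection_config`.
#' @param a_np Scattering factor in um2.
#' @param wavelength Sensing wavelength in nm.
#' @return Dimensionless SNR.
#' @export
snr <- function(config, a_np, wavelength = NULL) {
  if (!.is_shot_limited(config))
    stop("snr() assumes the shot-noise-limited regime (no system/detector noise)")
  sqrt(registered_signal(config, a_np, wavelength))
}

#' Noise-independent spectral figure of merit
#'
#' Single-molecule resonance shift over the resonance width of the bare
#' state: `FOM_lambda = delta_lambda / Gamma`.
#'
#' @param response A `binding_response`.
#' @return Dimensionless FOM.
#' @export
fom_spectral <- function(response) {
  stopifnot(inherits(response, "binding_response"))
  response$delta_lambda / response$fit_without$gamma
}

#' Noise-independent fixed-wavelength figure of merit
#'
#' Maximum relative intensity change over the dense fitted grid:
#' `FOM_I = max |delta_C(lambda)| / C(lambda)` with `C` the bare-state
#' fitted curve.
#'
#' @param response A `binding_response` (scattering or absorption).
#' @param kind Metadata label, `"scat"` or `"abs"`.
#' @return Dimensionless FOM.
#' @export
fom_intensity <- function(response, kind = c("scat", "abs")) {
  kind <- match.arg(kind)
  stopifnot(inherits(response, "binding_response"))
  base <- predict_lorentzian(response$fit_without, response$dense_wavelengths)
  ok <- base > 0
  max(abs(response$delta_curve[ok]) / base[ok])
}

#' Contrast-to-noise ratio
#'
#' `CNR = |s2 - s1| / sqrt(sigma1^2 + sigma2^2)`: the binding-induced
#' signal step over the combined root-mean-square noise of the two
#' states.
#'
#' @param signal_1,signal_2 Time-averaged signals without/with molecule.
#' @param sigma_1,sigma_2 RMS noise of each state (not both zero).
#' @return Dimensionless CNR (>= 0).
#' @export
cnr <- function(signal_1, signal_2, sigma_1, sigma_2) {
  stopifnot(sigma_1 >= 0, sigma_2 >= 0)
  if (sigma_1 == 0 && sigma_2 == 0)
    stop("CNR undefined: both noise terms are zero")
  abs(signal_2 - signal_1) / sqrt(sigma_1^2 + sigma_2^2)
}

#' Lorentzian peak-fit noise
#'
#' The standard deviation of the fitted resonance position is
#' proportional to the resonance width and inversely proportional to the
#' spectral SNR: `sigma_fit = eta * Gamma / SNR`, with the peak SNR
#' evaluated from the fitted cross section at resonance.
#'
#' @param fit A `lorentzian_fit` of a cross-section spectrum (um2).
#' @param config A shot-noise-limited `detection_config`.
#' @param eta Proportionality factor (default 0.21; see
#'   [estimate_eta_monte_carlo()]).
#' @return Peak-position noise in nm.
#' @export
fit_noise <- function(fit, config, eta = 0.21) {
  stopifnot(inherits(fit, "lorentzian_fit"), eta > 0)
  if (!.is_shot_limited(config))
    stop("fit_noise() assumes the shot-noise-limited regime")
  c_res <- predict_lorentzian(fit, fit$lambda_res)
  eta * fit$gamma / snr(config, c_res, fit$lambda_res)
}

#' Monte-Carlo estimate of the peak-fit noise factor eta
#'
#' Simulates Poisson-noised Lorentzian count spectra at a stated peak
#' SNR, fits each with the Lorentzian model by unweighted least squares,
#' and returns `SD(lambda_res) * SNR / Gamma` -- the dimensionless
#' factor relating fit noise to width over SNR. By construction the
#' result is independent of Gamma and of SNR (shot-noise scaling); it
#' does depend weakly on the sampling (number of points and span),
#' which defaults to the package's spectral sampling convention.
#'
#' @param gamma Resonance FWHM in nm.
#' @param snr Peak signal-to-noise ratio (peak counts = snr^2).
#' @param n_trials Number of simulated spectra (>= 100).
#' @param seed Integer seed; the simulation is reproducible given it.
#' @param n_points Spectral points per spectrum.
#' @param span Half-width of the sampled window in units of Gamma.
#' @param lambda_res True resonance position in nm.
#' @return Estimated eta (dimensionless).
#' @export
estimate_eta_monte_carlo <- function(gamma = 40, snr = 50, n_trials = 500,
                                     seed = 1, n_points = 21, span = 1.2,
                                     lambda_res = 800) {
  stopifnot(n_trials >= 100, gamma > 0, snr > 0, n_points >= 5)
  wl <- seq(lambda_res - span * gamma, lambda_res + span * gamma,
            length.out = n_points)
  truth <- snr^2 * (gamma / 2)^2 / ((wl - lambda_res)^2 + (gamma / 2)^2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  est <- numeric(n_trials)
  fails <- 0L
  for (i in seq_len(n_trials)) {
    y <- stats::rpois(n_points, truth)
    f <- tryCatch(fit_lorentzian(spectrum(wl, y, kind = "counts"),
                                 baseline = FALSE),
                  error = function(e) NULL)
    if (is.null(f)) { fails <- fails + 1L; est[i] <- NA_real_ }
    else est[i] <- f$lambda_res
  }
  if (fails > 0.05 * n_trials)
    stop(sprintf("too many fit failures in eta Monte Carlo: %d of %d",
                 fails, n_trials))
  stats::sd(est, na.rm = TRUE) * snr / gamma
}

# save/restore the global RNG state so seeded helpers do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

.sensing_result <- function(modality, sensing_wavelength, signal_1, signal_2,
                            sigma_1, sigma_2, cnr_value, fom,
                            cnr_simplified = NA_real_) {
  structure(list(modality = modality, sensing_wavelength = sensing_wavelength,
                 signal_1 = signal_1, signal_2 = signal_2,
                 sigma_1 = sigma_1, sigma_2 = sigma_2,
                 cnr = cnr_value, fom = fom, cnr_simplified = cnr_simplified),
            class = "sensing_result")
}

#' @export
print.sensing_result <- function(x, ...) {
  cat(sprintf("<sensing_result> %s @ %.1f nm: CNR %.4g (FOM %.4g)\n",
              x$modality, x$sensing_wavelength, x$cnr, x$fom))
  invisible(x)
}

#' Contrast-to-noise ratio of spectral sensing
#'
#' The signal is the fitted resonance position; the step is the binding
#' shift `delta_lambda` and the per-state noise the peak-fit noise
#' `eta Gamma_i / SNR_i` with state-specific width and resonance cross
#' section. The simplified form (valid when the binding-induced changes
#' of Gamma and C are negligible) `delta_lambda * SNR_1 / (eta Gamma_1
#' sqrt(2))` is reported alongside.
#'
#' @param response A `binding_response` built from scattering spectra.
#' @param config A shot-noise-limited `detection_config`.
#' @param eta Peak-fit noise factor (default 0.21).
#' @return A `sensing_result` with `modality = "spectral"`.
#' @export
cnr_spectral <- function(response, config = detection_config(), eta = 0.21) {
  stopifnot(inherits(response, "binding_response"))
  s1 <- fit_noise(response$fit_without, config, eta)
  s2 <- fit_noise(response$fit_with, config, eta)
  f1 <- response$fit_without
  simplified <- abs(response$delta_lambda) *
    snr(config, predict_lorentzian(f1, f1$lambda_res), f1$lambda_res) /
    (eta * f1$gamma * sqrt(2))
  .sensing_result("spectral",
                  sensing_wavelength = f1$lambda_res,
                  signal_1 = f1$lambda_res,
                  signal_2 = response$fit_with$lambda_res,
                  sigma_1 = s1, sigma_2 = s2,
                  cnr_value = cnr(f1$lambda_res, response$fit_with$lambda_res,
                                  s1, s2),
                  fom = fom_spectral(response),
                  cnr_simplified = simplified)
}

#' Contrast-to-noise ratio of fixed-wavelength scattering sensing
#'
#' At the sensing wavelength `lambda_max` the registered counts are
#' `s_i = Phi bw C_i(lambda_max) dt` and the per-state noise is the shot
#' noise `sqrt(s_i)`, so `CNR_I = |s2 - s1| / sqrt(s1 + s2)`. The
#' simplified form `FOM_I * SNR / sqrt(2)` is reported alongside.
#'
#' @param response A `binding_response` built from scattering spectra.
#' @param config A shot-noise-limited `detection_config`.
#' @return A `sensing_result` with `modality = "fixed_wavelength"`.
#' @export
cnr_fixed_wavelength <- function(response, config = detection_config()) {
  stopifnot(inherits(response, "binding_response"))
  if (!.is_shot_limited(config))
    stop("cnr_fixed_wavelength() assumes the shot-noise-limited regime")
  lmax <- response$lambda_max
  c1 <- predict_lorentzian(response$fit_without, lmax)
  c2 <- predict_lorentzian(response$fit_with, lmax)
  s1 <- registered_signal(config, c1, lmax)
  s2 <- registered_signal(config, c2, lmax)
  # simplified form: relative intensity change at the sensing wavelength
  # times the single-particle SNR there, over sqrt(2)
  simplified <- (abs(c2 - c1) / c1) * snr(config, c1, lmax) / sqrt(2)
  .sensing_result("fixed_wavelength", sensing_wavelength = lmax,
                  signal_1 = s1, signal_2 = s2,
                  sigma_1 = sqrt(s1), sigma_2 = sqrt(s2),
                  cnr_value = cnr(s1, s2, sqrt(s1), sqrt(s2)),
                  fom = fom_intensity(response),
                  cnr_simplified = simplified)
}

#' Photothermal model parameters
#'
#' @param c_th Scattering cross section of the time-varied thermal lens
#'   per watt of dissipated power, um2/W.
#' @param i_heat Heating-beam intensity, W/m2.
#' @param phi_probe Probe-beam photon flux density, photons s-1 m-2 nm-1.
#' @return A `photothermal_params` object.
#' @export
photothermal_params <- function(c_th = 1, i_heat = 1e9, phi_probe = 1e21) {
  stopifnot(c_th > 0, i_heat > 0, phi_probe > 0)
  structure(list(c_th = c_th, i_heat = i_heat, phi_probe = phi_probe),
            class = "photothermal_params")
}

#' Contrast-to-noise ratio of fixed-wavelength photothermal sensing
#'
#' The heating beam at `lambda_max` of the absorption difference
#' spectrum dissipates `P = C_abs I_heat`; the thermal lens scatters the
#' probe beam with cross section `C_th P`. The registered signal change
#' is `Phi_probe bw C_th dC_abs(lambda_max) I_heat dt` while the noise
#' `sqrt(Phi_probe bw A dt)` arises from the probe reference field only
#' and is independent of the heating intensity.
#'
#' @param response_abs A `binding_response` built from absorption
#'   spectra.
#' @param params A `photothermal_params`.
#' @param config A `detection_config` (detector area used for the
#'   reference-field shot noise).
#' @return A `sensing_result` with `modality = "photothermal"`.
#' @export
cnr_photothermal <- function(response_abs, params = photothermal_params(),
                             config = detection_config()) {
  stopifnot(inherits(response_abs, "binding_response"),
            inherits(params, "photothermal_params"))
  lmax <- response_abs$lambda_max
  c1 <- predict_lorentzian(response_abs$fit_without, lmax)
  c2 <- predict_lorentzian(response_abs$fit_with, lmax)
  # dissipated power (W) and thermal-lens cross sections (um2 -> m2)
  p1 <- c1 * 1e-12 * params$i_heat
  p2 <- c2 * 1e-12 * params$i_heat
  sig <- function(p) params$phi_probe * config$bandwidth *
    (params$c_th * p * 1e-12) * config$a_sys * config$dt
  s1 <- sig(p1); s2 <- sig(p2)
  sigma_probe <- sqrt(params$phi_probe * config$bandwidth *
                        (config$area_um2 * 1e-12) * config$dt)
  .sensing_result("photothermal", sensing_wavelength = lmax,
                  signal_1 = s1, signal_2 = s2,
                  sigma_1 = sigma_probe, sigma_2 = sigma_probe,
                  cnr_value = abs(s2 - s1) / sigma_probe,
                  fom = fom_intensity(response_abs, "abs"))
}

#' Apply a detector quantum-efficiency curve to a sensing result
#'
#' In the shot-noise-limited regime the CNR scales as the square root of
#' the detector QE at the sensing wavelength.
#'
#' @param result A `sensing_result`.
#' @param qe_curve Scalar QE in (0, 1] or a function of wavelength (nm).
#' @return The rescaled `sensing_result`.
#' @export
apply_qe <- function(result, qe_curve) {
  stopifnot(inherits(result, "sensing_result"))
  q <- if (is.function(qe_curve)) qe_curve(result$sensing_wavelength)
       else qe_curve
  if (q <= 0) stop("quantum efficiency is zero at the sensing wavelength")
  if (q > 1) stop("quantum efficiency must be in (0, 1]")
  result$cnr <- result$cnr * sqrt(q)
  if (!is.na(result$cnr_simplified))
    result$cnr_simplified <- result$cnr_simplified * sqrt(q)
  result
}
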