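# a synthetic binding response with controlled changes, noiseless
make_response <- function(shift = 0.4, amp = 0, width = 0, gamma = 40,
                          cmax = 0.01, n = 21) {
  wl <- seq(800 - 1.2 * gamma, 800 + 1.2 * gamma, length.out = n)
  binding_response(
    spectrum(wl, lorentz(wl, 800, gamma, cmax), "C_scat"),
    spectrum(wl, lorentz(wl, 800 + shift, gamma * (1 + width),
                         cmax * (1 + amp)), "C_scat"))
}

test_that("registered signal follows the photon-budget arithmetic", {
  cfg <- detection_config(phi = 1e18, bandwidth = 1, dt = 1e-2)
  # C = 1e-14 m2 = 0.01 um2 -> 100 counts
  expect_equal(registered_signal(cfg, 0.01), 100)
  expect_equal(registered_signal(cfg, 0), 0)
  cfg2 <- detection_config(phi = 1e18, bandwidth = 1, dt = 2e-2)
  expect_equal(registered_signal(cfg2, 0.01), 200)   # linear in dt
  # QE scales linearly; SNR as its square root
  cfg3 <- detection_config(phi = 1e18, dt = 1e-2, a_det = 0.25)
  expect_equal(registered_signal(cfg3, 0.01), 25)
  expect_equal(snr(cfg3, 0.01), 5)
})

test_that("noise components combine in quadrature", {
  expect_equal(shot_noise(0), 0)
  expect_equal(shot_noise(100), 10)
  cfg <- detection_config(sigma_sys = 3, dark_current = 16, dt = 1,
                          read_noise = 0)
  nm <- total_noise(cfg, 0)
  expect_equal(nm$sigma_det, 4)
  expect_equal(nm$total, 5)                         # 3-4-5 triangle
  cfg2 <- detection_config(dark_current = 100, dt = 1, read_noise = 10)
  expect_equal(total_noise(cfg2, 0)$sigma_det, sqrt(200))
  # all zero -> zero
  expect_equal(total_noise(detection_config(), 0)$total, 0)
  # Poisson draws: sample SD of mean-400 counts is 20 within 3 SE
  x <- withr::with_seed(7, stats::rpois(1e5, 400))
  se_sd <- 20 / sqrt(2 * (1e5 - 1))
  expect_lt(abs(stats::sd(x) - 20), 3 * se_sd + 0.05)
})

test_that("SNR is sqrt(counts) and scales as sqrt(dt)", {
  cfg <- detection_config(phi = 1e18, dt = 1e-2)
  s <- registered_signal(cfg, 1)                    # 1e4 counts
  expect_equal(snr(cfg, 1), 100)
  expect_equal(snr(cfg, 1), s / total_noise(cfg, s)$total)
  cfg2 <- detection_config(phi = 1e18, dt = 2e-2)
  expect_equal(snr(cfg2, 1) / snr(cfg, 1), sqrt(2), tolerance = 1e-12)
  expect_error(snr(detection_config(read_noise = 5), 1), "shot-noise-limited")
})

test_that("noise-independent FOMs follow their definitions", {
  r0 <- make_response(shift = 0)
  expect_equal(fom_spectral(r0), 0, tolerance = 1e-7)
  expect_equal(fom_intensity(r0), 0, tolerance = 1e-6)
  r <- make_response(shift = 0.39, gamma = 39)
  expect_equal(fom_spectral(r), 0.01, tolerance = 1e-3)
  # uniform 1% amplitude increase, no shift: relative change 0.01 everywhere
  ra <- make_response(shift = 0, amp = 0.01)
  expect_equal(fom_intensity(ra), 0.01, tolerance = 1e-3)
  # pure-shift case against brute-force dense maximum
  rs <- make_response(shift = 1, amp = 0, width = 0)
  dense <- seq(800 - 48, 800 + 48, by = 0.01)
  brute <- max(abs(lorentz(dense, 801, 40, 0.01) -
                     lorentz(dense, 800, 40, 0.01)) /
                 lorentz(dense, 800, 40, 0.01))
  expect_equal(fom_intensity(rs), brute, tolerance = 1e-3)
})

test_that("CNR definition and degenerate cases", {
  expect_equal(cnr(5, 5, 1, 1), 0)
  expect_equal(cnr(0, 10, sqrt(2), sqrt(2)), 5)
  expect_equal(cnr(0, 3, 2, 2), 3 / (2 * sqrt(2)))
  expect_error(cnr(0, 1, 0, 0), "undefined")
})

test_that("fit noise follows eta Gamma / SNR", {
  wl <- seq(740, 860, length.out = 15)
  f <- fit_lorentzian(spectrum(wl, lorentz(wl, 800, 40, 0.01), "C_scat"),
                      baseline = FALSE)
  cfg <- detection_config(phi = 1e21, dt = 1e-3)    # 1e4 counts at peak
  expect_equal(fit_noise(f, cfg, eta = 0.21), 0.21 * 40 / 100,
               tolerance = 1e-6)
  cfg4 <- detection_config(phi = 4e21, dt = 1e-3)
  expect_equal(fit_noise(f, cfg4, eta = 0.21) / fit_noise(f, cfg, eta = 0.21),
               0.5, tolerance = 1e-10)
})

test_that("eta Monte Carlo is near 0.21 and independent of Gamma and SNR", {
  e0 <- estimate_eta_monte_carlo(gamma = 40, snr = 50, n_trials = 400,
                                 seed = 11)
  expect_equal(e0, 0.21, tolerance = 0.15)
  e1 <- estimate_eta_monte_carlo(gamma = 60, snr = 50, n_trials = 400,
                                 seed = 12)
  e2 <- estimate_eta_monte_carlo(gamma = 40, snr = 150, n_trials = 400,
                                 seed = 13)
  expect_lt(abs(e1 - e0) / e0, 0.15)
  expect_lt(abs(e2 - e0) / e0, 0.15)
})

test_that("spectral CNR: full and simplified forms agree for small changes", {
  cfg <- detection_config()
  r <- make_response(shift = 0.2, amp = 0.005, width = 0.005)
  res <- cnr_spectral(r, cfg)
  expect_equal(res$cnr, res$cnr_simplified, tolerance = 0.02)
  r0 <- make_response(shift = 0)
  expect_equal(cnr_spectral(r0, cfg)$cnr, 0, tolerance = 1e-4)
  # proportionality to FOM * SNR across a photon-flux scan
  ratios <- vapply(c(1e20, 1e21, 1e22), function(phi) {
    cf <- detection_config(phi = phi)
    res <- cnr_spectral(r, cf)
    f1 <- r$fit_without
    res$cnr / (fom_spectral(r) *
                 snr(cf, predict_lorentzian(f1, f1$lambda_res)))
  }, 0)
  expect_lt(diff(range(ratios)) / mean(ratios), 1e-6)
})

test_that("fixed-wavelength CNR scales as sqrt(flux) and matches FOM*SNR/sqrt(2)", {
  r <- make_response(shift = 0.2, amp = 0.002, width = 0.002)
  c1 <- cnr_fixed_wavelength(r, detection_config(phi = 1e21))
  c4 <- cnr_fixed_wavelength(r, detection_config(phi = 4e21))
  expect_equal(c4$cnr / c1$cnr, 2, tolerance = 1e-8)
  expect_equal(c1$cnr, c1$cnr_simplified, tolerance = 0.02)
  r0 <- make_response(shift = 0)
  expect_equal(cnr_fixed_wavelength(r0, detection_config())$cnr, 0,
               tolerance = 1e-6)
})

test_that("photothermal CNR is linear in heating intensity, sqrt in probe flux", {
  wl <- seq(700, 900, length.out = 21)
  rabs <- binding_response(
    spectrum(wl, lorentz(wl, 790, 45, 0.03), "C_abs"),
    spectrum(wl, lorentz(wl, 790.3, 45, 0.0303), "C_abs"))
  cfg <- detection_config()
  p1 <- photothermal_params(i_heat = 1e9)
  p2 <- photothermal_params(i_heat = 2e9)
  expect_equal(cnr_photothermal(rabs, p2, cfg)$cnr /
                 cnr_photothermal(rabs, p1, cfg)$cnr, 2, tolerance = 1e-10)
  p4 <- photothermal_params(i_heat = 1e9, phi_probe = 4e21)
  expect_equal(cnr_photothermal(rabs, p4, cfg)$cnr /
                 cnr_photothermal(rabs, p1, cfg)$cnr, 2, tolerance = 1e-10)
  r0 <- binding_response(spectrum(wl, lorentz(wl, 790, 45, 0.03), "C_abs"),
                         spectrum(wl, lorentz(wl, 790, 45, 0.03), "C_abs"))
  expect_equal(cnr_photothermal(r0, p1, cfg)$cnr, 0, tolerance = 1e-6)
})

test_that("QE correction rescales CNR by its square root", {
  r <- make_response()
  res <- cnr_spectral(r, detection_config())
  expect_equal(apply_qe(res, 1)$cnr, res$cnr)
  expect_equal(apply_qe(res, 0.25)$cnr, res$cnr / 2)
  expect_error(apply_qe(res, 0), "zero")
  # a visible-optimized QE curve favors shorter sensing wavelengths
  qe_vis <- function(wl) pmax(0.9 - 8e-4 * (wl - 550), 0.05)
  r_red <- make_response()                       # resonance at 800
  wlb <- seq(600 - 48, 600 + 48, length.out = 21)
  r_blue <- binding_response(
    spectrum(wlb, lorentz(wlb, 600, 40, 0.01), "C_scat"),
    spectrum(wlb, lorentz(wlb, 600.4, 40, 0.01), "C_scat"))
  gain_red <- apply_qe(cnr_spectral(r_red, detection_config()), qe_vis)$cnr /
    cnr_spectral(r_red, detection_config())$cnr
  gain_blue <- apply_qe(cnr_spectral(r_blue, detection_config()), qe_vis)$cnr /
    cnr_spectral(r_blue, detection_config())$cnr
  expect_gt(gain_blue, gain_red)
})

test_that("every modality scales as sqrt(flux * time) in the shot-noise limit", {
  r <- make_response(shift = 0.2, amp = 0.003)
  wl <- seq(700, 900, length.out = 21)
  rabs <- binding_response(
    spectrum(wl, lorentz(wl, 790, 45, 0.03), "C_abs"),
    spectrum(wl, lorentz(wl, 790.2, 45, 0.0302), "C_abs"))
  phis <- 10^seq(20, 22, length.out = 5)
  vals <- sapply(phis, function(phi) {
    cfg <- detection_config(phi = phi)
    c(cnr_spectral(r, cfg)$cnr,
      cnr_fixed_wavelength(r, cfg)$cnr,
      cnr_photothermal(rabs, photothermal_params(phi_probe = phi), cfg)$cnr)
  })
  for (i in 1:3) {
    slope <- stats::coef(stats::lm(log(vals[i, ]) ~ log(phis)))[2]
    expect_equal(unname(slope), 0.5, tolerance = 0.01)
  }
})

test_that("empirical CNR from Poisson count pairs matches the analytic value", {
  s1 <- 9000; s2 <- 9300
  K <- 1e4
  x1 <- withr::with_seed(21, stats::rpois(K, s1))
  x2 <- withr::with_seed(22, stats::rpois(K, s2))
  emp <- abs(mean(x2) - mean(x1)) / sqrt(stats::var(x1) + stats::var(x2))
  ana <- cnr(s1, s2, sqrt(s1), sqrt(s2))
  # numerator SE dominates: Var(mean diff)/ (s1+s2) = 1/K
  se <- sqrt(1 / K + ana^2 / (2 * K))
  expect_lt(abs(emp - ana), 3 * se)
})
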