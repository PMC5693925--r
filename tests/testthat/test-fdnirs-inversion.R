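# Calibration, temporal reduction, multi-distance slope inversion, QC.

test_that("slope inversion is exact on analytic wavenumbers", {
  rho <- INST$fdnirs_distances
  for (mua in c(0.05, 0.1, 0.25)) {
    for (musp in c(4, 10, 18)) {
      k <- dpdw_wavenumbers(mua, musp, INST)
      ac <- exp(-k$k_real * rho) / rho^2
      ph <- k$k_imag * rho
      fit <- multidistance_fit(ac, ph, rho, INST)
      expect_equal(fit$mua, mua, tolerance = 1e-10)
      expect_equal(fit$musp, musp, tolerance = 1e-10)
      expect_equal(fit$r2_ac, 1, tolerance = 1e-12)
      expect_equal(fit$r2_phase, 1, tolerance = 1e-12)
      expect_true(fit$valid)
    }
  }
})

test_that("inversion agrees with a brute-force two-parameter search", {
  # oracle: numerically minimize squared slope mismatch over (mua, musp)
  set.seed(11)
  for (i in 1:20) {
    mua <- runif(1, 0.02, 0.3)
    musp <- runif(1, 3, 20)
    k <- dpdw_wavenumbers(mua, musp, INST)
    oracle <- optim(c(0.1, 10), function(p) {
      if (any(p <= 0)) return(1e6)
      kk <- dpdw_wavenumbers(p[1], p[2], INST)
      (kk$k_real - k$k_real)^2 + (kk$k_imag - k$k_imag)^2
    }, control = list(reltol = 1e-14, maxit = 5000))
    rho <- INST$fdnirs_distances
    fit <- multidistance_fit(exp(-k$k_real * rho) / rho^2, k$k_imag * rho,
                             rho, INST)
    expect_equal(fit$mua, oracle$par[1], tolerance = 1e-6)
    expect_equal(fit$musp, oracle$par[2], tolerance = 1e-6)
  }
})

test_that("equal slopes give the zero-absorption limit", {
  rho <- INST$fdnirs_distances
  s <- 1.2
  fit <- multidistance_fit(exp(-s * rho) / rho^2, s * rho, rho, INST)
  expect_equal(fit$mua, 0, tolerance = 1e-12)
  expect_true(fit$valid)
})

test_that("unphysical slopes are flagged invalid", {
  rho <- INST$fdnirs_distances
  # increasing amplitude with distance: negative S_AC
  fit <- multidistance_fit(exp(0.5 * rho), 0.3 * rho, rho, INST)
  expect_false(fit$valid)
  expect_false(fdnirs_qc(fit))
  expect_error(multidistance_fit(c(1, 2), c(0.1, 0.2), c(1.5, 2)), "3 distances")
})

test_that("temporal median is robust and estimates phase noise", {
  m <- temporal_median(rep(2.5, 50), rep(0.3, 50))
  expect_equal(m$ac_median, 2.5)
  expect_equal(m$phase_median, 0.3)
  expect_equal(m$phase_noise, 0)
  # one outlier in 100 points leaves the median untouched
  ac <- rep(1, 100); ac[17] <- 500
  ph <- rep(0.2, 100); ph[17] <- 3
  m2 <- temporal_median(ac, ph)
  expect_equal(m2$ac_median, 1)
  expect_equal(m2$phase_median, 0.2)
  # Gaussian phase noise is recovered within sampling error
  set.seed(5)
  est <- replicate(200, temporal_median(rep(1, 100),
                                        rnorm(100, 0, 0.02))$phase_noise)
  expect_equal(mean(est), 0.02, tolerance = 0.02)
  expect_error(temporal_median(numeric(0), numeric(0)), "empty")
})

test_that("phantom calibration recovers injected distortions and the round trip is exact", {
  wl <- INST$fdnirs_wavelengths
  known_mua <- rep(0.09, 8)
  known_musp <- evaluate_mie(11, 0.9, wl)
  # undistorted phantom -> identity factors
  clean <- simulate_phantom(known_mua, known_musp, INST, n_samples = 5)
  cal0 <- calibrate(clean, known_mua, known_musp, INST)
  expect_equal(cal0$amplitude_gain, rep(1, 32), tolerance = 1e-12)
  expect_equal(cal0$phase_offset, rep(0, 32), tolerance = 1e-12)

  # injected distortions are recovered exactly (noise-free)
  set.seed(3)
  channels <- expand.grid(rho_cm = INST$fdnirs_distances,
                          wavelength_nm = wl, KEEP.OUT.ATTRS = FALSE)
  channels$gain <- exp(rnorm(32, 0, 0.3))
  channels$phase_offset <- rnorm(32, 0, 0.2)
  distorted <- simulate_phantom(known_mua, known_musp, INST,
                                channels = channels, n_samples = 5)
  cal <- calibrate(distorted, known_mua, known_musp, INST)
  key_cal <- paste(cal$wavelength_nm, cal$rho_cm)
  key_ch <- paste(channels$wavelength_nm, channels$rho_cm)
  i <- match(key_cal, key_ch)
  expect_equal(cal$amplitude_gain, 1 / channels$gain[i], tolerance = 1e-10)
  expect_equal(cal$phase_offset, channels$phase_offset[i], tolerance = 1e-10)

  # distorted subject data + calibration -> true optical properties < 0.1%
  tis <- population_tissue()
  opt <- tissue_optics(tis, wl, EXT)
  for (j in c(1, 5, 8)) {
    ch <- channels[channels$wavelength_nm == wl[j], ]
    ch <- ch[match(INST$fdnirs_distances, ch$rho_cm), ]
    raw <- fdnirs_forward(opt$mua[j], opt$musp[j], INST, gain = ch$gain,
                          phase_offset = ch$phase_offset, n_samples = 5)
    raw$wavelength_nm <- wl[j]
    calraw <- apply_calibration(raw, cal)
    med <- vapply(split(seq_len(nrow(calraw)), calraw$rho_cm), function(i) {
      c(median(calraw$ac_amplitude[i]), median(calraw$phase_rad[i]))
    }, numeric(2))
    fit <- multidistance_fit(med[1, ], med[2, ], as.numeric(colnames(med)),
                             INST)
    expect_equal(fit$mua, opt$mua[j], tolerance = 1e-3)
    expect_equal(fit$musp, opt$musp[j], tolerance = 1e-3)
  }
  # missing channel is a calibration error
  expect_error(calibrate(clean[clean$rho_cm != 2, ], known_mua, known_musp,
                         INST), "missing channel")
})

test_that("slope-fit QC thresholds are inclusive on the keep side", {
  fit <- list(valid = TRUE, r2_ac = 0.95, r2_phase = 0.99,
              phase_noise = 0.05)
  expect_true(fdnirs_qc(fit))                       # exactly at both thresholds
  fit$phase_noise <- 0.06
  expect_false(fdnirs_qc(fit))                      # too noisy
  fit$phase_noise <- 0.01; fit$r2_ac <- 0.94
  expect_false(fdnirs_qc(fit))                      # poor linear fit
  fit$r2_ac <- 0.99
  expect_true(fdnirs_qc(fit))
})
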