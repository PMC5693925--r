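# Closed-form forward models: DPDW wavenumbers, FDNIRS decay, correlation
# diffusion g1/g2.

test_that("DPDW wavenumbers satisfy the algebraic identities on a grid", {
  v <- 2.99792458e10 / INST$refractive_index
  w <- 2 * pi * INST$modulation_frequency
  for (mua in c(0.02, 0.05, 0.1, 0.2, 0.3)) {
    for (musp in c(3, 6.4, 10, 15, 20)) {
      k <- dpdw_wavenumbers(mua, musp, INST)
      expect_gte(k$k_real, k$k_imag)
      expect_equal(k$k_real^2 - k$k_imag^2, 3 * mua * musp,
                   tolerance = 1e-12)
      expect_equal(k$k_real * k$k_imag, 3 * musp * w / (2 * v),
                   tolerance = 1e-12)
    }
  }
})

test_that("DPDW wavenumbers match high-precision evaluation of the closed form", {
  # frozen from a 50-digit evaluation at mua=0.1, musp=6.4, 110 MHz, n=1.4
  k <- dpdw_wavenumbers(0.1, 6.4, INST)
  expect_equal(k$k_real, 1.4031268703319401, tolerance = 1e-14)
  expect_equal(k$k_imag, 0.2208280196159560, tolerance = 1e-14)
  k2 <- dpdw_wavenumbers(0.1, 10, INST)
  expect_equal(k2$k_real, 1.7539085879149251, tolerance = 1e-14)
  expect_equal(k2$k_imag, 0.2760350245199450, tolerance = 1e-14)
})

test_that("DC limit collapses to sqrt(3 mua musp) with zero phase slope", {
  inst_dc <- instrument_config(modulation_frequency = 1e-3)
  k <- dpdw_wavenumbers(0.1, 10, inst_dc)
  expect_equal(k$k_real, sqrt(3 * 0.1 * 10), tolerance = 1e-9)
  expect_equal(k$k_imag, 0, tolerance = 1e-6)
})

test_that("non-positive optical properties are rejected", {
  expect_error(dpdw_wavenumbers(0, 10), "mua")
  expect_error(dpdw_wavenumbers(0.1, -1), "musp")
  expect_error(g1_semi_infinite(-1e-6, 0.1, 6.4, 2.1e-8), "tau")
  expect_error(fdnirs_forward(0.1, 10, INST, noise_ln_ac = -1), "noise")
})

test_that("noise-free FDNIRS forward data are exactly linear in distance", {
  k <- dpdw_wavenumbers(0.08, 9, INST)
  raw <- fdnirs_forward(0.08, 9, INST, n_samples = 3)
  one <- raw[raw$sample_index == 1, ]
  lnac <- log(one$ac_amplitude * one$rho_cm^2)
  slope_ac <- coef(lm(lnac ~ one$rho_cm))[2]
  slope_ph <- coef(lm(one$phase_rad ~ one$rho_cm))[2]
  expect_equal(unname(slope_ac), -k$k_real, tolerance = 1e-12)
  expect_equal(unname(slope_ph), k$k_imag, tolerance = 1e-12)
  # gain=1, offset=0 at rho = 2: phase is 2 k_imag
  expect_equal(one$phase_rad[one$rho_cm == 2], 2 * k$k_imag,
               tolerance = 1e-12)
})

test_that("g1 is normalized, decays to zero, and matches the frozen oracle", {
  tau <- INST$tau_grid
  g1 <- g1_semi_infinite(c(0, tau), 0.1, 6.4, 2.1e-8, INST)
  expect_equal(g1[1], 1)
  expect_true(all(diff(g1) < 0))
  expect_lt(g1[length(g1)], 1e-6)
  # frozen from a 50-digit term-by-term evaluation of the semi-infinite
  # solution (rho=2, mua=0.1, musp=6.4, 850 nm, n=1.4, CBFi=2.1e-8, tau=1e-5)
  expect_equal(g1_semi_infinite(1e-5, 0.1, 6.4, 2.1e-8, INST),
               0.74698119825581199, tolerance = 1e-13)
})

test_that("g1 decreases pointwise with flow on the optical-property grid", {
  tau_probe <- c(1e-6, 1e-5, 1e-4)
  for (mua in c(0.02, 0.1, 0.3)) {
    for (musp in c(3, 10, 20)) {
      prev <- NULL
      for (cbfi in c(0.5e-8, 2e-8, 5e-8)) {
        g <- g1_semi_infinite(tau_probe, mua, musp, cbfi, INST)
        expect_true(all(g > 0 & g < 1))
        if (!is.null(prev)) expect_true(all(g < prev))
        prev <- g
      }
    }
  }
})

test_that("g2 curves obey the Siegert intercept and bounds, and seeding is reproducible", {
  m <- g2_forward(0.1, 6.4, 2.1e-8, 0.5, INST, n_curves = 3)
  expect_equal(dim(m$curves), c(3, length(INST$tau_grid)))
  expect_true(all(abs(m$curves[, 1] - 1.5) < 0.01)) # tau ~ 1e-7: g1 ~ 1
  # exact Siegert intercept when the lag grid reaches down to negligible lags
  inst0 <- instrument_config(tau_grid = c(1e-13, 1e-6, 1e-4))
  m0 <- g2_forward(0.1, 6.4, 2.1e-8, 0.5, inst0, n_curves = 1)
  expect_equal(m0$curves[1, 1], 1.5, tolerance = 1e-6)
  expect_true(all(m$curves >= 1 - 1e-12 & m$curves <= 1.5 + 1e-12))
  a <- g2_forward(0.1, 6.4, 2.1e-8, 0.5, INST, noise_sd = 0.01, seed = 7)
  b <- g2_forward(0.1, 6.4, 2.1e-8, 0.5, INST, noise_sd = 0.01, seed = 7)
  expect_identical(a$curves, b$curves)
  expect_error(g2_forward(0.1, 6.4, 2.1e-8, 1.5), "beta")
})
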