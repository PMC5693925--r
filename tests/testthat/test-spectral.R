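# Chromophore unmixing, Mie power-law fitting, spectral QC, 850 nm
# extrapolation.

test_that("chromophore unmixing recovers generating concentrations exactly", {
  wl <- INST$fdnirs_wavelengths
  ts <- tissue_state(hbo = 37, hbr = 18)
  mua <- tissue_optics(ts, wl, EXT)$mua
  fit <- fit_chromophores(mua, wl, EXT, water_fraction = 0.75)
  expect_equal(fit$hbo, 37, tolerance = 1e-10)
  expect_equal(fit$hbr, 18, tolerance = 1e-10)
  expect_equal(fit$hbt, 55, tolerance = 1e-10)
  expect_equal(fit$so2, 37 / 55, tolerance = 1e-10)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-10)
  expect_lt(fit$fit_pvalue, 1e-10)
})

test_that("zero hemoglobin leaves only the water term", {
  wl <- INST$fdnirs_wavelengths
  e <- tissue_optics(tissue_state(hbo = 0, hbr = 0, cbfi = 0), wl, EXT)
  water <- extinction_table()
  wv <- 0.75 * water$mua_water[match(wl, water$wavelength_nm)]
  expect_equal(e$mua, wv, tolerance = 1e-12)
  fit <- fit_chromophores(e$mua, wl, EXT)
  expect_equal(fit$hbo + fit$hbr, 0, tolerance = 1e-8)
})

test_that("unmixing matches a brute-force grid search on random instances", {
  wl <- INST$fdnirs_wavelengths
  set.seed(21)
  for (i in 1:10) {
    hbo <- runif(1, 10, 80); hbr <- runif(1, 5, 40)
    mua <- tissue_optics(tissue_state(hbo = hbo, hbr = hbr), wl, EXT)$mua +
      rnorm(8, 0, 2e-4)
    fit <- fit_chromophores(mua, wl, EXT)
    # oracle: exhaustive grid around the truth, then refinement
    e <- tissue_optics(tissue_state(hbo = 1, hbr = 0, water_fraction = 0),
                       wl, EXT)$mua
    eR <- tissue_optics(tissue_state(hbo = 0, hbr = 1, water_fraction = 0),
                        wl, EXT)$mua
    wv <- 0.75 * tissue_optics(tissue_state(hbo = 0, hbr = 0), wl, EXT)$mua / 0.75
    y <- mua - wv
    grid_best <- function(h1, h2) {
      ss <- outer(h1, h2, Vectorize(function(a, b) sum((y - a * e - b * eR)^2)))
      ij <- which(ss == min(ss), arr.ind = TRUE)[1, ]
      c(h1[ij[1]], h2[ij[2]])
    }
    g1 <- grid_best(seq(0, 120, by = 1), seq(0, 60, by = 1))
    g2 <- grid_best(seq(g1[1] - 1, g1[1] + 1, by = 0.01),
                    seq(g1[2] - 1, g1[2] + 1, by = 0.01))
    expect_equal(fit$hbo, g2[1], tolerance = 0.02)
    expect_equal(fit$hbr, g2[2], tolerance = 0.02)
  }
})

test_that("negative least-squares solutions are clamped to zero", {
  wl <- INST$fdnirs_wavelengths
  # pure HbR spectrum minus a bit of HbO shape drives the HbO coefficient < 0
  e <- extinction_at(EXT, wl)
  y <- 20 * e$eps_hbr - 2 * e$eps_hbo + 0.75 * e$mua_water
  fit <- fit_chromophores(y, wl, EXT)
  expect_gte(fit$hbo, 0)
  expect_gte(fit$hbr, 0)
  expect_error(fit_chromophores(0.1, 700, EXT), "2 usable")
})

test_that("SO2 increases with HbO at fixed HbT", {
  wl <- INST$fdnirs_wavelengths
  so2_of <- function(hbo) {
    mua <- tissue_optics(tissue_state(hbo = hbo, hbr = 50 - hbo), wl, EXT)$mua
    fit_chromophores(mua, wl, EXT)$so2
  }
  vals <- vapply(seq(5, 45, by = 10), so2_of, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("Mie power-law fit recovers parameters exactly in log-log space", {
  wl <- INST$fdnirs_wavelengths
  musp <- evaluate_mie(13.7, 1.43, wl)
  fit <- fit_scattering_model(musp, wl)
  expect_equal(fit$a_500, 13.7, tolerance = 1e-10)
  expect_equal(fit$b_power, 1.43, tolerance = 1e-10)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-12)
  expect_true(all(abs(fit$residuals_log) < 1e-12))
  # flat spectrum: b = 0, a = the constant
  flat <- fit_scattering_model(rep(5, 8), wl)
  expect_equal(flat$b_power, 0, tolerance = 1e-12)
  expect_equal(flat$a_500, 5, tolerance = 1e-12)
})

test_that("log-log fit agrees with original-scale nonlinear least squares", {
  wl <- INST$fdnirs_wavelengths
  set.seed(9)
  for (i in 1:5) {
    a <- runif(1, 8, 20); b <- runif(1, 0.5, 2.5)
    musp <- evaluate_mie(a, b, wl)
    fit <- fit_scattering_model(musp, wl)
    nls_fit <- optim(c(10, 1), function(p) {
      sum((musp - evaluate_mie(p[1], p[2], wl))^2)
    }, control = list(reltol = 1e-14, maxit = 5000))
    expect_equal(fit$a_500, nls_fit$par[1], tolerance = 5e-3)
    expect_equal(fit$b_power, nls_fit$par[2], tolerance = 5e-3)
  }
})

test_that("Mie evaluation reproduces the reference points", {
  expect_equal(evaluate_mie(13.7, 1.43, 500), 13.7)
  expect_equal(round(evaluate_mie(13.7, 1.43, 850), 1), 6.4)
  expect_equal(evaluate_mie(5, 0, 1234), 5)
  expect_error(evaluate_mie(5, 1, -10), "positive")
})

test_that("spectral QC applies the p and R^2 thresholds inclusively", {
  expect_false(spectral_qc(0.99, 0.05))   # p too large
  expect_false(spectral_qc(0.5, 0.001))   # R^2 too small
  expect_true(spectral_qc(0.99, 0.001))
  expect_true(spectral_qc(0.6, 0.03))     # exactly at both thresholds
  expect_false(spectral_qc(NA, 0.001))
})

test_that("850 nm extrapolation is consistent with the forward spectral model", {
  wl <- INST$fdnirs_wavelengths
  for (seed in 1:5) {
    set.seed(seed)
    ts <- tissue_state(hbo = runif(1, 20, 60), hbr = runif(1, 8, 30),
                       a_500 = runif(1, 9, 18), b_power = runif(1, 0.8, 2))
    opt <- tissue_optics(ts, wl, EXT)
    chromo <- fit_chromophores(opt$mua, wl, EXT)
    scatter <- fit_scattering_model(opt$musp, wl)
    ext <- extrapolate_to_dcs(chromo, scatter, EXT)
    direct <- tissue_optics(ts, 850, EXT)
    expect_equal(ext$mua, direct$mua, tolerance = 1e-9)
    expect_equal(ext$musp, direct$musp, tolerance = 1e-9)
  }
})
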