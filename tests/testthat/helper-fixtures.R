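# Shared fixtures for the test suite. Everything is generated in code.

INST <- instrument_config()
EXT <- extinction_table()

# a faster instrument variant for pipeline-level tests: fewer samples/lags
inst_small <- function() {
  instrument_config(tau_grid = 10^seq(-7, -1, length.out = 64),
                    fdnirs_rate = 10, acquisition_duration = 2)
}

# the population-mean tissue of the cohort histograms (HbT 54 uM, SO2 0.66)
population_tissue <- function() {
  hbt <- 54; so2 <- 0.66
  tissue_state(hbo = so2 * hbt, hbr = (1 - so2) * hbt,
               a_500 = 13.7, b_power = 1.43, cbfi = 2.1e-8, beta = 0.5)
}

# noise-free FDNIRS round trip: forward -> medians -> slope fit, per wavelength
invert_noise_free <- function(tissue, instrument = INST, table = EXT) {
  opt <- tissue_optics(tissue, instrument$fdnirs_wavelengths, table)
  mua <- musp <- numeric(nrow(opt))
  for (j in seq_len(nrow(opt))) {
    raw <- fdnirs_forward(opt$mua[j], opt$musp[j], instrument, n_samples = 5)
    med <- vapply(split(seq_len(nrow(raw)), raw$rho_cm), function(i) {
      c(median(raw$ac_amplitude[i]), median(raw$phase_rad[i]))
    }, numeric(2))
    rho <- as.numeric(colnames(med))
    fit <- multidistance_fit(med[1, ], med[2, ], rho, instrument)
    mua[j] <- fit$mua; musp[j] <- fit$musp
  }
  list(wavelengths = instrument$fdnirs_wavelengths, mua = mua, musp = musp,
       truth = opt)
}

# truth-level records with demographic labels, for statistics tests
truth_records <- function(sim) {
  rec <- sim$truth
  i <- match(rec$subject_id, sim$subjects$subject_id)
  rec$sex <- sim$subjects$sex[i]
  rec$ga_weeks <- sim$subjects$ga_weeks[i]
  rec
}
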