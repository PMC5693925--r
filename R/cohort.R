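# Synthetic-cohort generator: demographic structure, physiological effects,
# and raw FDNIRS/DCS data via the closed-form forward models.

.LOCATIONS <- c("frontal_left", "frontal_mid", "frontal_right",
                "temporal_left", "temporal_right",
                "parietal_left", "parietal_right")

# side / lobe from the location vocabulary ("<lobe>_<side>")
location_side <- function(location) sub("^.*_", "", location)
location_lobe <- function(location) sub("_[^_]*$", "", location)

#' Configuration of the synthetic infant cohort
#'
#' Defaults emulate the study population: 30 healthy term infants (19 male,
#' 11 female; gestational age 39.2 +/- 1.2 weeks, postnatal age ~2.4 days)
#' measured at 7 cortical sites (left/middle/right frontal, left/right
#' temporal and parietal) with 3 probe repositionings per site. Baseline
#' physiology matches the reported population means: HbT 54 uM, SO2 0.66,
#' scattering a = 13.7 cm^-1 and b = 1.43, CBFi 2.1e-8 cm^2/s, beta 0.5.
#'
#' Effects are injected as the study reports them: multiplicative sex factors
#' (female relative to male) on HbT, SO2 and CBFi; a multiplicative
#' right-vs-left hemisphere factor on CBFi (reported +15.2%); additive
#' per-week gestational-age slopes on HbT and SO2, centered at
#' \code{ga_mean}. Between-subject spread uses log-normal draws for strictly
#' positive quantities and a logit-normal draw for SO2; repositioning adds
#' measurement-level variability of the same form.
#'
#' @param n_male,n_female subject counts.
#' @param ga_mean,ga_sd gestational age distribution, weeks.
#' @param postnatal_mean,postnatal_sd postnatal age, days (truncated >= 0.5).
#' @param locations measurement sites (subset of the 7-site vocabulary).
#' @param repetitions_per_site probe repositionings per site.
#' @param baseline a \code{\link{tissue_state}}-like list giving population
#'   means (hbo/hbr are derived from \code{hbt} x \code{so2}).
#' @param sex_effects multiplicative female/male factors, named
#'   \code{hbt}, \code{so2}, \code{cbfi}.
#' @param hemisphere_effect multiplicative right/left factor on CBFi.
#' @param ga_slopes additive per-week effects, named \code{hbt} (uM/week) and
#'   \code{so2} (fraction/week).
#' @param between_sd between-subject spread: log-SDs for \code{hbt},
#'   \code{cbfi}, \code{a_500}, \code{b_power} and logit-SD for \code{so2}.
#' @param within_sd measurement-level (repositioning) spread, same scales.
#' @param noise instrument noise: \code{fdnirs_ln_ac}, \code{fdnirs_phase}
#'   (rad), \code{dcs_g2} standard deviations.
#' @param channel_gain_log_sd,channel_phase_offset_sd spread of the fixed
#'   per-channel instrument gain (log scale) and phase offset (rad) that the
#'   phantom calibration must remove.
#' @param sao2_range uniform range of arterial saturation draws.
#' @param seed integer seed; seeded runs are bit-reproducible.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_male = 19, n_female = 11,
                          ga_mean = 39.2, ga_sd = 1.2,
                          postnatal_mean = 2.4, postnatal_sd = 1.1,
                          locations = .LOCATIONS,
                          repetitions_per_site = 3,
                          baseline = list(hbt = 54, so2 = 0.66,
                                          a_500 = 13.7, b_power = 1.43,
                                          cbfi = 2.1e-8, beta = 0.5,
                                          water_fraction = 0.75),
                          sex_effects = c(hbt = 0.88, so2 = 0.93,
                                          cbfi = 1.18),
                          hemisphere_effect = 1.152,
                          ga_slopes = c(hbt = 7, so2 = 0.05),
                          between_sd = c(hbt = 0.22, so2 = 0.45,
                                         cbfi = 0.30, a_500 = 0.20,
                                         b_power = 0.20),
                          within_sd = c(hbt = 0.08, so2 = 0.12,
                                        cbfi = 0.12, a_500 = 0.06,
                                        b_power = 0.06),
                          noise = c(fdnirs_ln_ac = 0.02,
                                    fdnirs_phase = 0.02,
                                    dcs_g2 = 0.005),
                          channel_gain_log_sd = 0.3,
                          channel_phase_offset_sd = 0.2,
                          sao2_range = c(0.95, 0.99),
                          seed = 1L) {
  stopifnot(n_male + n_female >= 1, n_male >= 0, n_female >= 0,
            repetitions_per_site >= 1,
            all(locations %in% .LOCATIONS),
            hemisphere_effect > 0, all(sex_effects > 0),
            all(between_sd >= 0), all(within_sd >= 0), all(noise >= 0),
            channel_gain_log_sd >= 0, channel_phase_offset_sd >= 0,
            baseline$hbt > 0, baseline$so2 > 0, baseline$so2 < 1)
  structure(list(
    n_male = n_male, n_female = n_female,
    ga_mean = ga_mean, ga_sd = ga_sd,
    postnatal_mean = postnatal_mean, postnatal_sd = postnatal_sd,
    locations = locations, repetitions_per_site = repetitions_per_site,
    baseline = baseline, sex_effects = sex_effects,
    hemisphere_effect = hemisphere_effect, ga_slopes = ga_slopes,
    between_sd = between_sd, within_sd = within_sd, noise = noise,
    channel_gain_log_sd = channel_gain_log_sd,
    channel_phase_offset_sd = channel_phase_offset_sd,
    sao2_range = sao2_range, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Null cohort configuration
#'
#' Convenience wrapper: all effects at their null value (factors 1, slopes 0)
#' and/or all variability and noise at zero — useful for type-I-error
#' simulations and exact recovery tests.
#'
#' @param ... overrides passed on to \code{\link{cohort_config}}.
#' @param null_effects zero out sex/hemisphere/GA effects.
#' @param zero_noise zero out all biological spread and instrument noise.
#' @return a \code{cohort_config}.
#' @export
null_cohort_config <- function(..., null_effects = TRUE, zero_noise = FALSE) {
  args <- list(...)
  set_default <- function(key, value) {
    if (!key %in% names(args)) args[[key]] <<- value
  }
  if (null_effects) {
    set_default("sex_effects", c(hbt = 1, so2 = 1, cbfi = 1))
    set_default("hemisphere_effect", 1)
    set_default("ga_slopes", c(hbt = 0, so2 = 0))
  }
  if (zero_noise) {
    set_default("between_sd",
                c(hbt = 0, so2 = 0, cbfi = 0, a_500 = 0, b_power = 0))
    set_default("within_sd",
                c(hbt = 0, so2 = 0, cbfi = 0, a_500 = 0, b_power = 0))
    set_default("noise", c(fdnirs_ln_ac = 0, fdnirs_phase = 0, dcs_g2 = 0))
    set_default("channel_gain_log_sd", 0)
    set_default("channel_phase_offset_sd", 0)
  }
  do.call(cohort_config, args)
}

# lognormal multiplicative deviate with unit mean-log (exp(N(0, sd)))
rlnorm0 <- function(n, sdlog) if (sdlog > 0) exp(rnorm(n, 0, sdlog)) else rep(1, n)

# logit-scale additive perturbation of a probability
perturb_logit <- function(p, sd) {
  if (sd <= 0) return(p)
  stats::plogis(stats::qlogis(p) + rnorm(length(p), 0, sd))
}

clamp01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

#' Simulate the subjects table
#'
#' Draws the demographic table: ids, sex, gestational and postnatal age and
#' pulse-oximeter arterial saturation (HGB left blank, as in routine care of
#' healthy neonates).
#'
#' @param config a \code{\link{cohort_config}}.
#' @return data.frame with columns \code{subject_id}, \code{sex},
#'   \code{ga_weeks}, \code{postnatal_age_days}, \code{sao2_frac},
#'   \code{hgb_g_dl}.
#' @export
simulate_subjects <- function(config = cohort_config()) {
  n <- config$n_male + config$n_female
  data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    sex = c(rep("M", config$n_male), rep("F", config$n_female)),
    ga_weeks = pmin(pmax(rnorm(n, config$ga_mean, config$ga_sd), 37), 42),
    postnatal_age_days = pmax(rnorm(n, config$postnatal_mean,
                                    config$postnatal_sd), 0.5),
    sao2_frac = runif(n, config$sao2_range[1], config$sao2_range[2]),
    hgb_g_dl = NA_real_,
    stringsAsFactors = FALSE
  )
}

# Measurement-level ground truth for each subject x location x repetition.
simulate_truth <- function(subjects, config) {
  b <- config$baseline
  n <- nrow(subjects)
  # subject-level states
  sexf <- ifelse(subjects$sex == "F", 1, 0)
  dga <- subjects$ga_weeks - config$ga_mean
  hbt_i <- (b$hbt + config$ga_slopes[["hbt"]] * dga) *
    ifelse(sexf == 1, config$sex_effects[["hbt"]], 1) *
    rlnorm0(n, config$between_sd[["hbt"]])
  so2_mu <- (b$so2 + config$ga_slopes[["so2"]] * dga) *
    ifelse(sexf == 1, config$sex_effects[["so2"]], 1)
  so2_i <- perturb_logit(clamp01(so2_mu), config$between_sd[["so2"]])
  cbfi_i <- b$cbfi * ifelse(sexf == 1, config$sex_effects[["cbfi"]], 1) *
    rlnorm0(n, config$between_sd[["cbfi"]])
  a_i <- b$a_500 * rlnorm0(n, config$between_sd[["a_500"]])
  bp_i <- b$b_power * rlnorm0(n, config$between_sd[["b_power"]])

  grid <- expand.grid(repetition = seq_len(config$repetitions_per_site),
                      location = config$locations,
                      subject = seq_len(n),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- nrow(grid)
  i <- grid$subject
  side <- location_side(grid$location)
  hbt <- hbt_i[i] * rlnorm0(m, config$within_sd[["hbt"]])
  so2 <- perturb_logit(so2_i[i], config$within_sd[["so2"]])
  cbfi <- cbfi_i[i] *
    ifelse(side == "right", config$hemisphere_effect, 1) *
    rlnorm0(m, config$within_sd[["cbfi"]])
  a_500 <- a_i[i] * rlnorm0(m, config$within_sd[["a_500"]])
  b_power <- bp_i[i] * rlnorm0(m, config$within_sd[["b_power"]])
  out <- data.frame(
    subject_id = subjects$subject_id[i],
    location = grid$location,
    side = side,
    lobe = location_lobe(grid$location),
    repetition = grid$repetition,
    hbo_um = so2 * hbt,
    hbr_um = (1 - so2) * hbt,
    hbt_um = hbt,
    so2_frac = so2,
    a_500 = a_500,
    b_power = b_power,
    cbfi_cm2s = cbfi,
    beta = b$beta,
    water_frac = b$water_fraction,
    sao2_frac = subjects$sao2_frac[i],
    stringsAsFactors = FALSE
  )
  # same ordering as the fitted results tables (subject, location, repetition)
  out <- out[order(out$subject_id, out$location, out$repetition), ]
  rownames(out) <- NULL
  out
}

#' Simulate a synthetic infant cohort
#'
#' Draws the demographic table and per-measurement ground-truth tissue
#' states, then emits raw multi-distance FDNIRS amplitude/phase time series
#' and raw DCS autocorrelation curves through the closed-form forward models
#' (\code{\link{fdnirs_forward}}, \code{\link{g2_forward}}). A fixed
#' per-channel instrument gain and phase offset (shared with
#' \code{\link{simulate_phantom}} via the returned \code{channels} table) is
#' applied so the phantom-calibration stage has real work to do.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param instrument an \code{\link{instrument_config}}.
#' @param table an \code{\link{extinction_table}}.
#' @param emit_raw if \code{FALSE}, skip raw-data generation and return only
#'   subjects + ground truth (fast path for statistical simulations).
#' @return object of class \code{synthetic_cohort}: list with
#'   \code{subjects}, \code{truth}, \code{fdnirs}, \code{dcs},
#'   \code{channels} (per-channel gain/offset) and the configs.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            instrument = instrument_config(),
                            table = extinction_table(),
                            emit_raw = TRUE) {
  if (config$n_male + config$n_female < 1) stop("cohort must have subjects")
  set.seed(config$seed)
  subjects <- simulate_subjects(config)
  truth <- simulate_truth(subjects, config)

  wl <- instrument$fdnirs_wavelengths
  rho <- instrument$fdnirs_distances
  channels <- expand.grid(rho_cm = rho, wavelength_nm = wl,
                          KEEP.OUT.ATTRS = FALSE)
  nch <- nrow(channels)
  channels$gain <- rlnorm0(nch, config$channel_gain_log_sd)
  channels$phase_offset <- if (config$channel_phase_offset_sd > 0) {
    rnorm(nch, 0, config$channel_phase_offset_sd)
  } else rep(0, nch)

  out <- list(subjects = subjects, truth = truth,
              channels = channels[, c("wavelength_nm", "rho_cm",
                                      "gain", "phase_offset")],
              config = config, instrument = instrument)
  if (!emit_raw) {
    out$fdnirs <- NULL
    out$dcs <- NULL
    class(out) <- "synthetic_cohort"
    return(out)
  }

  e <- extinction_at(table, wl)
  nm <- nrow(truth)
  ns <- n_fdnirs_samples(instrument)
  nw <- length(wl); nd <- length(rho)

  # per measurement x wavelength optical properties
  mua_mat <- outer(truth$hbo_um, e$eps_hbo) + outer(truth$hbr_um, e$eps_hbr) +
    outer(truth$water_frac, e$mua_water)                        # nm x nw
  musp_mat <- truth$a_500 %o% rep(1, nw) *
    exp(outer(-truth$b_power, log(wl / 500)))                   # nm x nw
  v <- light_speed_tissue(instrument)
  w <- omega_rad(instrument)
  s <- sqrt(1 + (w / (v * mua_mat))^2)
  half <- 3 * mua_mat * musp_mat / 2
  kr <- sqrt(half * (s + 1)); ki <- sqrt(half * (s - 1))

  # expand: rows ordered measurement (slowest) > wavelength > distance > sample
  gain_ch <- matrix(channels$gain, nrow = nd)            # nd x nw
  off_ch <- matrix(channels$phase_offset, nrow = nd)
  # per (meas, wl, dist): ln AC and phase, each then repeated ns times
  lnac0 <- rep(t(kr), each = nd) * (-rep(rho, times = nm * nw)) -
    2 * log(rep(rho, times = nm * nw)) +
    log(rep(as.vector(gain_ch), times = nm))
  ph0 <- rep(t(ki), each = nd) * rep(rho, times = nm * nw) +
    rep(as.vector(off_ch), times = nm)
  nrows <- nm * nw * nd * ns
  lnac <- rep(lnac0, each = ns)
  ph <- rep(ph0, each = ns)
  if (config$noise[["fdnirs_ln_ac"]] > 0) {
    lnac <- lnac + rnorm(nrows, 0, config$noise[["fdnirs_ln_ac"]])
  }
  if (config$noise[["fdnirs_phase"]] > 0) {
    ph <- ph + rnorm(nrows, 0, config$noise[["fdnirs_phase"]])
  }
  fdnirs <- data.frame(
    subject_id = rep(truth$subject_id, each = nw * nd * ns),
    location = rep(truth$location, each = nw * nd * ns),
    repetition = rep(truth$repetition, each = nw * nd * ns),
    wavelength_nm = rep(rep(wl, each = nd * ns), times = nm),
    rho_cm = rep(rep(rho, each = ns), times = nm * nw),
    sample_index = rep(seq_len(ns), times = nm * nw * nd),
    ac_amplitude = exp(lnac),
    phase_rad = ph,
    stringsAsFactors = FALSE
  )

  # DCS: mua at the DCS wavelength from the same spectral model
  e850 <- extinction_at(table, instrument$dcs_wavelength)
  mua850 <- truth$hbo_um * e850$eps_hbo + truth$hbr_um * e850$eps_hbr +
    truth$water_frac * e850$mua_water
  musp850 <- evaluate_mie(truth$a_500, truth$b_power,
                          instrument$dcs_wavelength)
  tau <- instrument$tau_grid
  ntau <- length(tau)
  ncv <- n_dcs_curves(instrument)
  g2_list <- vector("list", nm)
  for (j in seq_len(nm)) {
    g1 <- g1_semi_infinite(tau, mua850[j], musp850[j], truth$cbfi_cm2s[j],
                           instrument)
    g2_list[[j]] <- rep(1 + truth$beta[j] * g1^2, times = ncv)
  }
  g2 <- unlist(g2_list, use.names = FALSE)
  if (config$noise[["dcs_g2"]] > 0) {
    g2 <- g2 + rnorm(length(g2), 0, config$noise[["dcs_g2"]])
  }
  dcs <- data.frame(
    subject_id = rep(truth$subject_id, each = ncv * ntau),
    location = rep(truth$location, each = ncv * ntau),
    repetition = rep(truth$repetition, each = ncv * ntau),
    curve_index = rep(rep(seq_len(ncv), each = ntau), times = nm),
    tau_s = rep(tau, times = nm * ncv),
    g2 = g2,
    stringsAsFactors = FALSE
  )

  out$fdnirs <- fdnirs
  out$dcs <- dcs
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects (%d M / %d F), %d sites x %d repetitions\n",
              nrow(x$subjects), sum(x$subjects$sex == "M"),
              sum(x$subjects$sex == "F"), length(x$config$locations),
              x$config$repetitions_per_site))
  cat(sprintf("  %d ground-truth measurements; raw data: %s\n",
              nrow(x$truth),
              if (is.null(x$fdnirs)) "not emitted" else
                sprintf("%d FDNIRS rows, %d DCS rows",
                        nrow(x$fdnirs), nrow(x$dcs))))
  invisible(x)
}

#' Simulate a solid-phantom calibration measurement
#'
#' Forward-models FDNIRS data for a homogeneous phantom with known optical
#' properties, injecting per-channel gain and phase distortions, so the
#' calibration stage can be exercised end to end.
#'
#' @param known_mua,known_musp phantom optical properties per instrument
#'   wavelength (cm^-1).
#' @param instrument an \code{\link{instrument_config}}.
#' @param channels optional data.frame (\code{wavelength_nm}, \code{rho_cm},
#'   \code{gain}, \code{phase_offset}); identity distortions by default.
#' @param noise_ln_ac,noise_phase Gaussian noise SDs per sample.
#' @param n_samples samples per channel.
#' @return raw FDNIRS-style data.frame with columns \code{wavelength_nm},
#'   \code{rho_cm}, \code{sample_index}, \code{ac_amplitude},
#'   \code{phase_rad}.
#' @export
simulate_phantom <- function(known_mua, known_musp,
                             instrument = instrument_config(),
                             channels = NULL,
                             noise_ln_ac = 0, noise_phase = 0,
                             n_samples = NULL) {
  wl <- instrument$fdnirs_wavelengths
  if (length(known_mua) != length(wl) || length(known_musp) != length(wl)) {
    stop("known phantom properties must match the instrument wavelength list")
  }
  if (is.null(n_samples)) n_samples <- n_fdnirs_samples(instrument)
  rho <- instrument$fdnirs_distances
  if (is.null(channels)) {
    channels <- expand.grid(rho_cm = rho, wavelength_nm = wl,
                            KEEP.OUT.ATTRS = FALSE)
    channels$gain <- 1
    channels$phase_offset <- 0
  }
  parts <- vector("list", length(wl))
  for (j in seq_along(wl)) {
    ch <- channels[channels$wavelength_nm == wl[j], ]
    ch <- ch[match(rho, ch$rho_cm), ]
    if (anyNA(ch$gain)) stop("channels table missing entries for ", wl[j], " nm")
    d <- fdnirs_forward(known_mua[j], known_musp[j], instrument,
                        gain = ch$gain, phase_offset = ch$phase_offset,
                        noise_ln_ac = noise_ln_ac, noise_phase = noise_phase,
                        n_samples = n_samples)
    d$wavelength_nm <- wl[j]
    parts[[j]] <- d
  }
  out <- do.call(rbind, parts)
  out[, c("wavelength_nm", "rho_cm", "sample_index",
          "ac_amplitude", "phase_rad")]
}
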