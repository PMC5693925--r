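# FDNIRS calibration and multi-distance slope inversion.

#' Calibrate FDNIRS channels against a solid phantom
#'
#' Derives a per-channel (wavelength x distance) amplitude gain and phase
#' offset by comparing the median measured phantom amplitude/phase with the
#' semi-infinite DPDW model prediction for the phantom's known optical
#' properties: \code{amplitude_gain = predicted / measured} and
#' \code{phase_offset = measured - predicted}. Applying the factors to
#' subject data (see \code{\link{apply_calibration}}) removes instrument
#' gains and phase offsets.
#'
#' @param phantom_raw raw phantom table with columns \code{wavelength_nm},
#'   \code{rho_cm}, \code{ac_amplitude}, \code{phase_rad} (e.g. from
#'   \code{\link{simulate_phantom}}).
#' @param known_mua,known_musp phantom optical properties, one value per
#'   instrument wavelength (cm^-1).
#' @param instrument an \code{\link{instrument_config}}.
#' @return data.frame of class \code{calibration_factors} with one row per
#'   channel: \code{wavelength_nm}, \code{rho_cm}, \code{amplitude_gain},
#'   \code{phase_offset}.
#' @export
calibrate <- function(phantom_raw, known_mua, known_musp,
                      instrument = instrument_config()) {
  wl <- instrument$fdnirs_wavelengths
  rho <- instrument$fdnirs_distances
  if (length(known_mua) != length(wl) || length(known_musp) != length(wl)) {
    stop("known phantom properties must have one value per instrument wavelength")
  }
  need <- c("wavelength_nm", "rho_cm", "ac_amplitude", "phase_rad")
  missing <- setdiff(need, names(phantom_raw))
  if (length(missing)) stop("phantom_raw lacks column(s): ",
                            paste(missing, collapse = ", "))
  grid <- expand.grid(rho_cm = rho, wavelength_nm = wl,
                      KEEP.OUT.ATTRS = FALSE)
  out <- grid[, c("wavelength_nm", "rho_cm")]
  out$amplitude_gain <- NA_real_
  out$phase_offset <- NA_real_
  for (i in seq_len(nrow(out))) {
    j <- which(wl == out$wavelength_nm[i])
    sel <- phantom_raw$wavelength_nm == out$wavelength_nm[i] &
      phantom_raw$rho_cm == out$rho_cm[i]
    if (!any(sel)) {
      stop(sprintf("phantom data missing channel (%g nm, %g cm)",
                   out$wavelength_nm[i], out$rho_cm[i]))
    }
    meas_ac <- stats::median(phantom_raw$ac_amplitude[sel])
    meas_ph <- stats::median(phantom_raw$phase_rad[sel])
    k <- dpdw_wavenumbers(known_mua[j], known_musp[j], instrument)
    r <- out$rho_cm[i]
    model_ac <- exp(-k$k_real * r) / r^2
    model_ph <- k$k_imag * r
    out$amplitude_gain[i] <- model_ac / meas_ac
    out$phase_offset[i] <- meas_ph - model_ph
  }
  class(out) <- c("calibration_factors", "data.frame")
  out
}

#' Apply calibration factors to raw FDNIRS data
#'
#' @param raw raw FDNIRS table (columns \code{wavelength_nm}, \code{rho_cm},
#'   \code{ac_amplitude}, \code{phase_rad}, plus any identifiers).
#' @param factors a \code{\link{calibrate}} result.
#' @return the table with calibrated \code{ac_amplitude} and \code{phase_rad}.
#' @export
apply_calibration <- function(raw, factors) {
  # numeric channel key: wavelengths (nm) and distances (cm) are < 1e4
  key_raw <- raw$wavelength_nm * 1e4 + raw$rho_cm
  key_fac <- factors$wavelength_nm * 1e4 + factors$rho_cm
  idx <- match(key_raw, key_fac)
  if (anyNA(idx)) {
    bad <- unique(paste(raw$wavelength_nm, raw$rho_cm)[is.na(idx)])
    stop("calibration factors missing for channel(s): ",
         paste(bad, collapse = "; "))
  }
  raw$ac_amplitude <- raw$ac_amplitude * factors$amplitude_gain[idx]
  raw$phase_rad <- raw$phase_rad - factors$phase_offset[idx]
  raw
}

#' Reduce one channel's time series to medians
#'
#' The study reduces the ~100 samples of each (wavelength, distance) channel
#' to their median amplitude and phase before slope fitting; the standard
#' deviation of the phase samples is retained as the channel's phase noise
#' for quality control.
#'
#' @param ac_amplitude,phase_rad numeric vectors of samples (same length, >= 1).
#' @return list with \code{ac_median}, \code{phase_median}, \code{phase_noise}.
#' @export
temporal_median <- function(ac_amplitude, phase_rad) {
  if (length(ac_amplitude) < 1 || length(phase_rad) < 1) {
    stop("empty channel series")
  }
  pn <- if (length(phase_rad) > 1) stats::sd(phase_rad) else 0
  list(ac_median = stats::median(ac_amplitude),
       phase_median = stats::median(phase_rad),
       phase_noise = pn)
}

# slope and R^2 of an ordinary least-squares line (closed form)
ols_line <- function(x, y) {
  sxx <- stats::var(x)
  slope <- stats::cov(x, y) / sxx
  r2 <- if (stats::var(y) > 0) stats::cor(x, y)^2 else 1
  list(slope = slope, r2 = r2)
}

#' Multi-distance slope inversion for absorption and scattering
#'
#' Fits ordinary least-squares lines to \eqn{\ln(AC\cdot\rho^2)} and phase
#' versus distance. Identifying the negated amplitude slope with the real
#' DPDW wavenumber (\eqn{S_{AC} = k_{re}}) and the phase slope with the
#' imaginary one (\eqn{S_\phi = k_{im}}), the exact inversions are
#' \deqn{\mu_s' = \frac{2v}{3\omega} S_{AC} S_\phi, \qquad
#'       \mu_a = \frac{\omega}{2v}\left(\frac{S_{AC}}{S_\phi} -
#'               \frac{S_\phi}{S_{AC}}\right).}
#'
#' @param ac_median,phase_median median amplitude and phase per distance.
#' @param rho source-detector distances in cm (>= 3 finite values required).
#' @param instrument an \code{\link{instrument_config}}.
#' @param phase_noise optional worst-channel phase noise (rad), carried into
#'   the returned object for quality control.
#' @return object of class \code{slope_fit}: \code{mua}, \code{musp},
#'   \code{s_ac}, \code{s_phase}, \code{r2_ac}, \code{r2_phase},
#'   \code{phase_noise}, \code{valid}.
#' @export
multidistance_fit <- function(ac_median, phase_median, rho,
                              instrument = instrument_config(),
                              phase_noise = NA_real_) {
  ok <- is.finite(ac_median) & ac_median > 0 & is.finite(phase_median) &
    is.finite(rho)
  if (sum(ok) < 3) stop("need at least 3 distances with finite values")
  rho <- rho[ok]
  lnac <- log(ac_median[ok] * rho^2)
  ph <- phase_median[ok]
  fa <- ols_line(rho, lnac)
  fp <- ols_line(rho, ph)
  s_ac <- -fa$slope
  s_phase <- fp$slope
  valid <- is.finite(s_ac) && is.finite(s_phase) && s_ac > 0 && s_phase > 0
  v <- light_speed_tissue(instrument)
  w <- omega_rad(instrument)
  if (valid) {
    musp <- (2 * v / (3 * w)) * s_ac * s_phase
    mua <- (w / (2 * v)) * (s_ac / s_phase - s_phase / s_ac)
    valid <- valid && is.finite(mua) && is.finite(musp) && musp > 0 && mua >= 0
  } else {
    mua <- NA_real_; musp <- NA_real_
  }
  structure(list(mua = mua, musp = musp,
                 s_ac = s_ac, s_phase = s_phase,
                 r2_ac = fa$r2, r2_phase = fp$r2,
                 phase_noise = phase_noise, valid = valid),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("multi-distance slope fit: mua = %.4f, mus' = %.3f cm^-1%s\n",
              x$mua, x$musp, if (!x$valid) "  [INVALID]" else ""))
  cat(sprintf("  slopes: S_AC = %.4f, S_phi = %.4f cm^-1; R^2 = %.4f / %.4f; phase noise = %s rad\n",
              x$s_ac, x$s_phase, x$r2_ac, x$r2_phase,
              ifelse(is.na(x$phase_noise), "NA",
                     sprintf("%.4f", x$phase_noise))))
  invisible(x)
}

#' FDNIRS slope-fit quality control
#'
#' A wavelength's slope fit is kept iff the worst-channel phase noise does
#' not exceed \code{phase_noise_max} (study threshold 0.05 rad), both
#' regression R^2 values are at least \code{r2_min} (study threshold 0.95),
#' and the inverted coefficients are physical. Comparisons are inclusive on
#' the keep side.
#'
#' @param fit a \code{\link{multidistance_fit}} result.
#' @param phase_noise_max,r2_min thresholds.
#' @return logical.
#' @export
fdnirs_qc <- function(fit, phase_noise_max = 0.05, r2_min = 0.95) {
  pn_ok <- is.na(fit$phase_noise) || fit$phase_noise <= phase_noise_max
  isTRUE(fit$valid) && pn_ok &&
    is.finite(fit$r2_ac) && is.finite(fit$r2_phase) &&
    fit$r2_ac >= r2_min && fit$r2_phase >= r2_min
}
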