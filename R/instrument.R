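#' Instrument configuration
#'
#' Describes the hybrid FDNIRS-DCS instrument: an intensity-modulated
#' (110 MHz) frequency-domain NIRS channel measured at 8 near-infrared
#' wavelengths and 4 source-detector separations, and a DCS channel at 850 nm
#' and 2 cm separation whose correlator reports intensity autocorrelation on a
#' log-spaced lag grid.
#'
#' @param modulation_frequency FDNIRS source modulation frequency in Hz.
#' @param fdnirs_wavelengths FDNIRS laser wavelengths in nm.
#' @param fdnirs_distances source-detector separations in cm, strictly
#'   increasing.
#' @param dcs_wavelength DCS laser wavelength in nm.
#' @param dcs_distance DCS source-detector separation in cm.
#' @param tau_grid autocorrelation lag grid in seconds, strictly increasing.
#' @param refractive_index tissue refractive index (dimensionless).
#' @param fdnirs_rate FDNIRS sampling rate in Hz.
#' @param dcs_rate DCS curve rate in Hz.
#' @param acquisition_duration duration of one measurement in seconds.
#'
#' @return An object of class \code{instrument_config} (a validated list).
#' @export
#' @examples
#' inst <- instrument_config()
#' inst$fdnirs_wavelengths
instrument_config <- function(modulation_frequency = 110e6,
                              fdnirs_wavelengths = c(672, 689, 701, 724,
                                                     771, 783, 803, 829),
                              fdnirs_distances = c(1.5, 2.0, 2.5, 3.0),
                              dcs_wavelength = 850,
                              dcs_distance = 2.0,
                              tau_grid = 10^seq(-7, -1, length.out = 128),
                              refractive_index = 1.4,
                              fdnirs_rate = 10,
                              dcs_rate = 1.2,
                              acquisition_duration = 10) {
  stopifnot(
    is.numeric(modulation_frequency), modulation_frequency > 0,
    all(fdnirs_wavelengths > 0), all(fdnirs_distances > 0),
    all(diff(fdnirs_distances) > 0),
    dcs_wavelength > 0, dcs_distance > 0,
    all(tau_grid > 0), all(diff(tau_grid) > 0),
    refractive_index > 0, fdnirs_rate > 0, dcs_rate > 0,
    acquisition_duration > 0
  )
  structure(list(
    modulation_frequency = modulation_frequency,
    fdnirs_wavelengths = fdnirs_wavelengths,
    fdnirs_distances = fdnirs_distances,
    dcs_wavelength = dcs_wavelength,
    dcs_distance = dcs_distance,
    tau_grid = tau_grid,
    refractive_index = refractive_index,
    fdnirs_rate = fdnirs_rate,
    dcs_rate = dcs_rate,
    acquisition_duration = acquisition_duration
  ), class = "instrument_config")
}

# angular modulation frequency (rad/s)
omega_rad <- function(instrument) 2 * pi * instrument$modulation_frequency

# speed of light in the tissue (cm/s)
light_speed_tissue <- function(instrument) .C_LIGHT_CM_S / instrument$refractive_index

# number of FDNIRS samples / DCS curves in one acquisition
n_fdnirs_samples <- function(instrument) {
  round(instrument$fdnirs_rate * instrument$acquisition_duration)
}
n_dcs_curves <- function(instrument) {
  floor(instrument$dcs_rate * instrument$acquisition_duration)
}

#' @export
print.instrument_config <- function(x, ...) {
  cat("FDNIRS-DCS instrument configuration\n")
  cat(sprintf("  modulation: %.0f MHz, n = %.2f\n",
              x$modulation_frequency / 1e6, x$refractive_index))
  cat(sprintf("  FDNIRS: %d wavelengths (%s nm), distances %s cm, %g Hz\n",
              length(x$fdnirs_wavelengths),
              paste(x$fdnirs_wavelengths, collapse = ", "),
              paste(x$fdnirs_distances, collapse = ", "),
              x$fdnirs_rate))
  cat(sprintf("  DCS: %g nm at %g cm, %d-point tau grid [%.1e, %.1e] s, %g Hz\n",
              x$dcs_wavelength, x$dcs_distance, length(x$tau_grid),
              min(x$tau_grid), max(x$tau_grid), x$dcs_rate))
  cat(sprintf("  acquisition: %g s\n", x$acquisition_duration))
  invisible(x)
}
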