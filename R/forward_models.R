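#' Diffuse photon density wave (DPDW) wavenumbers
#'
#' Real and imaginary parts of the complex wavenumber of the damped spherical
#' wave solving the frequency-domain photon diffusion equation in a
#' homogeneous medium. For source modulation at angular frequency
#' \eqn{\omega} and light speed in tissue \eqn{v = c/n},
#' \deqn{k_{re} = \sqrt{\tfrac{3\mu_a\mu_s'}{2}\left(\sqrt{1+(\omega/v\mu_a)^2}+1\right)},\quad
#'       k_{im} = \sqrt{\tfrac{3\mu_a\mu_s'}{2}\left(\sqrt{1+(\omega/v\mu_a)^2}-1\right)}.}
#' In the semi-infinite multi-distance geometry \eqn{k_{re}} is the decay rate
#' of \eqn{\ln(AC\cdot\rho^2)} with distance and \eqn{k_{im}} the phase slope.
#' The pair satisfies the exact identities
#' \eqn{k_{re}^2 - k_{im}^2 = 3\mu_a\mu_s'} and
#' \eqn{k_{re} k_{im} = 3\mu_s'\omega/(2v)}.
#'
#' @param mua absorption coefficient(s), cm^-1, > 0.
#' @param musp reduced scattering coefficient(s), cm^-1, > 0.
#' @param instrument an \code{\link{instrument_config}}.
#' @return list with numeric vectors \code{k_real} and \code{k_imag} (cm^-1).
#' @export
#' @examples
#' dpdw_wavenumbers(0.1, 10, instrument_config())
dpdw_wavenumbers <- function(mua, musp, instrument = instrument_config()) {
  if (any(!is.finite(mua)) || any(mua <= 0)) {
    stop("mua must be positive and finite")
  }
  if (any(!is.finite(musp)) || any(musp <= 0)) {
    stop("musp must be positive and finite")
  }
  v <- light_speed_tissue(instrument)
  w <- omega_rad(instrument)
  s <- sqrt(1 + (w / (v * mua))^2)
  half <- 3 * mua * musp / 2
  list(
    k_real = sqrt(half * (s + 1)),
    k_imag = sqrt(half * (s - 1))
  )
}

#' Simulate raw multi-distance FDNIRS data
#'
#' Emits AC amplitude and phase time series at each source-detector distance
#' for one tissue and one wavelength, using the semi-infinite DPDW decay
#' \eqn{AC(\rho) = g\,e^{-k_{re}\rho}/\rho^2} and
#' \eqn{\phi(\rho) = k_{im}\rho + \phi_0}. Amplitude units are arbitrary
#' (per-channel gain); optional Gaussian noise is applied to
#' \eqn{\ln AC} and to the phase independently per sample.
#'
#' @param mua,musp tissue optical properties at this wavelength (cm^-1).
#' @param instrument an \code{\link{instrument_config}}.
#' @param gain amplitude gain, scalar or one value per distance.
#' @param phase_offset phase offset in rad, scalar or one per distance.
#' @param noise_ln_ac standard deviation of Gaussian noise on ln(AC), >= 0.
#' @param noise_phase standard deviation of Gaussian phase noise in rad, >= 0.
#' @param n_samples number of time samples per channel; defaults to
#'   \code{fdnirs_rate * acquisition_duration}.
#' @return data.frame with columns \code{rho_cm}, \code{sample_index},
#'   \code{ac_amplitude}, \code{phase_rad}.
#' @export
fdnirs_forward <- function(mua, musp, instrument = instrument_config(),
                           gain = 1, phase_offset = 0,
                           noise_ln_ac = 0, noise_phase = 0,
                           n_samples = NULL) {
  if (noise_ln_ac < 0 || noise_phase < 0) stop("noise std must be >= 0")
  if (is.null(n_samples)) n_samples <- n_fdnirs_samples(instrument)
  rho <- instrument$fdnirs_distances
  nd <- length(rho)
  gain <- rep_len(gain, nd)
  phase_offset <- rep_len(phase_offset, nd)
  if (any(gain <= 0)) stop("gain must be positive")
  k <- dpdw_wavenumbers(mua, musp, instrument)
  ac0 <- gain * exp(-k$k_real * rho) / rho^2
  ph0 <- k$k_imag * rho + phase_offset
  n <- nd * n_samples
  ln_ac <- rep(log(ac0), each = n_samples)
  ph <- rep(ph0, each = n_samples)
  if (noise_ln_ac > 0) ln_ac <- ln_ac + rnorm(n, 0, noise_ln_ac)
  if (noise_phase > 0) ph <- ph + rnorm(n, 0, noise_phase)
  data.frame(
    rho_cm = rep(rho, each = n_samples),
    sample_index = rep(seq_len(n_samples), times = nd),
    ac_amplitude = exp(ln_ac),
    phase_rad = ph
  )
}

# Extrapolated zero-boundary distance (cm) for the semi-infinite geometry,
# using the effective-reflection approximation R_eff = 0.493 for n = 1.4.
extrapolated_boundary <- function(musp, refractive_index = 1.4) {
  reff <- 0.493
  (2 / (3 * musp)) * (1 + reff) / (1 - reff)
}

# Wavenumber of light in the medium, cm^-1 (wavelength in nm).
light_wavenumber <- function(wavelength_nm, refractive_index = 1.4) {
  2 * pi * refractive_index / (wavelength_nm * 1e-7)
}

#' Normalized field autocorrelation for the semi-infinite medium
#'
#' Evaluates the semi-infinite homogeneous solution of the correlation
#' diffusion equation,
#' \deqn{G_1(\rho,\tau) = \frac{3\mu_s'}{4\pi}\left[\frac{e^{-K(\tau) r_1}}{r_1}
#'   - \frac{e^{-K(\tau) r_b}}{r_b}\right],}
#' with \eqn{K(\tau) = \sqrt{3\mu_a\mu_s' + 6\mu_s'^2 k_0^2\,\mathrm{CBFi}\,\tau}},
#' \eqn{r_1 = \sqrt{\rho^2 + (1/\mu_s')^2}},
#' \eqn{r_b = \sqrt{\rho^2 + (1/\mu_s' + 2 z_b)^2}}, \eqn{z_b} the extrapolated
#' zero boundary and \eqn{k_0 = 2\pi n/\lambda} the wavenumber of light in the
#' medium, and returns the normalized \eqn{g_1(\tau) = G_1(\rho,\tau)/G_1(\rho,0)}.
#' Red-blood-cell motion is modeled as effective Brownian diffusion with
#' diffusion coefficient CBFi (cm^2/s).
#'
#' @param tau lag times in seconds, >= 0 (vectorized).
#' @param mua,musp optical properties at the DCS wavelength (cm^-1).
#' @param cbfi blood flow index, cm^2/s, >= 0.
#' @param instrument an \code{\link{instrument_config}} (supplies \code{rho},
#'   DCS wavelength and refractive index).
#' @return numeric vector of \eqn{g_1(\tau)} values in [0, 1].
#' @export
#' @examples
#' g1_semi_infinite(1e-5, mua = 0.1, musp = 6.4, cbfi = 2.1e-8)
g1_semi_infinite <- function(tau, mua, musp, cbfi,
                             instrument = instrument_config()) {
  if (any(tau < 0)) stop("tau must be >= 0")
  stopifnot(mua > 0, musp > 0, cbfi >= 0)
  rho <- instrument$dcs_distance
  n <- instrument$refractive_index
  k0 <- light_wavenumber(instrument$dcs_wavelength, n)
  zb <- extrapolated_boundary(musp, n)
  r1 <- sqrt(rho^2 + (1 / musp)^2)
  rb <- sqrt(rho^2 + (1 / musp + 2 * zb)^2)
  G1 <- function(tt) {
    K <- sqrt(3 * mua * musp + 6 * musp^2 * k0^2 * cbfi * tt)
    exp(-K * r1) / r1 - exp(-K * rb) / rb
  }
  G1(tau) / G1(0)
}

#' Simulate DCS intensity autocorrelation curves
#'
#' Generates \code{n_curves} intensity autocorrelation curves on the
#' instrument's lag grid via the Siegert relation
#' \eqn{g_2(\tau) = 1 + \beta g_1^2(\tau)}, optionally adding zero-mean
#' Gaussian noise with a constant (or per-lag) standard deviation.
#'
#' @param mua,musp optical properties at the DCS wavelength (cm^-1).
#' @param cbfi blood flow index, cm^2/s.
#' @param beta coherence factor in (0, 1].
#' @param instrument an \code{\link{instrument_config}}.
#' @param n_curves number of curves (the study correlator emits 12 per 10 s).
#' @param noise_sd Gaussian noise standard deviation per g2 sample; scalar or
#'   one value per lag bin.
#' @param seed optional integer seed for bit-reproducible noise.
#' @return object of class \code{dcs_measurement}: list with \code{tau_s},
#'   \code{curves} (n_curves x n_tau matrix) and \code{rho_cm}.
#' @export
g2_forward <- function(mua, musp, cbfi, beta,
                       instrument = instrument_config(),
                       n_curves = NULL, noise_sd = 0, seed = NULL) {
  stopifnot(beta > 0, beta <= 1)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  if (is.null(n_curves)) n_curves <- n_dcs_curves(instrument)
  if (n_curves < 1) stop("n_curves must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  tau <- instrument$tau_grid
  g1 <- g1_semi_infinite(tau, mua, musp, cbfi, instrument)
  base <- 1 + beta * g1^2
  curves <- matrix(base, nrow = n_curves, ncol = length(tau), byrow = TRUE)
  if (any(noise_sd > 0)) {
    sd_row <- rep_len(noise_sd, length(tau))
    noise <- matrix(rnorm(n_curves * length(tau)), nrow = n_curves) *
      matrix(sd_row, nrow = n_curves, ncol = length(tau), byrow = TRUE)
    curves <- curves + noise
  }
  structure(list(tau_s = tau, curves = curves,
                 rho_cm = instrument$dcs_distance),
            class = "dcs_measurement")
}

#' @export
print.dcs_measurement <- function(x, ...) {
  cat(sprintf("DCS measurement: %d curve(s), %d lag bins [%.1e, %.1e] s, rho = %g cm\n",
              nrow(x$curves), length(x$tau_s), min(x$tau_s), max(x$tau_s),
              x$rho_cm))
  invisible(x)
}
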