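#' Load the bundled chromophore extinction table
#'
#' Reads the packaged table of oxy-/deoxyhemoglobin extinction coefficients
#' (cm^-1 per uM, natural-log base) and pure-water absorption (cm^-1) at the
#' 8 FDNIRS wavelengths and 850 nm, or a user-supplied CSV with the same
#' columns (\code{wavelength_nm}, \code{eps_hbo}, \code{eps_hbr},
#' \code{mua_water}; \code{#} comment lines allowed).
#'
#' @param path optional path to an alternative table.
#' @return data.frame of class \code{extinction_table}.
#' @export
extinction_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "extinction_coefficients.csv",
                        package = "neoflow", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, comment.char = "#")
  required <- c("wavelength_nm", "eps_hbo", "eps_hbr", "mua_water")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("extinction table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(tab$eps_hbo < 0) || any(tab$eps_hbr < 0) || any(tab$mua_water < 0)) {
    stop("extinction table entries must be >= 0")
  }
  tab <- tab[order(tab$wavelength_nm), required]
  class(tab) <- c("extinction_table", "data.frame")
  tab
}

# Interpolate extinction / water columns at arbitrary wavelengths (nm).
extinction_at <- function(table, wavelengths) {
  rng <- range(table$wavelength_nm)
  if (any(wavelengths < rng[1] | wavelengths > rng[2])) {
    stop("requested wavelength outside the extinction table range [",
         rng[1], ", ", rng[2], "] nm")
  }
  interp <- function(col) {
    stats::approx(table$wavelength_nm, table[[col]], xout = wavelengths)$y
  }
  data.frame(wavelength_nm = wavelengths,
             eps_hbo = interp("eps_hbo"),
             eps_hbr = interp("eps_hbr"),
             mua_water = interp("mua_water"))
}

#' Ground-truth tissue state
#'
#' Bundles the optical and physiological parameters of one tissue volume used
#' by the forward models: hemoglobin concentrations, water fraction, the Mie
#' power-law scattering parameters, the blood flow index, the DCS coherence
#' factor, and arterial saturation.
#'
#' @param hbo,hbr oxy-/deoxyhemoglobin concentrations, uM, >= 0.
#' @param water_fraction volumetric water fraction in [0, 1] (brain default 0.75).
#' @param a_500 reduced scattering at 500 nm, cm^-1, > 0.
#' @param b_power scattering power (dimensionless).
#' @param cbfi blood flow index, cm^2/s, >= 0.
#' @param beta DCS coherence factor in (0, 1].
#' @param sao2 arterial oxygen saturation fraction in [0, 1].
#' @return object of class \code{tissue_state}.
#' @export
tissue_state <- function(hbo, hbr, water_fraction = 0.75,
                         a_500 = 13.7, b_power = 1.43,
                         cbfi = 2.1e-8, beta = 0.5, sao2 = 0.97) {
  stopifnot(hbo >= 0, hbr >= 0, a_500 > 0, cbfi >= 0,
            water_fraction >= 0, water_fraction <= 1,
            sao2 >= 0, sao2 <= 1, beta > 0, beta <= 1)
  structure(list(hbo = hbo, hbr = hbr, water_fraction = water_fraction,
                 a_500 = a_500, b_power = b_power, cbfi = cbfi,
                 beta = beta, sao2 = sao2),
            class = "tissue_state")
}

#' @export
print.tissue_state <- function(x, ...) {
  hbt <- x$hbo + x$hbr
  cat(sprintf(paste0("tissue state: HbO %.2f, HbR %.2f, HbT %.2f uM ",
                     "(SO2 %.1f%%), water %.2f\n"),
              x$hbo, x$hbr, hbt, if (hbt > 0) 100 * x$hbo / hbt else NA,
              x$water_fraction))
  cat(sprintf("  mus' = %.2f (lambda/500)^-%.2f cm^-1; CBFi %.3g cm^2/s; beta %.2f; SaO2 %.2f\n",
              x$a_500, x$b_power, x$cbfi, x$beta, x$sao2))
  invisible(x)
}

#' Spectral forward model for one tissue state
#'
#' Absorption from the chromophore mixing model
#' \eqn{\mu_a(\lambda) = \varepsilon_{HbO}(\lambda)\,C_{HbO} +
#' \varepsilon_{HbR}(\lambda)\,C_{HbR} + f_{H_2O}\,\mu_{a,H_2O}(\lambda)} and
#' reduced scattering from the Mie power law.
#'
#' @param tissue a \code{\link{tissue_state}}.
#' @param wavelengths wavelengths in nm.
#' @param table an \code{\link{extinction_table}}.
#' @return data.frame with \code{wavelength_nm}, \code{mua}, \code{musp}.
#' @export
tissue_optics <- function(tissue, wavelengths, table = extinction_table()) {
  e <- extinction_at(table, wavelengths)
  data.frame(
    wavelength_nm = wavelengths,
    mua = e$eps_hbo * tissue$hbo + e$eps_hbr * tissue$hbr +
      tissue$water_fraction * e$mua_water,
    musp = evaluate_mie(tissue$a_500, tissue$b_power, wavelengths)
  )
}

#' Mie scattering power law
#'
#' \eqn{\mu_s'(\lambda) = a\,(\lambda/500\,\mathrm{nm})^{-b}} where \eqn{a}
#' reflects scatterer number density and \eqn{b} (the scattering power) the
#' effective particle size.
#'
#' @param a_500 reduced scattering at the 500 nm reference, cm^-1.
#' @param b_power scattering power.
#' @param wavelength wavelength(s), nm, > 0.
#' @return reduced scattering coefficient(s), cm^-1.
#' @export
#' @examples
#' evaluate_mie(13.7, 1.43, 850) # the fixed DCS-wavelength scattering value
evaluate_mie <- function(a_500, b_power, wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  a_500 * (wavelength / 500)^(-b_power)
}

# 2-chromophore nonnegative least squares: active-set at p = 2.
nnls2 <- function(E, y) {
  fit2 <- function(cols) {
    Ec <- E[, cols, drop = FALSE]
    drop(solve(crossprod(Ec), crossprod(Ec, y)))
  }
  cf <- fit2(1:2)
  if (all(cf >= 0)) return(cf)
  # clamp the negative one(s) to zero, refit the other
  out <- c(0, 0)
  if (cf[1] < 0 && cf[2] < 0) {
    # try each single-chromophore fit, keep the better feasible one
    c1 <- max(fit2(1), 0); c2 <- max(fit2(2), 0)
    ss1 <- sum((y - E[, 1] * c1)^2); ss2 <- sum((y - E[, 2] * c2)^2)
    if (ss1 <= ss2) out[1] <- c1 else out[2] <- c2
    return(out)
  }
  keep <- if (cf[1] < 0) 2L else 1L
  out[keep] <- max(fit2(keep), 0)
  out
}

#' Fit hemoglobin concentrations to an absorption spectrum
#'
#' Subtracts the assumed water contribution from the measured
#' \eqn{\mu_a(\lambda)} and solves the linear mixing model for oxy- and
#' deoxyhemoglobin concentrations by nonnegative least squares. Reports
#' HbT = HbO + HbR, SO2 = HbO/HbT, a goodness-of-fit R^2 (squared correlation
#' between measured and reconstructed \eqn{\mu_a}) and the regression F-test
#' p-value.
#'
#' @param mua measured absorption coefficients, cm^-1 (one per wavelength).
#' @param wavelengths wavelengths in nm (>= 2 required).
#' @param table an \code{\link{extinction_table}}.
#' @param water_fraction assumed water fraction (brain default 0.75).
#' @return object of class \code{chromophore_fit}: hbo, hbr, hbt (uM), so2
#'   (fraction), fit_r2, fit_pvalue, fitted values and residuals.
#' @export
fit_chromophores <- function(mua, wavelengths, table = extinction_table(),
                             water_fraction = 0.75) {
  ok <- is.finite(mua) & is.finite(wavelengths)
  mua <- mua[ok]; wavelengths <- wavelengths[ok]
  if (length(mua) < 2) stop("need at least 2 usable wavelengths")
  e <- extinction_at(table, wavelengths)
  y <- mua - water_fraction * e$mua_water
  E <- cbind(hbo = e$eps_hbo, hbr = e$eps_hbr)
  cf <- nnls2(E, y)
  fitted_mua <- drop(E %*% cf) + water_fraction * e$mua_water
  res <- mua - fitted_mua
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  n <- length(y); p <- 2L
  r2 <- if (stats::var(mua) > 0 && stats::var(fitted_mua) > 0) {
    stats::cor(mua, fitted_mua)^2
  } else if (ss_res < 1e-24) 1 else 0
  pval <- if (n > p) {
    if (ss_res < 1e-24) 0 else {
      f <- max(ss_tot - ss_res, 0) / p / (ss_res / (n - p))
      stats::pf(f, p, n - p, lower.tail = FALSE)
    }
  } else NA_real_
  hbt <- cf[1] + cf[2]
  structure(list(
    hbo = unname(cf[1]), hbr = unname(cf[2]), hbt = unname(hbt),
    so2 = if (hbt > 0) unname(cf[1] / hbt) else NA_real_,
    fit_r2 = r2, fit_pvalue = pval,
    wavelengths = wavelengths, mua = mua, fitted = fitted_mua,
    residuals = res, water_fraction = water_fraction
  ), class = "chromophore_fit")
}

#' @export
print.chromophore_fit <- function(x, ...) {
  cat(sprintf("chromophore fit: HbO %.2f, HbR %.2f, HbT %.2f uM, SO2 %.1f%%\n",
              x$hbo, x$hbr, x$hbt, 100 * x$so2))
  cat(sprintf("  %d wavelengths, R^2 = %.4f, p = %.3g (water fraction %.2f)\n",
              length(x$wavelengths), x$fit_r2, x$fit_pvalue,
              x$water_fraction))
  invisible(x)
}

#' @export
coef.chromophore_fit <- function(object, ...) {
  c(hbo = object$hbo, hbr = object$hbr)
}

#' Fit the Mie power law to a scattering spectrum
#'
#' Linear regression of \eqn{\ln\mu_s'} on \eqn{\ln(\lambda/500)}: the slope
#' estimates \eqn{-b} and the intercept \eqn{\ln a}. Exact on data generated
#' by the power law. Reports R^2 and the regression F-test p-value.
#'
#' @param musp measured reduced scattering coefficients, cm^-1.
#' @param wavelengths wavelengths in nm (>= 2 usable required).
#' @return object of class \code{scattering_fit}: a_500, b_power, fit_r2,
#'   fit_pvalue, fitted values and residuals (on the original scale).
#' @export
fit_scattering_model <- function(musp, wavelengths) {
  ok <- is.finite(musp) & musp > 0 & is.finite(wavelengths)
  musp_u <- musp[ok]; wl <- wavelengths[ok]
  if (length(musp_u) < 2) stop("need at least 2 usable (positive) wavelengths")
  x <- log(wl / 500)
  y <- log(musp_u)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  res <- y - (intercept + slope * x)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  n <- length(y)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else if (ss_res < 1e-24) 1 else 0
  pval <- if (n > 2) {
    if (ss_res < 1e-24) 0 else {
      f <- (ss_tot - ss_res) / (ss_res / (n - 2))
      stats::pf(f, 1, n - 2, lower.tail = FALSE)
    }
  } else NA_real_
  a <- exp(intercept)
  structure(list(
    a_500 = a, b_power = -slope, fit_r2 = r2, fit_pvalue = pval,
    wavelengths = wl, musp = musp_u,
    fitted = evaluate_mie(a, -slope, wl),
    residuals_log = res
  ), class = "scattering_fit")
}

#' @export
print.scattering_fit <- function(x, ...) {
  cat(sprintf("Mie power-law fit: mus'(lambda) = %.3f (lambda/500)^-%.3f cm^-1\n",
              x$a_500, x$b_power))
  cat(sprintf("  %d wavelengths, R^2 = %.4f, p = %.3g\n",
              length(x$wavelengths), x$fit_r2, x$fit_pvalue))
  invisible(x)
}

#' @export
coef.scattering_fit <- function(object, ...) {
  c(a_500 = object$a_500, b_power = object$b_power)
}

#' Spectral fit quality control
#'
#' A spectral fit is kept iff its regression p-value does not exceed
#' \code{p_max} and its R^2 is at least \code{r2_min} (both comparisons
#' inclusive on the keep side). Study thresholds: p <= 0.03, R^2 >= 0.6.
#'
#' @param fit_r2,fit_pvalue diagnostics, e.g. from
#'   \code{\link{fit_chromophores}} or \code{\link{fit_scattering_model}}.
#' @param p_max,r2_min thresholds.
#' @return logical.
#' @export
spectral_qc <- function(fit_r2, fit_pvalue, p_max = 0.03, r2_min = 0.6) {
  is.finite(fit_r2) & is.finite(fit_pvalue) &
    fit_pvalue <= p_max & fit_r2 >= r2_min
}

#' Extrapolate fitted spectra to the DCS wavelength
#'
#' Reconstructs \eqn{\mu_a} at the DCS wavelength from the fitted chromophore
#' concentrations and the water term, and \eqn{\mu_s'} from the fitted Mie
#' power law.
#'
#' @param chromo a \code{\link{fit_chromophores}} result.
#' @param scatter a \code{\link{fit_scattering_model}} result.
#' @param table an \code{\link{extinction_table}} (must cover the wavelength).
#' @param water_fraction assumed water fraction.
#' @param wavelength target wavelength in nm (default 850, the DCS laser).
#' @return list with \code{mua} and \code{musp} at the target wavelength.
#' @export
extrapolate_to_dcs <- function(chromo, scatter, table = extinction_table(),
                               water_fraction = chromo$water_fraction,
                               wavelength = 850) {
  e <- extinction_at(table, wavelength)
  list(
    mua = e$eps_hbo * chromo$hbo + e$eps_hbr * chromo$hbr +
      water_fraction * e$mua_water,
    musp = evaluate_mie(scatter$a_500, scatter$b_power, wavelength)
  )
}
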