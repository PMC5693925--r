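# DCS curve averaging and correlation-diffusion fitting.

#' Average the intensity autocorrelation curves of one measurement
#'
#' The study averages the 12 curves the correlator emits during one 10 s
#' acquisition and fits the averaged curve.
#'
#' @param meas a \code{dcs_measurement} (see \code{\link{g2_forward}}) or a
#'   numeric matrix with one curve per row.
#' @return numeric vector: the pointwise mean g2 curve.
#' @export
average_curves <- function(meas) {
  curves <- if (inherits(meas, "dcs_measurement")) meas$curves else meas
  if (is.null(dim(curves))) curves <- matrix(curves, nrow = 1)
  if (nrow(curves) < 1 || ncol(curves) < 1) stop("no curves to average")
  if (any(!is.finite(curves))) stop("curves contain non-finite values")
  colMeans(curves)
}

#' Fit CBFi and beta to an averaged g2 curve
#'
#' Minimizes the sum of squared differences between the measured mean
#' intensity autocorrelation and the Siegert-relation model
#' \eqn{g_2(\tau) = 1 + \beta g_1^2(\tau)}, with \eqn{g_1} the semi-infinite
#' correlation-diffusion solution (\code{\link{g1_semi_infinite}}), over
#' (CBFi, \eqn{\beta}) using the Nelder-Mead derivative-free simplex method.
#' CBFi is log-parameterized to enforce positivity. By default \eqn{\beta} is
#' initialized from the early-lag plateau (mean of the first 3 g2 values
#' minus 1) and CBFi at 1e-8 cm^2/s.
#'
#' The absorption at the DCS wavelength is taken per measurement from the
#' FDNIRS chain; the scattering coefficient conventionally stays fixed at the
#' cohort-average 850 nm value (6.4 cm^-1) to avoid propagating scattering
#' noise into the flow index.
#'
#' @param g2_mean averaged g2 curve (one value per lag).
#' @param mua,musp optical properties at the DCS wavelength, cm^-1.
#' @param instrument an \code{\link{instrument_config}}; supplies the lag
#'   grid (overridden by \code{tau}).
#' @param tau optional lag grid in seconds matching \code{g2_mean}.
#' @param cbfi_init,beta_init initial values (beta_init \code{NULL} = from data).
#' @param tau_range optional c(min, max) clipping of the fitted lag range.
#' @param reltol relative convergence tolerance passed to the simplex.
#' @param maxit maximum number of simplex iterations.
#' @return object of class \code{dcs_fit} with elements \code{cbfi},
#'   \code{beta}, \code{residual_ss}, \code{converged}, \code{n_iterations},
#'   \code{degenerate} (no decay information), the data and fitted curve.
#' @export
#' @examples
#' inst <- instrument_config()
#' m <- g2_forward(0.12, 6.4, 2.1e-8, 0.5, inst)
#' fit_cbfi(average_curves(m), mua = 0.12, musp = 6.4, instrument = inst)
fit_cbfi <- function(g2_mean, mua, musp,
                     instrument = instrument_config(), tau = NULL,
                     cbfi_init = 1e-8, beta_init = NULL,
                     tau_range = NULL, reltol = 1e-10, maxit = 2000) {
  stopifnot(mua > 0, musp > 0)
  if (is.null(tau)) tau <- instrument$tau_grid
  if (length(tau) != length(g2_mean)) {
    stop("tau grid and g2 curve lengths differ")
  }
  if (any(!is.finite(g2_mean))) stop("g2 curve contains non-finite values")
  keep <- rep(TRUE, length(tau))
  if (!is.null(tau_range)) {
    keep <- tau >= tau_range[1] & tau <= tau_range[2]
    if (sum(keep) < 3) stop("tau_range leaves fewer than 3 lags")
  }
  tt <- tau[keep]; yy <- g2_mean[keep]
  g1 <- function(cbfi) g1_semi_infinite(tt, mua, musp, cbfi, instrument)
  obj <- function(par) {
    model <- 1 + par[2] * g1(exp(par[1]))^2
    sum((model - yy)^2)
  }
  b0 <- if (is.null(beta_init)) mean(head(yy, 3)) - 1 else beta_init
  degenerate <- !is.finite(b0) || b0 < 1e-3
  b0 <- min(max(b0, 0.01), 1)
  opt <- stats::optim(c(log(cbfi_init), b0), obj, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = maxit))
  cbfi <- exp(opt$par[1])
  beta <- opt$par[2]
  structure(list(
    cbfi = cbfi, beta = beta, residual_ss = opt$value,
    converged = opt$convergence == 0,
    n_iterations = unname(opt$counts["function"]),
    degenerate = degenerate || beta < 1e-3,
    tau = tt, g2 = yy,
    fitted = 1 + beta * g1(cbfi)^2,
    mua = mua, musp = musp
  ), class = "dcs_fit")
}

#' @export
print.dcs_fit <- function(x, ...) {
  cat(sprintf("DCS correlation-diffusion fit%s\n",
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  cat(sprintf("  CBFi = %.4g cm^2/s, beta = %.4f, residual SS = %.3g (%d evaluations)\n",
              x$cbfi, x$beta, x$residual_ss, x$n_iterations))
  if (x$degenerate) cat("  warning: curve carries little decay information\n")
  invisible(x)
}

#' @export
coef.dcs_fit <- function(object, ...) {
  c(cbfi = object$cbfi, beta = object$beta)
}

#' @export
fitted.dcs_fit <- function(object, ...) object$fitted

#' @export
residuals.dcs_fit <- function(object, ...) object$g2 - object$fitted

#' Plot a DCS fit
#'
#' Measured mean g2 curve and fitted Siegert/correlation-diffusion model on a
#' logarithmic lag axis.
#'
#' @param x a \code{dcs_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.dcs_fit <- function(x, ...) {
  graphics::plot(x$tau, x$g2, log = "x", col = "red", pch = 16, cex = 0.5,
                 xlab = expression(tau ~ "(s)"), ylab = expression(g[2](tau)),
                 main = "DCS intensity autocorrelation fit", ...)
  graphics::lines(x$tau, x$fitted, col = "blue", lwd = 2)
  graphics::legend("topright", legend = c("measured", "fitted"),
                   col = c("red", "blue"), pch = c(16, NA), lty = c(NA, 1))
  invisible(x)
}
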