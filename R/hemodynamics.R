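# Derivation of oxygen extraction and metabolism indices.

#' Derive hemodynamic quantities from FDNIRS and DCS outputs
#'
#' Combines tissue oxygen saturation (SO2, from the chromophore fit), the
#' blood flow index (CBFi, from the DCS fit) and the pulse-oximeter arterial
#' saturation (SaO2). Assuming the optical signal mixes arterial and venous
#' blood as \eqn{SO_2 = (1-\gamma)\,SaO_2 + \gamma\,SvO_2} with venous
#' fraction \eqn{\gamma}:
#' \deqn{SvO_2 = \frac{SO_2 - (1-\gamma)SaO_2}{\gamma},\qquad
#'       OEF = \frac{SaO_2 - SO_2}{\gamma\,SaO_2},\qquad
#'       CMRO_{2i} = CBFi\,(SaO_2 - SO_2).}
#' When a blood hemoglobin concentration is supplied, the oxygen carrying
#' capacity \eqn{CaO_2 = \kappa\,HGB\,SaO_2} (mL O2/dL, \eqn{\kappa = 1.34})
#' and the absolute \eqn{CMRO_2 = \kappa\,HGB\,CBFi\,(SaO_2-SO_2)} are added.
#'
#' All saturation arguments are fractions in [0, 1]. Vectorized.
#'
#' @param so2 tissue oxygen saturation (fraction).
#' @param cbfi blood flow index, cm^2/s.
#' @param sao2 arterial oxygen saturation (fraction, > 0).
#' @param gamma venous fraction of the optical signal in (0, 1]; the field
#'   convention 0.75 is the default (the assumption is flagged in the output).
#' @param kappa oxygen per gram of hemoglobin, mL O2/g (1.34).
#' @param hgb optional blood hemoglobin concentration, g/dL.
#' @return data.frame with columns \code{so2}, \code{cbfi}, \code{sao2},
#'   \code{svo2}, \code{oef}, \code{cmro2i}, \code{negative_oef} flag, and —
#'   when \code{hgb} is given — \code{cao2} and \code{cmro2}; attribute
#'   \code{gamma} records the assumed venous fraction.
#' @export
#' @examples
#' derive_hemodynamics(so2 = 0.66, cbfi = 2.1e-8, sao2 = 0.98)
derive_hemodynamics <- function(so2, cbfi, sao2, gamma = 0.75, kappa = 1.34,
                                hgb = NULL) {
  if (any(sao2 <= 0, na.rm = TRUE)) stop("sao2 must be > 0")
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  svo2 <- (so2 - (1 - gamma) * sao2) / gamma
  oef <- (sao2 - so2) / (gamma * sao2)
  cmro2i <- cbfi * (sao2 - so2)
  out <- data.frame(so2 = so2, cbfi = cbfi, sao2 = sao2,
                    svo2 = svo2, oef = oef, cmro2i = cmro2i,
                    negative_oef = !is.na(oef) & oef < 0)
  if (!is.null(hgb)) {
    out$cao2 <- kappa * hgb * sao2
    out$cmro2 <- kappa * hgb * cbfi * (sao2 - so2)
  }
  attr(out, "gamma") <- gamma
  out
}
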