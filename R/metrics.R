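#' Solute flux through the membrane
#'
#' Mass flux of dissolved fructans carried by the permeate, `Ji = Fp * Cp / A`.
#' Inputs are SI (volumetric flow in m^3 s^-1, concentration in kg m^-3, area
#' in m^2); the result is reported in kg h^-1 m^-2, the unit used for
#' membrane productivity.
#'
#' @param permeate_flow Permeate volumetric flow, m^3 s^-1.
#' @param permeate_conc Permeate solute concentration, kg m^-3.
#' @param area Membrane filtration area, m^2.
#' @return Solute flux in kg h^-1 m^-2.
#' @examples
#' solute_flux(1e-5, 20, 0.5)  # 1.44 kg/h/m2
#' @export
solute_flux <- function(permeate_flow, permeate_conc, area) {
  if (!is.finite(area) || area <= 0) {
    stop("membrane area must be strictly positive", call. = FALSE)
  }
  if (any(permeate_flow < 0) || any(permeate_conc < 0)) {
    stop("permeate flow and concentration must be non-negative", call. = FALSE)
  }
  permeate_flow * permeate_conc / area * 3600
}

#' Apparent rejection coefficient
#'
#' `Ro = 1 - Cp / Ci`: the fraction of solute retained by the membrane.
#' `Ro = 1` is total rejection, `Ro = 0` free passage; negative values
#' indicate preferential permeation.
#'
#' @param cp Permeate concentration, kg m^-3.
#' @param ci Bulk (retentate-side) concentration, kg m^-3; must be positive.
#' @return Dimensionless rejection in (-Inf, 1].
#' @examples
#' apparent_rejection(18.5, 100)
#' @export
apparent_rejection <- function(cp, ci) {
  if (any(!is.finite(ci)) || any(ci <= 0)) {
    stop("bulk concentration must be strictly positive", call. = FALSE)
  }
  1 - cp / ci
}

#' Permeate concentration from rejection
#'
#' Inverse of [apparent_rejection()]: `Cp = Cr * (1 - Ro)` for retentate
#' concentration `Cr` under a constant apparent rejection `Ro`.
#'
#' @param cr Retentate concentration, kg m^-3.
#' @param ro Apparent rejection, `ro <= 1`.
#' @return Permeate concentration, kg m^-3.
#' @export
permeate_conc <- function(cr, ro) {
  if (any(ro > 1)) {
    stop("apparent rejection cannot exceed 1", call. = FALSE)
  }
  cr * (1 - ro)
}

#' Sum of squared errors between two paired series
#'
#' The model-validation score used to compare simulated and measured
#' concentration profiles: `SSE = sum((predicted - observed)^2)`.
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return Non-negative scalar in squared units of the inputs.
#' @export
sum_squared_error <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop(sprintf("length mismatch: predicted has %d values, observed %d",
                 length(predicted), length(observed)), call. = FALSE)
  }
  if (length(predicted) < 1L) {
    stop("series must contain at least one value", call. = FALSE)
  }
  sum((predicted - observed)^2)
}
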