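#' Flux-versus-concentration curve
#'
#' Measurements of permeate flux at a series of bulk fructan concentrations
#' under fixed TMP, temperature and crossflow velocity.  Fluxes given in
#' kg h^-1 m^-2 are converted to m s^-1 assuming a permeate density of
#' 1000 kg m^-3 (dilute-solution convention; a message records the
#' assumption).
#'
#' @param conc Bulk concentrations, kg m^-3; strictly positive, distinct.
#' @param flux Permeate fluxes, in the unit given by `unit`.
#' @param unit `"m_s"` (default) or `"kg_h_m2"`.
#' @return Data frame of class `"flux_curve"` with columns `conc` and
#'   `flux` (m s^-1).
#' @export
flux_curve <- function(conc, flux, unit = c("m_s", "kg_h_m2")) {
  unit <- match.arg(unit)
  if (length(conc) != length(flux)) stop("conc and flux lengths differ", call. = FALSE)
  if (any(conc <= 0) || anyDuplicated(conc)) {
    stop("concentrations must be strictly positive and distinct", call. = FALSE)
  }
  if (unit == "kg_h_m2") {
    message("converting flux from kg/h/m2 to m/s assuming permeate density 1000 kg/m3")
    flux <- flux / 3600 / 1000
  }
  structure(data.frame(conc = conc, flux = flux),
            class = c("flux_curve", "data.frame"))
}

#' Estimate limiting-flux parameters from a flux curve
#'
#' The gel-polarization law predicts a straight line of flux against the
#' natural logarithm of concentration, `J = k * ln(Clim) - k * ln(C)`.  An
#' ordinary least-squares fit of `J` on `ln(C)` therefore yields the
#' mass-transfer coefficient as minus the slope and the limit concentration
#' as the concentration at which the fitted line crosses zero flux.
#'
#' @param curve A [flux_curve()].
#' @param driving_solute Passed through to [flux_params()].
#' @return A [flux_params()] object with attributes `r2`, `residuals` and
#'   `intercept` (fit diagnostics).
#' @examples
#' p <- flux_params(6.31e-6, 337.61)
#' fc <- gen_flux_curve(p, conc = c(50, 100, 150, 200, 250), cv = 0, seed = 1)
#' fit_flux_params(fc)
#' @export
fit_flux_params <- function(curve, driving_solute = "fc") {
  stopifnot(inherits(curve, "flux_curve"))
  if (nrow(curve) < 2L) stop("at least two points are required", call. = FALSE)
  if (nrow(curve) < 3L) {
    warning("only two points: parameters are exactly determined, no diagnostics",
            call. = FALSE)
  }
  if (max(curve$conc) / min(curve$conc) < 2) {
    warning("concentration span is narrow (< 2x): extrapolation to Clim is unreliable",
            call. = FALSE)
  }
  fit <- stats::lm(flux ~ log(conc), data = curve)
  a <- stats::coef(fit)[[1]]
  b <- stats::coef(fit)[[2]]
  if (!is.finite(b) || b >= 0) {
    stop("flux does not decrease with log-concentration: limiting-flux model violated",
         call. = FALSE)
  }
  p <- flux_params(k = -b, c_lim = exp(-a / b), driving_solute = driving_solute)
  tss <- sum((curve$flux - mean(curve$flux))^2)
  attr(p, "r2") <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  attr(p, "residuals") <- stats::residuals(fit)
  attr(p, "intercept") <- a
  p
}

#' Rejection-versus-composition correlation
#'
#' Correlates the apparent rejection of each solute with the FOS:Fc ratio of
#' the feed, so that rejections for a new batch can be predicted from its
#' composition alone.  For FOS the rejection falls steeply with the ratio
#' and a linear form is the default; for Fc the rejection is nearly constant
#' and the default form is the mean.
#'
#' @param ratio Feed FOS:Fc ratios.
#' @param ro_fos,ro_fc Apparent rejections observed at those ratios
#'   (fractions in `[0, 1]`).
#' @param form_fos,form_fc `"linear"` or `"constant"` per solute.
#' @return Object of class `"rejection_correlation"`: per-solute intercept
#'   and slope over the ratio domain.
#' @examples
#' corr <- fit_rejection_correlation(ratio = c(0.23, 0.39),
#'                                   ro_fos = c(0.55, 0.185),
#'                                   ro_fc = c(0.76, 0.83))
#' predict_rejection(corr, 0.31)
#' @export
fit_rejection_correlation <- function(ratio, ro_fos, ro_fc,
                                      form_fos = c("linear", "constant"),
                                      form_fc = c("constant", "linear")) {
  form_fos <- match.arg(form_fos)
  form_fc <- match.arg(form_fc)
  if (length(ratio) != length(ro_fos) || length(ratio) != length(ro_fc)) {
    stop("ratio and rejection vectors must have equal length", call. = FALSE)
  }
  one <- function(y, form) {
    if (form == "constant") {
      c(intercept = mean(y), slope = 0)
    } else {
      if (length(ratio) < 2L) {
        stop("linear form needs at least two points", call. = FALSE)
      }
      b <- stats::coef(stats::lm(y ~ ratio))
      c(intercept = b[[1]], slope = b[[2]])
    }
  }
  structure(list(fos = c(one(ro_fos, form_fos), form = form_fos),
                 fc = c(one(ro_fc, form_fc), form = form_fc),
                 domain = range(ratio)),
            class = "rejection_correlation")
}

#' @rdname fit_rejection_correlation
#' @param corr A `rejection_correlation`.
#' @export
predict_rejection <- function(corr, ratio) {
  stopifnot(inherits(corr, "rejection_correlation"))
  eval_one <- function(cf) {
    as.numeric(cf[["intercept"]]) + as.numeric(cf[["slope"]]) * ratio
  }
  raw <- data.frame(ratio = ratio,
                    ro_fos = eval_one(corr$fos), ro_fc = eval_one(corr$fc))
  clipped <- raw$ro_fos < 0 | raw$ro_fos > 1 | raw$ro_fc < 0 | raw$ro_fc > 1
  if (any(clipped)) {
    message(sprintf("rejection predictions clipped to [0, 1] at %d ratio value(s)",
                    sum(clipped)))
  }
  raw$ro_fos <- pmin(pmax(raw$ro_fos, 0), 1)
  raw$ro_fc <- pmin(pmax(raw$ro_fc, 0), 1)
  raw
}

#' Score a simulated trajectory against observed concentrations
#'
#' Interpolates the trajectory at the observation times ([concentration_profiles()])
#' and returns the sum of squared errors per (stream, solute) series.
#'
#' @param traj A [simulate_uf()] trajectory.
#' @param observed Data frame with columns `time` (s), `stream`
#'   (`"retentate"` or `"permeate"`), `solute` (`"fc"` or `"fos"`) and
#'   `conc` (kg m^-3).
#' @return Data frame with columns `stream`, `solute`, `n`, `sse`.
#' @export
validate_profiles <- function(traj, observed) {
  need <- c("time", "stream", "solute", "conc")
  if (!all(need %in% names(observed))) {
    stop("observed table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  groups <- unique(observed[c("stream", "solute")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    g <- observed[observed$stream == groups$stream[i] &
                    observed$solute == groups$solute[i], ]
    prof <- concentration_profiles(traj, g$time)
    col <- paste0("c_", groups$solute[i],
                  if (groups$stream[i] == "retentate") "_ret" else "_perm")
    data.frame(stream = groups$stream[i], solute = groups$solute[i],
               n = nrow(g), sse = sum_squared_error(prof[[col]], g$conc))
  })
  do.call(rbind, out)
}
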