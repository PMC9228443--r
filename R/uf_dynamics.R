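#' Limiting-flux model parameters
#'
#' Parameters of the concentration-polarization limiting-flux law
#' `Jlim = k * ln(Clim / (Ro * C) - (1 - Ro) / Ro)`: the film mass-transfer
#' coefficient `k` and the limit (gel) concentration `c_lim` at which the
#' permeate flux vanishes.  `driving_solute` selects which concentration
#' drives the boundary layer: the long-chain fraction (`"fc"`, the default,
#' since Fc dominates the polarized layer) or the total fructan
#' concentration (`"total"`).
#'
#' @param k Mass-transfer coefficient, m s^-1 (> 0).
#' @param c_lim Limit concentration, kg m^-3 (> 0).
#' @param driving_solute `"fc"` or `"total"`.
#' @return An object of class `"flux_params"`.
#' @examples
#' flux_params(k = 6.31e-6, c_lim = 337.61)
#' @export
flux_params <- function(k, c_lim, driving_solute = c("fc", "total")) {
  driving_solute <- match.arg(driving_solute)
  if (!is.finite(k) || k <= 0) stop("k must be positive", call. = FALSE)
  if (!is.finite(c_lim) || c_lim <= 0) stop("c_lim must be positive", call. = FALSE)
  structure(list(k = k, c_lim = c_lim, driving_solute = driving_solute),
            class = "flux_params")
}

#' @export
print.flux_params <- function(x, ...) {
  cat(sprintf("limiting-flux parameters: k = %.4g m/s, Clim = %.2f kg/m3, driven by %s\n",
              x$k, x$c_lim, toupper(x$driving_solute)))
  invisible(x)
}

#' Limiting permeate flux
#'
#' Evaluates `Jlim = k * ln(Clim / (Ro * C) - (1 - Ro) / Ro)` for driving
#' concentration `C`.  The argument of the logarithm equals 1 when
#' `C = Clim`, for any rejection, so the flux vanishes exactly at the limit
#' concentration; values of `C` at or above `Clim` return 0 (the membrane is
#' blinded by the polarized layer).  With total rejection (`ro = 1`) the law
#' reduces to the classical gel-polarization form `k * ln(Clim / C)`.
#'
#' @param c_drive Driving (bulk) concentration, kg m^-3; strictly positive.
#' @param ro Apparent rejection of the driving solute, in (0, 1].
#' @param params A [flux_params()] object.
#' @return Permeate flux in m s^-1 (vectorized over `c_drive`).
#' @examples
#' p <- flux_params(6.31e-6, 337.61)
#' limiting_flux(100, ro = 0.8, p)
#' limiting_flux(337.61, ro = 0.8, p)  # exactly zero
#' @export
limiting_flux <- function(c_drive, ro, params) {
  stopifnot(inherits(params, "flux_params"))
  if (any(!is.finite(c_drive)) || any(c_drive <= 0)) {
    stop("driving concentration must be strictly positive", call. = FALSE)
  }
  if (!is.finite(ro) || ro <= 0 || ro > 1) {
    stop("rejection of the driving solute must lie in (0, 1]", call. = FALSE)
  }
  arg <- params$c_lim / (ro * c_drive) - (1 - ro) / ro
  j <- ifelse(c_drive >= params$c_lim | arg <= 1, 0, params$k * log(arg))
  as.numeric(j)
}

#' Batch ultrafiltration system specification
#'
#' Describes a batch concentration run: permeate is withdrawn while
#' retentate recirculates to the tank, so tank volume falls and retained
#' solutes concentrate.  Apparent rejections are constant over the run.
#'
#' @param area Membrane area, m^2.
#' @param v0 Initial tank volume, m^3.
#' @param c0_fc,c0_fos Initial concentrations of long-chain fructans and
#'   FOS, kg m^-3.
#' @param ro_fc,ro_fos Apparent rejections; the driving solute's rejection
#'   must lie in (0, 1].
#' @param params A [flux_params()] object.
#' @return An object of class `"uf_system"`.
#' @examples
#' uf_system(0.5, 0.1, c0_fc = 71.6, c0_fos = 17.1, ro_fc = 0.8, ro_fos = 0.55,
#'           params = flux_params(6.31e-6, 337.61))
#' @export
uf_system <- function(area, v0, c0_fc, c0_fos, ro_fc, ro_fos, params) {
  stopifnot(inherits(params, "flux_params"))
  if (!is.finite(area) || area <= 0) stop("area must be positive", call. = FALSE)
  if (!is.finite(v0) || v0 <= 0) stop("v0 must be positive", call. = FALSE)
  if (c0_fc < 0 || c0_fos < 0) stop("initial concentrations must be non-negative", call. = FALSE)
  if (ro_fc > 1 || ro_fos > 1) stop("rejections cannot exceed 1", call. = FALSE)
  # one membrane, one boundary layer: the Fc rejection drives Jlim either way
  if (ro_fc <= 0) stop("driving-solute rejection must be positive", call. = FALSE)
  structure(list(area = area, v0 = v0,
                 c0 = c(fc = c0_fc, fos = c0_fos),
                 ro = c(fc = ro_fc, fos = ro_fos),
                 params = params),
            class = "uf_system")
}

drive_conc <- function(c_fc, c_fos, params) {
  if (params$driving_solute == "fc") c_fc else c_fc + c_fos
}

#' Time derivatives of the batch ultrafiltration balance
#'
#' Right-hand side of the batch model: `dV/dt = -Jlim * A` and, per solute,
#' `dC_i/dt = (C_i / V) * Jlim * A * Ro_i`.  Both solutes see the same
#' limiting flux (one membrane, one boundary layer), driven by the
#' concentration selected in [flux_params()].  Two auxiliary states
#' accumulate the permeate mass of each solute,
#' `dMp_i/dt = C_i * (1 - Ro_i) * Jlim * A`, closing the mass balance.
#'
#' @param state Named numeric: `v` (m^3), `c_fc`, `c_fos` (kg m^-3),
#'   `mp_fc`, `mp_fos` (kg).
#' @param spec A [uf_system()] object.
#' @return Named list with `deriv` (state derivatives) and `jlim` (m s^-1).
#' @export
uf_rhs <- function(state, spec) {
  v <- state[["v"]]
  if (!is.finite(v) || v <= 0) stop("tank volume must be positive", call. = FALSE)
  c_fc <- state[["c_fc"]]
  c_fos <- state[["c_fos"]]
  cd <- drive_conc(c_fc, c_fos, spec$params)
  jlim <- if (cd <= 0) 0 else limiting_flux(cd, spec$ro[["fc"]], spec$params)
  ja <- jlim * spec$area
  deriv <- c(
    v = -ja,
    c_fc = c_fc / v * ja * spec$ro[["fc"]],
    c_fos = c_fos / v * ja * spec$ro[["fos"]],
    mp_fc = c_fc * (1 - spec$ro[["fc"]]) * ja,
    mp_fos = c_fos * (1 - spec$ro[["fos"]]) * ja
  )
  list(deriv = deriv, jlim = jlim)
}

#' Simulate a batch ultrafiltration run
#'
#' Integrates the batch balance with the adaptive `lsoda` solver
#' (deSolve), stopping at `t_end`, when the tank volume reaches
#' `v_min_frac * v0`, or when the limiting flux vanishes (driving
#' concentration reaching `Clim`), whichever comes first.  Permeate
#' concentrations are derived pointwise as `Cp_i = C_i * (1 - Ro_i)`.
#'
#' @param spec A [uf_system()] object.
#' @param t_end Simulation horizon, s.
#' @param v_min_frac Stop when `V <= v_min_frac * v0` (default 0.05).
#' @param n_out Number of output grid points (default 361).
#' @param rtol,atol Solver tolerances (defaults 1e-8, 1e-10).
#' @return A data frame of class `"uf_trajectory"` with columns `time` (s),
#'   `v` (m^3), retentate concentrations `c_fc`, `c_fos`, permeate
#'   concentrations `cp_fc`, `cp_fos` (kg m^-3), `jlim` (m s^-1),
#'   cumulative permeate volume `vp` (m^3) and cumulative permeate masses
#'   `mp_fc`, `mp_fos` (kg).  Attribute `termination` records why the run
#'   ended (`"t_end"`, `"v_min"` or `"flux_zero"`); attribute `spec` keeps
#'   the system definition.
#' @examples
#' sys <- uf_system(0.5, 0.1, 71.6, 17.1, 0.8, 0.55,
#'                  params = flux_params(6.31e-6, 337.61))
#' traj <- simulate_uf(sys, t_end = 3600)
#' head(traj)
#' @export
simulate_uf <- function(spec, t_end, v_min_frac = 0.05, n_out = 361,
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "uf_system"))
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be positive", call. = FALSE)
  if (!is.finite(v_min_frac) || v_min_frac <= 0 || v_min_frac >= 1) {
    stop("v_min_frac must lie in (0, 1)", call. = FALSE)
  }
  y0 <- c(v = spec$v0, c_fc = spec$c0[["fc"]], c_fos = spec$c0[["fos"]],
          mp_fc = 0, mp_fos = 0)
  j0 <- uf_rhs(y0, spec)$jlim
  if (j0 <= 0) {
    out <- traj_frame(0, matrix(y0, nrow = 1,
                                dimnames = list(NULL, names(y0))), spec)
    return(finish_traj(out, spec, "flux_zero"))
  }
  v_min <- v_min_frac * spec$v0
  times <- seq(0, t_end, length.out = n_out)
  rhs_desolve <- function(t, y, parms) {
    r <- uf_rhs(y, parms)
    list(r$deriv, jlim = r$jlim)
  }
  rootfun <- function(t, y, parms) {
    r <- uf_rhs(y, parms)
    c(y[["v"]] - v_min, r$jlim)
  }
  sol <- deSolve::ode(y0, times, rhs_desolve, parms = spec,
                      method = "lsoda", rtol = rtol, atol = atol,
                      rootfunc = rootfun, events = list(root = TRUE,
                                                        terminalroot = c(1, 2)))
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0) {
    stop(sprintf("ODE solver failed (istate %d) at t = %.3f s; state: %s",
                 attr(sol, "istate")[1], max(sol[, "time"]),
                 paste(signif(sol[nrow(sol), -1], 6), collapse = ", ")),
         call. = FALSE)
  }
  m <- as.matrix(sol)
  termination <- "t_end"
  ind <- attr(sol, "indroot")
  if (!is.null(attr(sol, "troot")) && length(attr(sol, "troot"))) {
    termination <- if (!is.null(ind) && 2 %in% ind) "flux_zero" else "v_min"
  }
  out <- traj_frame(m[, "time"], m[, c("v", "c_fc", "c_fos", "mp_fc", "mp_fos")],
                    spec)
  finish_traj(out, spec, termination)
}

traj_frame <- function(time, states, spec) {
  states <- matrix(states, ncol = 5,
                   dimnames = list(NULL, c("v", "c_fc", "c_fos", "mp_fc", "mp_fos")))
  cd <- drive_conc(states[, "c_fc"], states[, "c_fos"], spec$params)
  jlim <- vapply(cd, function(ci) {
    if (ci <= 0) 0 else limiting_flux(ci, spec$ro[["fc"]], spec$params)
  }, numeric(1))
  data.frame(
    time = as.numeric(time),
    v = states[, "v"],
    c_fc = states[, "c_fc"],
    c_fos = states[, "c_fos"],
    cp_fc = states[, "c_fc"] * (1 - spec$ro[["fc"]]),
    cp_fos = states[, "c_fos"] * (1 - spec$ro[["fos"]]),
    jlim = jlim,
    vp = spec$v0 - states[, "v"],
    mp_fc = states[, "mp_fc"],
    mp_fos = states[, "mp_fos"]
  )
}

finish_traj <- function(out, spec, termination) {
  rownames(out) <- NULL
  structure(out, class = c("uf_trajectory", "data.frame"),
            termination = termination, spec = spec)
}

#' Interpolate a trajectory at arbitrary sample times
#'
#' Monotone cubic (Fritsch-Carlson) interpolation of the retentate and
#' permeate concentration series at requested times, which must lie within
#' the simulated span.
#'
#' @param traj A [simulate_uf()] trajectory.
#' @param sample_times Times (s) within `range(traj$time)`.
#' @return Data frame with columns `time`, `c_fc_ret`, `c_fos_ret`,
#'   `c_fc_perm`, `c_fos_perm`.
#' @export
concentration_profiles <- function(traj, sample_times) {
  span <- range(traj$time)
  if (any(sample_times < span[1] - 1e-9) || any(sample_times > span[2] + 1e-9)) {
    stop(sprintf("sample times must lie within the simulated span [%g, %g] s",
                 span[1], span[2]), call. = FALSE)
  }
  if (nrow(traj) < 2L) {
    return(data.frame(time = sample_times,
                      c_fc_ret = traj$c_fc[1], c_fos_ret = traj$c_fos[1],
                      c_fc_perm = traj$cp_fc[1], c_fos_perm = traj$cp_fos[1]))
  }
  interp <- function(y) {
    stats::splinefun(traj$time, y, method = "monoH.FC")(sample_times)
  }
  data.frame(time = sample_times,
             c_fc_ret = interp(traj$c_fc),
             c_fos_ret = interp(traj$c_fos),
             c_fc_perm = interp(traj$cp_fc),
             c_fos_perm = interp(traj$cp_fos))
}
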