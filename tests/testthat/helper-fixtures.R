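# study design rebuilt in code, independent of the packaged CSV
table2_design <- function() {
  d <- data.frame(
    run = 1:16,
    x1 = c(0, -1, 0, 1, -1, 1, 1, 1, -1, 0, 0, 0, 0, 0, -1, 0),
    x2 = c(0, -1, 0, 0, 0, -1, 0, 1, 1, 1, 1, 0, -1, -1, 0, 0),
    x3 = c(0, 0, 0, -1, 1, 0, 1, 0, 0, -1, 1, 0, 1, -1, -1, 0),
    sf = c(2.80, 1.75, 2.74, 2.30, 1.80, 1.91, 2.25, 2.30,
           1.97, 2.28, 2.14, 2.60, 1.90, 2.22, 2.34, 2.70),
    ji = c(1.350, 0.270, 1.660, 1.010, 1.130, 0.630, 2.220, 2.600,
           1.350, 0.800, 1.510, 1.230, 0.790, 0.380, 0.560, 1.110)
  )
  lv <- agave_levels()
  ac <- decode_conditions(d[c("x1", "x2", "x3")], lv)
  d <- cbind(d["run"], ac[c("temperature", "tmp", "conc")],
             d[c("x1", "x2", "x3", "sf", "ji")])
  class(d) <- c("bbd_design", "data.frame")
  attr(d, "levels") <- lv
  d
}

study_flux_params <- function() flux_params(k = 6.31e-6, c_lim = 337.61)

reference_uf_system <- function(ro_fc = 0.8, ro_fos = 0.55) {
  uf_system(area = 0.5, v0 = 0.1, c0_fc = 71.6, c0_fos = 17.1,
            ro_fc = ro_fc, ro_fos = ro_fos, params = study_flux_params())
}

# fixed-step classical RK4 over the batch balance: the independent
# integration oracle for the adaptive solver
rk4_uf <- function(spec, t_end, dt) {
  state <- c(v = spec$v0, c_fc = spec$c0[["fc"]], c_fos = spec$c0[["fos"]],
             mp_fc = 0, mp_fos = 0)
  f <- function(s) uf_rhs(s, spec)$deriv
  n_steps <- round(t_end / dt)
  for (i in seq_len(n_steps)) {
    k1 <- f(state)
    k2 <- f(state + dt / 2 * k1)
    k3 <- f(state + dt / 2 * k2)
    k4 <- f(state + dt * k3)
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  state
}
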