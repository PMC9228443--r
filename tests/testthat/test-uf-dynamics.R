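p <- study_flux_params()

test_that("limiting flux follows the polarization law and vanishes at Clim", {
  # hand evaluation: ln(Clim / (Ro * C) - (1 - Ro) / Ro) * k
  expect_equal(limiting_flux(100, 0.8, p),
               6.31e-6 * log(337.61 / (0.8 * 100) - 0.2 / 0.8), tolerance = 1e-12)
  expect_equal(limiting_flux(100, 0.8, p), 8.701e-6, tolerance = 1e-4)
  expect_identical(limiting_flux(337.61, 0.8, p), 0)
  expect_identical(limiting_flux(400, 0.8, p), 0)
  # total rejection reduces to k * ln(Clim / C)
  expect_equal(limiting_flux(337.61 / exp(1), 1, p), 6.31e-6,
               tolerance = 1e-12)
  # strictly decreasing in the driving concentration
  cs <- seq(20, 330, by = 10)
  expect_true(all(diff(limiting_flux(cs, 0.8, p)) < 0))
  expect_error(limiting_flux(-5, 0.8, p), "positive")
  expect_error(limiting_flux(100, 0, p), "\\(0, 1\\]")
})

test_that("the batch balance derivatives have the expected structure", {
  sys <- reference_uf_system()
  st <- c(v = 0.1, c_fc = 100, c_fos = 20, mp_fc = 0, mp_fos = 0)
  r <- uf_rhs(st, sys)
  jl <- limiting_flux(100, 0.8, p)
  expect_equal(r$deriv[["v"]], -jl * 0.5, tolerance = 1e-12)
  expect_equal(r$deriv[["c_fc"]], 100 / 0.1 * jl * 0.5 * 0.8,
               tolerance = 1e-12)
  expect_equal(r$deriv[["c_fc"]], 3.4804e-3, tolerance = 1e-3)
  # zero rejection for FOS freezes its tank concentration
  sys0 <- uf_system(0.5, 0.1, 100, 20, 0.8, 0, params = p)
  r0 <- uf_rhs(c(v = 0.1, c_fc = 100, c_fos = 20, mp_fc = 0, mp_fos = 0), sys0)
  expect_equal(r0$deriv[["c_fos"]], 0)
  expect_true(r0$deriv[["v"]] < 0)
  # blinded membrane: all derivatives vanish
  rb <- uf_rhs(c(v = 0.1, c_fc = 400, c_fos = 20, mp_fc = 0, mp_fos = 0), sys)
  expect_true(all(rb$deriv == 0))
  expect_error(uf_rhs(c(v = 0, c_fc = 1, c_fos = 1, mp_fc = 0, mp_fos = 0), sys),
               "positive")
})

test_that("simulated trajectories conserve volume and solute mass", {
  sys <- reference_uf_system()
  traj <- simulate_uf(sys, t_end = 4 * 3600)
  expect_true(all(diff(traj$v) <= 0))
  expect_equal(traj$v + traj$vp, rep(sys$v0, nrow(traj)),
               tolerance = 1e-9)
  for (sl in c("fc", "fos")) {
    m0 <- sys$c0[[sl]] * sys$v0
    tank <- traj[[paste0("c_", sl)]] * traj$v
    expect_equal(tank + traj[[paste0("mp_", sl)]], rep(m0, nrow(traj)),
                 tolerance = 1e-6 * m0)
  }
  # permeate concentration is pointwise Cr * (1 - Ro)
  expect_equal(traj$cp_fc, traj$c_fc * (1 - 0.8), tolerance = 1e-12)
  expect_equal(traj$cp_fos, traj$c_fos * (1 - 0.55), tolerance = 1e-12)
})

test_that("total retention conserves the retained mass product C*V", {
  sys <- uf_system(0.5, 0.1, 71.6, 17.1, 1, 1, params = p)
  traj <- simulate_uf(sys, t_end = 2 * 3600)
  expect_equal(traj$c_fc * traj$v, rep(71.6 * 0.1, nrow(traj)),
               tolerance = 1e-8)
  expect_equal(traj$c_fos * traj$v, rep(17.1 * 0.1, nrow(traj)),
               tolerance = 1e-8)
})

test_that("termination events stop the run for volume and for flux", {
  sys <- reference_uf_system()
  traj <- simulate_uf(sys, t_end = 1e6, v_min_frac = 0.5)
  expect_identical(attr(traj, "termination"), "v_min")
  expect_equal(min(traj$v), 0.05, tolerance = 1e-6)
  blind <- uf_system(0.5, 0.1, 400, 20, 0.8, 0.55, params = p)
  tb <- simulate_uf(blind, t_end = 3600)
  expect_identical(attr(tb, "termination"), "flux_zero")
  expect_equal(nrow(tb), 1)
  long <- simulate_uf(sys, t_end = 600)
  expect_identical(attr(long, "termination"), "t_end")
})

test_that("adaptive solver agrees with the fixed-step RK4 oracle", {
  sys <- reference_uf_system()
  t_end <- 3600
  traj <- simulate_uf(sys, t_end = t_end, n_out = 2)
  oracle <- rk4_uf(sys, t_end, dt = 0.1)
  final <- traj[nrow(traj), ]
  expect_equal(final$v, oracle[["v"]], tolerance = 1e-5)
  expect_equal(final$c_fc, oracle[["c_fc"]], tolerance = 1e-5)
  expect_equal(final$c_fos, oracle[["c_fos"]], tolerance = 1e-5)
})

test_that("profile interpolation is exact at grid points and structurally sound", {
  sys <- reference_uf_system()
  traj <- simulate_uf(sys, t_end = 3600, n_out = 61)
  prof <- concentration_profiles(traj, traj$time[c(5, 20, 40)])
  expect_equal(prof$c_fc_ret, traj$c_fc[c(5, 20, 40)], tolerance = 1e-12)
  expect_equal(prof$c_fos_perm, traj$cp_fos[c(5, 20, 40)], tolerance = 1e-12)
  ts <- seq(0, 3600, by = 300)
  prof2 <- concentration_profiles(traj, ts)
  expect_true(all(diff(prof2$c_fc_ret) >= 0))   # Ro_fc > 0 concentrates Fc
  expect_equal(prof2$c_fc_perm / prof2$c_fc_ret, rep(0.2, length(ts)),
               tolerance = 1e-9)
  expect_error(concentration_profiles(traj, 7200), "span")
})
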