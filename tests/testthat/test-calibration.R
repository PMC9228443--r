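p_true <- study_flux_params()

test_that("noiseless flux curves invert exactly to (k, Clim)", {
  curve <- gen_flux_curve(p_true, conc = c(50, 100, 150, 200, 250),
                          cv = 0, seed = 1)
  fit <- fit_flux_params(curve)
  expect_equal(fit$k, p_true$k, tolerance = 1e-10)
  expect_equal(fit$c_lim, p_true$c_lim, tolerance = 1e-10)
  # consistency across modules: the fitted Clim is the flux root
  expect_equal(limiting_flux(fit$c_lim, 1, fit), 0, tolerance = 1e-15)
  # two points determine the line exactly
  two <- flux_curve(c(60, 240), limiting_flux(c(60, 240), 1, p_true))
  expect_warning(fit2 <- fit_flux_params(two), "two points")
  expect_equal(fit2$c_lim, p_true$c_lim, tolerance = 1e-10)
})

test_that("parameters are recovered within 5% under 2% multiplicative noise", {
  curve <- gen_flux_curve(p_true, conc = seq(50, 250, length.out = 10),
                          cv = 0.02, seed = 101)
  fit <- fit_flux_params(curve)
  expect_lt(abs(fit$k - p_true$k) / p_true$k, 0.05)
  expect_lt(abs(fit$c_lim - p_true$c_lim) / p_true$c_lim, 0.05)
  expect_gt(attr(fit, "r2"), 0.9)
})

test_that("a rising flux-concentration trend is rejected as a model violation", {
  bad <- flux_curve(c(50, 100, 200), c(1e-6, 2e-6, 4e-6))
  expect_error(fit_flux_params(bad), "violated")
})

test_that("rejection correlation reproduces the two-point line and constant mean", {
  corr <- fit_rejection_correlation(ratio = c(0.23, 0.39),
                                    ro_fos = c(0.55, 0.185),
                                    ro_fc = c(0.76, 0.83))
  expect_equal(as.numeric(corr$fos[["slope"]]), -2.28125, tolerance = 1e-9)
  expect_equal(as.numeric(corr$fos[["intercept"]]), 1.0746875, tolerance = 1e-9)
  pr <- predict_rejection(corr, 0.31)
  expect_equal(pr$ro_fos, 0.3675, tolerance = 1e-9)
  expect_equal(pr$ro_fc, 0.795, tolerance = 1e-9)
})

test_that("rejection predictions are clipped to [0, 1] with a log message", {
  corr <- fit_rejection_correlation(ratio = c(0.23, 0.39),
                                    ro_fos = c(0.55, 0.185),
                                    ro_fc = c(0.76, 0.83))
  expect_message(pr <- predict_rejection(corr, c(0.05, 0.6)), "clipped")
  expect_true(all(pr$ro_fos >= 0 & pr$ro_fos <= 1))
})

test_that("profile validation scores simulated-vs-observed series per stream", {
  sys <- reference_uf_system()
  ts <- seq(300, 3000, by = 300)
  obs <- gen_uf_timeseries(sys, ts, sigma = 0, seed = 1, t_end = 3600)
  traj <- simulate_uf(sys, t_end = 3600)
  sse0 <- validate_profiles(traj, obs)
  expect_equal(nrow(sse0), 4)
  expect_true(all(sse0$sse < 1e-12))
  # a constant offset of delta on n points scores n * delta^2
  obs_off <- obs
  obs_off$conc <- obs_off$conc + 2
  sse_off <- validate_profiles(traj, obs_off)
  expect_equal(sse_off$sse, rep(length(ts) * 4, 4), tolerance = 1e-9)
  # Gaussian noise sigma = 3: SSE/n within broad chi-square bounds
  obs_n <- gen_uf_timeseries(sys, ts, sigma = 3, seed = 77, t_end = 3600)
  sse_n <- validate_profiles(traj, obs_n)
  expect_true(all(sse_n$sse / length(ts) > 9 / 3))
  expect_true(all(sse_n$sse / length(ts) < 9 * 3))
})
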