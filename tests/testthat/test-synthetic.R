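test_that("synthetic batches close to 100% and span realistic FOS:Fc ratios", {
  b <- gen_batches(200, seed = 19)
  expect_equal(b$pct_fc + b$pct_fos + b$pct_md, rep(100, 200),
               tolerance = 1e-9)
  expect_true(all(b$pct_fc >= 60 & b$pct_fc <= 75))
  expect_true(all(b$pct_md >= 7 & b$pct_md <= 13))
  ratio <- b$pct_fos / b$pct_fc
  expect_gt(min(ratio), 0.15)
  expect_lt(max(ratio), 0.56)
  # covers the observed 0.23-0.44 span of real batches
  expect_lt(min(ratio), 0.23)
  expect_gt(max(ratio), 0.44)
  # every row is a valid composition
  comp <- composition(b$pct_fc[1], b$pct_fos[1], b$pct_md[1], unit = "percent")
  expect_s3_class(comp, "composition")
})

test_that("generators are pure functions of the seed", {
  expect_identical(gen_batches(10, seed = 4), gen_batches(10, seed = 4))
  expect_false(identical(gen_batches(10, seed = 4), gen_batches(10, seed = 5)))
  p <- study_flux_params()
  expect_identical(gen_flux_curve(p, cv = 0.05, seed = 8),
                   gen_flux_curve(p, cv = 0.05, seed = 8))
  # the global RNG stream is untouched
  set.seed(123); before <- .Random.seed
  invisible(gen_batches(5, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("noiseless design responses refit to the generating polynomial", {
  truth <- c("(Intercept)" = 2.71, x1 = 0.1125, x2 = 0.11375, x3 = -0.13125,
             "x1:x3" = 0.1225, "x1^2" = -0.345, "x2^2" = -0.3825,
             "x3^2" = -0.1925)
  dd <- gen_bbd_responses(box_behnken(), truth, sigma = 0, response = "sf")
  fit <- fit_rsm(dd, "sf", "quadratic_reduced")
  expect_equal(coef(fit)[names(truth)], truth, tolerance = 1e-9)
})

test_that("noisy design responses at the design's residual scale refit well", {
  truth <- c("(Intercept)" = 2.71, x1 = 0.1125, x2 = 0.11375, x3 = -0.13125,
             "x1:x3" = 0.1225, "x1^2" = -0.345, "x2^2" = -0.3825,
             "x3^2" = -0.1925)
  dd <- gen_bbd_responses(box_behnken(), truth, sigma = 0.07, seed = 21,
                          response = "sf")
  fit <- fit_rsm(dd, "sf", "quadratic_reduced")
  expect_gt(fit$r2, 0.90)
  expect_lt(fit$r2, 0.995)
})

test_that("synthetic flux curves are monotone and closed under estimation", {
  p <- study_flux_params()
  curve <- gen_flux_curve(p, conc = c(50, 100, 150, 200, 250), cv = 0, seed = 1)
  expect_true(all(diff(curve$flux) < 0))
  fit <- fit_flux_params(curve)
  expect_equal(fit$k, p$k, tolerance = 1e-10)
  expect_error(gen_flux_curve(p, conc = c(100, 400), cv = 0, seed = 1),
               "inside")
})

test_that("synthetic time series honour the rejection structure before noise", {
  sys <- reference_uf_system()
  ts <- seq(0, 3000, by = 600)
  obs <- gen_uf_timeseries(sys, ts, sigma = 0, seed = 1, t_end = 3600)
  ret_fc <- obs$conc[obs$stream == "retentate" & obs$solute == "fc"]
  perm_fc <- obs$conc[obs$stream == "permeate" & obs$solute == "fc"]
  expect_equal(perm_fc, ret_fc * (1 - 0.8), tolerance = 1e-9)
})

test_that("rejection is recoverable from a noisy time series by grid search", {
  truth_ro <- 0.8
  sys <- reference_uf_system(ro_fc = truth_ro)
  ts <- seq(300, 3300, by = 300)
  obs <- gen_uf_timeseries(sys, ts, sigma = 2, seed = 31, t_end = 3600)
  obs_fc <- obs[obs$solute == "fc", ]
  grid <- seq(0.5, 0.95, by = 0.01)
  sse <- vapply(grid, function(ro) {
    sys_try <- reference_uf_system(ro_fc = ro)
    traj <- simulate_uf(sys_try, t_end = 3600, n_out = 121)
    sum(validate_profiles(traj, obs_fc)$sse)
  }, numeric(1))
  expect_lt(abs(grid[which.min(sse)] - truth_ro), 0.05)
})
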