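test_that("compositions enforce closure and range at construction", {
  expect_s3_class(composition(0.6490, 0.2377, 0.1133), "composition")
  expect_error(composition(0.7, 0.2, 0.2), "does not close")
  expect_error(composition(-0.1, 0.6, 0.5), "\\[0, 1\\]")
  expect_error(composition(0.5, 0.5, NA), "finite")
  # percent inputs are stored as fractions
  cp <- composition(64.90, 23.77, 11.33, unit = "percent")
  expect_equal(sum(cp), 1, tolerance = 1e-12)
  # renormalization only through the explicit operation
  cn <- normalize_composition(65, 24, 11)
  expect_equal(sum(cn), 1, tolerance = 1e-12)
})

test_that("FOS:Fc ratio matches hand-derived values and rejects zero Fc", {
  expect_equal(fos_fc_ratio(composition(0.6490, 0.2377, 0.1133)),
               0.2377 / 0.6490, tolerance = 1e-12)
  expect_equal(round(fos_fc_ratio(composition(0.6490, 0.2377, 0.1133)), 5),
               0.36626)
  expect_equal(fos_fc_ratio(composition(0.5, 0.5, 0)), 1.0)
  expect_equal(round(fos_fc_ratio(composition(0.716, 0.171, 0.113)), 4),
               0.2388)
  expect_error(fos_fc_ratio(c(fc = 0, fos = 0.5)), "positive")
})

test_that("separation factor is a ratio of FOS:Fc ratios", {
  feed <- composition(0.6490, 0.2377, 0.1133)
  expect_equal(separation_factor(feed, feed), 1.0)
  expect_equal(separation_factor(1.225, 0.35), 3.50)
  # inverting SF = 2.74 at the study feed gives the enriched permeate ratio
  rp <- 2.74 * fos_fc_ratio(feed)
  expect_equal(separation_factor(rp, fos_fc_ratio(feed)), 2.74)
  expect_equal(rp, 2.74 * 0.2377 / 0.6490, tolerance = 1e-12)
  expect_equal(round(rp, 4), 1.0035)
  expect_error(separation_factor(1.0, 0), "positive")
})

test_that("solute flux converts SI inputs to kg/h/m2 and is bilinear", {
  expect_equal(solute_flux(0, 20, 0.5), 0)
  expect_equal(solute_flux(1e-5, 20, 0.5), 1.44)
  expect_equal(solute_flux(1e-5, 40, 0.5), 2 * solute_flux(1e-5, 20, 0.5))
  expect_equal(solute_flux(2e-5, 20, 0.5), 2 * solute_flux(1e-5, 20, 0.5))
  expect_error(solute_flux(1e-5, 20, 0), "positive")
})

test_that("apparent rejection and permeate concentration are mutual inverses", {
  expect_equal(apparent_rejection(0, 100), 1.0)
  expect_equal(apparent_rejection(50, 50), 0.0)
  expect_equal(apparent_rejection(18.5, 100), 0.815)
  expect_equal(permeate_conc(120, 0.795), 24.6)
  expect_equal(permeate_conc(120, 1), 0)
  expect_equal(permeate_conc(120, 0), 120)
  for (cp in c(0.3, 18.5, 99.9)) {
    expect_equal(permeate_conc(100, apparent_rejection(cp, 100)), cp,
                 tolerance = 1e-12)
  }
  expect_error(apparent_rejection(10, 0), "positive")
  expect_error(permeate_conc(100, 1.2), "exceed")
})

test_that("sum of squared errors behaves as a paired score", {
  expect_equal(sum_squared_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(sum_squared_error(c(1, 2), c(0, 0)), 5)
  p <- c(3, 1, 4, 1, 5); o <- c(2, 7, 1, 8, 2)
  expect_equal(sum_squared_error(p[c(3, 1, 5, 2, 4)], o[c(3, 1, 5, 2, 4)]),
               sum_squared_error(p, o))
  expect_error(sum_squared_error(1:3, 1:2), "mismatch")
})
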