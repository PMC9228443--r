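d <- table2_design()

test_that("linear coefficients equal the orthogonal-contrast closed form", {
  fit <- fit_rsm(d, "ji", form = "linear")
  for (x in c("x1", "x2", "x3")) {
    closed <- (mean(d$ji[d[[x]] == 1]) - mean(d$ji[d[[x]] == -1])) / 2
    expect_equal(coef(fit)[[x]], closed, tolerance = 1e-10)
  }
  expect_equal(coef(fit)[["(Intercept)"]], mean(d$ji), tolerance = 1e-10)
})

test_that("reduced quadratic SF fit re-expands to the published actual-unit model", {
  fit <- fit_rsm(d, "sf", form = "quadratic_reduced")
  expect_setequal(fit$terms,
                  c("x1", "x2", "x3", "x1:x3", "x1^2", "x2^2", "x3^2"))
  ac <- actual_coefficients(fit)
  expect_equal(round(ac[["(Intercept)"]], 2), -1.54)  # prints as -1.53 at lower precision
  expect_equal(ac[["temperature"]], 0.1291667, tolerance = 1e-6)
  expect_equal(ac[["tmp"]], 0.630625, tolerance = 1e-9)
  expect_equal(ac[["conc"]], 0.005425, tolerance = 1e-9)
  expect_equal(ac[["temperature:conc"]], 0.1225 / 750, tolerance = 1e-9)
  expect_equal(ac[["temperature^2"]], -0.345 / 225, tolerance = 1e-9)
  expect_equal(ac[["tmp^2"]], -0.095625, tolerance = 1e-9)
  expect_equal(ac[["conc^2"]], -7.7e-5, tolerance = 1e-9)
})

test_that("prediction is invariant under coded/actual re-expression", {
  fit <- fit_rsm(d, "sf", form = "quadratic_reduced")
  set.seed(3)
  pts <- data.frame(temperature = runif(30, 30, 60), tmp = runif(30, 1, 5),
                    conc = runif(30, 50, 150))
  expect_equal(predict(fit, pts, method = "coded"),
               predict(fit, pts, method = "actual"), tolerance = 1e-9)
})

test_that("prediction at the centre equals the fitted intercept and response mean", {
  fit <- fit_rsm(d, "ji", form = "linear")
  expect_equal(predict(fit, c(0, 0, 0), units = "coded"), mean(d$ji),
               tolerance = 1e-12)
  expect_equal(round(predict(fit, c(45, 3, 100))[1], 4), 1.1625)
})

test_that("dropping zero-truth terms leaves a noiseless fit unchanged", {
  truth <- c("(Intercept)" = 2.71, x1 = 0.1125, x2 = 0.11375, x3 = -0.13125,
             "x1:x3" = 0.1225, "x1^2" = -0.345, "x2^2" = -0.3825,
             "x3^2" = -0.1925)
  dd <- gen_bbd_responses(box_behnken(), truth, sigma = 0, response = "sf")
  full <- fit_rsm(dd, "sf", "quadratic")
  red <- fit_rsm(dd, "sf", "quadratic_reduced")
  expect_equal(coef(full)[names(truth)], truth, tolerance = 1e-9)
  expect_equal(coef(red)[names(truth)], truth, tolerance = 1e-9)
  expect_equal(coef(full)[["x1:x2"]], 0, tolerance = 1e-10)
})

test_that("constant response is flagged rather than reported as a fit", {
  dd <- d
  dd$sf <- 2.5
  fit <- fit_rsm(dd, "sf", "linear")
  expect_true(all(abs(coef(fit)[-1]) < 1e-12))
  expect_true(is.na(fit$r2))
})

test_that("ANOVA partial sums of squares decompose the residual exactly", {
  an <- anova_rsm(d, "sf", form = "quadratic")
  g <- function(tm) an$ss[an$term == tm]
  expect_equal(g("Lack of fit") + g("Pure error"), g("Residual"),
               tolerance = 1e-9)
  expect_equal(an$df[an$term == "Pure error"], 3)     # 4 centre replicates
  expect_equal(an$df[an$term == "Total"], 15)
  # orthogonal coded columns: closed-form SS for a linear term is
  # 8 * ((mean at +1 - mean at -1) / 2)^2
  closed <- 8 * ((mean(d$sf[d$x1 == 1]) - mean(d$sf[d$x1 == -1])) / 2)^2
  expect_equal(g("x1"), closed, tolerance = 1e-10)
  # r2 identity
  expect_equal(attr(an, "r2"), 1 - g("Residual") / g("Total"),
               tolerance = 1e-12)
})

test_that("pure error comes from the centre replicates alone", {
  an <- anova_rsm(d, "sf", form = "quadratic")
  ctr <- d$sf[d$x1 == 0 & d$x2 == 0 & d$x3 == 0]
  expect_equal(an$ss[an$term == "Pure error"], sum((ctr - mean(ctr))^2),
               tolerance = 1e-12)
  # without replicates the rows are omitted with a warning
  d13 <- gen_bbd_responses(box_behnken(n_center = 1),
                           c("(Intercept)" = 2, x1 = 0.3), sigma = 0.1,
                           seed = 5, response = "sf")
  expect_warning(an13 <- anova_rsm(d13, "sf", "linear"), "replicated")
  expect_false(any(an13$term %in% c("Pure error", "Lack of fit")))
})

test_that("solute-flux ANOVA matches its published summary", {
  an <- anova_rsm(d, "ji", form = "linear")
  expect_equal(an$ss[an$term == "x2"], 2.19, tolerance = 0.005)
  expect_equal(an$ss[an$term == "Total"], 5.98, tolerance = 0.005)
  expect_equal(100 * attr(an, "r2"), 75.01, tolerance = 0.05)
})
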