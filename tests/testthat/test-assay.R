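test_that("fluorescence slopes are recovered with honest uncertainty", {
  tt <- seq(0, 29) * 60
  exact <- fluorescence_slope(tt, 5 + 2 * tt)
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$se, 0, tolerance = 1e-9)

  flat <- fluorescence_slope(tt, rep(7, 30))
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  # seeded noisy line: slope within 3 SE of truth
  fx <- generate_assay_fixtures(
    true_params = list(slopes = c(control = 100), background = 20,
                       dose_response = list(Top = 1, Bottom = 0, LogIC50 = 0),
                       atpase = list(activity = 0.1, vanadate_rate = 0.01,
                                     time_min = 60, protein_mg = 0.05,
                                     standard_slope = 1)),
    noise_sd = list(fluorescence = 5, response = 0, absorbance = 0),
    seed = 8)
  d <- fx$fluorescence
  est <- fluorescence_slope(d$time, d$signal, 20)
  expect_lt(abs(est$slope - 100), 3 * est$se + 1e-9)

  expect_error(fluorescence_slope(c(0, 60), c(1, 2)), "at least 3")
  expect_error(fluorescence_slope(c(0, 60, 30), c(1, 2, 3)),
               "strictly increasing")
})

test_that("calcein efflux follows the inverse slope-ratio normalization", {
  expect_equal(calcein_efflux(5, 5), 1.0)
  expect_equal(calcein_efflux(50, 100), 2.0)
  expect_equal(calcein_efflux(200, 100), 0.5)
  expect_error(calcein_efflux(0, 100), "exactly zero")
  expect_error(calcein_efflux(1, 0), "non-zero")
  expect_warning(calcein_efflux(1e-9, 100), "near zero")
  # identity for any non-zero slope
  for (m in c(-3, 0.2, 17)) expect_equal(calcein_efflux(m, m), 1.0)
})

test_that("noiseless dose-response fits recover parameters exactly", {
  conc <- 10^seq(-2, 2.5, length.out = 8)
  y <- dose_response_curve(conc, top = 1, bottom = 0, log_ic50 = 0.5)
  fit <- fit_dose_response(conc, y)
  expect_equal(fit$Top, 1, tolerance = 1e-6)
  expect_equal(fit$Bottom, 0, tolerance = 1e-6)
  expect_equal(fit$LogIC50, 0.5, tolerance = 1e-6)
  expect_equal(fit$se_logIC50, 0, tolerance = 1e-6)
  expect_equal(fit$ic50, 10^0.5, tolerance = 1e-5)

  # self-consistency: the fitted curve at X = LogIC50 is the midpoint
  mid <- dose_response_curve(10^fit$LogIC50, fit$Top, fit$Bottom, fit$LogIC50)
  expect_equal(mid, (fit$Top + fit$Bottom) / 2, tolerance = 1e-12)

  expect_error(fit_dose_response(c(-1, 1, 10, 100), rep(1, 4)), "positive")
  expect_error(fit_dose_response(c(1, 1, 10, 10), rep(1, 4)), "4 distinct")
})

test_that("stimulation-shaped data converge with Top below Bottom", {
  conc <- 10^seq(-2, 2.5, length.out = 8)
  y <- dose_response_curve(conc, top = 0.2, bottom = 1.4, log_ic50 = 1)
  fit <- fit_dose_response(conc, y)
  expect_lt(fit$Top, fit$Bottom)
  expect_equal(fit$LogIC50, 1, tolerance = 1e-5)
})

test_that("noisy dose-response fits are unbiased with calibrated intervals", {
  conc <- 10^seq(-2, 3, length.out = 12)
  est <- numeric(100); cover <- 0
  for (s in 1:100) {
    fx <- generate_assay_fixtures(
      noise_sd = list(fluorescence = 0, response = 0.05, absorbance = 0),
      seed = s, concentrations_uM = conc)
    fit <- fit_dose_response(fx$dose_response$concentration_uM,
                             fx$dose_response$response)
    est[s] <- fit$LogIC50
    if (abs(fit$LogIC50 - 0.5) <= 1.96 * fit$se_logIC50) cover <- cover + 1
  }
  expect_lt(abs(mean(est) - 0.5), 0.02)
  expect_gte(cover, 90)
})

test_that("the fit is invariant to concentration rescaling up to a shift", {
  conc <- 10^seq(-2, 2.5, length.out = 8)
  y <- dose_response_curve(conc, 1, 0, 0.5) +
    alscreen:::.with_seed(3, rnorm(8, sd = 0.02))
  f1 <- fit_dose_response(conc, y)
  f2 <- fit_dose_response(conc * 1000, y)  # e.g. nM instead of uM
  expect_equal(f2$LogIC50 - f1$LogIC50, 3, tolerance = 1e-6)
  expect_equal(f2$Top, f1$Top, tolerance = 1e-6)
  expect_equal(f2$se_logIC50, f1$se_logIC50, tolerance = 1e-6)
})

test_that("log-scale IC50 conversion matches the reported pairings", {
  expect_equal(round(ic50_from_log(-0.96), 2), 0.11)
  expect_equal(round(ic50_from_log(2.51)), 324)
  expect_equal(ic50_from_log(0), 1.0)
  # inverse identity on positive values
  for (v in c(0.03, 1, 250)) expect_equal(ic50_from_log(log10(v)), v,
                                          tolerance = 1e-12)
})

test_that("sensitive ATPase activity follows the standard-curve arithmetic", {
  standards <- data.frame(absorbance = c(0, 0.25, 0.5, 1),
                          nmol = c(0, 0.25, 0.5, 1))
  test <- list(absorbance = 0.5, time_min = 60, protein_mg = 0.05)
  van <- list(absorbance = 0.1, time_min = 60, protein_mg = 0.05,
              vanadate = TRUE)
  a <- sensitive_atpase_activity(test, van, standards)
  expect_equal(a, (0.5 - 0.1) / (60 * 0.05), tolerance = 1e-9)

  # equal phosphate with and without vanadate gives zero
  same <- list(absorbance = 0.3, time_min = 60, protein_mg = 0.05,
               vanadate = TRUE)
  expect_equal(sensitive_atpase_activity(
    list(absorbance = 0.3, time_min = 60, protein_mg = 0.05), same, standards),
    0, tolerance = 1e-9)

  # negative activity is reported with a warning, not hidden
  expect_warning(
    neg <- sensitive_atpase_activity(
      list(absorbance = 0.05, time_min = 60, protein_mg = 0.05), van,
      standards),
    "negative")
  expect_lt(neg, 0)

  bad <- data.frame(absorbance = c(0, 1), nmol = c(1, 0))
  expect_error(sensitive_atpase_activity(test, van, bad), "non-positive slope")
  expect_error(sensitive_atpase_activity(
    test, list(absorbance = 0.1, time_min = 60, protein_mg = 0.05,
               vanadate = FALSE), standards),
    "vanadate")
})

test_that("fixture ATPase tables recover the known activity", {
  for (s in 1:5) {
    fx <- generate_assay_fixtures(
      noise_sd = list(fluorescence = 0, response = 0, absorbance = 0.002),
      seed = s)
    truth <- attr(fx, "truth")$atpase
    a <- sensitive_atpase_activity(as.list(fx$atpase[1, ]),
                                   as.list(fx$atpase[2, ]), fx$standards)
    # absorbance noise of 0.002 propagates to ~0.002/(60*0.05) per reading
    expect_lt(abs(a - truth$activity), 0.01)
  }
})
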