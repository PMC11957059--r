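# Shuffling-rate fitting and (kh, ke) inference.

test_that("the one-phase fit is exact on noiseless exponential data", {
  ser <- exact_series(0.1, 0.95, seq(0, 36, by = 6))
  fit <- fit_ks(ser, n_boot = 50, seed = 1)
  expect_equal(fit$ks, 0.1, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.95, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-12)
  expect_true(fit$ci_ks[1] <= 0.1 && fit$ci_ks[2] >= 0.1)
  expect_equal(unname(coef(fit)), c(fit$ks, fit$amplitude))
  expect_equal(predict(fit, c(0, 1e9)), c(0, 0.95), tolerance = 1e-6)
})

test_that("the fixed-amplitude variant pins p_inf at the 1:1 saturation", {
  ser <- exact_series(0.2, 62 / 64, seq(0, 24, by = 4))
  fit <- fit_ks(ser, fix_amplitude = TRUE, n_boot = 0)
  expect_equal(fit$amplitude, 62 / 64)
  expect_equal(fit$ks, 0.2, tolerance = 1e-6)
})

test_that("degenerate series are handled as specified", {
  expect_error(fit_ks(exact_series(0.1, 0.9, c(0, 6, 12))), "at least 4")
  dec <- data.frame(time_h = c(0, 6, 12, 24), hetero = c(0.8, 0.5, 0.3, 0.1))
  expect_error(fit_ks(dec), "decreases")
  zero <- data.frame(time_h = c(0, 6, 12, 24, 36), hetero = rep(0, 5))
  fit <- fit_ks(zero, seed = 2)
  expect_lt(fit$ks, 1e-6)
  expect_lte(fit$ci_ks[1], 1e-6) # CI covers zero
})

test_that("ks estimates are stable across simulation seeds", {
  p <- rate_params(kh = 0.8, ke = 1.2)
  tg <- seq(0, 8, 0.5)
  fits <- lapply(c(1, 2), function(s) {
    sim <- simulate_shuffling(p, 800, t_grid = tg, seed = s)
    fit_ks(sim$series, seed = s)
  })
  expect_lt(abs(fits[[1]]$ks - fits[[2]]$ks) /
              fits[[1]]$ks, 0.2)
  # seed-2 estimate inside seed-1 bootstrap interval
  expect_true(fits[[2]]$ks >= fits[[1]]$ci_ks[1] * 0.9 &&
                fits[[2]]$ks <= fits[[1]]$ci_ks[2] * 1.1)
})

test_that("predict_ks reports replicate spread and handles kh = 0", {
  expect_equal(predict_ks(0, 5)$ks, 0)
  f <- predict_ks(0.8, 1.2, quick_settings(n = 500, reps = 3))
  expect_length(f$ks_reps, 3)
  expect_gt(f$ks, 0)
  expect_lt(f$ks_sd / f$ks, 0.3)
})

test_that("(kh, ke) are recovered from (kcat, ks) by contour bisection", {
  kh_true <- 0.6; ke_true <- 3
  kc <- kcat(kh_true, ke_true)
  ks_true <- predict_ks(kh_true, ke_true,
                        quick_settings(n = 1000, reps = 3, seed = 11))$ks
  est <- estimate_from_kcat_ks(kc, ks_true,
                               settings = quick_settings(n = 1000, reps = 3,
                                                         seed = 77),
                               ke_range = c(1.05 * kc, 120))
  expect_equal(kcat(est$kh, est$ke), kc, tolerance = 1e-9)
  expect_lt(abs(est$ke - ke_true) / ke_true, 0.15)
  expect_lt(abs(est$kh - kh_true) / kh_true, 0.15)
})

test_that("an unattainable shuffling rate raises an infeasibility report", {
  expect_error(
    estimate_from_kcat_ks(0.3, 50,
                          settings = quick_settings(n = 400, reps = 2),
                          ke_range = c(0.5, 30)),
    "attainable range")
})

test_that("closed-form inversion from (kcat, fcs) is exact and monotone", {
  est <- estimate_from_kcat_fcs(0.5, 57 / 64)
  expect_equal(est$x, 1, tolerance = 1e-9)
  expect_equal(est$kh, 1, tolerance = 1e-9)
  expect_equal(est$ke, 1, tolerance = 1e-9)
  # identity: reproduce the constraints to numerical precision
  for (kc in c(0.08, 0.4, 0.9)) {
    for (fc in c(0.05, 0.5, 0.95)) {
      e <- estimate_from_kcat_fcs(kc, fc)
      expect_equal(kcat(e$kh, e$ke), kc, tolerance = 1e-9)
      expect_equal(fcs(e$kh, e$ke), fc, tolerance = 1e-9)
    }
  }
  # KaiC-EE regime: exchange rate of order 0.1 /h
  ee <- estimate_from_kcat_fcs(0.08, 0.95)
  expect_equal(ee$x, 1.391, tolerance = 1e-3)
  expect_equal(ee$ke, 0.1375, tolerance = 1e-3)
  expect_equal(ee$kh, 0.1913, tolerance = 1e-3)
  # higher CS fraction at fixed activity means relatively more hydrolysis
  xs <- vapply(c(0.2, 0.5, 0.8), function(fc)
    estimate_from_kcat_fcs(0.3, fc)$x, numeric(1))
  expect_true(all(diff(xs) > 0))
  kes <- vapply(c(0.2, 0.5, 0.8), function(fc)
    estimate_from_kcat_fcs(0.3, fc)$ke, numeric(1))
  expect_true(all(diff(kes) < 0))
  expect_error(estimate_from_kcat_fcs(0.3, 1), "boundary")
  expect_error(estimate_from_kcat_fcs(0.3, 0), "boundary")
})
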