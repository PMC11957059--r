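# Synthetic trace generation and seven-peak deconvolution.

test_that("peak model validates its geometry", {
  expect_error(peak_model(centers = c(17.5, 17.4, 18, 18.5, 19, 19.5, 20)),
               "increasing")
  expect_error(peak_model(widths = 0), "positive")
  expect_error(peak_model(amplitudes = c(-1, rep(1, 6))), "non-negative")
})

test_that("noiseless traces place peaks only where the distribution has
          mass, and the integrated area equals the scale", {
  pk <- peak_model()
  tr <- generate_trace(hex_dist(c(0.5, 0, 0, 0, 0, 0, 0.5)), pk)
  # two peaks: local maxima near 17.5 and 20.5 ml, nothing in between
  mid <- tr$signal[tr$volume > 18.3 & tr$volume < 19.7]
  expect_lt(max(mid), 0.02 * max(tr$signal))
  expect_equal(tr$volume[which.max(tr$signal * (tr$volume < 19))], 17.5,
               tolerance = 0.02)
  # quadrature oracle: trapezoid area of (signal - baseline) equals scale
  for (d in list(delta_dist(3), hex_dist(c(0.2, 0.1, 0.1, 0.2, 0.1, 0.1, 0.2)))) {
    tr <- generate_trace(d, pk, scale = 2.5)
    area <- sum(diff(tr$volume) *
                  (tr$signal[-length(tr$signal)] + tr$signal[-1]) / 2)
    expect_equal(area, 2.5, tolerance = 1e-6)
  }
})

test_that("exponentially modified Gaussian peaks integrate to unit area too", {
  pk <- peak_model(shape = "emg", tau = 0.08)
  tr <- generate_trace(delta_dist(2), pk, volume = seq(15, 24, by = 0.005))
  area <- sum(diff(tr$volume) *
                (tr$signal[-length(tr$signal)] + tr$signal[-1]) / 2)
  expect_equal(area, 1, tolerance = 1e-4)
})

test_that("deconvolution recovers the generating fractions at low noise", {
  pk <- peak_model()
  truth <- hex_dist(c(0.25, 0.05, 0.1, 0.15, 0.1, 0.05, 0.3))
  peak_max <- max(generate_trace(truth, pk)$signal)
  tr <- generate_trace(truth, pk, noise_sd = 0.01 * peak_max, seed = 7)
  fit <- deconvolve(tr, seed = 1)
  expect_s3_class(fit$dist, "hex_dist")
  expect_lt(max(abs(coef(fit) - as.numeric(truth))), 0.02)
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-9)
  expect_true(all(coef(fit) >= 0))
  expect_lt(fit$rel_resid, 0.1)
})

test_that("a homo-only trace deconvolves to the two end peaks", {
  pk <- peak_model()
  tr <- generate_trace(hex_dist(c(0.5, 0, 0, 0, 0, 0, 0.5)), pk,
                       noise_sd = 0.005, seed = 3)
  fit <- deconvolve(tr, seed = 2)
  expect_gte(sum(coef(fit)[c(1, 7)]), 0.99)
  expect_lte(hetero_fraction(fit$dist), 0.01)
})

test_that("degenerate and malformed inputs are rejected", {
  pk <- peak_model()
  flat <- chromatogram(seq(16, 22, 0.01), rep(0, 601))
  expect_error(deconvolve(flat, pk), "degenerate")
  short <- generate_trace(delta_dist(0), pk, volume = seq(16, 18, 0.01))
  expect_error(deconvolve(short, pk), "cover")
})

test_that("a trace series assembles into a time-ordered shuffle series", {
  pk <- peak_model()
  phs <- c(0, 0.3, 0.6)
  traces <- lapply(seq_along(phs), function(i) {
    h <- phs[i]
    d <- hex_dist(c((1 - h) / 2, h * dbinom(1:5, 6, 0.5) / sum(dbinom(1:5, 6, 0.5)),
                    (1 - h) / 2))
    generate_trace(d, pk, noise_sd = 0.003, seed = 10 + i,
                   time_h = c(0, 6, 12)[i])
  })
  ser <- series_from_traces(traces[c(2, 1, 3)], pk) # unordered input
  expect_equal(ser$times, c(0, 6, 12))
  expect_equal(hetero_fraction(ser), phs, tolerance = 0.02)
  expect_error(series_from_traces(traces[1]), "at least 2")
  dup <- traces
  dup[[2]]$time_h <- 0
  expect_error(series_from_traces(dup), "duplicate")
})

test_that("chromatogram CSV round-trips", {
  tr <- generate_trace(delta_dist(6), peak_model(), noise_sd = 0.01, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_chromatogram(tr, path)
  back <- read_chromatogram(path, time_h = 3)
  expect_equal(back$volume, tr$volume)
  expect_equal(back$signal, tr$signal, tolerance = 1e-12)
  expect_equal(back$time_h, 3)
})
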