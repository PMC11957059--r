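# Properties of the stochastic shuffling simulators.

wt_like <- rate_params(kh = 0.8, ke = 1.2)

test_that("no hydrolysis means no competent state and no shuffling", {
  p <- rate_params(kh = 0, ke = 5)
  sim <- simulate_shuffling(p, 300, t_grid = seq(0, 12, 2), seed = 1)
  expect_equal(hetero_fraction(sim$series), rep(0, 7))
})

test_that("subunits, tags and totals are conserved along trajectories", {
  sim <- simulate_shuffling(wt_like, 100, t_grid = seq(0, 4, 1), seed = 2)
  cc <- conservation_check(sim)
  expect_true(cc$subunits_conserved)
  expect_true(cc$tags_conserved)
  expect_equal(unique(cc$subunits), 600)   # 100 hexamers x 6
  expect_equal(unique(cc$tagged), 300)     # half the pool fully tagged
  sime <- simulate_shuffling(rate_params(kh = 0.5, ke = 2, kdcs = 200,
                                         krcs = 1000),
                             200, t_grid = seq(0, 3, 1), method = "explicit",
                             seed = 3)
  cce <- conservation_check(sime)
  expect_true(cce$subunits_conserved) # hexamers x 6 + free oligomer subunits
  expect_true(cce$tags_conserved)
  expect_equal(unique(cce$subunits), 1200)
})

test_that("with shuffling disabled the ADP histogram is Binomial(6, kh/(kh+ke))
          and the CS fraction matches the closed form", {
  n <- 4000
  sim <- simulate_shuffling(wt_like, n, t_grid = c(0, 3, 5), seed = 4,
                            shuffle_on = FALSE)
  emp <- sim$d_hist[3, ]
  ref <- dbinom(0:6, 6, wt_like$kh / (wt_like$kh + wt_like$ke))
  expect_lt(max(abs(emp - ref)), 4 * sqrt(max(ref * (1 - ref)) / n))
  expect_equal(sum(emp[3:7]), fcs(wt_like$kh, wt_like$ke), tolerance = 0.04)
})

test_that("per-monomer ADP occupancy converges to kh/(kh+ke) regardless of
          shuffling", {
  n <- 2000
  sim <- simulate_shuffling(wt_like, n, t_grid = c(0, 4, 6), seed = 5)
  occ <- sim$nuc_totals[3, 2] / (6 * n)
  expect_equal(occ, wt_like$kh / (wt_like$kh + wt_like$ke), tolerance = 0.03)
})

test_that("long runs converge to the random binomial ladder", {
  sim <- simulate_shuffling(wt_like, 2000, t_grid = c(0, 10, 15), seed = 6)
  final <- sim$series$p[3, ]
  expect_lt(max(abs(final - as.numeric(random_distribution()))), 0.03)
})

test_that("hetero fraction is non-decreasing in expectation from an unmixed
          start", {
  tg <- seq(0, 8, 1)
  ph <- rowMeans(vapply(1:4, function(s)
    hetero_fraction(simulate_shuffling(wt_like, 500, t_grid = tg,
                                       seed = 10 + s)$series),
    numeric(length(tg))))
  expect_true(all(diff(ph) > -0.015))
})

test_that("tag-relabelling symmetry: the late-time distribution is symmetric
          under k <-> 6-k at a 1:1 mix", {
  sims <- vapply(1:4, function(s)
    simulate_shuffling(wt_like, 1000, t_grid = c(0, 6, 9),
                       seed = 20 + s)$series$p[3, ], numeric(7))
  avg <- rowMeans(sims)
  expect_lt(max(abs(avg - rev(avg))), 0.04)
})

test_that("fast-equilibrium and explicit-rate simulators agree when
          dissociation is fast (kdcs/max(kh, ke) >= 100)", {
  p <- rate_params(kh = 0.5, ke = 2, kdcs = 200, krcs = 1000)
  tg <- seq(0, 4, 0.5)
  seeds <- 1:6
  phE <- rowMeans(vapply(seeds, function(s)
    hetero_fraction(simulate_shuffling(p, 400, t_grid = tg,
                                       method = "explicit", seed = s)$series),
    numeric(length(tg))))
  phF <- rowMeans(vapply(seeds, function(s)
    hetero_fraction(simulate_shuffling(p, 400, t_grid = tg,
                                       method = "fast_eq", seed = 100 + s)$series),
    numeric(length(tg))))
  expect_lt(max(abs(phE - phF)), 0.07)
})

test_that("the explicit method keeps the free-oligomer pool small at the
          default association rate", {
  p <- rate_params(kh = 0.5, ke = 2, kdcs = 200, krcs = 1000)
  sim <- simulate_shuffling(p, 400, t_grid = seq(0, 3, 1),
                            method = "explicit", seed = 9)
  expect_lt(max(sim$free_oligomers$subunits) / (400 * 6), 0.05)
})

test_that("a coarse synchronisation interval is flagged in run metadata", {
  sim <- simulate_shuffling(wt_like, 200, t_grid = c(0, 1), seed = 1,
                            dt_mix = 1 / (6 * (wt_like$kh + wt_like$ke)))
  expect_length(sim$warnings, 1)
  expect_match(sim$warnings, "dt_mix")
})

test_that("input validation rejects malformed simulation requests", {
  expect_error(simulate_shuffling(wt_like, 50), "at least 100")
  expect_error(simulate_shuffling(wt_like, 200, tag_split = 1.5), "tag_split")
  expect_error(simulate_shuffling(wt_like, 200, t_grid = c(2, 1)), "increasing")
  expect_error(simulate_shuffling(rate_params(kh = 1, ke = 1, conc_pnp = 1),
                                  200, init = "steady_state"), "ATP-only")
})

test_that("AMP-PNP competition reduces to the ATP-only model when [PNP] = 0
          and shuts down shuffling when exchange can only install PNP", {
  p0 <- rate_params(kh = 0.8, ke = 1.2, conc_atp = 1, conc_pnp = 0)
  a <- simulate_pnp(p0, 400, t_grid = seq(0, 6, 1), seed = 31)
  b <- simulate_shuffling(p0, 400, t_grid = seq(0, 6, 1), seed = 31)
  expect_equal(a$series$p, b$series$p) # same seed policy, identical reduction
  # no ATP anywhere (zero residual ATP, some initial ADP): the initial ADP
  # exchanges to AMP-PNP, hydrolysis becomes impossible and the hetero
  # fraction plateaus far below the mixed limit
  pn <- rate_params(kh = 0.8, ke = 1.2, conc_atp = 0, conc_pnp = 1)
  sim <- simulate_pnp(pn, 600, t_grid = seq(0, 20, 2), seed = 32,
                      init_adp_frac = 0.1, init_pnp_frac = 0.9)
  ph <- hetero_fraction(sim$series)
  expect_lt(ph[length(ph)], 0.6)
  late <- ph[6:11]
  expect_lt(max(late) - min(late), 0.02) # plateau
})

test_that("raising the AMP-PNP share of the buffer slows mixing", {
  ph36 <- vapply(c(0, 0.7), function(pnp) {
    p <- rate_params(kh = 0.8, ke = 1.2, conc_atp = 0.3, conc_pnp = pnp,
                     KA = 5)
    mean(vapply(1:3, function(s)
      hetero_fraction(series_dist(
        simulate_pnp(p, 400, t_grid = c(0, 3, 6), seed = 40 + s)$series, 3)),
      numeric(1)))
  }, numeric(1))
  expect_gt(ph36[1], ph36[2])
})

test_that("shuffling rate falls with the exchange rate at fixed ATPase
          activity", {
  ks_at <- function(kcat, ke) {
    predict_ks(invert_kcat(kcat, ke), ke,
               quick_settings(n = 500, reps = 2, seed = 7))$ks
  }
  for (kc in c(0.2, 0.5, 0.8)) {
    ks <- vapply(c(1.5, 6, 24), function(ke) ks_at(kc, ke), numeric(1))
    expect_true(all(diff(ks) < 0), info = sprintf("kcat = %g", kc))
  }
})
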