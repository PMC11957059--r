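# Dissociation-mode kinematics and the L-statistic classification.

test_that("cooperative break-up randomises immediately: L stays near zero and
          the distribution converges to the binomial ladder", {
  ser <- simulate_mode("cooperative", n_hexamers = 4000,
                       t_grid = seq(0, 8, 0.5), seed = 1)
  tr <- l_trajectory(ser, "cooperative")
  expect_true(all(tr$L >= 0))
  expect_lt(max(tr$L), 0.06)
  final <- ser$p[nrow(ser$p), ]
  expect_lt(max(abs(final - as.numeric(random_distribution()))), 0.03)
})

test_that("at 40% hetero-hexamers the sequential mode is dominated by 1- and
          5-tag species while the stochastic mode is nearly flat", {
  ss <- simulate_mode("sequential", n_hexamers = 4000,
                      t_grid = seq(0, 25, 0.5), seed = 2)
  so <- simulate_mode("stochastic", n_hexamers = 4000,
                      t_grid = seq(0, 25, 0.5), seed = 2)
  d_seq <- interpolate_at_qmix(ss, 0.4)
  d_sto <- interpolate_at_qmix(so, 0.4)
  expect_gt(sum(d_seq[c(2, 6)]), 3 * sum(d_seq[3:5]))
  hetero_sto <- as.numeric(d_sto[2:6]) / sum(d_sto[2:6])
  expect_lt(max(hetero_sto) / min(hetero_sto), 1.7) # nearly equal percentage
})

test_that("stochastic cuts produce every fragment size with equal frequency
          (chi-square on cross-assembled tag counts)", {
  # from a pure-tagged/pure-native start, a cross-assembled hexamer carries
  # k equal to the size of its tagged fragment, so early hetero counts read
  # out the fragment-size distribution
  ser <- simulate_mode("stochastic", n_hexamers = 8000,
                       t_grid = c(0, 0.15), seed = 3, step_frac = 0.05)
  counts <- ser$p[2, 2:6] * 8000
  expect_gt(sum(counts), 150)
  pval <- chisq.test(round(counts))$p.value
  expect_gt(pval, 0.01)
})

test_that("monomer and tag totals are conserved by every mode", {
  for (m in c("sequential", "cooperative", "stochastic")) {
    ser <- simulate_mode(m, n_hexamers = 500, t_grid = seq(0, 4, 1),
                         seed = 4)
    ktot <- as.vector(ser$p %*% (0:6)) * 500
    expect_equal(ktot, rep(ktot[1], length(ktot)), tolerance = 1e-9)
    expect_equal(rowSums(ser$p), rep(1, nrow(ser$p)))
  }
})

test_that("sequential-mode L dominates stochastic-mode L at matched qmix and
          all modes converge to the random ladder", {
  ts <- l_trajectory(simulate_mode("sequential", 5000,
                                   t_grid = seq(0, 30, 0.5), seed = 5),
                     "sequential")
  to <- l_trajectory(simulate_mode("stochastic", 5000,
                                   t_grid = seq(0, 30, 0.5), seed = 5),
                     "stochastic")
  g <- seq(0.2, 0.9, 0.1)
  Ls <- approx(ts$qmix[!duplicated(ts$qmix)], ts$L[!duplicated(ts$qmix)], g)$y
  Lo <- approx(to$qmix[!duplicated(to$qmix)], to$L[!duplicated(to$qmix)], g)$y
  expect_true(all(Ls > Lo))
  expect_gt(tail(ts$qmix, 1), 0.9)
  expect_lt(tail(ts$L, 1), 0.15) # approaching the random ladder
})

test_that("interpolation at a target mixing stage follows the spec contract", {
  times <- c(0, 1, 2)
  p <- rbind(c(0.5, 0, 0, 0, 0, 0, 0.5),
             c(0.4, 0.05, 0.05, 0, 0.05, 0.05, 0.4),
             c(0.3, 0.1, 0.1, 0, 0.1, 0.1, 0.3))
  ser <- shuffle_series(times, p)
  # exact hit returned unchanged
  expect_equal(as.numeric(interpolate_at_qmix(ser, 0.2)), p[2, ])
  # midway between two points: arithmetic mean (rows already normalised)
  expect_equal(as.numeric(interpolate_at_qmix(ser, 0.3)),
               (p[2, ] + p[3, ]) / 2)
  expect_error(interpolate_at_qmix(ser, 0.99), "outside")
  expect_s3_class(interpolate_at_qmix(ser, 0.99, extrapolate = TRUE),
                  "hex_dist")
})

test_that("held-out simulations are classified into their generating mode", {
  refs <- mode_reference_curves(n_hexamers = 3000, n_seeds = 3, seed = 50,
                                t_grid = seq(0, 25, 0.5))
  for (m in c("sequential", "cooperative", "stochastic")) {
    obs <- l_trajectory(simulate_mode(m, 3000, t_grid = seq(0, 25, 1),
                                      seed = 99), m)
    obs <- obs[obs$qmix > 0.05 & obs$qmix < 0.95, ]
    cls <- classify_mode(obs, refs)
    expect_equal(cls$mode, m)
    expect_named(cls$scores, c("sequential", "cooperative", "stochastic"))
  }
  # an all-zero L trajectory is the cooperative signature
  flat <- structure(data.frame(qmix = seq(0.1, 0.9, 0.1), L = 0,
                               mode = "observed"),
                    class = c("l_trajectory", "data.frame"))
  expect_equal(classify_mode(flat, refs)$mode, "cooperative")
  expect_error(classify_mode(flat[0, ], refs), "empty")
})
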