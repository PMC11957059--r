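# Shared helpers for building small in-code fixtures.

# a shuffle_series whose hetero fraction follows an exact one-phase
# exponential, with the hetero mass spread evenly over k = 1..5
exact_series <- function(ks, p_inf, times) {
  ph <- p_inf * (1 - exp(-ks * times))
  p <- t(vapply(ph, function(h) c((1 - h) / 2, rep(h / 5, 5), (1 - h) / 2),
                numeric(7)))
  shuffle_series(times, p)
}

# quick low-cost simulation settings for tests
quick_settings <- function(n = 600, reps = 2, seed = 42, t_grid = NULL,
                           max_t = 150) {
  sim_settings(n_hexamers = n, n_reps = reps, base_seed = seed,
               t_grid = t_grid, max_t = max_t)
}

# hexamer distribution concentrated on a single tag count
delta_dist <- function(k) {
  p <- rep(0, 7)
  p[k + 1] <- 1
  hex_dist(p)
}
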