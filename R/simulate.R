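# Stochastic simulation of nucleotide-coupled subunit shuffling.

#' Time series of hexamer tag-count distributions
#'
#' @param times sampling times in hours, strictly increasing.
#' @param p matrix with one row per time and 7 columns (fractions for
#'   k = 0..6 tagged subunits).
#' @return an object of class `shuffle_series`.
#' @export
shuffle_series <- function(times, p) {
  times <- as.numeric(times)
  p <- as.matrix(p)
  if (nrow(p) != length(times) || ncol(p) != 7L)
    stop("p must be a length(times) x 7 matrix")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  for (i in seq_len(nrow(p)))
    if (!is_valid_hex_dist(p[i, ]))
      stop(sprintf("row %d is not a valid hexamer distribution", i))
  dimnames(p) <- list(NULL, paste0("p", 0:6))
  structure(list(times = times, p = p), class = "shuffle_series")
}

#' @export
print.shuffle_series <- function(x, ...) {
  cat(sprintf("Shuffle series: %d time points, %.3g to %.3g h\n",
              length(x$times), min(x$times), max(x$times)))
  ph <- hetero_fraction(x)
  cat(sprintf("hetero fraction: %.4f (start) -> %.4f (end)\n",
              ph[1], ph[length(ph)]))
  invisible(x)
}

#' @export
as.data.frame.shuffle_series <- function(x, ...) {
  data.frame(time_h = x$times, x$p, check.names = FALSE)
}

#' @rdname hetero_fraction
#' @export
hetero_fraction.shuffle_series <- function(dist) {
  apply(dist$p, 1, function(r) sum(r[2:6]))
}

#' @rdname hetero_fraction
#' @export
hetero_fraction.shuffle_sim <- function(dist) hetero_fraction(dist$series)

#' Extract the distribution at one time point
#'
#' @param series a [shuffle_series()].
#' @param i time index.
#' @return a [hex_dist()].
#' @export
series_dist <- function(series, i) hex_dist(series$p[i, ])

#' Write / read a shuffle series as CSV
#'
#' Columns `time_h`, `p0`..`p6`.
#' @param series a [shuffle_series()].
#' @param path file path.
#' @return `read_series` returns a [shuffle_series()]; `write_series` its
#'   path, invisibly.
#' @export
write_series <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- read.csv(path)
  need <- c("time_h", paste0("p", 0:6))
  if (!all(need %in% names(df)))
    stop("series CSV needs columns time_h, p0..p6")
  shuffle_series(df$time_h, as.matrix(df[, paste0("p", 0:6)]))
}

#' Simulate nucleotide-coupled subunit shuffling
#'
#' Stochastic simulation of a population of hexamers under per-monomer ATP
#' hydrolysis (rate `kh`) and nucleotide exchange (rate `ke`), coupled to
#' subunit exchange among competent-state (CS) hexamers -- those with two or
#' more ADP-bound monomers.  Two coupling methods are available:
#'
#' * `"fast_eq"` (default): shuffling is taken to equilibrate fast relative
#'   to the nucleotide reactions (the CS dissociation rate `kdcs` of about
#'   1/s is orders of magnitude above `kh` and `ke`), so at synchronisation
#'   intervals `dt_mix` all subunits of all current CS-hexamers are pooled
#'   and repartitioned uniformly at random into new hexamers.  Per-monomer
#'   reactions are advanced by tau-leaping with step `dt_mix`.
#' * `"explicit"`: full event-driven (Gillespie) dynamics in which
#'   CS-hexamers dissociate at rate `kdcs` into two contiguous oligomer arcs
#'   and complementary-size free oligomers re-associate at rate `krcs` per
#'   pair.  Free oligomers keep their nucleotide and tag states and continue
#'   per-monomer kinetics; ground-state hexamers never dissociate.  This
#'   method is the finite-rate oracle for the fast-equilibrium approximation.
#'
#' @param params a [rate_params()].
#' @param n_hexamers number of hexamers (>= 100).
#' @param tag_split fraction of hexamers that start fully tagged (default
#'   0.5, the 1:1 mixing experiment).
#' @param t_grid sampling times, hours, increasing (first point 0 records the
#'   initial state).
#' @param init `"all_T"` (freshly purified protein in ATP buffer; optionally
#'   with residual ADP via `init_adp_frac`) or `"steady_state"` (binomial
#'   nucleotide occupancy at `kh/(kh+ke)`).
#' @param method `"fast_eq"` or `"explicit"`.
#' @param seed integer seed; if non-NULL, `set.seed(seed)` is called.
#' @param dt_mix fast-equilibrium synchronisation interval, hours; default
#'   `0.1 / (6 (kh + ke))`, well below the per-hexamer reaction timescale.
#' @param cut_rule how a dissociating CS-hexamer is cut into two arcs
#'   (explicit method): `"uniform"` over the 15 unordered interface pairs, or
#'   `"weakened"` over pairs of ADP-weakened interfaces only.
#' @param shuffle_on set FALSE to disable subunit exchange entirely (used to
#'   verify the binomial nucleotide steady state).
#' @param init_adp_frac residual ADP fraction at t = 0 for `init = "all_T"`.
#' @param init_pnp_frac fraction of monomers starting AMP-PNP-bound (models
#'   protein pre-equilibrated in analogue-containing buffer; the remaining
#'   residual-ATP fraction is `1 - init_adp_frac - init_pnp_frac`).
#' @param exchange_n whether AMP-PNP-bound monomers undergo nucleotide
#'   exchange at the full rate `ke` (default TRUE; only relevant when
#'   `conc_pnp > 0`).
#' @return an object of class `shuffle_sim`: the tag-distribution
#'   [shuffle_series()], ADP-count and (j, k) occupancy trajectories, subunit
#'   conservation tallies, and run metadata.
#' @examples
#' p <- rate_params(kh = 0.8, ke = 1.2)
#' sim <- simulate_shuffling(p, n_hexamers = 200, t_grid = seq(0, 6, 1), seed = 1)
#' hetero_fraction(sim$series)
#' @export
simulate_shuffling <- function(params, n_hexamers = 5000, tag_split = 0.5,
                               t_grid = seq(0, 36, by = 2),
                               init = c("all_T", "steady_state"),
                               method = c("fast_eq", "explicit"),
                               seed = NULL, dt_mix = NULL,
                               cut_rule = c("uniform", "weakened"),
                               shuffle_on = TRUE, init_adp_frac = 0,
                               init_pnp_frac = 0, exchange_n = TRUE) {
  if (!inherits(params, "rate_params")) stop("params must be rate_params")
  init <- match.arg(init)
  method <- match.arg(method)
  cut_rule <- match.arg(cut_rule)
  if (n_hexamers < 100) stop("n_hexamers must be at least 100")
  if (tag_split < 0 || tag_split > 1) stop("tag_split must lie in [0, 1]")
  t_grid <- as.numeric(t_grid)
  if (any(diff(t_grid) <= 0) || any(t_grid < 0))
    stop("t_grid must be non-negative and increasing")
  if (params$kh + params$ke <= 0) stop("kh + ke must be positive")

  # incoming-nucleotide identity on exchange: ATP with probability
  # KA [ATP] / (KA [ATP] + [PNP])
  if (params$conc_atp + params$conc_pnp <= 0)
    stop("total nucleotide concentration must be positive")
  w_atp <- params$KA * params$conc_atp /
    (params$KA * params$conc_atp + params$conc_pnp)

  if (init_adp_frac < 0 || init_pnp_frac < 0 ||
      init_adp_frac + init_pnp_frac > 1)
    stop("initial ADP and AMP-PNP fractions must be non-negative and sum to at most 1")
  init_d <- switch(init,
                   all_T = init_adp_frac,
                   steady_state = {
                     if (params$conc_pnp > 0)
                       stop("steady_state init is only defined for ATP-only runs")
                     params$kh / (params$kh + params$ke)
                   })
  init_n <- if (init == "all_T") init_pnp_frac else 0
  n_tagged <- round(n_hexamers * tag_split)
  if (!is.null(seed)) set.seed(seed)

  warnings <- character()
  if (method == "fast_eq") {
    tau <- 1 / (6 * (params$kh + params$ke))
    if (is.null(dt_mix)) dt_mix <- 0.1 * tau
    if (dt_mix > 0.5 * tau)
      warnings <- c(warnings, sprintf(
        "dt_mix = %.3g h is not small against the per-hexamer reaction time %.3g h",
        dt_mix, tau))
    res <- .sim_fast_eq_cpp(n_hexamers, n_tagged, params$kh, params$ke,
                            t_grid, dt_mix, w_atp, exchange_n, init_d,
                            init_n, shuffle_on)
    free <- NULL
  } else {
    if (!shuffle_on) stop("shuffle_on = FALSE is only supported for fast_eq")
    res <- .sim_explicit_cpp(n_hexamers, n_tagged, params$kh, params$ke,
                             t_grid, params$kdcs, params$krcs, w_atp,
                             exchange_n, init_d, init_n,
                             if (cut_rule == "weakened") 1L else 0L)
    free <- list(subunits = res$free_subunits,
                 olig_sizes = res$olig_sizes,
                 n_hexamers = res$n_hexamers)
  }

  denom <- rowSums(res$pk_counts)
  series <- shuffle_series(t_grid, res$pk_counts / denom)
  jk <- if (!is.null(res$jk_counts))
    array(t(res$jk_counts), dim = c(7, 7, length(t_grid)),
          dimnames = list(paste0("k", 0:6), paste0("j", 0:6), NULL)) / n_hexamers
  structure(list(series = series,
                 d_hist = res$d_hist / denom,
                 jk = jk,
                 nuc_totals = res$nuc_totals,
                 tag_totals = if (!is.null(res$tag_totals)) res$tag_totals
                              else rep(6L * n_tagged, length(t_grid)),
                 free_oligomers = free,
                 final_state = if (method == "fast_eq")
                   list(nuc = res$nuc_final, tag = res$tag_final),
                 params = params, n_hexamers = n_hexamers,
                 tag_split = tag_split, method = method, init = init,
                 seed = seed, dt_mix = if (method == "fast_eq") dt_mix,
                 cut_rule = if (method == "explicit") cut_rule,
                 warnings = warnings),
            class = "shuffle_sim")
}

#' Simulate shuffling under ATP / AMP-PNP competition
#'
#' Three-nucleotide extension of [simulate_shuffling()]: on a nucleotide
#' exchange event the incoming nucleotide is ATP with probability
#' `KA [ATP] / (KA [ATP] + [PNP])` and AMP-PNP otherwise.  AMP-PNP-bound
#' monomers cannot hydrolyse and count as ATP-like for interface stability
#' (only ADP counts toward the competent state).
#'
#' @inheritParams simulate_shuffling
#' @return a `shuffle_sim` object.
#' @export
simulate_pnp <- function(params, n_hexamers = 5000, tag_split = 0.5,
                         t_grid = seq(0, 36, by = 2), seed = NULL,
                         init_adp_frac = 0, init_pnp_frac = 0,
                         exchange_n = TRUE, ...) {
  if (!inherits(params, "rate_params")) stop("params must be rate_params")
  if (params$conc_atp < 0 || params$conc_pnp < 0)
    stop("concentrations must be non-negative")
  simulate_shuffling(params, n_hexamers = n_hexamers, tag_split = tag_split,
                     t_grid = t_grid, init = "all_T", method = "fast_eq",
                     seed = seed, init_adp_frac = init_adp_frac,
                     init_pnp_frac = init_pnp_frac,
                     exchange_n = exchange_n, ...)
}

#' @export
print.shuffle_sim <- function(x, ...) {
  cat(sprintf("Shuffling simulation (%s method), %d hexamers, %d time points\n",
              x$method, x$n_hexamers, length(x$series$times)))
  cat(sprintf("  kh = %.4g /h, ke = %.4g /h (kcat = %.4g /h)\n",
              x$params$kh, x$params$ke, kcat(x$params$kh, x$params$ke)))
  ph <- hetero_fraction(x$series)
  cat(sprintf("  hetero fraction: %.4f -> %.4f over %.3g h\n",
              ph[1], ph[length(ph)], max(x$series$times)))
  if (length(x$warnings)) cat("  warnings:", x$warnings, sep = "\n   ")
  invisible(x)
}

#' @export
summary.shuffle_sim <- function(object, ...) {
  cc <- conservation_check(object)
  out <- list(hetero = hetero_fraction(object$series),
              times = object$series$times,
              conservation = cc,
              cs_fraction_end = sum(object$d_hist[nrow(object$d_hist), 3:7]))
  class(out) <- "summary.shuffle_sim"
  out
}

#' @export
print.summary.shuffle_sim <- function(x, ...) {
  cat("Hetero-hexamer fraction over time:\n")
  print(data.frame(time_h = x$times, hetero = round(x$hetero, 4)))
  cat(sprintf("Subunits conserved: %s; tags conserved: %s\n",
              x$conservation$subunits_conserved, x$conservation$tags_conserved))
  cat(sprintf("CS-hexamer fraction at final time: %.4f\n", x$cs_fraction_end))
  invisible(x)
}

#' @export
plot.shuffle_sim <- function(x, ...) {
  ph <- hetero_fraction(x$series)
  plot(x$series$times, ph, type = "b", pch = 16,
       xlab = "time (h)", ylab = "hetero-hexamer fraction",
       ylim = c(0, 1), ...)
  abline(h = 62 / 64, lty = 3)
  invisible(x)
}

#' Subunit and tag conservation report
#'
#' Tallies total subunits, tagged subunits and per-nucleotide counts at each
#' recorded time of a simulation and reports whether they are constant over
#' the trajectory (they must be: shuffling permutes monomers but never
#' creates or destroys them).
#'
#' @param sim a `shuffle_sim` object.
#' @return a list with per-time totals and logical flags
#'   `subunits_conserved`, `tags_conserved`.
#' @export
conservation_check <- function(sim) {
  if (!inherits(sim, "shuffle_sim")) stop("sim must be a shuffle_sim")
  nuc <- sim$nuc_totals
  subunits <- rowSums(nuc)
  if (!is.null(sim$free_oligomers)) {
    # explicit method already counts free subunits inside nuc_totals
  }
  tags <- as.numeric(sim$tag_totals)
  list(subunits = subunits,
       tagged = tags,
       nucleotides = nuc,
       subunits_conserved = length(unique(subunits)) == 1L,
       tags_conserved = length(unique(tags)) == 1L)
}
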