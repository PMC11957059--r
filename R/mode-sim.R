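# Dissociation-pattern kinematics: sequential, cooperative and stochastic
# hydrolysis modes produce different hexamer break-up fragments, hence
# different tag-count distributions along the mixing trajectory.  This module
# has no nucleotide states: breakup_rate only sets the time axis and cancels
# from L-versus-qmix curves.

mode_labels <- c("sequential", "cooperative", "stochastic")

#' Simulate a candidate dissociation mode
#'
#' Event-driven simulation of hexamer break-up and reassembly for one of the
#' three canonical AAA+ hydrolysis patterns:
#'
#' * `"sequential"`: ordered hydrolysis around the ring leaves two adjacent
#'   weak interfaces, so the hexamer splits into a monomer and a pentamer at
#'   a uniformly random ring position;
#' * `"cooperative"`: all interfaces fail together and the hexamer splits
#'   into six monomers;
#' * `"stochastic"`: two loose interfaces arise at a uniformly random pair of
#'   the 15 unordered interface pairs, producing every fragment size 1--5
#'   with equal expected frequency.
#'
#' Fragments enter a common pool at each event epoch and complementary sizes
#' (1+5, 2+4, 3+3; six monomers at a time for the cooperative mode) rejoin
#' uniformly at random -- reassembly is fast relative to breakup.
#'
#' @param mode one of `"sequential"`, `"cooperative"`, `"stochastic"`.
#' @param n_hexamers population size (>= 100); half tagged, half native.
#' @param breakup_rate per-hexamer breakup rate, 1/h.
#' @param t_grid sampling times, hours.
#' @param seed integer seed.
#' @param step_frac expected fraction of hexamers breaking per internal step
#'   (controls time discretisation; fragments produced within one step share
#'   a reassembly pool).
#' @return a [shuffle_series()] of tag-count distributions.
#' @export
simulate_mode <- function(mode = mode_labels, n_hexamers = 10000,
                          breakup_rate = 1, t_grid = seq(0, 30, by = 0.5),
                          seed = NULL, step_frac = 0.02) {
  mode <- match.arg(mode)
  if (n_hexamers < 100) stop("n_hexamers must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  t_grid <- as.numeric(t_grid)
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")

  n <- n_hexamers
  tags <- matrix(FALSE, n, 6)
  tags[seq_len(round(n / 2)) + (n - round(n / 2)), ] <- TRUE

  dt <- step_frac / breakup_rate
  p_break <- -expm1(-breakup_rate * dt)
  rec <- matrix(0, length(t_grid), 7)
  record <- function(i) {
    k <- rowSums(tags)
    tabulate(k + 1L, 7L) / n
  }
  ri <- 1L
  t <- 0
  while (ri <= length(t_grid) && t_grid[ri] <= 1e-12) {
    rec[ri, ] <- record()
    ri <- ri + 1L
  }
  t_end <- t_grid[length(t_grid)]
  while (ri <= length(t_grid)) {
    nb <- rbinom(1, n, p_break)
    if (nb >= 2) {
      rows <- sample.int(n, nb)
      tags[rows, ] <- reassemble_fragments(tags[rows, , drop = FALSE], mode)
    }
    t <- t + dt
    while (ri <= length(t_grid) && t >= t_grid[ri] - 1e-12) {
      rec[ri, ] <- record()
      ri <- ri + 1L
    }
    if (t > t_end + dt) break
  }
  shuffle_series(t_grid, rec)
}

# Break each row (a hexamer, ring positions 1..6) into fragments according to
# the mode, then randomly rejoin complementary sizes.  Returns a matrix of
# the same shape whose rows are the reassembled hexamers.
reassemble_fragments <- function(rows, mode) {
  nb <- nrow(rows)
  if (mode == "cooperative") {
    pool <- sample(as.vector(t(rows)))
    return(matrix(pool, nb, 6, byrow = TRUE))
  }
  if (mode == "sequential") {
    cut <- sample.int(6, nb, replace = TRUE)
    monos <- rows[cbind(seq_len(nb), cut)]
    pentas <- matrix(FALSE, nb, 5)
    for (i in seq_len(nb))
      pentas[i, ] <- rows[i, ((cut[i] + seq_len(5) - 1L) %% 6L) + 1L]
    ord <- sample.int(nb)
    return(cbind(monos[ord], pentas))
  }
  # stochastic: two cut sites uniform among the 15 unordered interface pairs
  frag <- vector("list", 5)
  for (i in seq_len(nb)) {
    ab <- sort(sample.int(6, 2))
    s1 <- ab[2] - ab[1]
    arc1 <- rows[i, ((ab[1] + seq_len(s1) - 1L) %% 6L) + 1L]
    arc2 <- rows[i, ((ab[2] + seq_len(6 - s1) - 1L) %% 6L) + 1L]
    frag[[s1]] <- c(frag[[s1]], list(arc1))
    frag[[6 - s1]] <- c(frag[[6 - s1]], list(arc2))
  }
  out <- matrix(FALSE, nb, 6)
  oi <- 1L
  for (s in 1:2) {
    a <- frag[[s]]; b <- frag[[6 - s]]
    if (length(a)) {
      ord <- sample.int(length(b))
      for (i in seq_along(a)) {
        out[oi, ] <- c(a[[i]], b[[ord[i]]])
        oi <- oi + 1L
      }
    }
  }
  th <- frag[[3]]
  if (length(th)) {
    ord <- sample.int(length(th))
    for (i in seq(1, length(ord), by = 2)) {
      out[oi, ] <- c(th[[ord[i]]], th[[ord[i + 1]]])
      oi <- oi + 1L
    }
  }
  out
}

#' L-versus-qmix trajectory of a shuffle series
#'
#' @param series a [shuffle_series()].
#' @param mode label attached to the trajectory (a dissociation mode or
#'   `"observed"`).
#' @return an `l_trajectory`: data frame with columns `qmix`, `L`, `mode`.
#' @export
l_trajectory <- function(series, mode = "observed") {
  q <- vapply(seq_along(series$times),
              function(i) suppressWarnings(qmix(series$p[i, ])), numeric(1))
  L <- vapply(seq_along(series$times),
              function(i) distance_L(series$p[i, ]), numeric(1))
  structure(data.frame(qmix = q, L = L, mode = mode),
            class = c("l_trajectory", "data.frame"))
}

#' Interpolate the tag distribution at a target hetero-hexamer fraction
#'
#' Linear interpolation of each fraction p_k against the hetero-hexamer
#' fraction, renormalised to sum to one.  Used to compare distributions of
#' different experiments or modes at a common mixing stage (e.g. 40\%
#' hetero-hexamers).
#'
#' @param series a [shuffle_series()].
#' @param target_pmix target hetero-hexamer fraction.
#' @param extrapolate if TRUE and the target lies outside the observed range,
#'   a per-k linear fit over all points is extrapolated instead of erroring.
#' @return a [hex_dist()].
#' @export
interpolate_at_qmix <- function(series, target_pmix, extrapolate = FALSE) {
  ph <- hetero_fraction(series)
  hit <- which(abs(ph - target_pmix) <= 1e-9)
  if (length(hit)) return(hex_dist(series$p[hit[1], ]))
  below <- which(ph < target_pmix)
  above <- which(ph > target_pmix)
  if (!length(below) || !length(above)) {
    if (!extrapolate)
      stop(sprintf(
        "target hetero fraction %.3g outside observed range [%.3g, %.3g]",
        target_pmix, min(ph), max(ph)))
    p <- vapply(1:7, function(k) {
      fit <- stats::lm.fit(cbind(1, ph), series$p[, k])
      sum(fit$coefficients * c(1, target_pmix))
    }, numeric(1))
    p <- pmax(p, 0)
    return(hex_dist(p / sum(p)))
  }
  i <- max(below[ph[below] == max(ph[below])])
  j <- min(above[ph[above] == min(ph[above])])
  w <- (target_pmix - ph[i]) / (ph[j] - ph[i])
  p <- (1 - w) * series$p[i, ] + w * series$p[j, ]
  hex_dist(p / sum(p))
}

#' Averaged reference L-curves for the three dissociation modes
#'
#' Simulates each mode over several seeds and averages L on a common qmix
#' grid, reporting the seed-to-seed spread.
#'
#' @param n_hexamers population size per run.
#' @param n_seeds number of replicate runs per mode (>= 2).
#' @param seed base seed; run r of a mode uses `seed + r`.
#' @param qmix_grid grid on which curves are averaged.
#' @param ... further arguments to [simulate_mode()].
#' @return named list of three `l_trajectory` objects with extra column `sd`.
#' @export
mode_reference_curves <- function(n_hexamers = 10000, n_seeds = 10, seed = 1,
                                  qmix_grid = seq(0.05, 0.95, by = 0.05),
                                  ...) {
  out <- list()
  for (m in mode_labels) {
    Ls <- matrix(NA_real_, n_seeds, length(qmix_grid))
    for (r in seq_len(n_seeds)) {
      tr <- l_trajectory(simulate_mode(m, n_hexamers = n_hexamers,
                                       seed = seed + r, ...), m)
      ok <- !duplicated(tr$qmix)
      Ls[r, ] <- approx(tr$qmix[ok], tr$L[ok], xout = qmix_grid, rule = 2)$y
    }
    df <- data.frame(qmix = qmix_grid, L = colMeans(Ls), mode = m,
                     sd = apply(Ls, 2, sd))
    out[[m]] <- structure(df, class = c("l_trajectory", "data.frame"))
  }
  out
}

#' Classify an observed L-trajectory by dissociation mode
#'
#' Interpolates each reference curve at the observed qmix values and scores
#' each mode by the mean absolute deviation in L; the smallest score wins.
#'
#' @param observed an `l_trajectory` (e.g. from experimental or held-out
#'   simulated data).
#' @param reference_curves named list of three reference `l_trajectory`
#'   objects, as from [mode_reference_curves()].
#' @return list with elements `mode` (best label) and `scores` (named mean
#'   absolute L deviation per mode).
#' @export
classify_mode <- function(observed, reference_curves) {
  if (!nrow(observed)) stop("observed trajectory is empty")
  if (!all(mode_labels %in% names(reference_curves)))
    stop("reference_curves must contain all three modes")
  scores <- vapply(mode_labels, function(m) {
    ref <- reference_curves[[m]]
    ok <- !duplicated(ref$qmix)
    Lhat <- approx(ref$qmix[ok], ref$L[ok], xout = observed$qmix, rule = 2)$y
    mean(abs(observed$L - Lhat))
  }, numeric(1))
  list(mode = names(which.min(scores)), scores = scores)
}
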