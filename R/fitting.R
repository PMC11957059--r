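# Estimation: one-phase exponential shuffling-rate fit, and inference of
# (kh, ke) from ATPase activity combined with either the shuffling rate
# (contour intersection, simulation-based) or the CS-hexamer fraction
# (closed form up to a 1-D root).

SAT_1TO1 <- 62 / 64 # theoretical hetero saturation of a 1:1 mixture

#' Fit the shuffling rate by a one-phase exponential
#'
#' Least-squares fit of `p_het(t) = p_inf * (1 - exp(-ks t))` to the
#' hetero-hexamer fraction of a shuffle series, with the saturation
#' amplitude `p_inf` free in (0, 62/64] (the theoretical 1:1 limit) or
#' fixed.  Uncertainty is estimated by resampling residuals.
#'
#' @param series a [shuffle_series()], or a data frame with columns `time_h`
#'   and `hetero`.
#' @param fix_amplitude if TRUE, `p_inf` is fixed at 62/64.
#' @param n_boot bootstrap replicates for the confidence interval.
#' @param seed seed for the bootstrap resampling.
#' @return an object of class `ks_fit` with elements `ks` (1/h),
#'   `amplitude`, `sse`, `ci_ks` (95\% bootstrap interval) and the data.
#' @examples
#' t <- seq(0, 36, by = 6)
#' s <- shuffle_series(t, t(sapply(0.95 * (1 - exp(-0.1 * t)), function(ph)
#'   c(1 - ph, rep(ph / 5, 5), 0))))
#' fit_ks(s)
#' @export
fit_ks <- function(series, fix_amplitude = FALSE, n_boot = 200, seed = NULL) {
  if (inherits(series, "shuffle_series")) {
    tt <- series$times
    ph <- hetero_fraction(series)
  } else if (is.data.frame(series) && all(c("time_h", "hetero") %in% names(series))) {
    tt <- series$time_h
    ph <- series$hetero
  } else stop("series must be a shuffle_series or a time_h/hetero data frame")
  if (length(tt) < 4) stop("at least 4 time points are required to fit ks")
  if (any(ph < -1e-9) || any(ph > 1 + 1e-9))
    stop("hetero fractions must lie in [0, 1]")
  if (min(tt) > 0.25 * max(tt))
    stop("the series must include a time point near t = 0")
  slope <- stats::cov(tt, ph) / stats::var(tt)
  if (slope < 0 && ph[1] > max(ph[-1]))
    stop("fit failure: hetero fraction decreases over time")
  if (!is.null(seed)) set.seed(seed)
  if (max(ph) < 1e-8) {
    # no mixing signal at all: the rate is indistinguishable from zero
    return(structure(list(ks = 0, amplitude = 0, sse = 0, ci_ks = c(0, 0),
                          boot = numeric(0), times = tt, hetero = ph,
                          fix_amplitude = fix_amplitude),
                     class = "ks_fit"))
  }

  one_fit <- function(y) {
    if (fix_amplitude) {
      fn <- function(par) SAT_1TO1 * (1 - exp(-par[1] * tt)) - y
      start <- 0.5 / max(stats::median(tt), 1e-6)
      f <- minpack.lm::nls.lm(par = start, lower = 0, upper = Inf, fn = fn,
                              control = minpack.lm::nls.lm.control(maxiter = 200))
      c(f$par[1], SAT_1TO1, sum(f$fvec^2))
    } else {
      fn <- function(par) par[2] * (1 - exp(-par[1] * tt)) - y
      pinf0 <- min(max(max(y), 0.1), SAT_1TO1)
      ks0 <- {
        half <- which(y >= pinf0 / 2)
        if (length(half) && tt[half[1]] > 0) log(2) / tt[half[1]] else
          0.5 / max(stats::median(tt), 1e-6)
      }
      f <- minpack.lm::nls.lm(par = c(ks0, pinf0), lower = c(0, 1e-6),
                              upper = c(Inf, SAT_1TO1), fn = fn,
                              control = minpack.lm::nls.lm.control(maxiter = 200))
      c(f$par, sum(f$fvec^2))
    }
  }

  est <- one_fit(ph)
  fitted <- est[2] * (1 - exp(-est[1] * tt))
  res <- ph - fitted
  boot <- numeric(0)
  if (n_boot > 0) {
    boot <- vapply(seq_len(n_boot), function(b) {
      yb <- fitted + sample(res, replace = TRUE)
      yb <- pmin(pmax(yb, 0), 1)
      one_fit(yb)[1]
    }, numeric(1))
  }
  structure(list(ks = est[1], amplitude = est[2], sse = est[3],
                 ci_ks = if (length(boot)) unname(quantile(boot, c(0.025, 0.975)))
                         else c(NA_real_, NA_real_),
                 boot = boot, times = tt, hetero = ph,
                 fix_amplitude = fix_amplitude),
            class = "ks_fit")
}

#' @export
print.ks_fit <- function(x, ...) {
  cat(sprintf("One-phase exponential shuffling fit: ks = %.4g /h", x$ks))
  if (!anyNA(x$ci_ks))
    cat(sprintf("  (95%% CI %.4g-%.4g)", x$ci_ks[1], x$ci_ks[2]))
  cat(sprintf("\n  amplitude p_inf = %.4f%s, SSE = %.3g, %d points\n",
              x$amplitude, if (x$fix_amplitude) " (fixed)" else "",
              x$sse, length(x$times)))
  if (!is.null(x$ks_sd))
    cat(sprintf("  replicate spread: sd(ks) = %.3g over %d seeds\n",
                x$ks_sd, length(x$ks_reps)))
  invisible(x)
}

#' @export
coef.ks_fit <- function(object, ...) {
  c(ks = object$ks, p_inf = object$amplitude)
}

#' @export
predict.ks_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$times
        else if (is.data.frame(newdata)) newdata$time_h else as.numeric(newdata)
  object$amplitude * (1 - exp(-object$ks * tt))
}

#' @export
plot.ks_fit <- function(x, ...) {
  plot(x$times, x$hetero, pch = 16, xlab = "time (h)",
       ylab = "hetero-hexamer fraction", ylim = c(0, 1), ...)
  tt <- seq(0, max(x$times), length.out = 200)
  lines(tt, x$amplitude * (1 - exp(-x$ks * tt)), col = 2)
  invisible(x)
}

# analytic proxy for the shuffling-rate scale: slow eigenvalue of the
# ADP-count birth-death chain 0 -> 1 -> 2 (first passage into the CS state),
# used only to choose simulation horizons adaptively
ks_scale_guess <- function(kh, ke) {
  if (kh <= 0) return(0)
  a <- 6 * kh; b <- 5 * kh
  tr <- a + ke + b
  (tr - sqrt(tr^2 - 4 * a * b)) / 2
}

#' Simulation settings for shuffling-rate prediction
#'
#' @param n_hexamers population size per replicate.
#' @param n_reps number of seed replicates (>= 2).
#' @param base_seed replicate r uses seed `base_seed + r`.
#' @param t_grid sampling times; NULL chooses a horizon of about 4 expected
#'   shuffling times (25 points) from the analytic rate scale.
#' @param max_t cap on the adaptive horizon, hours.
#' @return a list of settings for [predict_ks()] and
#'   [estimate_from_kcat_ks()].
#' @export
sim_settings <- function(n_hexamers = 2000, n_reps = 5, base_seed = 100,
                         t_grid = NULL, max_t = 400) {
  list(n_hexamers = n_hexamers, n_reps = n_reps, base_seed = base_seed,
       t_grid = t_grid, max_t = max_t)
}

#' Predict the shuffling rate from hydrolysis and exchange rates
#'
#' Runs the fast-equilibrium shuffling simulation (1:1 mix, all-ATP start)
#' over several seeds and fits the one-phase exponential to the seed-averaged
#' hetero-fraction curve.  The shuffling rate depends only on `kh` and `ke`.
#'
#' @param kh,ke hydrolysis and exchange rates, 1/h.
#' @param settings a [sim_settings()] list.
#' @param ... passed to [fit_ks()].
#' @return a `ks_fit` with extra elements `ks_reps` (per-seed estimates) and
#'   `ks_sd` (their spread).
#' @export
predict_ks <- function(kh, ke, settings = sim_settings(), ...) {
  if (kh < 0 || ke < 0) stop("rates must be non-negative")
  if (kh == 0) {
    tg <- if (is.null(settings$t_grid)) seq(0, 36, length.out = 10) else settings$t_grid
    out <- list(ks = 0, amplitude = 0, sse = 0, ci_ks = c(0, 0), boot = numeric(0),
                times = tg, hetero = rep(0, length(tg)), fix_amplitude = FALSE,
                ks_reps = rep(0, settings$n_reps), ks_sd = 0)
    class(out) <- "ks_fit"
    return(out)
  }
  lam <- ks_scale_guess(kh, ke)
  tg <- settings$t_grid
  if (is.null(tg)) {
    t_end <- min(max(4 / lam, 2), settings$max_t)
    tg <- seq(0, t_end, length.out = 25)
  }
  params <- rate_params(kh = kh, ke = ke)
  ph <- matrix(NA_real_, settings$n_reps, length(tg))
  ks_reps <- numeric(settings$n_reps)
  for (r in seq_len(settings$n_reps)) {
    sim <- simulate_shuffling(params, n_hexamers = settings$n_hexamers,
                              t_grid = tg, seed = settings$base_seed + r)
    ph[r, ] <- hetero_fraction(sim$series)
    ks_reps[r] <- fit_ks(data.frame(time_h = tg, hetero = ph[r, ]),
                         n_boot = 0)$ks
  }
  fit <- fit_ks(data.frame(time_h = tg, hetero = colMeans(ph)),
                seed = settings$base_seed, ...)
  fit$ks_reps <- ks_reps
  fit$ks_sd <- sd(ks_reps)
  fit
}

#' Infer (kh, ke) from ATPase activity and shuffling rate
#'
#' The measured ATPase activity fixes a contour `kcat(kh, ke) = kcat_target`
#' in the (kh, ke) plane; along it (parameterised by ke, with kh from
#' [invert_kcat()]) the simulated shuffling rate decreases monotonically
#' with ke.  The intersection with the shuffling-rate contour
#' `ks = ks_target` is found by bisection on log(ke) using seed-averaged
#' simulated rates with common random numbers.
#'
#' @param kcat_target measured ATPase activity, 1/h.
#' @param ks_target measured shuffling rate, 1/h.
#' @param settings a [sim_settings()] list.
#' @param ke_range search interval for ke, 1/h; the lower end must exceed
#'   `kcat_target`.
#' @param tol_rel relative matching tolerance on the simulated ks.
#' @param max_iter bisection iteration cap.
#' @return an object of class `rate_estimate`.
#' @export
estimate_from_kcat_ks <- function(kcat_target, ks_target,
                                  settings = sim_settings(),
                                  ke_range = c(1.05 * kcat_target, 2000),
                                  tol_rel = 0.05, max_iter = 12) {
  if (ks_target <= 0) stop("ks_target must be positive")
  if (kcat_target <= 0) stop("kcat_target must be positive")
  if (ke_range[1] <= kcat_target)
    ke_range[1] <- 1.05 * kcat_target
  eval_ks <- function(ke) {
    kh <- invert_kcat(kcat_target, ke)
    predict_ks(kh, ke, settings = settings, n_boot = 0)$ks
  }
  lo <- ke_range[1]; hi <- ke_range[2]
  ks_lo <- eval_ks(lo)  # low ke => high kh => fast shuffling
  ks_hi <- eval_ks(hi)
  if (ks_target > ks_lo || ks_target < ks_hi)
    stop(sprintf(paste0("ks_target %.4g /h outside the attainable range ",
                        "[%.4g, %.4g] /h on the kcat = %.4g contour for ke in ",
                        "[%.4g, %.4g]"),
                 ks_target, ks_hi, ks_lo, kcat_target, lo, hi))
  ke_mid <- NA_real_; ks_mid <- NA_real_
  trace <- data.frame(ke = c(lo, hi), ks = c(ks_lo, ks_hi))
  for (i in seq_len(max_iter)) {
    ke_mid <- exp((log(lo) + log(hi)) / 2)
    ks_mid <- eval_ks(ke_mid)
    trace <- rbind(trace, data.frame(ke = ke_mid, ks = ks_mid))
    if (abs(ks_mid - ks_target) <= tol_rel * ks_target) break
    if (ks_mid > ks_target) lo <- ke_mid else hi <- ke_mid
  }
  kh <- invert_kcat(kcat_target, ke_mid)
  structure(list(kh = kh, ke = ke_mid,
                 constraints_used = sprintf(
                   "kcat = %.4g /h (exact), ks = %.4g /h (simulated match)",
                   kcat_target, ks_target),
                 residuals = c(kcat = kcat(kh, ke_mid) - kcat_target,
                               ks = ks_mid - ks_target),
                 ks_achieved = ks_mid, search = trace),
            class = "rate_estimate")
}

#' Infer (kh, ke) from ATPase activity and CS-hexamer fraction
#'
#' Solves `fcs(x) = 1 - (1 + 6x)/(1 + x)^6 = fcs_target` for `x = kh/ke`
#' (strictly increasing, so the root is unique), then recovers the scale
#' from `kcat = kh ke / (kh + ke)`: `ke = kcat (1 + x) / x`, `kh = x ke`.
#' Used to extrapolate the model to full-length KaiC phospho-mimics, whose
#' CS fraction is known but whose shuffling cannot be resolved directly.
#'
#' @param kcat_target measured ATPase activity, 1/h.
#' @param fcs_target CS-hexamer fraction, strictly between 0 and 1.
#' @return an object of class `rate_estimate`.
#' @export
estimate_from_kcat_fcs <- function(kcat_target, fcs_target) {
  if (kcat_target <= 0) stop("kcat_target must be positive")
  if (fcs_target <= 0 || fcs_target >= 1)
    stop(sprintf(paste0("fcs_target = %g lies on the boundary: fcs -> 0 ",
                        "corresponds to ke -> Inf and fcs -> 1 to ke -> 0; ",
                        "no finite estimate exists"), fcs_target))
  x <- solve_fcs_x(fcs_target)
  ke <- kcat_target * (1 + x) / x
  kh <- x * ke
  structure(list(kh = kh, ke = ke,
                 constraints_used = sprintf(
                   "kcat = %.4g /h, fcs = %.4g (closed form, x = kh/ke = %.4g)",
                   kcat_target, fcs_target, x),
                 residuals = c(kcat = kcat(kh, ke) - kcat_target,
                               fcs = fcs(kh, ke) - fcs_target),
                 x = x),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("Inferred kinetic rates\n")
  cat(sprintf("  kh = %.4g /h, ke = %.4g /h\n", x$kh, x$ke))
  cat("  constraints:", x$constraints_used, "\n")
  cat(sprintf("  residuals: kcat %.3g, %s %.3g\n", x$residuals[1],
              names(x$residuals)[2], x$residuals[2]))
  invisible(x)
}

#' @export
coef.rate_estimate <- function(object, ...) c(kh = object$kh, ke = object$ke)
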