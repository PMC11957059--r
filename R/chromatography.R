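# Synthetic ion-exchange elution traces of tag-ladder hexamer mixtures and
# their deconvolution into seven tag-count fractions.

#' Chromatogram container
#'
#' @param volume elution volumes, ml, strictly increasing.
#' @param signal absorbance-like values, same length as `volume`.
#' @param label optional run label.
#' @param time_h optional incubation time of the sample, hours.
#' @return an object of class `chromatogram`.
#' @export
chromatogram <- function(volume, signal, label = NULL, time_h = NA_real_) {
  volume <- as.numeric(volume); signal <- as.numeric(signal)
  if (length(volume) != length(signal))
    stop("volume and signal must have equal length")
  if (any(diff(volume) <= 0)) stop("volume grid must be strictly increasing")
  if (any(!is.finite(signal))) stop("signal must be finite")
  structure(list(volume = volume, signal = signal, label = label,
                 time_h = time_h), class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("Chromatogram%s: %d points, %.2f-%.2f ml%s\n",
              if (!is.null(x$label)) paste0(" '", x$label, "'") else "",
              length(x$volume), min(x$volume), max(x$volume),
              if (is.finite(x$time_h)) sprintf(", t = %g h", x$time_h) else ""))
  invisible(x)
}

#' @export
plot.chromatogram <- function(x, ...) {
  plot(x$volume, x$signal, type = "l", xlab = "elution volume (ml)",
       ylab = "signal (a.u.)", ...)
  invisible(x)
}

#' Seven-peak elution model for the tag ladder
#'
#' Hexamers with k = 0..6 tags elute as seven peaks whose centres increase
#' with tag count (the 2xFLAG tag adds negative charge, so tagged species
#' elute at higher salt).  The default geometry places the native
#' homo-hexamer at 17.5 ml and the fully tagged one at 20.5 ml with
#' intermediate centres linearly spaced 0.5 ml apart.
#'
#' @param centers 7 peak centres, ml, strictly increasing.
#' @param widths 7 positive width parameters (Gaussian sd), ml; usually a
#'   single shared value recycled.
#' @param amplitudes 7 non-negative area weights.
#' @param shape `"gaussian"` or `"emg"` (exponentially modified Gaussian,
#'   with tail constant `tau`).
#' @param baseline constant signal offset.
#' @param tau exponential tail constant for `shape = "emg"`, ml.
#' @return an object of class `peak_model`.
#' @export
peak_model <- function(centers = seq(17.5, 20.5, by = 0.5),
                       widths = 0.15, amplitudes = rep(1, 7),
                       shape = c("gaussian", "emg"), baseline = 0,
                       tau = 0.1) {
  shape <- match.arg(shape)
  centers <- as.numeric(centers)
  widths <- rep_len(as.numeric(widths), 7L)
  amplitudes <- rep_len(as.numeric(amplitudes), 7L)
  if (length(centers) != 7L) stop("exactly 7 peak centres are required")
  if (any(diff(centers) <= 0))
    stop("peak centres must be strictly increasing with tag count")
  if (any(widths <= 0)) stop("peak widths must be positive")
  if (any(amplitudes < 0)) stop("peak amplitudes must be non-negative")
  structure(list(centers = centers, widths = widths, amplitudes = amplitudes,
                 shape = shape, baseline = baseline, tau = tau),
            class = "peak_model")
}

#' @export
print.peak_model <- function(x, ...) {
  cat(sprintf("Seven-peak %s model, centres %.2f-%.2f ml, baseline %.3g\n",
              x$shape, x$centers[1], x$centers[7], x$baseline))
  print(round(rbind(center = x$centers, width = x$widths,
                    amplitude = x$amplitudes), 4))
  invisible(x)
}

# unit-area peak function
peak_fun <- function(v, center, width, shape, tau) {
  if (shape == "gaussian") return(stats::dnorm(v, center, width))
  # exponentially modified Gaussian (tail toward larger elution volume)
  z <- (v - center) / width
  k <- width / tau
  exp(0.5 * k^2 - z * k) * stats::pnorm(z - k) / tau
}

peak_matrix <- function(volume, centers, widths, shape, tau) {
  vapply(1:7, function(k) peak_fun(volume, centers[k], widths[k], shape, tau),
         numeric(length(volume)))
}

#' Render a synthetic chromatogram from a tag-count distribution
#'
#' The trace is `baseline + scale * sum_k p_k * peak(v; center_k, width_k)`
#' plus Gaussian noise; peaks have unit area, so the integrated signal above
#' baseline equals `scale` (absorbance per hexamer is assumed
#' tag-independent, making peak area proportional to molar fraction).
#'
#' @param dist a [hex_dist()] (fractions for k = 0..6).
#' @param peaks a [peak_model()].
#' @param noise_sd Gaussian noise standard deviation, signal units.
#' @param seed integer seed for the noise.
#' @param volume elution-volume grid, ml.
#' @param scale total peak area (signal units x ml).
#' @param label,time_h metadata stored on the chromatogram.
#' @return a [chromatogram()].
#' @export
generate_trace <- function(dist, peaks, noise_sd = 0, seed = NULL,
                           volume = seq(16, 22, by = 0.01), scale = 1,
                           label = NULL, time_h = NA_real_) {
  if (!is_valid_hex_dist(dist)) stop("invalid hexamer distribution")
  if (!inherits(peaks, "peak_model")) stop("peaks must be a peak_model")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  B <- peak_matrix(volume, peaks$centers, peaks$widths, peaks$shape, peaks$tau)
  sig <- peaks$baseline + scale * as.vector(B %*% as.numeric(dist))
  if (noise_sd > 0) sig <- sig + rnorm(length(volume), 0, noise_sd)
  chromatogram(volume, sig, label = label, time_h = time_h)
}

#' Deconvolve a chromatogram into seven tag-count fractions
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box
#' constraints): free parameters are the seven non-negative peak areas, one
#' shared peak width, per-peak centre offsets bounded within
#' `center_window` of the initial calibration centres, and a constant
#' baseline.  Three jittered restarts are attempted before declaring
#' failure.  Fractions are the fitted areas normalised to sum to one.
#'
#' @param trace a [chromatogram()] spanning all seven initial centres.
#' @param init a [peak_model()] giving initial centres/width (from
#'   homo-hexamer calibration runs).
#' @param center_window allowed centre shift, ml.
#' @param n_starts number of jittered restarts.
#' @param seed seed for the restart jitter.
#' @return an object of class `chrom_fit` with elements `dist`
#'   (a [hex_dist()]), `peaks` (fitted [peak_model()]), `rss`, `rel_resid`
#'   (residual norm relative to the signal norm) and `trace`.
#' @export
deconvolve <- function(trace, init = peak_model(), center_window = 0.15,
                       n_starts = 3, seed = NULL) {
  if (!inherits(trace, "chromatogram")) stop("trace must be a chromatogram")
  if (!inherits(init, "peak_model")) stop("init must be a peak_model")
  v <- trace$volume
  if (min(v) > init$centers[1] - 2 * init$widths[1] ||
      max(v) < init$centers[7] + 2 * init$widths[7])
    stop("trace does not cover the span of the initialised peaks")
  y <- trace$signal
  ymax <- max(y)
  if (ymax <= 0 || ymax - min(y) <= .Machine$double.eps^0.5)
    stop("degenerate input: trace carries no signal to deconvolve")
  if (!is.null(seed)) set.seed(seed)

  w0 <- mean(init$widths)
  area0 <- sum(diff(v) * (head2(y) + tail2(y)) / 2) # trapezoid, gross area
  resid_fn <- function(par) {
    a <- par[1:7]; w <- par[8]; dc <- par[9:15]; b <- par[16]
    B <- peak_matrix(v, init$centers + dc, rep(w, 7), init$shape, init$tau)
    as.vector(B %*% a) + b - y
  }
  lower <- c(rep(0, 7), w0 / 3, rep(-center_window, 7), 0)
  upper <- c(rep(2 * abs(area0) + 1, 7), w0 * 3, rep(center_window, 7), ymax)
  best <- NULL
  for (s in seq_len(n_starts)) {
    a_start <- rep(max(area0, ymax * w0) / 7, 7) *
      (if (s == 1) 1 else runif(7, 0.5, 1.5))
    start <- c(a_start, w0 * (if (s == 1) 1 else runif(1, 0.8, 1.25)),
               rep(0, 7), max(min(y), 0))
    fit <- try(minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("deconvolution failed to converge after bounded restarts")
  par <- best$fit$par
  areas <- par[1:7]
  rel <- sqrt(best$rss / sum((y - mean(y))^2))
  if (sum(areas) <= .Machine$double.eps^0.5)
    stop(sprintf("all peak amplitudes fitted to zero (relative residual %.3g)",
                 rel))
  if (rel > 0.5)
    stop(sprintf("deconvolution failed: best relative residual %.3g", rel))
  fitted_peaks <- peak_model(centers = init$centers + par[9:15],
                             widths = rep(par[8], 7), amplitudes = areas,
                             shape = init$shape, baseline = par[16],
                             tau = init$tau)
  structure(list(dist = hex_dist(areas / sum(areas)), peaks = fitted_peaks,
                 rss = best$rss, rel_resid = rel, trace = trace,
                 n_starts = n_starts),
            class = "chrom_fit")
}

head2 <- function(x) x[-length(x)]
tail2 <- function(x) x[-1]

#' @export
print.chrom_fit <- function(x, ...) {
  cat("Seven-peak deconvolution\n")
  cat(sprintf("  relative residual: %.4g\n", x$rel_resid))
  cat("  fractions (k = 0..6):\n  ")
  cat(sprintf("%.4f", as.numeric(x$dist)), "\n")
  cat(sprintf("  hetero fraction: %.4f\n", hetero_fraction(x$dist)))
  invisible(x)
}

#' @export
coef.chrom_fit <- function(object, ...) as.numeric(object$dist)

#' @export
fitted.chrom_fit <- function(object, ...) {
  p <- object$peaks
  B <- peak_matrix(object$trace$volume, p$centers, p$widths, p$shape, p$tau)
  as.vector(B %*% p$amplitudes) + p$baseline
}

#' @export
residuals.chrom_fit <- function(object, ...) {
  object$trace$signal - fitted(object)
}

#' @export
plot.chrom_fit <- function(x, ...) {
  plot(x$trace, ...)
  lines(x$trace$volume, fitted(x), col = 2, lty = 2)
  legend("topright", c("data", "fit"), col = 1:2, lty = 1:2, bty = "n")
  invisible(x)
}

#' Assemble a shuffle series from a set of chromatograms
#'
#' Deconvolves each trace and orders the recovered distributions by their
#' `time_h` metadata.
#'
#' @param traces list of [chromatogram()] objects with `time_h` set.
#' @param init initial [peak_model()] passed to [deconvolve()].
#' @param ... further arguments to [deconvolve()].
#' @return a [shuffle_series()].
#' @export
series_from_traces <- function(traces, init = peak_model(), ...) {
  if (length(traces) < 2) stop("at least 2 time-stamped traces are required")
  times <- vapply(traces, function(tr) tr$time_h, numeric(1))
  if (anyNA(times)) stop("every trace needs time_h metadata")
  if (anyDuplicated(times)) stop("duplicate time points in trace set")
  ord <- order(times)
  p <- t(vapply(traces[ord],
                function(tr) as.numeric(deconvolve(tr, init, ...)$dist),
                numeric(7)))
  shuffle_series(times[ord], p)
}

#' Chromatogram CSV I/O
#'
#' Two-column CSV with header `volume_ml,signal`.
#' @param trace a [chromatogram()].
#' @param path file path.
#' @param label,time_h metadata attached on read.
#' @return `read_chromatogram` returns a [chromatogram()].
#' @export
write_chromatogram <- function(trace, path) {
  write.csv(data.frame(volume_ml = trace$volume, signal = trace$signal),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chromatogram
#' @export
read_chromatogram <- function(path, label = NULL, time_h = NA_real_) {
  df <- read.csv(path)
  if (!all(c("volume_ml", "signal") %in% names(df)))
    stop("chromatogram CSV needs columns volume_ml, signal")
  chromatogram(df$volume_ml, df$signal, label = label, time_h = time_h)
}
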