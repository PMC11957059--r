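# End-to-end synthetic experiments: named scenarios for the measured CI
# mutants and full-length phospho-mimics, rendered as complete in-silico
# mixing experiments (trajectory -> chromatograms -> deconvolution inputs)
# with known ground truth.

#' Synthetic mixing-experiment scenario
#'
#' @param label unique scenario label.
#' @param params a [rate_params()].
#' @param tag_split fraction of hexamers starting fully tagged (default 0.5,
#'   the 1:1 mix).
#' @param times chromatography sampling times, hours.
#' @param noise_sd chromatogram noise as a fraction of the peak maximum.
#' @param n_hexamers population size.
#' @param seed integer seed.
#' @return an object of class `scenario`.
#' @export
scenario <- function(label, params, tag_split = 0.5,
                     times = c(0, 6, 12, 24, 36), noise_sd = 0.01,
                     n_hexamers = 2000, seed = 1) {
  if (!inherits(params, "rate_params")) stop("params must be rate_params")
  if (any(diff(times) <= 0)) stop("sampling times must be increasing")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(label = label, params = params, tag_split = tag_split,
                 times = as.numeric(times), noise_sd = noise_sd,
                 n_hexamers = n_hexamers, seed = seed),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': kh = %.4g /h, ke = %.4g /h, %d hexamers, t = %s h\n",
              x$label, x$params$kh, x$params$ke, x$n_hexamers,
              paste(x$times, collapse = "/")))
  if (x$params$conc_pnp > 0)
    cat(sprintf("  ATP:AMP-PNP competition, [ATP] = %g mM, [PNP] = %g mM, KA = %g\n",
                x$params$conc_atp, x$params$conc_pnp, x$params$KA))
  invisible(x)
}

#' Preset scenarios for the measured KaiC constructs
#'
#' Named presets reproducing the study conditions: the CI point mutants with
#' their measured ATPase activities (S48T 0.09, S157C 0.29, wild type 0.43,
#' S157P 0.73 /h), a catalytically dead control, ATP:AMP-PNP titrations
#' (1 mM AMP-PNP with 0--1 mM ATP), and the full-length phospho-mimics
#' KaiC-AA (0.79 /h, vanishing CS fraction, exchange rate of order
#' 10^3 /h) and KaiC-EE (0.08 /h, CS fraction 0.95, rates from the
#' closed-form inversion).  The nucleotide exchange rate is 25.5 /h for the
#' wild type in ATP buffer, 10 /h for the CI point mutants and 12 /h in
#' AMP-PNP buffer.
#'
#' @param n_hexamers population size stored on each preset.
#' @param seed base seed; preset i uses `seed + i`.
#' @return named list of [scenario()] objects.
#' @export
preset_scenarios <- function(n_hexamers = 2000, seed = 1) {
  mk <- function(i, label, kh, ke, times = c(0, 6, 12, 24, 36), ...) {
    scenario(label, rate_params(kh = kh, ke = ke, ...),
             times = times, n_hexamers = n_hexamers, seed = seed + i)
  }
  ee <- estimate_from_kcat_fcs(kcat_target = 0.08, fcs_target = 0.95)
  out <- list(
    WT       = mk(1, "WT", invert_kcat(0.43, 25.5), 25.5),
    S48T     = mk(2, "S48T", invert_kcat(0.09, 10), 10,
                  times = c(0, 12, 24, 48, 72, 96)),
    S157C    = mk(3, "S157C", invert_kcat(0.29, 10), 10),
    S157P    = mk(4, "S157P", invert_kcat(0.73, 10), 10,
                  times = c(0, 2, 4, 6, 12, 24)),
    dead     = mk(5, "dead", 0, 10),
    AA       = mk(6, "AA", invert_kcat(0.79, 1000), 1000),
    EE       = mk(7, "EE", ee$kh, ee$ke, times = c(0, 2, 4, 6, 9, 12))
  )
  # ATP:AMP-PNP titrations: 1 mM AMP-PNP, ATP from 0 to 1 mM, AMP-PNP-buffer
  # exchange rate 12 /h
  atps <- c(0, 0.25, 0.5, 1)
  for (i in seq_along(atps)) {
    lab <- sprintf("PNP_atp%g", atps[i])
    out[[lab]] <- scenario(lab,
      rate_params(kh = invert_kcat(0.43, 25.5), ke = 12, KA = 15,
                  conc_atp = atps[i], conc_pnp = 1),
      times = c(0, 6, 12, 24, 36), n_hexamers = n_hexamers,
      seed = seed + 7 + i)
  }
  out
}

#' Build a complete synthetic experiment from a scenario
#'
#' Simulates the scenario, renders one chromatogram per sampling time, and
#' returns the ground-truth series together with the traces and a manifest
#' linking them.  If `outdir` is given, traces and the manifest are also
#' written as CSV.
#'
#' @param scn a [scenario()].
#' @param peaks a [peak_model()] used for rendering.
#' @param outdir optional output directory for trace CSVs and
#'   `manifest.csv`.
#' @return list with elements `truth` (a [shuffle_series()]), `sim` (the
#'   full `shuffle_sim`), `traces` (list of [chromatogram()]), and
#'   `manifest` (data frame: filename, time_h, label).
#' @export
build_experiment <- function(scn, peaks = peak_model(), outdir = NULL) {
  if (!inherits(scn, "scenario")) stop("scn must be a scenario")
  simfun <- if (scn$params$conc_pnp > 0) simulate_pnp else simulate_shuffling
  sim <- simfun(scn$params, n_hexamers = scn$n_hexamers,
                tag_split = scn$tag_split, t_grid = scn$times,
                seed = scn$seed)
  # noise is specified relative to the tallest rendered peak
  ref <- generate_trace(hex_dist(c(0.5, 0, 0, 0, 0, 0, 0.5)), peaks)
  noise_abs <- scn$noise_sd * max(ref$signal - peaks$baseline)
  traces <- lapply(seq_along(scn$times), function(i) {
    generate_trace(series_dist(sim$series, i), peaks,
                   noise_sd = noise_abs, seed = scn$seed * 1000 + i,
                   label = scn$label, time_h = scn$times[i])
  })
  manifest <- data.frame(
    filename = sprintf("%s_t%03d.csv", scn$label, round(scn$times)),
    time_h = scn$times, label = scn$label)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(traces))
      write_chromatogram(traces[[i]], file.path(outdir, manifest$filename[i]))
    write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  }
  list(truth = sim$series, sim = sim, traces = traces, manifest = manifest)
}

#' Read an experiment manifest and deconvolve its traces
#'
#' @param manifest_path path to a manifest CSV (columns filename, time_h,
#'   label); trace files are resolved relative to the manifest directory.
#' @param init initial [peak_model()] for the deconvolution.
#' @param ... passed to [deconvolve()].
#' @return a [shuffle_series()].
#' @export
series_from_manifest <- function(manifest_path, init = peak_model(), ...) {
  man <- read.csv(manifest_path)
  if (!all(c("filename", "time_h") %in% names(man)))
    stop("manifest needs columns filename and time_h")
  dir <- dirname(manifest_path)
  traces <- lapply(seq_len(nrow(man)), function(i)
    read_chromatogram(file.path(dir, man$filename[i]),
                      label = if ("label" %in% names(man)) man$label[i],
                      time_h = man$time_h[i]))
  series_from_traces(traces, init = init, ...)
}
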