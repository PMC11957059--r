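# Configuration-driven pipeline entry point and reproducibility metadata.
# Configs are flat YAML files; every run writes a run-record JSON next to
# its outputs.

#' Run a configured pipeline task
#'
#' Dispatches on the `task` field of a YAML config file:
#'
#' * `simulate`: [simulate_shuffling()] / [simulate_pnp()]; writes a series
#'   CSV (fields: `kh`, `ke`, optional `kdcs`, `krcs`, `KA`, `conc_atp`,
#'   `conc_pnp`, `n_hexamers`, `t_from`/`t_to`/`t_by`, `init`, `method`,
#'   `seed`, `out`).
#' * `simulate_mode`: [simulate_mode()] (fields `mode`, `n_hexamers`,
#'   `seed`, `t_from`/`t_to`/`t_by`, `out`).
#' * `fit_ks`: [fit_ks()] on a series CSV (fields `series`, `out`).
#' * `estimate`: [estimate_from_kcat_fcs()] when `fcs` is given, else
#'   [estimate_from_kcat_ks()] (fields `kcat`, `fcs` or `ks`, `seed`, `out`).
#' * `deconvolve`: [series_from_manifest()] (fields `manifest`, `out`).
#'
#' Outputs are deterministic given the config and seed.  On any error,
#' partial outputs of the run are removed and the error is re-thrown.
#'
#' @param config path to a YAML config file.
#' @param outdir output directory (default: the config's directory).
#' @return invisibly, the run record (also written as
#'   `<out>.run.json`).
#' @export
run_pipeline <- function(config, outdir = dirname(config)) {
  cfg <- yaml::read_yaml(config)
  if (is.null(cfg$task))
    stop("config field 'task' is required (simulate, simulate_mode, fit_ks, estimate, deconvolve)")
  if (is.null(cfg$out)) stop("config field 'out' is required")
  need_num <- function(field, min = -Inf) {
    v <- cfg[[field]]
    if (is.null(v)) stop(sprintf("config field '%s' is required", field))
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < min)
      stop(sprintf("config field '%s': expected a number >= %g", field, min))
    v
  }
  opt_num <- function(field, default) {
    if (is.null(cfg[[field]])) default else need_num(field)
  }
  out_path <- file.path(outdir, cfg$out)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)

  run <- function() {
    switch(cfg$task,
      simulate = {
        params <- rate_params(kh = need_num("kh", 0), ke = need_num("ke", 0),
                              kdcs = opt_num("kdcs", 3600),
                              krcs = opt_num("krcs", 360000),
                              KA = opt_num("KA", 15),
                              conc_atp = opt_num("conc_atp", 1),
                              conc_pnp = opt_num("conc_pnp", 0))
        tg <- seq(opt_num("t_from", 0), opt_num("t_to", 36),
                  by = opt_num("t_by", 2))
        sim <- simulate_shuffling(params,
          n_hexamers = opt_num("n_hexamers", 2000),
          t_grid = tg, init = if (is.null(cfg$init)) "all_T" else cfg$init,
          method = if (is.null(cfg$method)) "fast_eq" else cfg$method,
          seed = need_num("seed"))
        write_series(sim$series, out_path)
        written <<- out_path
        list(hetero_final = unname(utils::tail(hetero_fraction(sim$series), 1)))
      },
      simulate_mode = {
        ser <- simulate_mode(cfg$mode %||% "stochastic",
          n_hexamers = opt_num("n_hexamers", 10000),
          t_grid = seq(opt_num("t_from", 0), opt_num("t_to", 30),
                       by = opt_num("t_by", 0.5)),
          seed = need_num("seed"))
        write_series(ser, out_path)
        written <<- out_path
        list(qmix_final = unname(utils::tail(hetero_fraction(ser), 1)) / (62 / 64))
      },
      fit_ks = {
        ser <- read_series(file.path(outdir, cfg$series))
        fit <- fit_ks(ser, seed = opt_num("seed", 1))
        rep <- list(ks = fit$ks, amplitude = fit$amplitude,
                    ci_ks = fit$ci_ks, sse = fit$sse)
        jsonlite::write_json(rep, out_path, auto_unbox = TRUE, digits = NA)
        written <<- out_path
        rep["ks"]
      },
      estimate = {
        est <- if (!is.null(cfg$fcs))
          estimate_from_kcat_fcs(need_num("kcat", 0), need_num("fcs"))
        else
          estimate_from_kcat_ks(need_num("kcat", 0), need_num("ks"),
            settings = sim_settings(base_seed = opt_num("seed", 100)))
        rep <- list(kh = est$kh, ke = est$ke,
                    constraints = est$constraints_used,
                    residuals = as.list(est$residuals))
        jsonlite::write_json(rep, out_path, auto_unbox = TRUE, digits = NA)
        written <<- out_path
        rep[c("kh", "ke")]
      },
      deconvolve = {
        ser <- series_from_manifest(file.path(outdir, cfg$manifest))
        write_series(ser, out_path)
        written <<- out_path
        list(hetero_final = unname(utils::tail(hetero_fraction(ser), 1)))
      },
      stop(sprintf("unknown task '%s'", cfg$task))
    )
  }

  summary <- tryCatch(run(), error = function(e) {
    unlink(written)
    stop(e)
  })
  record <- list(command = cfg$task,
                 config = cfg,
                 seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("kaishuffle")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 outputs = basename(written),
                 summary = summary)
  write_run_record(record, paste0(out_path, ".run.json"))
  invisible(record)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run record
#'
#' @param record named list of reproducibility metadata.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_run_record <- function(record, path) {
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
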