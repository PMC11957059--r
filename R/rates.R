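# Kinetic rate parameters and the closed-form quantities derived from them.

#' Kinetic rate parameters for the shuffling model
#'
#' Container for every rate constant of the nucleotide-coupled shuffling
#' model.  Time unit is hours throughout.
#'
#' @param kh per-monomer ATP hydrolysis rate (T to D), 1/h.
#' @param ke per-monomer nucleotide exchange rate (D to T), 1/h.
#' @param kdcs dissociation rate of competent-state hexamers, 1/h.  The
#'   default 3600/h (1/s) is fast compared to hydrolysis and exchange, which
#'   justifies the fast-equilibrium treatment of shuffling.
#' @param krcs association rate per complementary free-oligomer pair
#'   (population-scale effective rate), 1/h.  The default `kdcs/2` keeps the
#'   steady free-oligomer fraction well below 5\% for wild-type-like
#'   parameters while letting the free pool hold enough fragments that
#'   re-association draws from many dissociated hexamers (the condition for
#'   the dissociation/association chain to reach its well-mixed
#'   equilibrium).
#' @param KA dimensionless ATP:AMP-PNP binding affinity ratio.
#' @param conc_atp,conc_pnp nucleotide concentrations, mM.
#' @return an object of class `rate_params`.
#' @export
rate_params <- function(kh, ke, kdcs = 3600, krcs = kdcs / 2, KA = 15,
                        conc_atp = 1, conc_pnp = 0) {
  vals <- c(kh = kh, ke = ke, kdcs = kdcs, krcs = krcs, KA = KA,
            conc_atp = conc_atp, conc_pnp = conc_pnp)
  if (anyNA(vals)) stop("rate parameters must not be NA")
  if (any(vals[c("kh", "ke", "kdcs", "krcs", "conc_atp", "conc_pnp")] < 0))
    stop("rates and concentrations must be non-negative")
  if (KA <= 0) stop("affinity ratio KA must be positive")
  structure(as.list(vals), class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Shuffling-model rate parameters (1/h; concentrations in mM)\n")
  cat(sprintf("  kh = %.4g  ke = %.4g  kdcs = %.4g  krcs = %.4g\n",
              x$kh, x$ke, x$kdcs, x$krcs))
  cat(sprintf("  KA = %.4g  [ATP] = %.4g  [AMP-PNP] = %.4g\n",
              x$KA, x$conc_atp, x$conc_pnp))
  if (x$kh + x$ke > 0)
    cat(sprintf("  implied ATPase activity kcat = %.4g 1/h, CS fraction fcs = %.4g\n",
                kcat(x$kh, x$ke), fcs(x$kh, x$ke)))
  invisible(x)
}

#' ATPase activity from hydrolysis and exchange rates
#'
#' Net per-monomer ATP consumption over one hydrolysis-plus-exchange cycle
#' at nonequilibrium steady state: `kcat = kh * ke / (kh + ke)`.  Symmetric
#' in its arguments and bounded by `min(kh, ke)`.
#'
#' @param kh,ke hydrolysis and exchange rates, 1/h.
#' @return ATPase activity, 1/h.
#' @export
kcat <- function(kh, ke) {
  if (any(kh < 0) || any(ke < 0)) stop("rates must be non-negative")
  if (any(kh + ke == 0)) stop("kcat is undefined when both rates are zero")
  kh * ke / (kh + ke)
}

#' Hydrolysis rate from ATPase activity at fixed exchange rate
#'
#' Inverts `kcat = kh * ke / (kh + ke)` for kh.  Requires `ke > kcat`
#' (the activity can never exceed either rate).
#'
#' @param kcat_target measured ATPase activity, 1/h.
#' @param ke nucleotide exchange rate, 1/h.
#' @return hydrolysis rate kh, 1/h.
#' @export
invert_kcat <- function(kcat_target, ke) {
  if (kcat_target < 0) stop("kcat must be non-negative")
  if (ke <= kcat_target)
    stop(sprintf("infeasible: ke (%.4g) must exceed the target kcat (%.4g)",
                 ke, kcat_target))
  kcat_target * ke / (ke - kcat_target)
}

#' Steady-state competent-state hexamer fraction
#'
#' With per-monomer ADP occupancy `p = kh / (kh + ke)`, the competent-state
#' (CS) fraction is the binomial probability of two or more ADP among six
#' subunits, which reduces to `fcs = 1 - (1 + 6 x) / (1 + x)^6` with
#' `x = kh / ke`.
#'
#' @param kh,ke hydrolysis and exchange rates, 1/h.  `ke = 0` with `kh > 0`
#'   returns 1 (the all-ADP limit).
#' @return fraction of CS-hexamers at steady state.
#' @export
fcs <- function(kh, ke) {
  if (any(kh < 0) || any(ke < 0)) stop("rates must be non-negative")
  n <- max(length(kh), length(ke))
  kh <- rep_len(kh, n); ke <- rep_len(ke, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- if (kh[i] == 0) 0
    else if (ke[i] == 0) 1
    else pbinom(1, 6, kh[i] / (kh[i] + ke[i]), lower.tail = FALSE)
  }
  out
}

# Solve fcs(x) = target for x = kh/ke; fcs is strictly increasing in x.
solve_fcs_x <- function(fcs_target, tol = 1e-12) {
  if (fcs_target <= 0 || fcs_target >= 1)
    stop("fcs target must lie strictly between 0 and 1")
  f <- function(x) 1 - (1 + 6 * x) / (1 + x)^6 - fcs_target
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, c(0, upper), tol = tol)$root
}

#' Steady-state nucleotide distribution of a hexamer
#'
#' Under ATP-only conditions with no reverse reactions, each monomer is
#' independently ADP-bound with probability `kh / (kh + ke)`, so the ADP
#' count per hexamer is Binomial(6, p).
#'
#' @param params a [rate_params()] (ATP-only: `conc_pnp` must be 0), or NULL
#'   if `kh`/`ke` are given directly.
#' @param kh,ke alternative direct specification of the two rates.
#' @return an object of class `nuc_steady` with elements `p_adp` (per-monomer
#'   ADP occupancy) and `hist` (ADP-count distribution, 7 entries).
#' @export
steady_state <- function(params = NULL, kh = NULL, ke = NULL) {
  if (!is.null(params)) {
    if (!inherits(params, "rate_params")) stop("params must be rate_params")
    if (params$conc_pnp > 0)
      stop("closed-form steady state is only available for ATP-only conditions")
    kh <- params$kh; ke <- params$ke
  }
  if (kh + ke <= 0) stop("kh + ke must be positive")
  p_adp <- kh / (kh + ke)
  structure(list(p_adp = p_adp, hist = dbinom(0:6, 6, p_adp)),
            class = "nuc_steady")
}

#' @export
print.nuc_steady <- function(x, ...) {
  cat(sprintf("Per-monomer ADP occupancy: %.4f\n", x$p_adp))
  cat("ADP-count distribution per hexamer (0..6):\n")
  print(round(setNames(x$hist, paste0("d", 0:6)), 4))
  cat(sprintf("CS-hexamer fraction (>= 2 ADP): %.4f\n", sum(x$hist[3:7])))
  invisible(x)
}
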