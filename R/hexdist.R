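# Hexamer tag-count distributions and the mixing statistics defined on them.

#' Hexamer tag-count distribution
#'
#' Construct and validate a distribution over the number of tagged subunits
#' (k = 0..6) in a hexamer population: seven non-negative fractions summing
#' to one.  This is the observable recovered from chromatogram deconvolution
#' and produced by the shuffling simulators.
#'
#' @param p numeric vector of length 7, fractions for k = 0..6.
#' @return an object of class `hex_dist` (a named numeric vector with names
#'   `k0`..`k6`).
#' @examples
#' hex_dist(c(0.5, 0, 0, 0, 0, 0, 0.5))   # unmixed 1:1 start
#' random_distribution()                   # fully mixed binomial ladder
#' @export
hex_dist <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 7L)
    stop("a hexamer distribution has exactly 7 entries (k = 0..6)")
  if (anyNA(p) || any(p < -1e-12))
    stop("hexamer distribution entries must be non-negative")
  s <- sum(p)
  if (abs(s - 1) > 1e-9)
    stop(sprintf("hexamer distribution must sum to 1 (got %.12g)", s))
  p <- pmax(p, 0)
  structure(setNames(p, paste0("k", 0:6)), class = "hex_dist")
}

is_valid_hex_dist <- function(p) {
  length(p) == 7L && !anyNA(p) && all(p >= -1e-12) && abs(sum(p) - 1) <= 1e-9
}

#' @export
print.hex_dist <- function(x, digits = 4, ...) {
  cat("Hexamer tag-count distribution (k = 0..6)\n")
  print(round(unclass(x), digits))
  cat(sprintf("hetero-hexamer fraction: %.4f\n", hetero_fraction(x)))
  invisible(x)
}

#' Hetero-hexamer fraction
#'
#' The fraction of hexamers carrying between 1 and 5 tagged subunits, i.e.
#' the mixed ("hetero") species that appear as two homo-hexamer pools
#' exchange subunits.
#'
#' @param dist a [hex_dist()], a length-7 fraction vector, or a
#'   [shuffle_series()] (one fraction per time point).
#' @return a fraction in \[0, 1\]: `sum(p[k], k = 1..5)`.
#' @export
hetero_fraction <- function(dist) UseMethod("hetero_fraction")

#' @rdname hetero_fraction
#' @export
hetero_fraction.default <- function(dist) {
  if (!is_valid_hex_dist(dist))
    stop("invalid hexamer distribution (negative entries or not normalised)")
  sum(dist[2:6])
}

#' Random (fully mixed) tag-count distribution
#'
#' The binomial ladder `choose(6, k) / 2^6` reached when monomers from a 1:1
#' tagged:native pool assemble at random.
#'
#' @return a [hex_dist()].
#' @export
random_distribution <- function() {
  hex_dist(choose(6, 0:6) / 64)
}

#' Normalised mixing fraction
#'
#' The hetero-hexamer fraction normalised by its fully mixed value
#' `62/64`, so that `qmix = 1` corresponds to complete randomisation of a
#' 1:1 mixture.  Values slightly above 1 can arise from sampling noise and
#' are returned as-is with a warning rather than clipped.
#'
#' @param dist a [hex_dist()] or length-7 fraction vector.
#' @return the normalised mixing fraction.
#' @export
qmix <- function(dist) {
  q <- hetero_fraction(dist) / (62 / 64)
  if (q > 1 + 1e-9)
    warning(sprintf("qmix = %.4f exceeds 1 (distribution more mixed than random)", q))
  q
}

#' Distribution distance to the scaled random ladder
#'
#' The summed absolute deviation, over the hetero species k = 1..5, between
#' an observed tag-count distribution and the random binomial ladder scaled
#' to the same mixing stage: `L = sum_k |p_k - qmix * pS_k|`.  L is zero both
#' for unmixed and for perfectly randomised populations and discriminates
#' dissociation modes along the mixing trajectory.
#'
#' @param dist a [hex_dist()] or length-7 fraction vector.
#' @return non-negative statistic L.
#' @export
distance_L <- function(dist) {
  if (!is_valid_hex_dist(dist))
    stop("invalid hexamer distribution (negative entries or not normalised)")
  pS <- choose(6, 0:6) / 64
  q <- hetero_fraction(dist) / (62 / 64)
  sum(abs(dist[2:6] - q * pS[2:6]))
}

#' Swap tag labels of a distribution
#'
#' Relabelling tagged as untagged maps p_k to p_(6-k); shuffling dynamics are
#' invariant under this relabelling when the mixing ratio is 1:1.
#'
#' @param dist a [hex_dist()].
#' @return the relabelled [hex_dist()].
#' @export
relabel_tags <- function(dist) {
  hex_dist(rev(as.numeric(dist)))
}
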