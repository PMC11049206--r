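# Kimura two-parameter distance.

#' Kimura two-parameter (K2P) distance
#'
#' Substitution-model-corrected divergence between two aligned sequences,
#' distinguishing transitions (A<->G, C<->T) from transversions:
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`, where `P` and `Q` are
#' the proportions of transition and transversion columns among the
#' gap-free, unambiguous alignment columns.
#'
#' @param P,Q Transition and transversion proportions (vectors recycle).
#' @return Numeric vector of distances in substitutions per site.
#' @examples
#' kimura2p(0.1, 0.05)
#' @export
kimura2p <- function(P, Q) {
  if (any(P < 0) || any(Q < 0) || any(P + Q > 1)) {
    abort("`P` and `Q` must be non-negative with P + Q <= 1")
  }
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  if (any(a <= 0) || any(b <= 0)) {
    abort("K2P distance is undefined at saturation (1 - 2P - Q or 1 - 2Q <= 0)",
          class = "satmapper_error_saturation")
  }
  -0.5 * log(a * sqrt(b))
}

# NA instead of an error at saturation; used when averaging over hits,
# where saturated hits are excluded from the divergence mean (but still
# counted as masked bp) with a warning upstream.
kimura2p_safe <- function(P, Q) {
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  out <- rep(NA_real_, length(a))
  ok <- !is.na(a) & a > 0 & b > 0
  out[ok] <- -0.5 * log(a[ok] * sqrt(b[ok]))
  out
}

# Expected K2P estimate when each site substitutes independently with
# probability p and transition:transversion odds kappa. Used to calibrate
# the synthetic mutation process.
k2p_expected <- function(p, kappa) {
  kimura2p(p * kappa / (kappa + 1), p / (kappa + 1))
}

# Inverse of k2p_expected in p, by bisection. Targets that would require
# more than half the sites to substitute are refused: beyond that point
# copies are effectively randomized and the divergence is unrecoverable
# (the K2P estimate saturates almost surely on real monomer lengths).
k2p_site_probability <- function(d_target, kappa) {
  stopifnot(d_target >= 0, kappa > 0)
  if (d_target == 0) return(0)
  p_cap <- 0.5
  if (k2p_expected(p_cap, kappa) < d_target) {
    abort("`d_target` is beyond the saturation domain of the K2P model",
          class = "satmapper_error_saturation")
  }
  stats::uniroot(function(p) k2p_expected(p, kappa) - d_target,
                 interval = c(1e-12, p_cap), tol = 1e-12)$root
}
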