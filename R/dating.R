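# Divergence-time calibration: under the stepwise mutation model the
# expected (delta-mu)^2 between two populations separated tau generations
# ago is 2*beta*tau, so tau = D / (2*beta) and years = tau * G.

#' Dating configuration
#'
#' @param beta Microsatellite mutation rate per locus per gamete per
#'   generation. Default `1.2e-3`, the dinucleotide rate used for highly
#'   polymorphic sheep panels.
#' @param gen_interval_years Mean generation interval in years. Default
#'   `4.0`; `3.5` is the common literature alternative for Mediterranean
#'   sheep (see the methods vignette for why 4.0 is the default here).
#' @param decimals Rounding applied to the years report.
#' @return A `dating_config` list.
#' @export
dating_config <- function(beta = 1.2e-3, gen_interval_years = 4.0,
                          decimals = 1L) {
  if (beta <= 0) stop("beta must be > 0")
  if (gen_interval_years <= 0) stop("gen_interval_years must be > 0")
  structure(list(beta = beta, gen_interval_years = gen_interval_years,
                 decimals = as.integer(decimals)),
            class = "dating_config")
}

#' Divergence time in generations
#'
#' Elementwise `tau = D / (2 * beta)` on a `(delta-mu)^2` matrix.
#'
#' @param dmu2 A `pairwise_matrix` tagged `"dmu2"` (or any non-negative
#'   symmetric matrix), or a scalar distance.
#' @param cfg A [dating_config()].
#' @return Matching `pairwise_matrix` tagged `"generations"`, or scalar.
#' @export
divergence_generations <- function(dmu2, cfg = dating_config()) {
  if (any(dmu2 < 0, na.rm = TRUE)) stop("(delta-mu)^2 entries must be >= 0")
  tau <- unclass(dmu2) / (2 * cfg$beta)
  if (is.matrix(tau))
    pairwise_matrix(tau, rownames(tau), "generations")
  else tau
}

#' Divergence time in years
#'
#' `years = D / (2 * beta) * G`, rounded to `cfg$decimals` decimals.
#'
#' @inheritParams divergence_generations
#' @return Matching `pairwise_matrix` tagged `"years"`, or scalar.
#' @export
divergence_years <- function(dmu2, cfg = dating_config()) {
  tau <- divergence_generations(dmu2, cfg)
  yrs <- round(unclass(tau) * cfg$gen_interval_years, cfg$decimals)
  if (is.matrix(yrs))
    pairwise_matrix(yrs, rownames(yrs), "years")
  else yrs
}
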