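#' Environmental gradients: survival and reproduction factors
#'
#' The landscape runs from pole (x = 1) to equator (x = x_max) with two
#' opposing linear gradients. Nominal (density-free) resident winter
#' survival increases as `0.01 * x`, from 0.01 at x = 1 to 1 at x = 100;
#' the reproduction location factor decreases as `1 - 0.01 * x * (1 -
#' c_loc_r)`, from ~1 at x = 1 to 0.8 at x = 100 under the default
#' `c_loc_r = 0.8`. Density dependence multiplies both.
#'
#' `nominal_resident_survival()` is the density-free survival with any
#' scenario shift applied and clamped to `[0, 1]`.
#' `resident_survival()` multiplies it by the survival density factor
#' `1 - (1 - c_dens_s) * n_res / K`; with the default `c_dens_s = 0.6` the
#' factor hits zero at a resident density of 2.5 K.
#' `reproduction_factor()` returns the total reproduction correction
#' `c_tot = (1 - 0.01 * x * (1 - c_loc_r)) * (1 - (1 - c_dens_r) * n_total
#' / K)`, the factor multiplying the raw brood draw. All results are
#' clamped to `[0, 1]`.
#'
#' @param x Landscape column index (vectorized), in `[1, x_max]`.
#' @param surv_delta Additive shift of the nominal survival term.
#' @param n_res Resident count of the patch (non-negative, vectorized).
#' @param n_total Total individual count of the patch, both phenotypes.
#' @param params A [sim_params()] object.
#' @param x_max Landscape extent used to validate `x`.
#'
#' @return A numeric vector of probabilities (or factors) in `[0, 1]`.
#' @examples
#' nominal_resident_survival(1)            # 0.01 at the polar edge
#' nominal_resident_survival(100)          # 1 at the equatorial edge
#' resident_survival(100, n_res = 250)     # 0: density 2.5 K is lethal
#' reproduction_factor(100, n_total = 0)   # 0.8: pure location term
#' @export
nominal_resident_survival <- function(x, surv_delta = 0, x_max = 100L) {
  if (length(x) == 0L) return(numeric(0))
  if (any(is.na(x)) || any(x < 1) || any(x > x_max))
    stop("column index 'x' outside the landscape [1, x_max]", call. = FALSE)
  clamp01(0.01 * x + surv_delta)
}

#' @rdname nominal_resident_survival
#' @export
resident_survival <- function(x, n_res, params = sim_params()) {
  if (any(n_res < 0)) stop("'n_res' must be non-negative", call. = FALSE)
  s0 <- nominal_resident_survival(x, params$surv_delta, params$x_max)
  clamp01(s0 * (1 - (1 - params$c_dens_s) * n_res / params$K))
}

#' @rdname nominal_resident_survival
#' @export
reproduction_factor <- function(x, n_total, params = sim_params()) {
  if (any(n_total < 0)) stop("'n_total' must be non-negative", call. = FALSE)
  if (length(x) == 0L) return(numeric(0))
  if (any(is.na(x)) || any(x < 1) || any(x > params$x_max))
    stop("column index 'x' outside the landscape [1, x_max]", call. = FALSE)
  loc <- 1 - 0.01 * x * (1 - params$c_loc_r)
  dens <- 1 - (1 - params$c_dens_r) * n_total / params$K
  clamp01(loc * dens)
}
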