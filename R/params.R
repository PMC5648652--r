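#' Simulation parameters
#'
#' Constructs the full parameter set of the individual-based model. Defaults
#' are the standard values used throughout: a 100 x 25 breeding landscape
#' with carrying capacity `K = 100` per patch, migrant winter survival
#' `s_m = 0.5`, density-dependence strengths `c_dens_s = 0.6` (winter
#' survival) and `c_dens_r = 0.4` (reproduction), reproduction location
#' dependence `c_loc_r = 0.8`, mutation probability `m = 1e-4`, dispersal
#' probability `d = 0.1` with maximum dispersal distance `delta = 2` cells,
#' and brood sizes drawn uniformly from `{0, ..., max_brood = 6}`.
#'
#' `surv_delta` and `migr_repro_factor` carry the abrupt environmental
#' changes: `surv_delta` is added to the nominal resident survival `0.01 * x`
#' (then clamped to `[0, 1]`), and `migr_repro_factor` multiplies the
#' offspring number of migrant parents (0.8 under the degraded
#' migrant-reproduction scenario). Both are identities by default; scenario
#' machinery switches them on via [apply_change()].
#'
#' @param K Carrying capacity per patch (positive integer).
#' @param s_m Migrant winter-survival probability in `[0, 1]`.
#' @param c_dens_s Strength of survival density dependence in `[0, 1]`
#'   (1 = no density dependence).
#' @param c_dens_r Strength of reproduction density dependence in `[0, 1]`.
#' @param c_loc_r Strength of reproduction location dependence in `[0, 1]`
#'   (1 = no location dependence).
#' @param m Per-offspring mutation probability in `[0, 1]`.
#' @param d Per-survivor dispersal probability in `[0, 1]`.
#' @param delta Maximum dispersal distance in cells (positive integer;
#'   Chebyshev radius of the dispersal neighborhood).
#' @param x_max,y_max Landscape extent (positive integers).
#' @param max_brood Upper bound of the discrete-uniform brood-size draw.
#' @param surv_delta Additive shift of nominal resident survival.
#' @param migr_repro_factor Multiplicative factor on migrant offspring
#'   number, in `(0, 1]`.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params()
#' p$K
#' sim_params(x_max = 100, y_max = 5, K = 50)  # reduced landscape
#' @export
sim_params <- function(K = 100L, s_m = 0.5, c_dens_s = 0.6, c_dens_r = 0.4,
                       c_loc_r = 0.8, m = 1e-4, d = 0.1, delta = 2L,
                       x_max = 100L, y_max = 25L, max_brood = 6L,
                       surv_delta = 0, migr_repro_factor = 1) {
  p <- list(K = K, s_m = s_m, c_dens_s = c_dens_s,
            c_dens_r = c_dens_r, c_loc_r = c_loc_r, m = m, d = d,
            delta = delta, x_max = x_max, y_max = y_max,
            max_brood = max_brood, surv_delta = surv_delta,
            migr_repro_factor = migr_repro_factor)
  class(p) <- "sim_params"
  validate_sim_params(p)
  for (nm in c("K", "delta", "x_max", "y_max", "max_brood"))
    p[[nm]] <- as.integer(p[[nm]])
  p
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  chk_prob <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single probability in [0, 1]", nm),
           call. = FALSE)
  }
  for (nm in c("s_m", "c_dens_s", "c_dens_r", "c_loc_r", "m", "d"))
    chk_prob(p[[nm]], nm)
  chk_posint <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != as.integer(v))
      stop(sprintf("'%s' must be a positive integer", nm), call. = FALSE)
  }
  for (nm in c("K", "delta", "x_max", "y_max", "max_brood"))
    chk_posint(p[[nm]], nm)
  if (!is.numeric(p$surv_delta) || length(p$surv_delta) != 1L ||
      is.na(p$surv_delta))
    stop("'surv_delta' must be a single number", call. = FALSE)
  if (!is.numeric(p$migr_repro_factor) || length(p$migr_repro_factor) != 1L ||
      is.na(p$migr_repro_factor) || p$migr_repro_factor <= 0 ||
      p$migr_repro_factor > 1)
    stop("'migr_repro_factor' must be in (0, 1]", call. = FALSE)
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (sim_params)\n")
  cat(sprintf("  landscape: %d x %d patches, K = %d per patch\n",
              x$x_max, x$y_max, x$K))
  cat(sprintf("  survival:  migrant s_m = %g; resident 0.01*x %s, c_dens_s = %g\n",
              x$s_m,
              if (x$surv_delta != 0) sprintf("%+g", x$surv_delta) else "",
              x$c_dens_s))
  cat(sprintf("  reproduction: brood ~ U{0..%d}, c_loc_r = %g, c_dens_r = %g, migrant factor = %g\n",
              x$max_brood, x$c_loc_r, x$c_dens_r, x$migr_repro_factor))
  cat(sprintf("  dispersal: d = %g, delta = %d; mutation: m = %g\n",
              x$d, x$delta, x$m))
  invisible(x)
}

clamp01 <- function(v) pmin(pmax(v, 0), 1)
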