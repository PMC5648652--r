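#' Migration decision: the self-consistent threshold partition
#'
#' An individual migrates when its expected local winter survival falls
#' strictly below its genetic threshold T; it stays when the expectation is
#' greater than or equal to T. The expectation includes resident density,
#' which is itself the outcome of the decisions, so the partition is taken
#' as the fixed point of the sorted-threshold rule: with patch thresholds
#' sorted ascending, the realized resident count n* is the largest n such
#' that the n-th smallest threshold does not exceed
#' `resident_survival(x, n, params)`. Because the sorted thresholds are
#' non-decreasing and survival is non-increasing in the resident count,
#' that condition holds exactly for a prefix, and the n* individuals with
#' the smallest thresholds stay. Ties at the marginal threshold value are
#' broken uniformly at random.
#'
#' This realizes perfect anticipation: every resident's T is at most the
#' survival realized at density n*, and (up to ties at the margin) every
#' migrant's T exceeds it.
#'
#' @param thresholds Numeric vector of threshold values in `[0, 1]` for all
#'   individuals of one patch.
#' @param x Landscape column of the patch.
#' @param params A [sim_params()] object.
#'
#' @return A factor of length `length(thresholds)` with levels
#'   `migrant`, `resident`, aligned with the input.
#' @examples
#' set.seed(1)
#' table(decide_migration(rep(0.5, 20), x = 30))  # all migrate at low x
#' table(decide_migration(rep(0.5, 20), x = 60))  # low density: all stay
#' @export
decide_migration <- function(thresholds, x, params = sim_params()) {
  if (length(thresholds) &&
      (any(thresholds < 0) || any(thresholds > 1) || anyNA(thresholds)))
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  n <- length(thresholds)
  out <- factor(rep("migrant", n), levels = c("migrant", "resident"))
  if (n == 0L) return(out)
  ord <- order(thresholds, stats::runif(n))  # random order among ties
  rhs <- resident_survival(rep(x, n), seq_len(n), params)
  stay <- thresholds[ord] <= rhs             # prefix of the sorted order
  out[ord[stay]] <- "resident"
  out
}

#' Zero-density decision crossover
#'
#' The landscape column at which an individual with threshold `T` switches
#' from the migratory to the residential phenotype when density plays no
#' role: the smallest x whose nominal resident survival
#' (`0.01 * x + surv_delta`, clamped) reaches `T`. Below the crossover the
#' expected survival is strictly smaller than `T` and the individual
#' migrates; from the crossover on it stays. `NA` if no column qualifies.
#'
#' @param threshold Threshold value T in `[0, 1]`.
#' @param params A [sim_params()] object (its `surv_delta` and `x_max`
#'   are used).
#' @return The crossover column, or `NA`.
#' @examples
#' decision_crossover(0.5)                                  # 50
#' decision_crossover(0.5, sim_params(surv_delta = -0.2))   # 70
#' @export
decision_crossover <- function(threshold, params = sim_params()) {
  x <- seq_len(params$x_max)
  s <- nominal_resident_survival(x, params$surv_delta, params$x_max)
  ok <- s >= threshold
  if (!any(ok)) return(NA_integer_)
  min(x[ok])
}

# Landscape-wide decision step: fills pop$resident for every individual.
# Same fixed point as decide_migration(), vectorized over patches via a
# single radix sort on (patch, threshold, random tie-break).
assign_phenotypes <- function(pop, params) {
  n <- population_size(pop)
  if (n == 0L) {
    pop$resident <- logical(0)
    return(pop)
  }
  p <- patch_index(pop)
  ord <- order(p, pop$threshold, stats::runif(n), method = "radix")
  ps <- p[ord]
  starts <- which(!duplicated(ps))
  runlen <- diff(c(starts, n + 1L))
  rank <- sequence(runlen)                    # within-patch rank by T
  s0 <- clamp01(0.01 * pop$x[ord] + params$surv_delta)
  rhs <- s0 * pmax(1 - (1 - params$c_dens_s) * rank / params$K, 0)
  stay <- pop$threshold[ord] <= rhs
  res <- logical(n)
  res[ord] <- stay
  pop$resident <- res
  pop
}
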