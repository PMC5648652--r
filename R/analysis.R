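#' Per-generation summary of a population
#'
#' Phenotypes are summed and thresholds averaged per x-column (over all
#' rows of the landscape). Individuals that have not yet faced a winter
#' ("undecided", e.g. fresh offspring at the end of a run) are excluded
#' from the phenotype counts but included in occupancy totals and the
#' threshold mean.
#'
#' @param pop A [pm_population()] with phenotypes assigned (undecided
#'   individuals are tolerated and excluded from phenotype counts).
#' @param zone_threshold Fraction defining the partial-migration-zone
#'   borders (default 0.01, i.e. 1%).
#' @param front_direction Direction of the range expansion for the range
#'   front, `"from_low_x"` or `"from_high_x"`.
#'
#' @return An object of class `pm_summary`: a list with `generation`, the
#'   per-column data frame `per_x` (columns `x`, `n_migrant`,
#'   `n_resident`, `n_total`, `mean_T`), the zone statistics (see
#'   [pm_zone()]) and `range_front`.
#' @examples
#' pop <- pm_population(x = 40L, y = 3L, threshold = 0.2,
#'                      resident = TRUE, x_max = 100, y_max = 25)
#' s <- summarize_generation(pop)
#' s$per_x[40, ]
#' @export
summarize_generation <- function(pop, zone_threshold = 0.01,
                                 front_direction = c("from_low_x",
                                                     "from_high_x")) {
  front_direction <- match.arg(front_direction)
  xm <- pop$x_max
  dec <- !is.na(pop$resident)
  n_mig <- tabulate(pop$x[dec & !pop$resident], nbins = xm)
  n_res <- tabulate(pop$x[dec & pop$resident], nbins = xm)
  n_tot <- tabulate(pop$x, nbins = xm)
  sum_T <- numeric(xm)
  if (population_size(pop) > 0L) {
    s <- rowsum(pop$threshold, pop$x)
    sum_T[as.integer(rownames(s))] <- s[, 1L]
  }
  mean_T <- ifelse(n_tot > 0L, sum_T / n_tot, NA_real_)
  per_x <- data.frame(x = seq_len(xm), n_migrant = n_mig,
                      n_resident = n_res, n_total = n_tot, mean_T = mean_T)
  out <- list(generation = pop$generation, per_x = per_x)
  out <- c(out, pm_zone(per_x, zone_threshold))
  out$range_front <- range_front_per_x(per_x, front_direction)
  class(out) <- "pm_summary"
  out
}

#' Borders, width and location of the partial-migration zone
#'
#' The polar border is the smallest x-column in which residents make up at
#' least `threshold_frac` (default 1%) of that column's decided
#' individuals; the equatorial border is the largest x-column in which
#' migrants make up at least `threshold_frac`. Width is their difference
#' and the zone's location is their midpoint (possibly half-integer).
#' All values are `NA` when no column qualifies.
#'
#' @param summary A `pm_summary` or its `per_x` data frame.
#' @param threshold_frac Qualifying phenotype fraction per column.
#' @return A list with `polar_border`, `equatorial_border`, `zone_width`,
#'   `zone_midpoint`.
#' @examples
#' pop <- pm_population(x = rep(c(10L, 50L, 90L), c(4L, 4L, 4L)),
#'                      y = rep(1L, 12),
#'                      threshold = rep(0.5, 12),
#'                      resident = c(rep(FALSE, 4), rep(c(TRUE, FALSE), 2),
#'                                   rep(TRUE, 4)))
#' pm_zone(summarize_generation(pop))   # zone is the mixed column x = 50
#' @export
pm_zone <- function(summary, threshold_frac = 0.01) {
  per_x <- if (inherits(summary, "pm_summary")) summary$per_x else summary
  dec <- per_x$n_migrant + per_x$n_resident
  has <- dec > 0L
  res_ok <- has & per_x$n_resident > 0L &
    per_x$n_resident / pmax(dec, 1L) >= threshold_frac
  mig_ok <- has & per_x$n_migrant > 0L &
    per_x$n_migrant / pmax(dec, 1L) >= threshold_frac
  polar <- if (any(res_ok)) min(per_x$x[res_ok]) else NA_integer_
  equat <- if (any(mig_ok)) max(per_x$x[mig_ok]) else NA_integer_
  list(polar_border = polar, equatorial_border = equat,
       zone_width = equat - polar, zone_midpoint = (polar + equat) / 2)
}

#' Range front of an expanding population
#'
#' The most advanced occupied x-column relative to the side of the
#' landscape the expansion started from: the largest occupied column for
#' an expansion from low x, the smallest for one from high x. Occupancy
#' means at least `min_count` individuals (default 1) in the column.
#'
#' @param summary A `pm_summary` or its `per_x` data frame.
#' @param direction `"from_low_x"` or `"from_high_x"`.
#' @param min_count Occupancy cutoff per column.
#' @return The front column, or `NA` for an empty landscape.
#' @examples
#' pop <- pm_population(x = c(2L, 7L), y = c(1L, 1L),
#'                      threshold = c(0.5, 0.5), x_max = 100, y_max = 25)
#' range_front(summarize_generation(pop), "from_low_x")  # 7
#' @export
range_front <- function(summary, direction = c("from_low_x", "from_high_x"),
                        min_count = 1L) {
  direction <- match.arg(direction)
  per_x <- if (inherits(summary, "pm_summary")) summary$per_x else summary
  range_front_per_x(per_x, direction, min_count)
}

range_front_per_x <- function(per_x, direction, min_count = 1L) {
  occ <- per_x$x[per_x$n_total >= min_count]
  if (!length(occ)) return(NA_integer_)
  if (direction == "from_low_x") max(occ) else min(occ)
}

#' @export
print.pm_summary <- function(x, ...) {
  cat(sprintf("pm_summary: generation %d, %d individuals\n",
              x$generation, sum(x$per_x$n_total)))
  cat(sprintf("  migrants %d, residents %d\n",
              sum(x$per_x$n_migrant), sum(x$per_x$n_resident)))
  if (!is.na(x$polar_border) && !is.na(x$equatorial_border))
    cat(sprintf("  PM zone: x in [%d, %d], width %d, midpoint %.1f\n",
                x$polar_border, x$equatorial_border, x$zone_width,
                x$zone_midpoint))
  else cat("  PM zone: undefined\n")
  cat(sprintf("  range front: %s\n", format(x$range_front)))
  invisible(x)
}

#' @export
plot.pm_summary <- function(x, ...) {
  per_x <- x$per_x
  ylim <- c(0, max(per_x$n_total, 1L))
  plot(per_x$x, per_x$n_migrant, pch = 1, ylim = ylim,
       xlab = "x-location", ylab = "individuals",
       main = sprintf("Generation %d", x$generation), ...)
  points(per_x$x, per_x$n_resident, pch = 16)
  if (!is.na(x$polar_border))
    abline(v = c(x$polar_border, x$equatorial_border), lty = 3)
  ok <- !is.na(per_x$mean_T)
  if (any(ok))
    lines(per_x$x[ok], per_x$mean_T[ok] * max(ylim), lwd = 2)
  legend("topleft", pch = c(1, 16, NA), lwd = c(NA, NA, 2),
         legend = c("migrants", "residents", "mean T (scaled)"),
         bty = "n")
  invisible(x)
}

#' Aggregate zone statistics across replicate runs
#'
#' Per-generation arithmetic mean and sample standard deviation across
#' replicates of the zone borders, width, midpoint, range front and total
#' population size. Missing values (e.g. an undefined zone early in a
#' range expansion) are excluded, with the contributing replicate count
#' reported per cell.
#'
#' @param reps A [run_replicates()] result (`pm_replicates`), or a list of
#'   `pm_run` objects sharing a generation grid.
#' @param statistics Which zone-table columns to aggregate.
#' @return A long-format data frame with columns `generation`,
#'   `statistic`, `mean`, `sd`, `n`. Class `pm_aggregate`.
#' @examples
#' set.seed(7)
#' p <- sim_params(x_max = 30, y_max = 2, K = 10)
#' reps <- run_replicates(scenario("compl-zero"), p, n_generations = 5,
#'                        n_replicates = 2, base_seed = 1)
#' head(aggregate_replicates(reps))
#' @export
aggregate_replicates <- function(reps,
                                 statistics = c("polar_border",
                                                "equatorial_border",
                                                "zone_width", "zone_midpoint",
                                                "range_front", "n_total")) {
  runs <- if (inherits(reps, "pm_replicates")) reps$runs else reps
  stopifnot(length(runs) >= 1L)
  gens <- runs[[1]]$zone$generation
  for (r in runs)
    if (!identical(r$zone$generation, gens))
      stop("replicates do not share a generation grid", call. = FALSE)
  out <- list()
  for (st in statistics) {
    mat <- vapply(runs, function(r) as.numeric(r$zone[[st]]),
                  numeric(length(gens)))
    mat <- matrix(mat, nrow = length(gens))
    nn <- rowSums(!is.na(mat))
    mn <- rowMeans(mat, na.rm = TRUE)
    mn[nn == 0L] <- NA_real_
    sdv <- apply(mat, 1L, function(v) stats::sd(v, na.rm = TRUE))
    out[[st]] <- data.frame(generation = gens, statistic = st,
                            mean = mn, sd = sdv, n = nn)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pm_aggregate", "data.frame")
  res
}
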