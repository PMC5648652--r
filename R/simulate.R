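#' Run one replicate of a scenario
#'
#' Initializes the population per the scenario, then iterates the
#' generation cycle, applying the scenario's abrupt environmental change
#' from its change generation onward. Each recorded generation is
#' summarized after the migration decision (so phenotype counts refer to
#' the individuals that actually decided that year); the zone statistics
#' and range front are collected into a per-generation table.
#'
#' @param scenario A [scenario()] object.
#' @param params A [sim_params()] object.
#' @param n_generations Number of generations to simulate. Generations
#'   `0 .. n_generations - 1` are decided and recorded.
#' @param seed Integer seed for this replicate; all randomness flows from
#'   it.
#' @param record_every Record every `record_every`-th generation
#'   (generation 0 and the last decided generation are always recorded).
#' @param zone_threshold Phenotype fraction defining the zone borders.
#' @param keep_per_x Keep the full per-(generation, x) table (needed for
#'   [write_replicate_csv()]); off by default to save memory.
#' @param verbose Log per-generation progress to stderr.
#'
#' @return An object of class `pm_run`: list with the `scenario`,
#'   `params`, `seed`, the per-generation `zone` data frame (columns
#'   `generation`, `n_total`, `n_migrant`, `n_resident`, `polar_border`,
#'   `equatorial_border`, `zone_width`, `zone_midpoint`, `range_front`),
#'   optionally `per_x`, and the `final` population.
#' @examples
#' p <- sim_params(x_max = 30, y_max = 2, K = 10)
#' run <- run_simulation(scenario("compl-zero"), p, n_generations = 10,
#'                       seed = 1)
#' run$zone[1:3, ]
#' @export
run_simulation <- function(scenario, params = sim_params(),
                           n_generations = 1000L, seed = 1L,
                           record_every = 1L, zone_threshold = 0.01,
                           keep_per_x = FALSE, verbose = FALSE) {
  validate_scenario(scenario)
  validate_sim_params(params)
  stopifnot(n_generations >= 1L)
  set.seed(as.integer(seed))
  front_dir <- if (scenario$init_region == "residents_only")
    "from_high_x" else "from_low_x"
  pop <- init_population(scenario, params)
  rec_zone <- vector("list", n_generations)
  rec_perx <- if (keep_per_x) vector("list", n_generations) else NULL
  nrec <- 0L
  for (g in seq_len(n_generations) - 1L) {
    pg <- apply_change(params, scenario, g)
    pop <- assign_phenotypes(pop, pg)
    if (g %% record_every == 0L || g == n_generations - 1L) {
      s <- summarize_generation(pop, zone_threshold, front_dir)
      nrec <- nrec + 1L
      rec_zone[[nrec]] <- data.frame(
        generation = g, n_total = sum(s$per_x$n_total),
        n_migrant = sum(s$per_x$n_migrant),
        n_resident = sum(s$per_x$n_resident),
        polar_border = s$polar_border,
        equatorial_border = s$equatorial_border,
        zone_width = s$zone_width, zone_midpoint = s$zone_midpoint,
        range_front = s$range_front)
      if (keep_per_x)
        rec_perx[[nrec]] <- cbind(generation = g, s$per_x)
      if (verbose)
        message(sprintf("[%s seed %d] generation %d: %d individuals",
                        scenario$name, seed, g, sum(s$per_x$n_total)))
    }
    pop <- winter_step(pop, pg)
    pop <- disperse_step(pop, pg)
    pop <- reproduce_step(pop, pg)
    pop$generation <- pop$generation + 1L
  }
  out <- list(scenario = scenario, params = params, seed = as.integer(seed),
              n_generations = as.integer(n_generations),
              zone = do.call(rbind, rec_zone[seq_len(nrec)]),
              final = pop)
  if (keep_per_x) out$per_x <- do.call(rbind, rec_perx[seq_len(nrec)])
  class(out) <- "pm_run"
  out
}

#' Run replicate simulations of a scenario
#'
#' Runs `n_replicates` independent trajectories; replicate `i` uses seed
#' `base_seed + i`, so a whole replicate set is reproducible from the base
#' seed alone.
#'
#' @inheritParams run_simulation
#' @param n_replicates Number of replicates (default: the scenario's).
#' @param base_seed Base seed; replicate i runs with `base_seed + i`.
#' @param ... Passed on to [run_simulation()].
#' @return An object of class `pm_replicates`: list with the `scenario`,
#'   `params`, `base_seed` and the list of `pm_run` objects in `runs`.
#' @examples
#' p <- sim_params(x_max = 30, y_max = 2, K = 10)
#' reps <- run_replicates(scenario("compl-zero"), p, n_generations = 5,
#'                        n_replicates = 2, base_seed = 10)
#' length(reps$runs)
#' @export
run_replicates <- function(scenario, params = sim_params(),
                           n_generations = 1000L,
                           n_replicates = scenario$n_replicates,
                           base_seed = 1L, verbose = FALSE, ...) {
  runs <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    if (verbose)
      message(sprintf("scenario %s: replicate %d/%d (seed %d)",
                      scenario$name, i, n_replicates, base_seed + i))
    runs[[i]] <- run_simulation(scenario, params, n_generations,
                                seed = base_seed + i, verbose = FALSE, ...)
  }
  out <- list(scenario = scenario, params = params,
              base_seed = as.integer(base_seed), runs = runs)
  class(out) <- "pm_replicates"
  out
}

#' @export
print.pm_run <- function(x, ...) {
  cat(sprintf("pm_run: scenario '%s', seed %d, %d generations\n",
              x$scenario$name, x$seed, x$n_generations))
  last <- x$zone[nrow(x$zone), ]
  cat(sprintf("  final: %d individuals (%d migrants, %d residents)\n",
              last$n_total, last$n_migrant, last$n_resident))
  if (!is.na(last$zone_midpoint))
    cat(sprintf("  final PM zone: [%d, %d], midpoint %.1f; range front %s\n",
                last$polar_border, last$equatorial_border,
                last$zone_midpoint, format(last$range_front)))
  invisible(x)
}

#' @export
summary.pm_run <- function(object, ...) {
  z <- object$zone
  cat(sprintf("Scenario '%s' (seed %d), generations %d..%d\n",
              object$scenario$name, object$seed, min(z$generation),
              max(z$generation)))
  print(utils::tail(z, 5L), row.names = FALSE)
  invisible(z)
}

#' @export
plot.pm_run <- function(x, ...) {
  z <- x$zone
  ylim <- c(1, x$params$x_max)
  plot(z$generation, z$zone_midpoint, type = "l", ylim = ylim,
       xlab = "generation", ylab = "x-location",
       main = sprintf("'%s' (seed %d)", x$scenario$name, x$seed), ...)
  lines(z$generation, z$polar_border, lty = 3)
  lines(z$generation, z$equatorial_border, lty = 3)
  lines(z$generation, z$range_front, lty = 2)
  legend("topleft", lty = c(1, 3, 2),
         legend = c("zone midpoint", "zone borders", "range front"),
         bty = "n")
  invisible(x)
}

#' @export
print.pm_replicates <- function(x, ...) {
  cat(sprintf("pm_replicates: scenario '%s', %d replicates (base seed %d)\n",
              x$scenario$name, length(x$runs), x$base_seed))
  invisible(x)
}

#' @export
plot.pm_replicates <- function(x, statistic = "zone_midpoint", ...) {
  ag <- aggregate_replicates(x, statistic)
  ok <- !is.na(ag$mean)
  plot(ag$generation[ok], ag$mean[ok], type = "l",
       xlab = "generation", ylab = statistic,
       main = sprintf("'%s': mean +/- sd over %d replicates",
                      x$scenario$name, length(x$runs)), ...)
  sdv <- ifelse(is.na(ag$sd), 0, ag$sd)
  lines(ag$generation[ok], (ag$mean + sdv)[ok], lty = 3)
  lines(ag$generation[ok], (ag$mean - sdv)[ok], lty = 3)
  invisible(x)
}
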