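#' Simulation scenarios: initialization and abrupt environmental change
#'
#' A scenario bundles where the species starts, how much genetic diversity
#' it starts with, and which abrupt environmental change (if any) is
#' switched on during the run.
#'
#' * `init_region` — `"complete"` (all columns), `"migrants_only"`
#'   (1 <= x <= 10, the polar end), or `"residents_only"`
#'   (90 <= x <= 100, the equatorial end). Every patch in the region is
#'   initialized at carrying capacity K.
#' * `init_diversity` — `"maximum"` (thresholds drawn independently,
#'   uniform on (0, 1]), `"zero"` (all T = 0.5), or `"zero_fitted"`
#'   (T already adapted to the starting populations: T = 0.1 when starting
#'   from residents, T = 0.9 when starting from migrants; only valid with
#'   an edge initialization).
#' * `change` — `"none"`, `"surv_up"` (resident survival +0.2),
#'   `"surv_down"` (resident survival -0.2), or `"migr_repro"` (migrant
#'   reproductive success x 0.8). The change is a step function applied
#'   from `change_generation` onward (default 300, when demographic
#'   equilibrium has been reached); for the whole-landscape zero-diversity
#'   start it is applied at generation 0, so that no genetic diversity can
#'   accumulate before the change.
#'
#' Scenario names follow the shorthand `compl`/`migr`/`res` for the region,
#' `full`/`zero`/`zerofit` for the diversity, plus a change suffix, e.g.
#' `"compl-zero-survdown"`.
#'
#' @param name Scenario name. If it matches the shorthand pattern the
#'   remaining fields are derived from it; explicit arguments override.
#' @param init_region,init_diversity,change See Details.
#' @param change_generation Generation from which the change applies.
#'   Default 300, except 0 for the complete/zero-diversity start.
#' @param n_replicates Default number of replicate runs (100).
#'
#' @return An object of class `pm_scenario`.
#' @examples
#' scenario("migr-full")
#' scenario("compl-zero-survdown")$change_generation  # 0: change at start
#' scenario("custom", init_region = "residents_only",
#'          init_diversity = "zero_fitted", change = "migr_repro")
#' @export
scenario <- function(name = NULL,
                     init_region = c("complete", "migrants_only",
                                     "residents_only"),
                     init_diversity = c("maximum", "zero", "zero_fitted"),
                     change = c("none", "surv_up", "surv_down", "migr_repro"),
                     change_generation = NULL, n_replicates = 100L) {
  parsed <- if (!is.null(name)) parse_scenario_name(name) else NULL
  init_region <- if (missing(init_region) && !is.null(parsed$init_region))
    parsed$init_region else match.arg(init_region)
  init_diversity <- if (missing(init_diversity) && !is.null(parsed$init_diversity))
    parsed$init_diversity else match.arg(init_diversity)
  change <- if (missing(change) && !is.null(parsed$change))
    parsed$change else match.arg(change)
  if (is.null(change_generation))
    change_generation <- if (change != "none" &&
                             init_region == "complete" &&
                             init_diversity == "zero") 0L else 300L
  if (is.null(name)) name <- scenario_shorthand(init_region, init_diversity, change)
  sc <- list(name = name, init_region = init_region,
             init_diversity = init_diversity, change = change,
             change_generation = as.integer(change_generation),
             n_replicates = as.integer(n_replicates))
  class(sc) <- "pm_scenario"
  validate_scenario(sc)
  sc
}

region_codes <- c(compl = "complete", migr = "migrants_only",
                  res = "residents_only")
diversity_codes <- c(full = "maximum", zero = "zero", zerofit = "zero_fitted")
change_codes <- c(survup = "surv_up", survdown = "surv_down",
                  migrepro = "migr_repro")

parse_scenario_name <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  out <- list()
  if (length(parts) >= 2L && parts[1] %in% names(region_codes) &&
      parts[2] %in% names(diversity_codes)) {
    out$init_region <- unname(region_codes[parts[1]])
    out$init_diversity <- unname(diversity_codes[parts[2]])
    out$change <- if (length(parts) >= 3L && parts[3] %in% names(change_codes))
      unname(change_codes[parts[3]]) else "none"
  }
  out
}

scenario_shorthand <- function(init_region, init_diversity, change) {
  nm <- paste(names(region_codes)[match(init_region, region_codes)],
              names(diversity_codes)[match(init_diversity, diversity_codes)],
              sep = "-")
  if (change != "none")
    nm <- paste(nm, names(change_codes)[match(change, change_codes)], sep = "-")
  nm
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "pm_scenario"))
  if (sc$init_diversity == "zero_fitted" && sc$init_region == "complete")
    stop("fitted zero diversity requires an edge initialization ",
         "(migrants_only or residents_only)", call. = FALSE)
  if (sc$change_generation < 0L)
    stop("'change_generation' must be non-negative", call. = FALSE)
  if (sc$n_replicates < 1L)
    stop("'n_replicates' must be positive", call. = FALSE)
  invisible(sc)
}

#' @export
print.pm_scenario <- function(x, ...) {
  cat(sprintf("pm_scenario '%s'\n", x$name))
  cat(sprintf("  init: %s, diversity %s\n", x$init_region, x$init_diversity))
  if (x$change == "none") cat("  change: none\n")
  else cat(sprintf("  change: %s from generation %d\n",
                   x$change, x$change_generation))
  invisible(x)
}

#' The default 24-scenario catalog
#'
#' All valid combinations of initialization region and initial genetic
#' diversity (8: the whole-landscape start admits `maximum` and `zero`
#' diversity, the two edge starts additionally admit the fitted
#' zero-diversity variant) crossed with the three abrupt environmental
#' changes — 24 scenarios in all. Range-expansion behaviour without change
#' is observed in the pre-change phase of these runs (the change applies at
#' generation 300, after demographic equilibrium), so unchanged runs are
#' not separate catalog entries; construct them directly with
#' [scenario()] when needed.
#'
#' @param n_replicates Replicates per scenario (default 100).
#' @return An object of class `pm_catalog`: a named list of
#'   [scenario()] objects.
#' @examples
#' length(scenario_catalog())  # 24
#' @export
scenario_catalog <- function(n_replicates = 100L) {
  combos <- list(c("complete", "maximum"), c("complete", "zero"),
                 c("migrants_only", "maximum"), c("migrants_only", "zero"),
                 c("migrants_only", "zero_fitted"),
                 c("residents_only", "maximum"), c("residents_only", "zero"),
                 c("residents_only", "zero_fitted"))
  changes <- c("surv_up", "surv_down", "migr_repro")
  out <- list()
  for (cb in combos)
    for (ch in changes) {
      sc <- scenario(init_region = cb[1], init_diversity = cb[2],
                     change = ch, n_replicates = n_replicates)
      out[[sc$name]] <- sc
    }
  class(out) <- "pm_catalog"
  out
}

#' @export
print.pm_catalog <- function(x, ...) {
  cat(sprintf("pm_catalog: %d scenarios\n", length(x)))
  df <- catalog_table(x)
  print(df, row.names = FALSE)
  invisible(x)
}

catalog_table <- function(cat) {
  data.frame(name = vapply(cat, `[[`, "", "name"),
             init_region = vapply(cat, `[[`, "", "init_region"),
             init_diversity = vapply(cat, `[[`, "", "init_diversity"),
             change = vapply(cat, `[[`, "", "change"),
             change_generation = vapply(cat, `[[`, 0L, "change_generation"),
             row.names = NULL)
}

#' Initialize a population for a scenario
#'
#' Every patch of the scenario's initialization region starts at carrying
#' capacity K; all other patches are empty. Thresholds follow the
#' scenario's diversity mode: independent uniform draws on (0, 1] for
#' `maximum`, T = 0.5 for `zero`, and T = 0.1 (resident start) or T = 0.9
#' (migrant start) for `zero_fitted`.
#'
#' @param scenario A [scenario()] object.
#' @param params A [sim_params()] object.
#' @return A [pm_population()] at generation 0 with undecided phenotypes.
#' @examples
#' set.seed(1)
#' pop <- init_population(scenario("migr-zero"), sim_params(y_max = 5, K = 20))
#' population_size(pop)  # 10 columns x 5 rows x 20
#' @export
init_population <- function(scenario, params = sim_params()) {
  validate_scenario(scenario)
  xr <- switch(scenario$init_region,
               complete = seq_len(params$x_max),
               migrants_only = seq_len(min(10L, params$x_max)),
               residents_only = seq.int(max(1L, params$x_max - 10L),
                                        params$x_max))
  cells <- expand.grid(x = xr, y = seq_len(params$y_max))
  n <- nrow(cells) * params$K
  x <- rep(cells$x, each = params$K)
  y <- rep(cells$y, each = params$K)
  thr <- switch(scenario$init_diversity,
                maximum = 1 - stats::runif(n),          # uniform on (0, 1]
                zero = rep(0.5, n),
                zero_fitted = rep(if (scenario$init_region == "residents_only")
                  0.1 else 0.9, n))
  pm_population(x = x, y = y, threshold = thr, generation = 0L,
                x_max = params$x_max, y_max = params$y_max)
}

#' Apply a scenario's abrupt environmental change
#'
#' Returns the parameter set in force at a given generation: identical to
#' `params` before `change_generation`, and with `surv_delta` (+0.2 or
#' -0.2) or `migr_repro_factor` (0.8) set from `change_generation` onward.
#' The change is a step function and the operation is idempotent.
#'
#' @param params A [sim_params()] object.
#' @param scenario A [scenario()] object.
#' @param generation Current generation.
#' @return A `sim_params` object.
#' @examples
#' sc <- scenario("compl-full-survdown")
#' apply_change(sim_params(), sc, 299)$surv_delta  # 0
#' apply_change(sim_params(), sc, 300)$surv_delta  # -0.2
#' @export
apply_change <- function(params, scenario, generation) {
  if (scenario$change == "none" || generation < scenario$change_generation)
    return(params)
  switch(scenario$change,
         surv_up = params$surv_delta <- 0.2,
         surv_down = params$surv_delta <- -0.2,
         migr_repro = params$migr_repro_factor <- 0.8)
  params
}
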