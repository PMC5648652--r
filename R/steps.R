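#' One generation of the individual-based model
#'
#' The yearly cycle has four stages, applied in order by
#' [run_generation()]:
#'
#' 1. **Migration decision** — each patch is partitioned into residents and
#'    migrants by the self-consistent threshold rule (see
#'    [decide_migration()]).
#' 2. **Winter survival** ([winter_step()]) — a migrant survives with the
#'    constant probability `s_m`; a resident survives with
#'    [resident_survival()] evaluated at its column and at the patch's
#'    resident count fixed at decision time.
#' 3. **Dispersal** ([disperse_step()]) — each survivor relocates with
#'    probability `d` to a cell drawn uniformly from the Chebyshev
#'    neighborhood of radius `delta` around its patch (origin excluded);
#'    out-of-range coordinates are reflected back off the landscape edges
#'    ("bouncing borders"), redrawing in the rare case reflection returns
#'    the origin cell. Individuals can never leave the breeding landscape.
#' 4. **Reproduction** ([reproduce_step()]) — each survivor draws a raw
#'    brood size from the discrete uniform `{0, ..., max_brood}`,
#'    multiplied by the reproduction correction [reproduction_factor()]
#'    (patch totals counted after dispersal, both phenotypes) and, for
#'    migrant parents, by `migr_repro_factor`. The non-integer expected
#'    number R is realized by stochastic rounding, `floor(R)` plus a
#'    Bernoulli draw on the fractional part, which preserves E\[R\].
#'    Offspring inherit the mother's threshold, mutated with probability
#'    `m` to a fresh uniform draw on `[0, 1]`. All parents die (discrete,
#'    non-overlapping generations).
#'
#' Randomness is taken from R's global RNG; seed with [set.seed()] (the
#' runners [run_simulation()] and [run_replicates()] do this per
#' replicate).
#'
#' @param pop A [pm_population()]. `winter_step()` requires phenotypes to
#'   be assigned for the current generation.
#' @param params A [sim_params()] object.
#'
#' @return A new `pm_population`. `run_generation()` increments the
#'   generation counter and leaves the offspring's phenotypes undecided.
#' @examples
#' set.seed(42)
#' pop <- init_population(scenario("compl-zero"), sim_params(y_max = 2, K = 10))
#' pop2 <- run_generation(pop, sim_params(y_max = 2, K = 10))
#' pop2$generation
#' @export
run_generation <- function(pop, params = sim_params()) {
  validate_population(pop)
  pop <- assign_phenotypes(pop, params)
  pop <- winter_step(pop, params)
  pop <- disperse_step(pop, params)
  pop <- reproduce_step(pop, params)
  pop$generation <- pop$generation + 1L
  pop
}

#' @rdname run_generation
#' @export
winter_step <- function(pop, params = sim_params()) {
  n <- population_size(pop)
  if (n == 0L) return(pop)
  if (anyNA(pop$resident))
    stop("phenotypes must be assigned before winter survival", call. = FALSE)
  p <- patch_index(pop)
  npatch <- pop$x_max * pop$y_max
  n_res <- tabulate(p[pop$resident], nbins = npatch)
  prob <- rep(params$s_m, n)
  res <- pop$resident
  prob[res] <- resident_survival(pop$x[res], n_res[p[res]], params)
  keep <- stats::runif(n) < prob
  subset_population(pop, keep)
}

#' @rdname run_generation
#' @export
disperse_step <- function(pop, params = sim_params()) {
  n <- population_size(pop)
  if (n == 0L || params$d == 0) return(pop)
  moving <- which(stats::runif(n) < params$d)
  if (!length(moving)) return(pop)
  off <- dispersal_offsets(params$delta)
  m <- length(moving)
  ox <- pop$x[moving]; oy <- pop$y[moving]
  nx <- integer(m); ny <- integer(m)
  todo <- seq_len(m)
  while (length(todo)) {
    k <- sample.int(nrow(off), length(todo), replace = TRUE)
    nx[todo] <- reflect_coord(ox[todo] + off[k, 1L], pop$x_max)
    ny[todo] <- reflect_coord(oy[todo] + off[k, 2L], pop$y_max)
    # on very small landscapes reflection can land back on the origin
    todo <- todo[nx[todo] == ox[todo] & ny[todo] == oy[todo]]
  }
  pop$x[moving] <- nx
  pop$y[moving] <- ny
  pop
}

#' @rdname run_generation
#' @export
reproduce_step <- function(pop, params = sim_params()) {
  n <- population_size(pop)
  if (n == 0L) {
    pop$resident <- rep(NA, 0L)
    return(pop)
  }
  p <- patch_index(pop)
  n_tot <- tabulate(p, nbins = pop$x_max * pop$y_max)
  c_tot <- reproduction_factor(pop$x, n_tot[p], params)
  brood <- sample.int(params$max_brood + 1L, n, replace = TRUE) - 1L
  R <- brood * c_tot
  if (params$migr_repro_factor != 1) {
    mig <- !is.na(pop$resident) & !pop$resident
    R[mig] <- R[mig] * params$migr_repro_factor
  }
  k <- floor(R)
  k <- as.integer(k + (stats::runif(n) < R - k))  # stochastic rounding
  idx <- rep.int(seq_len(n), k)
  thr <- pop$threshold[idx]
  if (length(thr)) {
    mut <- stats::runif(length(thr)) < params$m
    if (any(mut)) thr[mut] <- stats::runif(sum(mut))
  }
  pm_population(x = pop$x[idx], y = pop$y[idx], threshold = thr,
                generation = pop$generation,
                x_max = pop$x_max, y_max = pop$y_max)
}

subset_population <- function(pop, keep) {
  pop$x <- pop$x[keep]
  pop$y <- pop$y[keep]
  pop$threshold <- pop$threshold[keep]
  pop$resident <- pop$resident[keep]
  pop
}

# all (dx, dy) offsets with Chebyshev distance in [1, delta]
dispersal_offsets <- function(delta) {
  g <- expand.grid(dx = -delta:delta, dy = -delta:delta)
  as.matrix(g[g$dx != 0L | g$dy != 0L, , drop = FALSE])
}

# reflect coordinates off the edges at 1 and vmax until inside
reflect_coord <- function(v, vmax) {
  repeat {
    lo <- v < 1L
    if (any(lo)) v[lo] <- 2L - v[lo]
    hi <- v > vmax
    if (any(hi)) v[hi] <- 2L * vmax - v[hi]
    if (!any(lo) && !any(hi)) return(v)
  }
}
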