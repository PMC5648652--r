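# Independent oracles used across test files. All are deliberately written
# as plain scalar loops / enumerations, independent of the vectorized
# implementation paths they check.

# brute-force fixed point: largest n in 0..N such that the n-th smallest
# threshold is <= resident_survival(x, n); returns the resident count
oracle_resident_count <- function(thresholds, x, params) {
  ts <- sort(thresholds)
  n_star <- 0L
  for (n in seq_along(ts)) {
    s <- min(max((0.01 * x + params$surv_delta), 0), 1) *
      (1 - (1 - params$c_dens_s) * n / params$K)
    s <- min(max(s, 0), 1)
    if (ts[n] <= s) n_star <- n
  }
  n_star
}

# scalar reflection of a single coordinate off edges at 1 and vmax
oracle_reflect1 <- function(v, vmax) {
  while (v < 1 || v > vmax) {
    if (v < 1) v <- 2 - v
    if (v > vmax) v <- 2 * vmax - v
  }
  v
}

# all destination cells reachable from (x0, y0) by one dispersal event
oracle_destinations <- function(x0, y0, delta, x_max, y_max) {
  dest <- character(0)
  for (dx in -delta:delta) for (dy in -delta:delta) {
    if (dx == 0 && dy == 0) next
    nx <- oracle_reflect1(x0 + dx, x_max)
    ny <- oracle_reflect1(y0 + dy, y_max)
    if (nx == x0 && ny == y0) next  # redrawn, not a destination
    dest <- c(dest, paste(nx, ny))
  }
  sort(unique(dest))
}

# exact expected next-generation size for a single patch of n identical
# residents (T low enough that everyone stays), no dispersal, no mutation:
# survivors S ~ Binomial(n, s_r(x, n)); offspring mean per survivor is
# E[No] * c_tot(S), c_tot linear in S, so E[N'] = E[No] * loc *
# (E[S] - (1 - c_dens_r)/K * E[S^2])
oracle_expected_offspring <- function(n, x, params) {
  s <- min(max(0.01 * x + params$surv_delta, 0), 1) *
    (1 - (1 - params$c_dens_s) * n / params$K)
  s <- min(max(s, 0), 1)
  ES <- n * s
  ES2 <- n * s * (1 - s) + (n * s)^2
  loc <- 1 - 0.01 * x * (1 - params$c_loc_r)
  (params$max_brood / 2) * loc * (ES - (1 - params$c_dens_r) / params$K * ES2)
}
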