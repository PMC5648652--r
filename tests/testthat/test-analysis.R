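test_that("per-column summary counts phenotypes and averages thresholds", {
  pop <- pm_population(x = 40L, y = 3L, threshold = 0.2, resident = TRUE,
                       x_max = 100, y_max = 25)
  s <- summarize_generation(pop)
  expect_identical(s$per_x$n_migrant[40], 0L)
  expect_identical(s$per_x$n_resident[40], 1L)
  expect_equal(s$per_x$mean_T[40], 0.2)
  # empty columns: zero counts, missing mean threshold
  expect_identical(s$per_x$n_total[41], 0L)
  expect_true(is.na(s$per_x$mean_T[41]))
  expect_true(all(s$per_x$mean_T >= 0 & s$per_x$mean_T <= 1, na.rm = TRUE))
})

test_that("summary totals conserve the population", {
  set.seed(8)
  p <- sim_params(x_max = 25L, y_max = 3L, K = 8L)
  pop <- pm_population(x = sample(1:25, 400, TRUE), y = sample(1:3, 400, TRUE),
                       threshold = runif(400), x_max = 25, y_max = 3)
  pop <- partmig:::assign_phenotypes(pop, p)
  s <- summarize_generation(pop)
  expect_identical(sum(s$per_x$n_total), 400L)
  expect_identical(sum(s$per_x$n_migrant) + sum(s$per_x$n_resident), 400L)
  # direct enumeration oracle per column
  for (xc in c(1L, 7L, 25L)) {
    sel <- pop$x == xc
    expect_identical(s$per_x$n_resident[xc], sum(pop$resident[sel]))
    expect_identical(s$per_x$n_total[xc], sum(sel))
  }
  # undecided individuals count for occupancy but not phenotype
  pop$resident[1:10] <- NA
  s2 <- summarize_generation(pop)
  expect_identical(sum(s2$per_x$n_total), 400L)
  expect_identical(sum(s2$per_x$n_migrant) + sum(s2$per_x$n_resident), 390L)
})

test_that("zone borders follow the 1% per-column rule", {
  # hand-constructed profile: residents first reach 1% at x = 45,
  # migrants last reach 1% at x = 62
  per_x <- data.frame(x = 1:100, n_migrant = 0L, n_resident = 0L,
                      n_total = 0L, mean_T = NA_real_)
  per_x$n_migrant[1:44] <- 200L
  per_x$n_migrant[45:62] <- 100L
  per_x$n_resident[45:62] <- 100L
  per_x$n_resident[63:90] <- 200L
  per_x$n_total <- per_x$n_migrant + per_x$n_resident
  z <- pm_zone(per_x)
  expect_identical(z$polar_border, 45L)
  expect_identical(z$equatorial_border, 62L)
  expect_identical(z$zone_width, 17L)
  expect_equal(z$zone_midpoint, 53.5)
  # just under 1% does not qualify
  per_x$n_resident[40] <- 1L
  per_x$n_total[40] <- per_x$n_migrant[40] + 1L
  expect_identical(pm_zone(per_x)$polar_border, 45L)
  # at exactly 1% it does
  per_x$n_migrant[40] <- 99L
  per_x$n_total[40] <- 100L
  expect_identical(pm_zone(per_x)$polar_border, 40L)
  # threshold 0: any occupied column with a resident qualifies
  expect_identical(pm_zone(per_x, threshold_frac = 0)$polar_border, 40L)
})

test_that("undefined borders propagate as missing", {
  per_x <- data.frame(x = 1:50, n_migrant = 100L, n_resident = 0L,
                      n_total = 100L, mean_T = 0.5)
  z <- pm_zone(per_x)
  expect_true(is.na(z$polar_border))
  expect_identical(z$equatorial_border, 50L)
  expect_true(is.na(z$zone_width))
  empty <- data.frame(x = 1:50, n_migrant = 0L, n_resident = 0L,
                      n_total = 0L, mean_T = NA_real_)
  expect_true(is.na(pm_zone(empty)$equatorial_border))
})

test_that("zone borders bracket the mixed region on simulated summaries", {
  p <- sim_params(x_max = 60L, y_max = 3L, K = 20L)
  sc <- scenario("compl-full")
  set.seed(55)
  pop <- init_population(sc, p)
  for (g in 1:40) pop <- run_generation(pop, p)
  pop <- partmig:::assign_phenotypes(pop, p)
  s <- summarize_generation(pop)
  expect_false(is.na(s$polar_border))
  dec <- s$per_x$n_migrant + s$per_x$n_resident
  frac_res <- ifelse(dec > 0, s$per_x$n_resident / dec, NA)
  below <- which(s$per_x$x < s$polar_border & dec > 0)
  expect_true(all(frac_res[below] < 0.01))
  above <- which(s$per_x$x > s$equatorial_border & dec > 0)
  expect_true(all(1 - frac_res[above] < 0.01))
})

test_that("range front tracks the most advanced occupied column", {
  pop <- pm_population(x = rep(1:10, each = 2), y = rep(1:2, 10),
                       threshold = runif(20), x_max = 100, y_max = 25)
  s <- summarize_generation(pop)
  expect_identical(range_front(s, "from_low_x"), 10L)
  expect_identical(range_front(s, "from_high_x"), 1L)
  # brute-force oracle on a scattered population
  set.seed(9)
  xs <- sample(1:100, 40, TRUE)
  pop2 <- pm_population(x = xs, y = sample(1:25, 40, TRUE),
                        threshold = runif(40), x_max = 100, y_max = 25)
  s2 <- summarize_generation(pop2)
  expect_identical(range_front(s2, "from_low_x"), max(xs))
  # empty landscape: missing
  empty <- pm_population(integer(0), integer(0), numeric(0),
                         x_max = 100, y_max = 25)
  expect_true(is.na(range_front(summarize_generation(empty))))
})

test_that("replicate aggregation has the right moments", {
  mk <- function(mid) list(zone = data.frame(generation = 0:1,
                                             zone_midpoint = c(mid, NA)))
  ag <- aggregate_replicates(list(mk(50), mk(60)),
                             statistics = "zone_midpoint")
  g0 <- ag[ag$generation == 0, ]
  expect_equal(g0$mean, 55)
  expect_equal(g0$sd, sqrt(50))
  expect_identical(g0$n, 2)
  # missing values excluded with count reported
  g1 <- ag[ag$generation == 1, ]
  expect_identical(g1$n, 0)
  expect_true(is.na(g1$mean))
  # identical replicates have zero spread; singleton sets have NA sd
  ag2 <- aggregate_replicates(list(mk(42), mk(42)),
                              statistics = "zone_midpoint")
  expect_equal(ag2$sd[ag2$generation == 0], 0)
  ag3 <- aggregate_replicates(list(mk(42)), statistics = "zone_midpoint")
  expect_equal(ag3$mean[ag3$generation == 0], 42)
  expect_true(is.na(ag3$sd[ag3$generation == 0]))
  # replicates must share the generation grid
  bad <- list(zone = data.frame(generation = 5:6, zone_midpoint = c(1, 2)))
  expect_error(aggregate_replicates(list(mk(50), bad)), "generation grid")
})
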