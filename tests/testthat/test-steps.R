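one_patch_pop <- function(n, thr, x = 60L, y = 1L, x_max = 100L, y_max = 1L,
                          resident = rep(NA, n)) {
  pm_population(x = rep(x, n), y = rep(y, n), threshold = rep(thr, n),
                x_max = x_max, y_max = y_max, resident = resident)
}

test_that("winter survival: migrants face s_m, overcrowded residents die", {
  p <- sim_params(x_max = 100L, y_max = 1L)
  # 10 migrants with s_m = 0.5: mean survivors ~ Binomial(10, 0.5)
  set.seed(3)
  surv <- replicate(400, {
    pop <- one_patch_pop(10, 0.9, resident = rep(FALSE, 10))
    population_size(winter_step(pop, p))
  })
  expect_lt(abs(mean(surv) - 5), 3 * sqrt(10 * 0.25 / 400) * 2)
  # residents at density 2.5 K never survive
  set.seed(4)
  pop <- one_patch_pop(250, 0, x = 100L, resident = rep(TRUE, 250))
  expect_identical(population_size(winter_step(pop, p)), 0L)
  # a sole resident at x = 100 survives with probability 0.996
  expect_equal(resident_survival(100, 1), 0.996)
  set.seed(5)
  alone <- replicate(2000, {
    pop <- one_patch_pop(1, 0, x = 100L, resident = TRUE)
    population_size(winter_step(pop, p))
  })
  expect_gt(mean(alone), 0.99)
  expect_error(winter_step(one_patch_pop(3, 0.5), p), "phenotypes")
})

test_that("dispersal conserves individuals, stays in bounds, uses the full kernel", {
  p <- sim_params(x_max = 20L, y_max = 10L, d = 1)
  set.seed(11)
  pop <- pm_population(x = sample(1:20, 500, TRUE), y = sample(1:10, 500, TRUE),
                       threshold = runif(500), x_max = 20, y_max = 10)
  moved <- disperse_step(pop, p)
  expect_identical(population_size(moved), 500L)
  expect_true(all(moved$x >= 1 & moved$x <= 20))
  expect_true(all(moved$y >= 1 & moved$y <= 10))
  expect_identical(moved$threshold, pop$threshold)
  # d = 0 leaves everyone in place
  p0 <- sim_params(x_max = 20L, y_max = 10L, d = 0)
  same <- disperse_step(pop, p0)
  expect_identical(same$x, pop$x)
  expect_identical(same$y, pop$y)
  # interior origin: exactly the 24 cells of the Chebyshev-2 ring
  set.seed(12)
  dest <- replicate(3000, {
    m <- disperse_step(one_patch_pop(1, 0.5, x = 10L, y = 5L,
                                     x_max = 20L, y_max = 10L), p)
    paste(m$x, m$y)
  })
  expect_setequal(unique(dest), oracle_destinations(10, 5, 2, 20, 10))
  expect_identical(length(oracle_destinations(10, 5, 2, 20, 10)), 24L)
  # corner origin: destinations match the brute-force reflection oracle
  set.seed(13)
  dest_c <- replicate(3000, {
    m <- disperse_step(one_patch_pop(1, 0.5, x = 1L, y = 1L,
                                     x_max = 20L, y_max = 10L), p)
    paste(m$x, m$y)
  })
  expect_setequal(unique(dest_c), oracle_destinations(1, 1, 2, 20, 10))
})

test_that("reflection oracle agrees with the vectorized bouncing borders", {
  for (vmax in c(3L, 5L, 20L))
    for (v in (-4L):(vmax + 4L))
      expect_equal(partmig:::reflect_coord(v, vmax),
                   oracle_reflect1(v, vmax))
})

test_that("reproduction: offspring numbers, inheritance and parental death", {
  # zero reproduction factor -> no offspring
  p <- sim_params(x_max = 100L, y_max = 1L, K = 10L, c_dens_r = 0, m = 0)
  set.seed(21)
  pop <- one_patch_pop(30, 0.5, x = 50L, resident = rep(TRUE, 30))
  pop$x_max <- 100L
  kids <- reproduce_step(pop, p)  # density 3K with c_dens_r = 0 -> c_tot = 0
  expect_identical(population_size(kids), 0L)
  # expected offspring per parent is 3 * c_tot (E[brood] = 3)
  p2 <- sim_params(x_max = 100L, y_max = 1L, K = 100L, m = 0)
  ct <- reproduction_factor(50, 20, p2)
  set.seed(22)
  kids_n <- replicate(500, {
    pop <- one_patch_pop(20, 0.5, x = 50L, resident = rep(TRUE, 20))
    population_size(reproduce_step(pop, p2))
  })
  expect_lt(abs(mean(kids_n) - 20 * 3 * ct), 0.6)
  # offspring inherit the maternal threshold when m = 0
  set.seed(23)
  mom <- one_patch_pop(50, 0.123, x = 30L, resident = rep(TRUE, 50))
  brood <- reproduce_step(mom, p2)
  expect_true(all(brood$threshold == 0.123))
  expect_true(all(is.na(brood$resident)))  # offspring are undecided
  # migrant parents produce fewer offspring under migr_repro_factor
  p3 <- sim_params(x_max = 100L, y_max = 1L, m = 0, migr_repro_factor = 0.8)
  set.seed(24)
  mig_kids <- replicate(500, {
    pop <- one_patch_pop(20, 0.9, x = 50L, resident = rep(FALSE, 20))
    population_size(reproduce_step(pop, p3))
  })
  expect_lt(abs(mean(mig_kids) - 20 * 3 * ct * 0.8), 0.6)
})

test_that("mutation hits the expected fraction of offspring and stays in [0, 1]", {
  p <- sim_params(x_max = 100L, y_max = 1L, K = 1000L, m = 0.2)
  set.seed(31)
  pop <- one_patch_pop(800, 0.25, x = 40L, resident = rep(TRUE, 800))
  kids <- reproduce_step(pop, p)
  n_mut <- sum(kids$threshold != 0.25)
  n_kid <- population_size(kids)
  expect_gt(n_kid, 1000L)
  # mutant count ~ Binomial(n_kid, 0.2)
  expect_lt(abs(n_mut / n_kid - 0.2), 4 * sqrt(0.2 * 0.8 / n_kid))
  expect_true(all(kids$threshold >= 0 & kids$threshold <= 1))
})

test_that("a full generation matches the closed-form one-patch expectation", {
  # one patch, all residents (T = 0), no dispersal, no mutation: the
  # expected next-generation size has a closed form via the binomial
  # moments of the survivor count
  p <- sim_params(x_max = 100L, y_max = 1L, K = 50L, d = 0, m = 0)
  n0 <- 20L
  exp_n <- oracle_expected_offspring(n0, 60, p)
  set.seed(41)
  sizes <- replicate(600, {
    pop <- one_patch_pop(n0, 0, x = 60L)
    population_size(run_generation(pop, p))
  })
  se <- stats::sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - exp_n), 4 * se)
})

test_that("run_generation composes the four stages and increments time", {
  p <- sim_params(x_max = 30L, y_max = 2L, K = 10L)
  set.seed(51)
  pop <- pm_population(x = sample(1:30, 200, TRUE), y = sample(1:2, 200, TRUE),
                       threshold = runif(200), x_max = 30, y_max = 2)
  set.seed(77)
  a <- run_generation(pop, p)
  set.seed(77)
  b <- partmig:::assign_phenotypes(pop, p)
  b <- winter_step(b, p)
  b <- disperse_step(b, p)
  b <- reproduce_step(b, p)
  b$generation <- b$generation + 1L
  expect_identical(a, b)
  expect_identical(a$generation, 1L)
  # empty landscape stays empty
  empty <- pm_population(integer(0), integer(0), numeric(0),
                         x_max = 30, y_max = 2)
  expect_identical(population_size(run_generation(empty, p)), 0L)
})

test_that("thresholds stay in [0, 1] and cannot diversify without mutation", {
  p <- sim_params(x_max = 15L, y_max = 2L, K = 15L, m = 0)
  set.seed(61)
  init <- c(0.1, 0.35, 0.6, 0.85)
  pop <- pm_population(x = sample(1:15, 120, TRUE), y = sample(1:2, 120, TRUE),
                       threshold = sample(init, 120, TRUE),
                       x_max = 15, y_max = 2)
  for (g in 1:25) {
    pop <- run_generation(pop, p)
    expect_true(all(pop$threshold >= 0 & pop$threshold <= 1))
    expect_true(all(pop$threshold %in% init))
  }
})
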