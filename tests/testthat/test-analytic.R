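test_that("parameter validation enforces the model's domain", {
  expect_s3_class(model_params(ne = 100, u = 0.01, vm = 1e-3), "tbl_df")
  expect_error(model_params(ne = 0.5, u = 0.01, vm = 1e-3), "ne")
  expect_error(model_params(ne = 100, u = -1, vm = 1e-3), "u")
  expect_error(model_params(ne = 100, u = 0.01, vm = 0), "vm")
  expect_error(model_params(ne = 100, u = 0.01, vm = 1e-3, vs = -1), "vs")
  expect_error(model_params(ne = 100, u = 0.01, vm = 1e-3, ve = -0.1), "ve")
  # u must equal mu * l when both are given
  expect_error(model_params(ne = 100, u = 0.02, vm = 1e-3, mu = 1e-8,
                            l = 1e6), "mu")
  p <- model_params(ne = 100, mu = 1e-8, l = 1e6, vm = 1e-3)
  expect_equal(p$u, 0.01)
})

test_that("Gaussian fitness is one at the optimum and decays as specified", {
  p1 <- model_params(ne = 1, u = 0, vm = 1, vs = 1)
  expect_identical(gaussian_fitness(0, p1), 1)
  for (vs in c(0.3, 1, 7)) {
    prm <- model_params(ne = 1, u = 0, vm = 1, vs = vs, optimum = 2.5)
    expect_identical(gaussian_fitness(2.5, prm), 1)
    expect_equal(gaussian_fitness(2.5 + sqrt(2 * vs), prm), exp(-1))
  }
  # absorbing environmental variance widens the fitness function
  prm <- model_params(ne = 1, u = 0, vm = 1, vs = 0.5, ve = 0.5)
  expect_equal(gaussian_fitness(1, prm, absorb_ve = TRUE), exp(-0.5))
  expect_error(gaussian_fitness(NaN, p1), "finite")
  expect_error(gaussian_fitness(Inf, p1), "finite")
})

test_that("closed-form mean fitness agrees with quadrature of the integral", {
  expect_identical(mean_fitness_at(0, 0, 1), 1)
  expect_equal(mean_fitness_at(0, 2, 2), sqrt(0.5))
  cases <- expand.grid(pbar = c(0, 0.1, -0.7), vp = c(0.04, 0.5),
                       vs = c(0.5, 1))
  for (i in seq_len(nrow(cases))) {
    cf <- mean_fitness_at(cases$pbar[i], cases$vp[i], cases$vs[i])
    nm <- mean_fitness_numeric(cases$pbar[i], cases$vp[i], cases$vs[i])
    expect_equal(cf, nm, tolerance = 1e-10)
  }
  expect_error(mean_fitness_at(0, 1, 0), "vs")
})

test_that("expectation over mean-phenotype fluctuations matches its oracle and limits", {
  # infinite-size limit
  for (vp in c(0.01, 0.1, 1)) {
    expect_equal(expected_mean_fitness_given_vp(1e12, vp, 1),
                 sqrt(1 / (vp + 1)), tolerance = 1e-6)
  }
  expect_equal(expected_mean_fitness_given_vp(1e12, 0, 1), 1,
               tolerance = 1e-10)
  # degenerate inner integral
  expect_equal(expected_mean_fitness_numeric(1000, 0, 1), sqrt(2000 / 2001),
               tolerance = 1e-10)
  # direct substitution
  expect_equal(expected_mean_fitness_given_vp(10, 1, 1), sqrt(20 / 41))
  # nested-quadrature oracle at a representative point
  expect_equal(expected_mean_fitness_given_vp(1000, 0.04, 1),
               expected_mean_fitness_numeric(1000, 0.04, 1),
               tolerance = 1e-8)
  # monotone non-increasing in VP
  vps <- seq(0, 2, length.out = 40)
  w <- expected_mean_fitness_given_vp(500, vps, 1)
  expect_true(all(diff(w) <= 0))
})

test_that("stochastic house-of-cards variance interpolates its two regimes", {
  # strong-effect (house-of-cards) limit
  p <- model_params(ne = 1e9, u = 0.01, vm = 1, vs = 1)
  expect_equal(vg_shoc(p), 4 * 0.01 * 1, tolerance = 1e-6)
  # weak-effect (drift) limit
  p <- model_params(ne = 10, u = 0.01, vm = 1e-8, vs = 1)
  expect_equal(vg_shoc(p), 4 * 10 * 0.01 * 1e-8, tolerance = 1e-6)
  # ne * vm = vs forces the midpoint exactly
  p <- model_params(ne = 100, u = 0.07, vm = 0.01, vs = 1)
  expect_identical(vg_shoc(p), 2 * 0.07 * 1)
  # 1% convergence bands at ratio 100 and 0.01
  p <- model_params(ne = 100, u = 0.01, vm = 1, vs = 1)     # ratio 100
  expect_equal(vg_shoc(p) / (4 * 0.01), 1, tolerance = 0.011)
  p <- model_params(ne = 100, u = 0.01, vm = 1e-4, vs = 1)  # ratio 0.01
  expect_equal(vg_shoc(p) / (4 * 100 * 0.01 * 1e-4), 1, tolerance = 0.011)
  # monotone increasing in each of ne, u, vm
  base <- list(ne = 10^seq(0, 6, length.out = 20), u = 0.01, vm = 1e-3)
  expect_true(all(diff(vg_shoc(model_params(ne = base$ne, u = 0.01,
                                            vm = 1e-3))) > 0))
  expect_true(all(diff(vg_shoc(model_params(ne = 100, u = seq(0.001, 0.1,
                                                              length.out = 20),
                                            vm = 1e-3))) > 0))
  expect_true(all(diff(vg_shoc(model_params(ne = 100, u = 0.01,
                                            vm = 10^seq(-6, 0, length.out = 20)))) > 0))
})

test_that("equilibrium expected mean fitness composes variance and fluctuation laws", {
  # mutation-free population: only drift load remains
  p <- model_params(ne = c(10, 1000), u = 0, vm = 1e-3)
  expect_equal(expected_mean_fitness(p),
               sqrt(2 * c(10, 1000) / (1 + 2 * c(10, 1000))))
  # the closed form is exactly the composition of its two pieces
  p <- model_params(ne = 1000, u = 0.01, vm = 1e-3, vs = 1)
  expect_equal(expected_mean_fitness(p),
               expected_mean_fitness_given_vp(1000, vg_shoc(p), 1),
               tolerance = 1e-12)
  # with environmental variance, composition holds with vs + ve throughout
  p <- model_params(ne = 1000, u = 0.01, vm = 1e-3, vs = 1, ve = 0.5)
  expect_equal(expected_mean_fitness(p),
               expected_mean_fitness_given_vp(1000, vg_shoc(p), 1.5),
               tolerance = 1e-12)
  # large populations: load below 2U and within 25% of it
  p <- model_params(ne = 1e7, u = 0.01, vm = 1e-2, vs = 1)
  load <- 1 - expected_mean_fitness(p)
  expect_lt(load, 0.02)
  expect_gt(load, 0.75 * 0.02)
})

test_that("truncated load expansion reproduces the drift and mutation limits", {
  expect_equal(load_approx(model_params(ne = 100, u = 0, vm = 1e-3)),
               1 / 400)
  expect_equal(load_approx(model_params(ne = 1e9, u = 0.01, vm = 1, vs = 1)),
               2 * 0.01, tolerance = 1e-6)
  p <- model_params(ne = 1000, u = 0.01, vm = 1e-3, vs = 1)
  expect_equal(load_approx(p), 1 - expected_mean_fitness(p),
               tolerance = 0.1)
})

test_that("finite-optimum condition and thresholds follow the strict inequality", {
  # boundary: u exactly at the threshold is not enough
  p <- model_params(ne = 1, u = 0.01 / 8, vm = 0.01, vs = 1)
  expect_false(finite_optimum_condition(p)$finite)
  cond <- finite_optimum_condition(model_params(ne = 1, u = 0.01, vm = 0.01,
                                                vs = 1))
  expect_equal(cond$threshold_u, 1.25e-3)
  expect_true(cond$finite)
  cond <- finite_optimum_condition(model_params(ne = 1, mu = 1e-8, l = 1e6,
                                                vm = 0.01, vs = 1))
  expect_equal(cond$threshold_l, 1.25e5)
  # environmental variance relaxes the condition
  p <- model_params(ne = 1, u = 0.001, vm = 0.01, vs = 1, ve = 0.5)
  expect_true(finite_optimum_condition(p)$finite)
  p <- model_params(ne = 1, u = 0.001, vm = 0.01, vs = 1, ve = 0)
  expect_false(finite_optimum_condition(p)$finite)
})

test_that("the analytic optimizer matches numeric maximization", {
  p <- model_params(ne = 1, u = 0.01, vm = 0.01, vs = 1)
  opt <- optimal_ne(p)
  expect_true(opt$finite)
  expect_equal(opt$ne_star, (1 + sqrt(8)) / 0.07, tolerance = 1e-12)
  expect_equal(opt$ne_star, optimal_ne_numeric(p), tolerance = 1e-6)
  # no finite optimum when the condition fails
  opt <- optimal_ne(model_params(ne = 1, u = 0.001, vm = 0.01, vs = 1))
  expect_false(opt$finite)
  expect_true(is.na(opt$ne_star))
  # environmental variance can re-open the finite optimum
  opt <- optimal_ne(model_params(ne = 1, u = 0.001, vm = 0.01, vs = 1,
                                 ve = 0.5))
  expect_true(opt$finite)
})

test_that("expected mean fitness peaks at ne_star or is monotone, per the condition", {
  ne_grid <- 10^seq(0, 8, length.out = 120)
  for (u in c(0.02, 0.001)) {
    p1 <- model_params(ne = 1, u = u, vm = 0.01, vs = 1)
    w <- expected_mean_fitness(model_params(ne = ne_grid, u = u, vm = 0.01,
                                            vs = 1))
    opt <- optimal_ne(p1)
    if (opt$finite) {
      wstar <- expected_mean_fitness(dplyr::mutate(p1, ne = opt$ne_star))
      expect_true(all(wstar >= w))
    } else {
      expect_true(all(diff(w) >= 0))
    }
  }
})

test_that("environmental variance is equivalent to widening the fitness function", {
  a <- expected_mean_fitness(model_params(ne = 500, u = 0.01, vm = 1e-3,
                                          vs = 1, ve = 0.7))
  b <- expected_mean_fitness(model_params(ne = 500, u = 0.01, vm = 1e-3,
                                          vs = 1.7, ve = 0))
  expect_identical(a, b)
})

test_that("expected mean fitness strictly decreases with the mutation rate", {
  us <- seq(0, 0.2, length.out = 50)
  for (ne in c(50, 5000)) {
    w <- expected_mean_fitness(model_params(ne = ne, u = us, vm = 1e-3,
                                            vs = 1))
    expect_true(all(diff(w) < 0))
  }
})

test_that("all predictions assemble into one tidy table", {
  out <- model_params(ne = c(10, 100, 1000), u = 0.01, vm = 0.01) |>
    predict_fitness()
  expect_equal(nrow(out), 3)
  expect_equal(out$load, 1 - out$expected_wbar)
  expect_equal(out$pbar_var, 1 / (2 * c(10, 100, 1000)))
  expect_true(all(out$finite))
  expect_equal(unique(out$ne_star), (1 + sqrt(8)) / 0.07, tolerance = 1e-12)
})
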