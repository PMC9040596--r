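test_that("inoculum sampling is a seeded multinomial draw", {
  pool <- tiny_pool()
  a <- sample_inoculum(pool, n_cells = 2e5, seed = 11)
  b <- sample_inoculum(pool, n_cells = 2e5, seed = 11)
  expect_identical(a, b)
  expect_equal(sum(a$count), 2e5)
  # all mass on one taxon
  one <- sample_inoculum(taxon_pool("x", 1), n_cells = 2e5, seed = 1)
  expect_equal(one$count, 2e5)
})

test_that("rare taxa drop out of finite inocula at the binomial zero-class rate", {
  # P(count = 0) for rel abundance 1e-5 in 2e5 cells is (1 - 1e-5)^2e5
  p0 <- (1 - 1e-5)^2e5
  pool <- taxon_pool(c("rare", "rest"), c(1e-5, 1 - 1e-5))
  withr::with_seed(202, {
    draws <- rmultinom(10000, size = 2e5, prob = pool$rel_abundance)
  })
  expect_equal(mean(draws[1, ] == 0), p0, tolerance = 0.01 / p0)
  # the package draw follows the same law: same seed, same multinomial
  withr::with_seed(303, direct <- rmultinom(1, 2e5, pool$rel_abundance))
  expect_equal(sample_inoculum(pool, 2e5, seed = 303)$count,
               as.vector(direct))
})

test_that("single-taxon batch growth hits the stoichiometric closed form", {
  # all carbon consumed: N_final = N0 + Y * S0 / c_cell, independent of
  # mu and K_s
  params <- growth_params(S0 = 2e-4, Y = 0.2, c_cell = 2e-13)
  for (mu in c(0.05, 0.4, 0.8)) {
    pool <- taxon_pool("x", 1, growth_rate = mu)
    inoc <- tibble::tibble(taxon_id = "x", count = 2e5)
    sim <- simulate_batch(inoc, pool, params)
    expect_equal(sum(sim$state$n_final), 2e5 + 0.2 * 2e-4 / 2e-13,
                 tolerance = 1e-3)
  }
})

test_that("no substrate means no growth; empty taxa stay empty", {
  pool <- tiny_pool()
  inoc <- tibble::tibble(taxon_id = c("a", "b", "c"), count = c(100, 0, 50))
  sim0 <- simulate_batch(inoc, pool, growth_params(S0 = 0))
  expect_equal(sim0$state$n_final, c(100, 0, 50))
  sim <- simulate_batch(inoc, pool, growth_params())
  expect_equal(sim$state$n_final[2], 0)
  expect_true(all(sim$state$n_final >= sim$state$n0))
})

test_that("mass balance holds on random parameter draws", {
  withr::with_seed(77, {
    for (i in 1:8) {
      k <- sample(2:5, 1)
      pool <- taxon_pool(paste0("t", 1:k),
                         {p <- runif(k); p / sum(p)},
                         growth_rate = runif(k, 0.05, 0.9))
      params <- growth_params(S0 = 10^runif(1, -5, -3),
                              Y = runif(1, 0.1, 0.5),
                              c_cell = 10^runif(1, -13.5, -12.5))
      inoc <- tibble::tibble(taxon_id = pool$taxon_id,
                             count = sample(1e3:1e5, k))
      sim <- simulate_batch(inoc, pool, params)
      # (sum N_final - sum N0) * c_cell / Y == consumed carbon, 0.1% rel
      expect_lt(sim$mass_balance_error, 1e-3)
      expect_true(all(sim$state$n_final >= sim$state$n0))
      expect_true(sim$substrate >= 0 && sim$substrate <= params$S0)
    }
  })
})

test_that("adaptive integration agrees with a fixed-step Euler oracle", {
  params <- growth_params(S0 = 2e-5, Y = 0.2, c_cell = 2e-13)
  cases <- list(
    list(mu = c(0.8, 0.1), n0 = c(5e4, 5e4)),
    list(mu = c(0.55, 0.25, 0.8, 0.6, 0.35), n0 = c(2e4, 2e4, 2e4, 2e4, 2e4)),
    list(mu = 0.3, n0 = 1e5)
  )
  for (cs in cases) {
    k <- length(cs$mu)
    pool <- taxon_pool(paste0("t", 1:k), rep(1 / k, k),
                       growth_rate = cs$mu)
    inoc <- tibble::tibble(taxon_id = pool$taxon_id, count = cs$n0)
    sim <- simulate_batch(inoc, pool, params)
    oracle <- euler_batch(cs$n0, cs$mu, params)
    expect_equal(sim$state$n_final, oracle$N, tolerance = 1e-3)
  }
})

test_that("faster growers take larger final shares; equal rates preserve shares", {
  params <- growth_params()
  pool_neq <- taxon_pool(c("fast", "slow"), c(0.5, 0.5),
                         growth_rate = c(0.8, 0.1))
  inoc <- tibble::tibble(taxon_id = c("fast", "slow"), count = c(1e5, 1e5))
  sim <- simulate_batch(inoc, pool_neq, params)
  shares <- sim$state$n_final / sum(sim$state$n_final)
  expect_gt(shares[1], shares[2])
  pool_eq <- taxon_pool(c("x", "y"), c(0.5, 0.5),
                        growth_rate = c(0.3, 0.3))
  inoc2 <- tibble::tibble(taxon_id = c("x", "y"), count = c(1.5e5, 0.5e5))
  sim2 <- simulate_batch(inoc2, pool_eq, params)
  shares2 <- sim2$state$n_final / sum(sim2$state$n_final)
  expect_equal(shares2, c(0.75, 0.25), tolerance = 1e-3)
})

test_that("total final size is non-decreasing in the carbon pool", {
  pool <- tiny_pool()
  inoc <- sample_inoculum(pool, 1e5, seed = 5)
  totals <- vapply(c(0, 5e-5, 1e-4, 2e-4), function(S0) {
    sum(simulate_batch(inoc, pool, growth_params(S0 = S0))$state$n_final)
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("sequencing subsample follows multinomial law and is seeded", {
  comm <- tibble::tibble(taxon_id = c("A", "B"), count = c(1.8e8, 2e7))
  sub <- subsample_counts(comm, depth = 2e5, seed = 9)
  expect_equal(sum(sub$count), 2e5)
  # E[B] = 2e4, binomial SD ~ 134; a seeded draw sits within 3 SD
  expect_lt(abs(sub$count[2] - 2e4), 3 * sqrt(2e5 * 0.1 * 0.9))
  expect_identical(sub, subsample_counts(comm, depth = 2e5, seed = 9))
  # exact single-taxon community size
  one <- subsample_counts(tibble::tibble(taxon_id = "A", count = 500),
                          depth = 500, seed = 1)
  expect_equal(one$count, 500)
  expect_error(subsample_counts(comm, depth = 1e9), "exceeds")
})

test_that("replicate ensembles are reproducible and keep zero-draw taxa at zero", {
  pool <- taxon_pool(c("dom", "mid", "rare"), c(0.98, 0.0199, 1e-4))
  pool <- assign_growth_rates(pool)
  pool <- set_focal_rates(pool, "rare", 0.8)
  params <- growth_params(S0 = 2e-6)
  e1 <- run_replicate_ensemble(pool, params, n_replicates = 4,
                               n_cells = 2e3, depth = 2e3, seeds = 31)
  e2 <- run_replicate_ensemble(pool, params, n_replicates = 4,
                               n_cells = 2e3, depth = 2e3, seeds = 31)
  expect_identical(e1$results, e2$results)
  res <- tidy(e1)
  drawn_zero <- res[res$inoc_count == 0, ]
  expect_true(all(drawn_zero$final_count == 0))
  expect_true(all(drawn_zero$reads == 0))
  expect_equal(nrow(glance(e1)), 4)
  expect_error(
    run_replicate_ensemble(pool, params, n_replicates = 3, seeds = 1:2),
    "seed")
})
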