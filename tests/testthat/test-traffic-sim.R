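test_that("alpha = 0 gives an empty lattice in simulation and oracle", {
  prof <- make_profile(c(10, 10, 10))
  s <- simulate_steady_state(prof, 0, quick_config())
  expect_equal(s$J, 0)
  expect_equal(s$rho, 0)
  ex <- exact_steady_state(prof, 0, quick_config())
  expect_equal(ex$J, 0)
  expect_equal(ex$rho, 0)
})

test_that("single-site current matches the renewal closed form", {
  alpha <- 1; k <- 10; beta <- 35
  cfg <- sim_config(beta = beta, footprint = 1, burn_in_time = 200,
                    measure_time = 6000, sample_interval = 0.5, seed = 7)
  J_expected <- single_site_J(alpha, k, beta)  # 1/(1/1 + 1/10 + 1/35)
  ex <- exact_steady_state(make_profile(k), alpha, cfg)
  expect_equal(ex$J, J_expected, tolerance = 1e-10)
  s <- simulate_steady_state(make_profile(k), alpha, cfg)
  expect_lt(abs(s$J - J_expected), 3 * s$J_stderr)
  # on one codon gamma never fires: capture is followed directly by
  # termination, so gamma must not affect the exact current
  cfg2 <- cfg; cfg2$gamma <- 1
  expect_equal(exact_steady_state(make_profile(k), alpha, cfg2)$J,
               J_expected, tolerance = 1e-10)
})

test_that("simulator agrees with the master-equation oracle (property)", {
  for (i in 1:6) {
    draw <- withr::with_seed(100 + i, {
      L <- sample(2:5, 1)
      list(L = L, ell = sample(1:2, 1), k = runif(L, 0.5, 30),
           alpha = runif(1, 0.1, 2), gamma = runif(1, 2, 35))
    })
    cfg <- sim_config(gamma = draw$gamma, footprint = draw$ell,
                      burn_in_time = 200, measure_time = 3000,
                      sample_interval = 0.5, seed = 200 + i)
    prof <- make_profile(draw$k)
    ex <- exact_steady_state(prof, draw$alpha, cfg)
    s <- simulate_steady_state(prof, draw$alpha, cfg)
    expect_lt(abs(s$J - ex$J), 3.5 * s$J_stderr)
    expect_lt(abs(s$rho - ex$rho), 3.5 * s$rho_stderr)
  }
})

test_that("flux is conserved: entries per second equal exits", {
  cfg <- quick_config()
  s <- simulate_steady_state(make_profile(rep(10, 20)), 0.8, cfg)
  # over a finite window entries and exits differ by at most the number
  # of ribosomes resident on the lattice (~ L/footprint)
  expect_lt(abs(s$init_rate - s$J) * s$simulated_time, 20 / cfg$footprint + 1)
  ex <- exact_steady_state(make_profile(c(5, 9, 14)), 0.7, quick_config())
  expect_equal(ex$entry_flux, ex$J, tolerance = 1e-10)
})

test_that("exclusion caps the density at 1/footprint", {
  for (ell in c(2L, 3L)) {
    cfg <- sim_config(footprint = ell, burn_in_time = 100,
                      measure_time = 1000, sample_interval = 0.5, seed = 3)
    s <- simulate_steady_state(make_profile(rep(30, 12)), 50, cfg)
    expect_lte(s$rho, 1 / ell + 1e-12)
    expect_gt(s$rho, 0)
  }
})

test_that("density increases with initiation rate (exact oracle)", {
  prof <- make_profile(rep(8, 4))
  cfg <- sim_config(footprint = 2, burn_in_time = 0, measure_time = 1)
  rho <- vapply(c(0.1, 0.5, 2, 10), function(a)
    exact_steady_state(prof, a, cfg)$rho, 0)
  expect_true(all(diff(rho) > 0))
})

test_that("runs are reproducible from the seed and respond to it", {
  prof <- make_profile(rep(10, 15))
  a <- simulate_steady_state(prof, 0.5, quick_config())
  b <- simulate_steady_state(prof, 0.5, quick_config())
  expect_identical(a$J, b$J)
  expect_identical(a$rho, b$rho)
  c <- simulate_steady_state(prof, 0.5, quick_config(seed = 2))
  expect_false(identical(a$J, c$J))
})

test_that("invalid inputs are rejected", {
  prof <- make_profile(rep(10, 5))
  expect_error(simulate_steady_state(prof, -1, quick_config()), ">= 0")
  expect_error(sim_config(gamma = 0))
  expect_error(sim_config(n_batches = 1))
  expect_error(exact_steady_state(make_profile(rep(10, 40)), 1,
                                  quick_config(), state_cap = 100),
               "state")
})

test_that("tRNA retention separates the two-state model from plain TASEP", {
  # At high initiation the lattice is crowded and blocked ribosomes are
  # common. In the two-state model a blocked ribosome keeps its captured
  # tRNA and hops at the fast rate gamma once space opens; the collapsed
  # one-state comparator restarts the full capture+hop step, so its
  # current is measurably lower.
  k <- rep(10, 60)
  k[28:36] <- 3  # moderate mid-lattice bottleneck
  prof <- make_profile(k)
  cfg <- sim_config(burn_in_time = 300, measure_time = 8000,
                    sample_interval = 1, seed = 11)
  cfg1 <- cfg; cfg1$one_state <- TRUE
  two <- simulate_steady_state(prof, 2, cfg)
  one <- simulate_steady_state(prof, 2, cfg1)
  z <- (two$J - one$J) / sqrt(two$J_stderr^2 + one$J_stderr^2)
  expect_gt(z, 3)
  # at very low initiation collisions are rare and the models agree
  two_lo <- simulate_steady_state(prof, 0.02, cfg)
  one_lo <- simulate_steady_state(prof, 0.02, cfg1)
  z_lo <- abs(two_lo$J - one_lo$J) /
    sqrt(two_lo$J_stderr^2 + one_lo$J_stderr^2)
  expect_lt(z_lo, 3)
})
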