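test_that("identical (model, plan, seed) gives identical output bit-for-bit", {
  plan <- simulation_plan(50, seed = 99)
  expect_identical(simulate_birth_death(constant_h_chain(5), plan),
                   simulate_birth_death(constant_h_chain(5), plan))
  net <- example2_network(box = 20L)
  expect_identical(simulate_network(net, plan), simulate_network(net, plan))
  ms <- multistep_cycle_model(5, 5, 0.5)
  expect_identical(simulate_multistep_cycle(ms, plan),
                   simulate_multistep_cycle(ms, plan))
  tg <- telegraph_model(0.5, 0.5, 10, 0, 1)
  expect_identical(simulate_telegraph(tg, plan), simulate_telegraph(tg, plan))
})

test_that("birth-death SSA reproduces the exact stationary law", {
  x <- simulate_birth_death(constant_h_chain(5), simulation_plan(1e4, seed = 3))
  d <- stationary_birth_death(constant_h_chain(5))
  n_top <- max(d$states)
  expect_lt(tv_distance(empirical_pmf(x, n_top),
                        c(d$probabilities, numeric(n_top + 1 - length(d$probabilities)))),
            0.03)
  # sample VMR inside the 99% Gamma null band around 1
  ci <- vmr_null_interval(length(x), 0.01)
  v <- sample_vmr(x)$vmr
  expect_gt(v, ci[1]); expect_lt(v, ci[2])

  expect_equal(simulate_birth_death(birth_death_chain(function(n) 0, function(n) 1),
                                    simulation_plan(20, seed = 1)),
               rep(0L, 20))
})

test_that("linear autoregulation shifts the simulated VMR as the solver predicts", {
  x <- simulate_birth_death(linear_autoreg_chain(2, 1, 2),
                            simulation_plan(5000, seed = 13))
  expect_equal(sample_vmr(x)$vmr, 2, tolerance = 0.12)
  y <- simulate_birth_death(linear_autoreg_chain(18, -3, 3),
                            simulation_plan(5000, seed = 13))
  expect_equal(sample_vmr(y)$vmr, 0.5, tolerance = 0.08)
})

test_that("network SSA matches exact joint solves", {
  # independent genes: VMR ~ 1 each
  net <- network_chain(list(function(n) 3, function(n) 3),
                       list(function(n) 1, function(n) 1),
                       box = c(25L, 25L), init = c(0L, 0L))
  xy <- simulate_network(net, simulation_plan(4000, seed = 5))
  expect_equal(sample_vmr(xy[, 1])$vmr, 1, tolerance = 0.1)
  expect_equal(sample_vmr(xy[, 2])$vmr, 1, tolerance = 0.1)

  # the indicator-gated pair: sample VMR near 2e/(4e-1) for both genes
  ex2 <- simulate_network(example2_network(box = 20L),
                          simulation_plan(5000, seed = 17, burn_in = 50))
  expect_equal(sample_vmr(ex2[, 1])$vmr, 0.5506, tolerance = 0.12)
  expect_equal(sample_vmr(ex2[, 2])$vmr, 0.5506, tolerance = 0.12)

  # cascade child: super-Poissonian, consistent with the exact marginal
  casc <- cascade_network(parent_h = 4, a = 1, b = 1)
  xy2 <- simulate_network(casc, simulation_plan(4000, seed = 29))
  exact <- marginal_vmr(stationary_network(casc), 2)
  expect_gt(sample_vmr(xy2[, 2])$vmr, 1)
  expect_equal(sample_vmr(xy2[, 2])$vmr, exact, tolerance = 0.2 * exact)
})

test_that("multi-step cycle: k = 1 is Poisson, many stages are sub-Poissonian", {
  pois <- simulate_multistep_cycle(multistep_cycle_model(1, 1, 0.01),
                                   simulation_plan(400, seed = 7))
  expect_equal(mean(pois), 100, tolerance = 0.05)
  expect_equal(sample_vmr(pois)$vmr, 1, tolerance = 0.25)

  conc <- simulate_multistep_cycle(multistep_cycle_model(20, 20, 0.1),
                                   simulation_plan(1500, seed = 7))
  expect_equal(mean(conc), 10, tolerance = 0.15)
  expect_lt(sample_vmr(conc)$vmr, 0.8)  # VMR < 1 with no autoregulation
})

test_that("telegraph bursting agrees with closed form and the exact solver", {
  md <- telegraph_model(k_on = 0.1, k_off = 0.1, rho_on = 20, rho_off = 0, deg = 1)
  fano <- telegraph_fano(md)
  expect_equal(fano, 1 + 20 * 0.1 / (0.2 * 1.2))

  # independent exact route: encode the gene state as a 0/1 species
  net <- network_chain(
    f = list(function(n) if (n[1] == 1L) md$k_on else 0,
             function(n) if (n[1] == 1L) md$rho_on else md$rho_off),
    g = list(function(n) md$k_off, function(n) md$deg),
    box = c(1L, 120L), init = c(0L, 0L))
  exact <- marginal_vmr(stationary_network(net), 2)
  expect_equal(exact, fano, tolerance = 1e-6)

  x <- simulate_telegraph(md, simulation_plan(3000, seed = 47, burn_in = 100))
  expect_gt(sample_vmr(x)$vmr, 4)  # decisively super-Poissonian
  expect_equal(sample_vmr(x)$vmr, fano, tolerance = 0.3 * fano)

  # state-independent transcription reduces to a Poisson chain
  flat <- simulate_telegraph(telegraph_model(0.5, 0.5, 8, 8, 1),
                             simulation_plan(2000, seed = 53))
  expect_equal(sample_vmr(flat)$vmr, 1, tolerance = 0.15)
  stuck_on <- simulate_telegraph(telegraph_model(1, 0, 8, 0, 1),
                                 simulation_plan(2000, seed = 59),
                                 init_state = 1L)
  expect_equal(mean(stuck_on), 8, tolerance = 0.1)
  expect_equal(sample_vmr(stuck_on)$vmr, 1, tolerance = 0.15)
})

test_that("doubling the burn-in leaves the sampled VMR statistically unchanged", {
  n <- 2000
  a <- simulate_birth_death(constant_h_chain(5),
                            simulation_plan(n, burn_in = 20, seed = 61))
  b <- simulate_birth_death(constant_h_chain(5),
                            simulation_plan(n, burn_in = 40, seed = 62))
  se <- sqrt(2 / (n - 1))  # Gamma-null sd of the sample VMR
  expect_lt(abs(sample_vmr(a)$vmr - sample_vmr(b)$vmr), 2 * sqrt(2) * se)
})

test_that("runaway models hit the safety cap with a clear error", {
  bad <- birth_death_chain(function(n) 3 * n, function(n) 1)
  expect_error(
    simulate_birth_death(bad, simulation_plan(3, burn_in = 50, seed = 2,
                                              state_cap = 2000L)),
    "safety cap")
})
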