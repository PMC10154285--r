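test_that("relative growth rates follow f/g with the documented edge cases", {
  ch <- birth_death_chain(f = rep(5, 10), g = rep(1, 10))
  expect_equal(relative_growth_rates(ch), rep(5, 10))

  ex1 <- linear_autoreg_chain(k = 2, b = 1, c = 2)
  expect_equal(relative_growth_rates(ex1, n_upper = 3), c(1, 1.5, 2))

  zero <- birth_death_chain(f = rep(0, 5), g = rep(1, 5))
  expect_equal(relative_growth_rates(zero), rep(0, 5))

  # 0/0 is treated as 0 with a warning; positive f over g <= 0 is invalid
  oo <- birth_death_chain(f = c(2, 0), g = c(1, 0))
  expect_warning(h <- relative_growth_rates(oo), "0/0")
  expect_equal(h, c(2, 0))
  bad <- birth_death_chain(f = c(2, 2), g = c(1, 0))
  expect_error(relative_growth_rates(bad), class = "fanoreg_invalid_model")
})

test_that("rate-level classification distinguishes none/positive/negative/mixed", {
  expect_identical(classify_rate_autoregulation(constant_h_chain(5)), "none")
  expect_identical(classify_rate_autoregulation(linear_autoreg_chain(2, 1, 2)),
                   "positive")
  expect_identical(classify_rate_autoregulation(linear_autoreg_chain(9, -1, 2)),
                   "negative")
  mixed <- birth_death_chain(f = c(1, 2, 1), g = rep(1, 3))
  expect_identical(classify_rate_autoregulation(mixed), "mixed")
  one_state <- birth_death_chain(f = 1, g = 1)
  expect_error(classify_rate_autoregulation(one_state),
               class = "fanoreg_insufficient_states")
})

test_that("constant h gives the Poisson law exactly (product-form recursion)", {
  for (h in c(0.5, 5, 40)) {
    d <- stationary_birth_death(constant_h_chain(h))
    expect_lt(tv_distance(d$probabilities, dpois(d$states, h)), 1e-10)
    m <- distribution_moments(d)
    expect_equal(m$mean, h, tolerance = 1e-9)
    expect_equal(as.numeric(m$vmr), 1, tolerance = 1e-8)
  }
})

test_that("degenerate and divergent chains are handled", {
  d0 <- stationary_birth_death(birth_death_chain(f = function(n) 0,
                                                 g = function(n) 1))
  expect_equal(d0$probabilities, 1)
  expect_equal(d0$states, 0)
  expect_identical(attr(distribution_moments(d0)$vmr, "undefined"), TRUE)

  # h_n / n does not decay: no stationary law within the cap
  runaway <- birth_death_chain(f = function(n) 3 * n, g = function(n) 1)
  expect_error(stationary_birth_death(runaway, max_states = 2000),
               class = "fanoreg_truncation_error")
})

test_that("stationary distributions are normalised and satisfy detailed balance", {
  set.seed(11)
  for (rep in 1:10) {
    ch <- random_monotone_chain(sample(c(-1, 1), 1L))
    d <- stationary_birth_death(ch)
    expect_lt(abs(sum(d$probabilities) - 1), 1e-10)
    n <- d$states[-1L]
    flux_up <- d$probabilities[n] * ch$f(n)          # P_{n-1} f_n
    flux_dn <- d$probabilities[n + 1L] * ch$g(n) * n # P_n g_n n
    expect_lt(max(abs(flux_up - flux_dn)), 1e-12 * max(flux_up))
  }
})

test_that("Example-1 linear family matches VMR = 1 + b/(c-b) and mean k/(c-b)", {
  for (par in list(c(2, 1, 2), c(6, -2, 3), c(10, 0, 2), c(3, 0.5, 1),
                   c(18, -3, 3))) {
    d <- stationary_birth_death(linear_autoreg_chain(par[1], par[2], par[3]))
    m <- distribution_moments(d)
    expect_equal(as.numeric(m$vmr), 1 + par[2] / (par[3] - par[2]),
                 tolerance = 1e-8)
    expect_equal(m$mean, par[1] / (par[3] - par[2]), tolerance = 1e-8)
  }
})

test_that("monotone-h chains respect the dispersion bounds (equality iff constant)", {
  set.seed(7)
  for (rep in 1:40) {
    dir <- sample(c(-1, 1), 1L)
    ch <- random_monotone_chain(dir)
    v <- as.numeric(distribution_moments(stationary_birth_death(ch))$vmr)
    if (dir > 0) expect_gte(v, 1 - 1e-8) else expect_lte(v, 1 + 1e-8)
  }
  # equality holds exactly for constant h, and fails for chains whose h
  # varies where the stationary mass lives
  expect_lt(abs(as.numeric(
    distribution_moments(stationary_birth_death(constant_h_chain(3)))$vmr) - 1),
    1e-8)
  expect_gt(abs(as.numeric(distribution_moments(
    stationary_birth_death(linear_autoreg_chain(4, 0.5, 2)))$vmr) - 1), 1e-8)
})

test_that("distribution_moments handles point masses", {
  pm <- list(states = 0:5, probabilities = c(0, 0, 0, 1, 0, 0))
  m <- distribution_moments(pm)
  expect_equal(m$mean, 3)
  expect_equal(m$var, 0)
  expect_equal(as.numeric(m$vmr), 0)
})
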