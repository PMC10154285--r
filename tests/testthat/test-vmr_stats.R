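test_that("sample VMR uses the unbiased variance and flags degenerate input", {
  r <- sample_vmr(c(1, 2, 3))
  expect_equal(r$mean, 2)
  expect_equal(r$var, 1)
  expect_equal(r$vmr, 0.5)

  expect_equal(sample_vmr(rep(4, 4))$vmr, 0)
  expect_identical(sample_vmr(c(0, 0, 0))$flag, "undefined")
  expect_error(sample_vmr(3), class = "fanoreg_insufficient_data")
  expect_error(sample_vmr(c(-1, 2)), class = "fanoreg_data_error")
})

test_that("Gamma null interval brackets 1, shrinks with n, and inverts the cdf", {
  for (n in c(10, 101, 5000)) {
    ci <- vmr_null_interval(n)
    expect_lt(ci[1], 1); expect_gt(ci[2], 1)
  }
  w <- vapply(c(20, 100, 1000, 10000),
              function(n) diff(vmr_null_interval(n)), 0)
  expect_true(all(diff(w) < 0))

  # oracle: invert the regularized incomplete gamma cdf by bisection
  n <- 101; shape <- 50; scale <- 0.02
  inv <- function(p) uniroot(function(x) pgamma(x, shape, scale = scale) - p,
                             c(1e-8, 10), tol = 1e-12)$root
  ci <- vmr_null_interval(101, 0.05)
  expect_equal(ci, c(inv(0.025), inv(0.975)), tolerance = 1e-9)
  # Wilson-Hilferty cube-root normal approximation as a sanity cross-check
  wh <- function(p) shape * (1 - 1 / (9 * shape) +
                             qnorm(p) / (3 * sqrt(shape)))^3 * scale
  expect_equal(ci[1], wh(0.025), tolerance = 5e-3)
  expect_equal(ci[2], wh(0.975), tolerance = 5e-3)

  expect_error(vmr_null_interval(100, 1.2), class = "fanoreg_parameter_error")
  expect_error(vmr_null_interval(1), class = "fanoreg_parameter_error")
})

test_that("vmr_test flags clear departures and stays quiet under the null", {
  expect_identical(vmr_test(rep(5, 100))$flag, "significantly_below_1")

  set.seed(23)
  over <- rnbinom(500, size = 2.5, mu = 10)  # Fano = 1 + mu/size = 5
  expect_identical(vmr_test(over)$flag, "significantly_above_1")
  expect_lt(vmr_test(over)$p_value, 1e-6)

  rej <- vapply(1:400, function(i) {
    vmr_test(rpois(200, 10))$flag != "not_significant"
  }, TRUE)
  expect_lt(mean(rej), 0.09)  # ~0.05 expected; generous Monte-Carlo band

  expect_warning(vmr_test(rpois(10, 5)), "asymptotic")
  one_sided <- vmr_test(rep(5, 100), alternative = "less")
  expect_identical(one_sided$flag, "significantly_below_1")
})

test_that("mixture VMR follows exact moment arithmetic and the >= 1 theorem", {
  expect_equal(mixture_vmr(1, 7, 2.3), 2.3)
  expect_equal(mixture_vmr(c(.5, .5), c(4, 4), c(1, 1)), 1)

  # two Poisson components, means 2 and 10: E=6, E[X^2]=58, var=22
  v <- mixture_vmr(c(.5, .5), c(2, 10), c(1, 1))
  expect_equal(v, 22 / 6)
  expect_equal(v, 1 + (2 - 10)^2 / (2 * (2 + 10)))  # printed closed form

  set.seed(31)
  for (rep in 1:200) {
    k <- sample(2:5, 1L)
    w <- runif(k); w <- w / sum(w)
    mu <- runif(k, 0.5, 20)
    vm <- 1 + rexp(k)   # all components at or above Poisson dispersion
    expect_gte(mixture_vmr(w, mu, vm), 1 - 1e-12)
  }

  expect_error(mixture_vmr(c(.5, .4), c(1, 2), c(1, 1)),
               class = "fanoreg_parameter_error")
})

test_that("intrinsic + extrinsic components reproduce the pooled population VMR", {
  one <- decompose_vmr(list(c(1, 2, 3, 7)))
  expect_equal(one$vmr_ext, 0)
  expect_equal(one$vmr_int, pop_vmr(c(1, 2, 3, 7)))

  consts <- decompose_vmr(list(rep(2, 5), rep(9, 3)))
  expect_equal(consts$vmr_int, 0)
  expect_gt(consts$vmr_ext, 0)

  set.seed(41)
  for (rep in 1:25) {
    groups <- lapply(seq_len(sample(2:5, 1L)),
                     function(i) rpois(sample(3:30, 1L), runif(1, 1, 20)))
    dec <- decompose_vmr(groups)
    expect_equal(dec$vmr_int + dec$vmr_ext, pop_vmr(unlist(groups)),
                 tolerance = 1e-12)
  }

  expect_error(decompose_vmr(list(numeric(0))), class = "fanoreg_data_error")
})
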