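test_that("inner-filter correction matches its closed form and rejects bad input", {
  expect_equal(correct_inner_filter(5.0, 0, 0), 5.0)
  expect_equal(correct_inner_filter(1.0, 1.0, 1.0), 10.0)
  expect_equal(correct_inner_filter(2.0, 0.1, 0.1), 2 * 10^0.1)
  # corrected intensity never below observed for non-negative absorbance
  expect_true(all(correct_inner_filter(runif(20, 0.1, 5),
                                       runif(20, 0, 2), runif(20, 0, 2)) >=
                    0.1))
  expect_error(correct_inner_filter(-1, 0, 0))
  expect_error(correct_inner_filter(1, -0.1, 0))
})

test_that("decay model evaluates the exponential sum pointwise", {
  m1 <- multiexp_model(1, 10)
  expect_equal(decay_model(m1, 0), 1.0)
  expect_equal(decay_model(m1, 10), exp(-1))
  m2 <- multiexp_model(c(1, 1), c(2, 4))
  expect_equal(decay_model(m2, 4), exp(-2) + exp(-1))
  expect_equal(decay_model(m2, 0), 2)  # sum of amplitudes at t = 0
  expect_error(multiexp_model(1, -1))
  expect_error(multiexp_model(c(1, 1), 1))
})

test_that("average lifetime and fractional contributions follow the intensity weighting", {
  expect_equal(average_lifetime(multiexp_model(3, 5)), 5.0)
  m <- multiexp_model(c(1, 1), c(2, 4))
  expect_equal(average_lifetime(m), 20 / 6)
  expect_equal(fractional_contributions(m), c(1 / 3, 2 / 3))
  expect_equal(fractional_contributions(multiexp_model(7, 3)), 1.0)
  # vanishing-component limit
  expect_equal(average_lifetime(multiexp_model(c(1, 1e-12), c(2, 4))), 2,
               tolerance = 1e-9)
})

test_that("fractional contributions sum to 1 and <tau> is bounded by component lifetimes", {
  set.seed(42)
  for (i in 1:50) {
    k <- sample(1:3, 1)
    m <- multiexp_model(runif(k, 0.01, 10), runif(k, 0.1, 60))
    expect_equal(sum(fractional_contributions(m)), 1, tolerance = 1e-9)
    tau_bar <- average_lifetime(m)
    expect_gte(tau_bar, min(m$lifetimes) * (1 - 1e-12))
    expect_lte(tau_bar, max(m$lifetimes) * (1 + 1e-12))
  }
})

test_that("two-species intensity-weighted average is the fraction-weighted sum", {
  expect_equal(two_state_average(0.5, 2, 0.5, 12), 7.0)
  expect_equal(two_state_average(1, 2.3, 0, 11.6), 2.3)
  expect_equal(two_state_average(0.9, 2.3, 0.1, 11.6), 3.23)
  expect_error(two_state_average(0.6, 2, 0.6, 12))
})

test_that("reconvolution equals direct convolution and respects the delta-IRF identity", {
  # delta IRF in channel 1: pure decay curve
  t <- seq(0.5, 15.5, by = 1)
  irf <- decay_histogram(t, c(100, rep(0, 15)))
  m <- multiexp_model(1, 5)
  expect_equal(reconvolve(irf, m), decay_model(m, t - t[1]))
  # two equal IRF channels: average of the two shifted decays, checked
  # against an O(n^2) direct convolution on a small toy
  irf2 <- decay_histogram(t, c(50, 50, rep(0, 14)))
  dk <- decay_model(m, t - t[1])
  expect_equal(reconvolve(irf2, m), direct_convolve(c(0.5, 0.5, rep(0, 14)), dk))
  # scatter_fraction = 0 identical to scatter-free
  m0 <- multiexp_model(1, 5, scatter_fraction = 0)
  expect_identical(reconvolve(irf2, m), reconvolve(irf2, m0))
  # mismatched grids rejected
  irf3 <- decay_histogram(t + 0.3, c(100, rep(0, 15)))
  expect_error(reconvolve(irf3, m, times = t))
})

test_that("noiseless reconvolution fit recovers generating parameters", {
  s <- simulate_decay(1, lifetimes = 10, amplitudes = 1, poisson = FALSE)
  f <- fit_decay(s$decay, s$irf, n_components = 1)
  expect_equal(f$model$lifetimes, 10, tolerance = 1e-4)
  s2 <- simulate_decay(1, poisson = FALSE)  # tau = (2.3, 11.6), A 1:1
  f2 <- fit_decay(s2$decay, s2$irf, n_components = 2)
  expect_equal(f2$model$lifetimes, c(2.3, 11.6), tolerance = 1e-4)
  expect_equal(f2$model$amplitudes[1] / f2$model$amplitudes[2], 1,
               tolerance = 1e-3)
})

test_that("fitting two components to single-exponential data is flagged over-parameterized", {
  s <- simulate_decay(7, lifetimes = 8, amplitudes = 1)
  f <- fit_decay(s$decay, s$irf, n_components = 2)
  expect_true(f$overparameterized || min(f$fractional_contributions) < 0.01)
  expect_equal(f$average_lifetime, 8, tolerance = 0.05)
})

test_that("anisotropy follows the G-corrected polarization ratio", {
  expect_equal(anisotropy(3, 3, 2, 2)$r, 0)               # fully depolarized
  expect_equal(anisotropy(2, 1, 5, 5)$r, 0.25)
  expect_equal(anisotropy(1, 1e-12, 1, 1)$r, 1, tolerance = 1e-9)
  expect_equal(anisotropy(2, 1, 3, 6)$g_factor, 0.5)
  expect_error(anisotropy(0, 1, 1, 1))
})
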