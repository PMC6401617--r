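test_that("titration model honors its limits and the half-saturation point", {
  expect_equal(titration_model(5e-4, 0, 1e4, 7.2, 0.05), 7.2)
  # saturation: strong binding, large guest excess
  expect_equal(titration_model(5e-4, 1, 1e8, 7.2, 0.05), 7.25,
               tolerance = 1e-6)
  # half-saturation located by bisection on the exact quadratic
  h <- 5e-4; k <- 1.3e4
  g_half <- local({
    f <- function(g) hg_speciation(h, g, k)$complex - h / 2
    lo <- 0; hi <- 1
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  })
  expect_equal(titration_model(h, g_half, k, 7.2, 0.05), 7.2 + 0.025,
               tolerance = 1e-6)
  # monotone in guest concentration
  g <- seq(0, 2e-3, length.out = 30)
  expect_true(all(diff(titration_model(h, g, k, 7.2, 0.05)) > 0))
  expect_true(all(diff(titration_model(h, g, k, 7.2, -0.05)) < 0))
})

test_that("exact quadratic departs materially from the dilute-host hyperbola when H_t K_a is large", {
  # host depletion of the guest pushes the true bound fraction below the
  # total-guest hyperbola; the gap is material once H_t * K_a >> 0.1
  h <- 5e-3; k <- 1e4  # H_t * K_a = 50, far from dilute
  g <- seq(1e-4, 2e-2, length.out = 20)
  exact <- titration_model(h, g, k, 0, 1)
  dilute <- k * g / (1 + k * g)
  expect_true(all(exact <= dilute + 1e-12))
  expect_gt(max(dilute - exact), 0.05)
  # in the truly dilute regime (H_t * K_a << 0.1) the two coincide
  h2 <- 1e-6
  exact2 <- titration_model(h2, g, k, 0, 1)
  expect_equal(exact2, dilute, tolerance = 1e-3)
})

test_that("noiseless titration round-trip recovers K_a and the limiting shift", {
  d <- simulate_titration(1, sigma_shift = 0)
  f <- fit_titration(attr(d, "host_total_M"), d$guest_total_M, d$shift_ppm)
  expect_equal(f$k_assoc, 1.3e4, tolerance = 1e-4)
  expect_equal(unname(f$delta_max), 0.05, tolerance = 1e-4)
  expect_equal(unname(f$delta_free), 7.5, tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("dimer-host mode halves the effective host concentration", {
  # simulate with the dimer (2.5e-4 M) as the true 1:1 partner, fit with the
  # analytical monomer concentration (5e-4 M) in dimer mode
  d <- simulate_titration(2, h_total = 2.5e-4, sigma_shift = 0)
  f <- fit_titration(5e-4, d$guest_total_M, d$shift_ppm, mode = "dimer")
  expect_equal(f$h_effective, 2.5e-4)
  expect_equal(f$k_assoc, 1.3e4, tolerance = 1e-4)
  # with an explicit K_D the dimer fraction enters the effective host
  f2 <- fit_titration(5e-4, d$guest_total_M, d$shift_ppm, mode = "dimer",
                      k_dim = 4.1e5)
  x <- dimer_speciation(5e-4, 4.1e5)$x_molecule
  expect_equal(f2$h_effective, 5e-4 * x / 2)
})

test_that("global fit shares K_a across resonances", {
  g <- titration_design(2.5e-4, 1.3e4)
  s1 <- titration_model(2.5e-4, g, 1.3e4, 7.5, 0.05)
  s2 <- titration_model(2.5e-4, g, 1.3e4, 3.2, -0.08)
  f <- fit_titration(2.5e-4, g, cbind(shift_ppm_a = s1, shift_ppm_b = s2))
  expect_equal(f$k_assoc, 1.3e4, tolerance = 1e-4)
  expect_equal(unname(f$delta_max), c(0.05, -0.08), tolerance = 1e-4)
})

test_that("under-saturated titrations raise a weak-identifiability warning", {
  g <- seq(0, 2e-5, length.out = 8)  # far below saturation for K = 1e3
  s <- titration_model(5e-4, g, 1e3, 7.5, 0.05)
  expect_warning(fit_titration(5e-4, g, s), "weakly identified")
})

test_that("noisy recovery is unbiased at the few-percent level", {
  ka <- vapply(1:50, function(i) {
    d <- simulate_titration(i, h_total = 2.5e-4, k_assoc = 1.3e4)
    suppressWarnings(
      fit_titration(attr(d, "host_total_M"), d$guest_total_M,
                    d$shift_ppm))$k_assoc
  }, numeric(1))
  expect_lt(abs(median(ka) / 1.3e4 - 1), 0.1)
})
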