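test_that("all generators are bit-reproducible per seed and change with the seed", {
  expect_identical(simulate_decay(3)$decay$counts, simulate_decay(3)$decay$counts)
  expect_false(identical(simulate_decay(3)$decay$counts,
                         simulate_decay(4)$decay$counts))
  expect_identical(simulate_isotherm(3), simulate_isotherm(3))
  expect_false(identical(simulate_isotherm(3)$avg_tau_ns,
                         simulate_isotherm(4)$avg_tau_ns))
  expect_identical(simulate_titration(3), simulate_titration(3))
  expect_identical(simulate_vant_hoff(3), simulate_vant_hoff(3))
  expect_identical(simulate_quench(3, sigma_tau = 0.1),
                   simulate_quench(3, sigma_tau = 0.1))
})

test_that("changing only the seed changes only the noise, not the design", {
  a <- simulate_isotherm(1); b <- simulate_isotherm(2)
  expect_identical(a$conc_M, b$conc_M)
  expect_false(identical(a$avg_tau_ns, b$avg_tau_ns))
  # noiseless outputs are the exact model values regardless of seed
  expect_identical(simulate_isotherm(1, sigma_tau = 0),
                   simulate_isotherm(99, sigma_tau = 0))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123); r1 <- runif(1)
  set.seed(123); invisible(simulate_decay(5)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("noiseless decay simulation is proportional to the reconvolved model", {
  s <- simulate_decay(1, poisson = FALSE)
  mu <- reconvolve(s$irf, s$truth)
  expect_equal(s$decay$counts, mu / max(mu) * 10000, tolerance = 1e-12)
  expect_equal(max(s$decay$counts), 10000)
  expect_equal(s$decay$window_length, 200)
  expect_error(simulate_decay(1, n_channels = 0))
})

test_that("Poisson-sampled channels have variance compatible with their mean", {
  # pool replicate counts per channel across seeds; index-of-dispersion test
  reps <- vapply(1:40, function(i) simulate_decay(i)$decay$counts,
                 numeric(1024))
  keep <- rowMeans(reps) > 50  # channels with enough signal
  disp <- apply(reps[keep, ], 1, function(x) var(x) / mean(x))
  # dispersion ~ chi2_{39}/39 under Poisson; check the pooled mean
  expect_equal(mean(disp), 1, tolerance = 0.1)
  expect_gt(mean(disp > 0.5 & disp < 1.7), 0.95)
})

test_that("simulated vant-hoff data honor the generating thermodynamics", {
  d <- simulate_vant_hoff(1, delta_h = 0, delta_s = 80, noise_cv = 0)
  expect_equal(diff(range(d$K)), 0)  # dH = 0: K constant over T
  d2 <- simulate_vant_hoff(1, delta_h = -10, delta_s = 80, noise_cv = 0)
  expect_true(all(diff(d2$K) < 0))   # exothermic: K falls with T
})

test_that("every generated dataset is accepted by its fit operation unchanged", {
  d <- simulate_isotherm(6)
  expect_s3_class(suppressWarnings(fit_isotherm(d$conc_M, d$avg_tau_ns)),
                  "isotherm_fit")
  t <- simulate_titration(6)
  expect_s3_class(
    suppressWarnings(fit_titration(attr(t, "host_total_M"),
                                   t$guest_total_M, t$shift_ppm)),
    "titration_fit")
  v <- simulate_vant_hoff(6)
  expect_s3_class(fit_vant_hoff(v$temp_C, v$K), "vant_hoff_fit")
  q <- simulate_quench(6, sigma_tau = 0.05)
  expect_s3_class(suppressWarnings(fit_stern_volmer(q$q_conc_M, q$avg_tau_ns)),
                  "stern_volmer_fit")
  s <- simulate_decay(6)
  expect_s3_class(fit_decay(s$decay, s$irf, 2), "decay_fit")
})
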