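test_that("dimer speciation matches the quadratic closed form and its limits", {
  expect_equal(dimer_speciation(1e-4, 0)$x_molecule, 0)
  expect_equal(dimer_speciation(1e-4, 0)$monomer, 1e-4)
  # the 90%-dimer condition: 0.15 mM with K_D = 4.1e5
  sp <- dimer_speciation(1.5e-4, 4.1e5)
  expect_equal(sp$x_molecule, 0.9138, tolerance = 1e-4)
  # species-basis fraction at 0.2 mM, K_D = 2.1e4
  sp2 <- dimer_speciation(2e-4, 2.1e4)
  expect_equal(sp2$x_species, 0.5497, tolerance = 1e-3)
  expect_error(dimer_speciation(-1, 1))
})

test_that("closed-form speciation agrees with a bisection oracle over random cases", {
  set.seed(7)
  for (i in 1:1000) {
    ct <- 10^runif(1, -8, -2)
    kd <- 10^runif(1, 0, 8)
    sp <- dimer_speciation(ct, kd)
    m_oracle <- bisect_monomer(ct, kd)
    expect_equal(sp$monomer, m_oracle, tolerance = 1e-10)
    # mass balance to 1e-12 relative
    expect_lt(abs(sp$monomer + 2 * sp$dimer - ct) / ct, 1e-12)
    # species-basis fraction never exceeds molecule-basis
    expect_lte(sp$x_species, sp$x_molecule + 1e-15)
  }
})

test_that("dimer fractions increase monotonically in concentration and in K_D", {
  ct <- 10^seq(-7, -3, length.out = 40)
  x <- dimer_speciation(ct, 1e5)$x_molecule
  expect_true(all(diff(x) > 0))
  xs <- dimer_speciation(ct, 1e5)$x_species
  expect_true(all(diff(xs) > 0))
  ks <- 10^seq(1, 8, length.out = 30)
  xk <- vapply(ks, function(k) dimer_speciation(1e-4, k)$x_molecule,
               numeric(1))
  expect_true(all(diff(xk) > 0))
})

test_that("1:1 host-guest speciation solves the exact quadratic", {
  c0 <- 1e-3
  sp <- hg_speciation(c0, c0, 1 / c0)
  expect_equal(sp$complex, c0 * (3 - sqrt(5)) / 2, tolerance = 1e-12)
  # saturation limit: K -> inf with excess guest binds all host
  expect_equal(hg_speciation(1e-4, 1e-3, 1e12)$complex, 1e-4,
               tolerance = 1e-6)
  expect_equal(hg_speciation(1e-4, 1e-3, 0)$complex, 0)
  set.seed(11)
  for (i in 1:200) {
    h <- 10^runif(1, -6, -2); g <- 10^runif(1, -6, -2)
    k <- 10^runif(1, 0, 8)
    sp <- hg_speciation(h, g, k)
    expect_equal(sp$complex, bisect_complex(h, g, k), tolerance = 1e-8)
    expect_lt(abs(sp$free_host + sp$complex - h) / h, 1e-12)
    expect_lt(abs(sp$free_guest + sp$complex - g) / g, 1e-12)
    expect_lte(sp$complex, min(h, g) * (1 + 1e-12))
  }
})

test_that("coupled dimer+guest speciation conserves mass and honors its limits", {
  # K_a = 0 reduces exactly to plain dimer speciation
  cs <- coupled_speciation(1.5e-4, 1e-3, 4.1e5, 0)
  sp <- dimer_speciation(1.5e-4, 4.1e5)
  expect_equal(cs$monomer, sp$monomer, tolerance = 1e-10)
  expect_equal(cs$complex, 0)
  # full saturation: huge K_D and K_a with excess guest puts all host in DG
  cs2 <- coupled_speciation(1e-4, 1e-1, 1e10, 1e10)
  expect_equal(cs2$complex, 1e-4 / 2, tolerance = 1e-4)
  # random systems: monomer agrees with a brute-force bisection oracle
  set.seed(13)
  for (i in 1:100) {
    ct <- 10^runif(1, -6, -3); gt <- 10^runif(1, -6, -3)
    kd <- 10^runif(1, 2, 7); ka <- 10^runif(1, 1, 6)
    cs <- coupled_speciation(ct, gt, kd, ka)
    host_bal <- function(m) {
      d <- kd * m^2; g <- gt / (1 + ka * d)
      m + 2 * d + 2 * ka * d * g - ct
    }
    lo <- 0; hi <- ct
    for (j in 1:200) {
      mid <- (lo + hi) / 2
      if (host_bal(mid) > 0) hi <- mid else lo <- mid
    }
    expect_equal(cs$monomer, (lo + hi) / 2, tolerance = 1e-8)
    expect_lt(abs(cs$monomer + 2 * cs$dimer + 2 * cs$complex - ct) / ct,
              1e-10)
    expect_lt(abs(cs$free_guest + cs$complex - gt) / gt, 1e-10)
    expect_true(all(c(cs$monomer, cs$dimer, cs$free_guest, cs$complex) >= 0))
  }
})
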