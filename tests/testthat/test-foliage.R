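test_that("foliar rate matches direct evaluation and vanishes at tau = 0", {
  sp <- kamahi()
  expect_equal(foliar_rate(0, 0, sp, B = 1), 0)
  # at full canopy, production and abscission cancel to within exp(-e)
  expect_equal(foliar_rate(1, 0, sp, B = 1), -exp(-16.6) / 4.53)
  # intake above the one-year mortality threshold forces decline
  I_kill <- 1.01 * mortality_threshold(0.5, sp, B = 1)
  expect_lt(foliar_rate(0.5, I_kill, sp, B = 1), 0)
  expect_error(foliar_rate(1.2, 0, sp, 1), "tau")
  expect_error(foliar_rate(0.5, 0, sp, -1), "B")
})

test_that("intake threshold reproduces the fitted species table values", {
  tab <- read_species_params()
  expect_equal(nrow(tab), 5L)
  got <- vapply(tab$code, function(cd)
    signif(intake_threshold(get_species_params(tab, cd)), 3), numeric(1))
  expect_equal(unname(got), c(0.170, 0.170, 0.216, 0.234, 0.149))
  # threshold is linear in attainable mass
  beitaw <- get_species_params(tab, "BEITAW")
  expect_equal(intake_threshold(beitaw, B = 2),
               2 * intake_threshold(beitaw, B = 1))
  expect_error(species_params("X", a = 4, e = 0.9, f = 1e-5, p_diet = 0.1),
               "exceed 1")
})

test_that("mortality threshold is zero at bare canopy and increasing", {
  sp <- kamahi()
  expect_equal(mortality_threshold(0, sp, B = 1), 0)
  expect_equal(mortality_threshold(1, sp, B = 1), 1 - exp(-16.6) / 4.53,
               tolerance = 1e-12)
  grid <- seq(0.001, 1, length.out = 400)
  v <- mortality_threshold(grid, sp, B = 1)
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 0))
})

test_that("equilibrium canopy fraction agrees with a bisection oracle", {
  sp <- kamahi()
  Ip <- intake_threshold(sp, B = 1)
  # unbrowsed equilibrium is full canopy to within exp(-e)
  tau0 <- equilibrium_tau(sp, B = 1, I = 0)
  expect_lt(abs(tau0 - 1), 1e-6)
  expect_lt(abs(foliar_rate(tau0, 0, sp, 1)), 1e-10)
  # no equilibrium above the intake threshold
  expect_true(is.na(equilibrium_tau(sp, B = 1, I = 1.01 * Ip)))
  # below threshold: root-finder matches independent bisection
  for (frac in c(0.25, 0.5, 0.9)) {
    I <- frac * Ip
    tau_star <- equilibrium_tau(sp, B = 1, I = I)
    expect_lt(abs(foliar_rate(tau_star, I, sp, 1)), 1e-10)
    oracle <- bisect_equilibrium(sp, 1, I, lo = log(sp$e) / sp$e, hi = 1)
    expect_equal(tau_star, oracle, tolerance = 1e-8)
  }
})

test_that("intake above threshold collapses the canopy under integration", {
  sp <- kamahi()
  tr <- integrate_foliage(1, 1.5 * intake_threshold(sp), sp, B = 1,
                          times = seq(0, 50, 1))
  expect_true(any(tr$tau < 1e-3))
})

test_that("one-year integration brackets the mortality threshold", {
  sp <- kamahi()
  for (tau0 in seq(0.2, 1, 0.2)) {
    Im <- mortality_threshold(tau0, sp, B = 1)
    hi <- integrate_foliage(tau0, 1.05 * Im, sp, 1, c(0, 1))$tau[2]
    lo <- integrate_foliage(tau0, 0.50 * Im, sp, 1, c(0, 1))$tau[2]
    # the closed-form threshold slightly underestimates the exact
    # one-year-death intake at high tau; allow that documented margin
    expect_lt(hi, 0.06)
    expect_gt(lo, 0.1)
  }
})

test_that("cover index conversions invert each other on their domain", {
  expect_equal(fci_from_tau(0, 2), 0)
  expect_equal(fci_from_tau(1, 2.303), 1 - exp(-2.303))
  expect_equal(round(fci_from_tau(1, -log(0.1)), 3), 0.9)
  expect_equal(tau_from_fci(0, 1), 0)
  expect_equal(tau_from_fci(0.5, 1), -log(0.5), tolerance = 1e-12)
  # cap engages when observed cover exceeds the site-mean unbrowsed cover
  expect_equal(tau_from_fci(0.95, 1), 1)
  expect_error(tau_from_fci(1, 1), "fci")
  # invertible wherever the implied canopy fraction stays below one
  for (fci in c(0.05, 0.3, 0.62, 0.89)) {
    expect_equal(fci_from_tau(tau_from_fci(fci, 2.6), 2.6), fci,
                 tolerance = 1e-12)
  }
})

test_that("allometric foliar mass follows the power law", {
  expect_equal(attainable_foliage(1), 0.0406)
  expect_equal(attainable_foliage(10), 0.0406 * 10^1.53)
  d <- seq(1, 80, length.out = 100)
  B <- attainable_foliage(d)
  expect_true(all(diff(B) > 0))
  # superlinear: doubling DBH more than doubles foliage
  expect_true(all(attainable_foliage(2 * d) > 2 * B))
  expect_error(attainable_foliage(0), "dbh")
})

test_that("browse-index bins cover the unit interval consistently", {
  bins <- fbi_to_browse_fraction(0:4)
  expect_equal(bins$lower, c(0, 0.01, 0.25, 0.50, 0.75))
  expect_equal(bins$upper, c(0.01, 0.25, 0.50, 0.75, 1))
  expect_equal(bins$midpoint[5], 0.875)
  expect_true(all(bins$omega_midpoint + bins$midpoint == 1))
  # category 0 means under 1% browse, so intact fraction at least 0.99
  expect_gte(bins$omega_midpoint[1], 0.99)
  expect_error(fbi_to_browse_fraction(5), "invalid category")
})

test_that("cover categories bin and unbin consistently", {
  expect_equal(fci_category(c(0, 0.07, 0.1, 0.55, 1)),
               c(0L, 1L, 1L, 6L, 10L))
  expect_equal(fci_category_midpoint(c(0, 1, 10)), c(0, 0.05, 0.95))
  # midpoint lands back in its own category
  for (k in 1:10) expect_equal(fci_category(fci_category_midpoint(k)), k)
  expect_error(fci_category_midpoint(11), "invalid category")
})
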