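test_that("mortality by cover class is zero without intake and monotone", {
  sp <- kamahi()
  fo <- default_forest()
  none <- mortality_by_fci_category(sp, site_browse_params(0, 1, 0.3), fo,
                                    n_dbh_draws = 500, seed = 1)
  expect_true(all(none$mean == 0))
  pa <- site_browse_params(400, 1.5, 0.2)
  m <- mortality_by_fci_category(sp, pa, fo, n_dbh_draws = 4000, seed = 1)
  expect_true(all(m$mean >= 0 & m$mean <= 1))
  # denser canopy, higher mortality threshold, lower risk
  expect_true(all(diff(m$mean) <= 0))
})

test_that("degenerate site collapses the prediction to one tree", {
  sp <- kamahi()
  fo <- site_forest_state(300, log(25), 0, 1.0, 0)
  pa <- site_browse_params(350, 1.5, 0.25)
  m <- mortality_by_fci_category(sp, pa, fo, categories = 6,
                                 n_dbh_draws = 50, seed = 1)
  tau <- tau_from_fci(0.55, 1.0)
  expect_equal(m$mean, tree_mortality(tau, attainable_foliage(25),
                                      sp, pa, fo), tolerance = 1e-12)
})

test_that("DBH marginalisation is converged at the default draw count", {
  sp <- kamahi()
  fo <- default_forest()
  pa <- site_browse_params(400, 1.5, 0.2)
  m1 <- mortality_by_fci_category(sp, pa, fo, n_dbh_draws = 10000,
                                  seed = 1)
  m2 <- mortality_by_fci_category(sp, pa, fo, n_dbh_draws = 10000,
                                  seed = 2)
  expect_lt(max(abs(m1$mean - m2$mean)), 0.01 * max(m1$mean))
})

test_that("site-wide weighting averages the class triples", {
  per <- data.frame(mean = c(0.2, 0.05), lower = c(0.1, 0.01),
                    upper = c(0.4, 0.1))
  expect_equal(sitewide_mortality(per, c(1, 0)),
               c(mean = 0.2, lower = 0.1, upper = 0.4))
  expect_equal(sitewide_mortality(per, c(0.25, 0.75))[["mean"]],
               0.25 * 0.2 + 0.75 * 0.05)
  expect_error(sitewide_mortality(per, c(0.5, 0.6)), "sum to 1")
})

test_that("expected deaths compound annual mortality", {
  expect_equal(expected_deaths(0, 250, 5), 0)
  expect_equal(expected_deaths(1, 250, 5), 250)
  expect_equal(expected_deaths(0.01, 250, 5), 250 * (1 - 0.99^5))
  expect_equal(expected_deaths(0.01, 250, 5, method = "linear"), 12.5)
  # compounding never exceeds the linear approximation
  m <- seq(0, 1, 0.05)
  expect_true(all(expected_deaths(m, 100, 4) <=
                    expected_deaths(m, 100, 4, method = "linear") + 1e-12))
})

test_that("trap-catch conversions reproduce the published densities", {
  expect_equal(tci_to_density(3.88), 0)
  expect_equal(round(tci_to_density(c(47.4, 21.4, 35.4)), 1),
               c(11.0, 4.4, 8.0))
  expect_equal(tci_to_density(2), 0)  # floored below the intercept
  expect_equal(density_to_tci(tci_to_density(30)), 30, tolerance = 1e-12)
  expect_equal(density_to_intake(1, 1), 58.4)
  expect_equal(density_to_intake(0, 0.4), 0)
  expect_equal(density_to_intake(8.94, 1), 522.1, tolerance = 1e-3)
  expect_equal(intake_to_density(58.4, 1), 1)
})

test_that("management curve rises with possum density and finds a goal", {
  sp <- kamahi()
  fo <- default_forest()
  pa <- site_browse_params(400, 1.5, 0.2)
  w <- rep(0.1, 10)
  cur <- mortality_vs_tci_curve(sp, pa, fo, weights = w,
                                tci_grid = seq(0, 50, 5),
                                n_dbh_draws = 2000, seed = 2)
  expect_true(all(diff(cur$curve$mean) >= -1e-12))
  expect_true(all(cur$curve$lower <= cur$curve$mean + 1e-12 &
                    cur$curve$mean <= cur$curve$upper + 1e-12))
  # an always-acceptable threshold returns the top of the grid
  cur1 <- mortality_vs_tci_curve(sp, pa, fo, weights = w,
                                 tci_grid = seq(0, 50, 10), threshold = 1,
                                 n_dbh_draws = 200, seed = 2)
  expect_equal(cur1$tci_goal, 50)
  # a species the herbivore never eats is safe everywhere
  sp0 <- species_params("NONE", 4.53, 16.6, 3.3e-5, p_diet = 0)
  cur0 <- mortality_vs_tci_curve(sp0, pa, fo, weights = w,
                                 tci_grid = seq(0, 50, 10),
                                 n_dbh_draws = 200, seed = 2)
  expect_true(all(cur0$curve$mean == 0))
  expect_equal(cur0$tci_goal, 50)
})

test_that("goal is flagged unattainable when no density qualifies", {
  sp <- kamahi()
  fo <- default_forest()
  pa <- site_browse_params(400, 1.5, 0.2)
  cur <- mortality_vs_tci_curve(sp, pa, fo, weights = rep(0.1, 10),
                                tci_grid = c(20, 30), threshold = 1e-9,
                                n_dbh_draws = 200, seed = 2)
  expect_false(cur$attainable)
  expect_true(is.na(cur$tci_goal))
})
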