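test_that("leaf-area growth rate matches direct evaluation", {
  expect_equal(leaf_area_rate(2, 2, 1.5), 0)
  expect_equal(leaf_area_rate(1, exp(1), 1), 1)
  expect_equal(leaf_area_rate(2.0, 1.5, 2.1), (log(1.5) - log(2)) / 2.1)
  expect_error(leaf_area_rate(0, 1, 1), "excluded record")
})

test_that("consecutive pairs are extracted with bare crowns excluded", {
  obs <- data.frame(
    tree_id = c("a", "a", "a", "b", "b", "c", "c"),
    visit_time = c(0, 2, 5, 0, 2.5, 0, 2),
    fci_category = c(5, 6, 6, 4, 0, 3, 2),
    fbi_category = c(1, 0, 0, 2, 3, 0, 1),
    alive = TRUE)
  pairs <- extract_growth_pairs(obs)
  # b's second visit has a bare crown: that pair is dropped
  expect_equal(nrow(pairs), 3L)
  expect_equal(pairs$dt, c(2, 3, 2))
  expect_equal(pairs$b, c(1, 0, 0))
  expect_equal(pairs$L0[1], -log(1 - 0.45))
  expect_equal(pairs$dLdt,
               (log(pairs$Lt) - log(pairs$L0)) / pairs$dt)
})

test_that("growth regression recovers exact coefficients from clean data", {
  set.seed(1)
  L0 <- exp(rnorm(60, 0, 0.5))
  for (cf in list(c(c0 = 0.1, c1 = -0.2), c(c0 = 0.3, c1 = -0.45))) {
    pairs <- data.frame(tree_id = seq_along(L0), L0 = L0, Lt = NA,
                        dt = 2, b = 0,
                        dLdt = cf["c0"] + cf["c1"] * log(L0))
    # lm warns about the exact fit; that is the point here
    fit <- suppressWarnings(fit_growth_regression(pairs))
    expect_equal(fit$c0, unname(cf["c0"]), tolerance = 1e-10)
    expect_equal(fit$c1, unname(cf["c1"]), tolerance = 1e-10)
    expect_equal(fit$r_b, unname(-cf["c1"]), tolerance = 1e-10)
    expect_equal(fit$L_tilde, unname(exp(-cf["c0"] / cf["c1"])),
                 tolerance = 1e-10)
  }
  # c1 = -0.2, c0 = 0.1 gives the saturating pair (0.2, exp(0.5))
  expect_equal(exp(-0.1 / -0.2), exp(0.5))
})

test_that("regression recovers noisy coefficients within two SE", {
  set.seed(99)
  n <- 500
  L0 <- exp(rnorm(n, 0.2, 0.5))
  pairs <- data.frame(tree_id = 1:n, L0 = L0, Lt = NA, dt = 2, b = 2,
                      dLdt = 0.25 - 0.18 * log(L0) + rnorm(n, 0, 0.05))
  fit <- fit_growth_regression(pairs)
  expect_lt(abs(fit$c0 - 0.25), 2 * fit$c0_se)
  expect_lt(abs(fit$c1 + 0.18), 2 * fit$c1_se)
})

test_that("coefficient draws are deterministic, paired and transformed", {
  fit <- structure(data.frame(b = 0:1, n = 50,
                              c0 = c(0.2, 0.15), c0_se = c(0.01, 0.01),
                              c1 = c(-0.22, -0.2), c1_se = c(0.01, 0.01)),
                   class = c("growth_regression_fit", "data.frame"))
  d1 <- simulate_coefficient_draws(fit, n_draws = 200, seed = 5)
  d2 <- simulate_coefficient_draws(fit, n_draws = 200, seed = 5)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 400L)
  expect_true(all(d1$r > 0))
  # zero SEs collapse every draw onto the point estimates
  fit0 <- fit
  fit0$c0_se <- 0; fit0$c1_se <- 0
  d0 <- simulate_coefficient_draws(fit0, n_draws = 50, seed = 1)
  expect_true(all(d0$r[d0$b == 0] == 0.22))
  expect_true(all(abs(d0$L_tilde[d0$b == 1] - exp(0.15 / 0.2)) < 1e-12))
  # law of large numbers on the growth rate
  dn <- simulate_coefficient_draws(fit, n_draws = 20000, seed = 2)
  expect_equal(mean(dn$r[dn$b == 0]), 0.22, tolerance = 0.001)
})

test_that("species growth fit inverts noiseless saturating data exactly", {
  a_true <- 4.53; e_true <- 16.6
  tau <- c(1, 0.8, 0.5, 0.22, 0.07)
  draws <- data.frame(draw = rep(1:50, each = 5),
                      b = rep(0:4, 50),
                      r = rep((1 - exp(-e_true * tau)) / a_true, 50),
                      L_tilde = rep(1.8 * tau, 50))
  fit <- fit_species_growth(draws)
  expect_equal(fit$a, a_true, tolerance = 1e-4)
  expect_equal(fit$e, e_true, tolerance = 1e-4)
  # relative asymptotes are capped at one by construction
  expect_error(fit_species_growth(draws[draws$b > 2, ]),
               "categories 0-2")
})

test_that("heavier browse lowers the recovered asymptotic leaf area", {
  sp <- kamahi()
  fo <- default_forest(L_mean = 1.8, L_sd = 0.3)
  tr <- ground_truth(sp, site_browse_params(100, 1, 0.3), fo,
                     n_tagged = 1500, visit_years = c(0, 3), seed = 11)
  panel <- generate_growth_panel(tr)
  reg <- fit_growth_regression(extract_growth_pairs(panel))
  expect_true(all(diff(reg$L_tilde) < 0))
})
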