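test_that("plot-survey density scales counts to hectares", {
  sv <- data.frame(plot_id = rep(1:100, each = 3),
                   species_code = "WEIRAC",
                   dbh_cm = rep(c(12, 30, 8), 100))  # one stem under 10 cm
  d <- estimate_density(sv, "WEIRAC", n_plots = 100)
  expect_equal(d, 2 / (pi * 25) * 1e4)
  # 2.5 stems per 5-m plot is about 318 trees/ha
  sv2 <- data.frame(plot_id = rep(1:100, each = 3),
                    species_code = "WEIRAC", dbh_cm = 20)
  sv2 <- sv2[1:250, ]
  expect_equal(round(estimate_density(sv2, "WEIRAC", n_plots = 100)), 318)
  # linear in counts
  expect_equal(estimate_density(rbind(sv2, sv2), "WEIRAC", n_plots = 100),
               2 * estimate_density(sv2, "WEIRAC", n_plots = 100))
  expect_warning(d0 <- estimate_density(sv, "BEITAW", n_plots = 100),
                 "density is 0")
  expect_equal(d0, 0)
})

test_that("lognormal DBH fit recovers its parameters", {
  cfit <- fit_dbh_distribution(rep(25, 10))
  expect_equal(cfit$meanlog, log(25))
  expect_equal(cfit$sdlog, 0)
  set.seed(3)
  x <- rlnorm(1e4, 3.2, 0.4)
  fit <- fit_dbh_distribution(x)
  expect_lt(abs(fit$meanlog - 3.2), 2 * fit$meanlog_se)
  expect_lt(abs(fit$sdlog - 0.4), 2 * fit$sdlog_se)
  expect_equal(fit$mean_dbh, exp(fit$meanlog + fit$sdlog^2 / 2))
  expect_error(fit_dbh_distribution(c(10, 20)), "insufficient data")
})

test_that("leaf-area fit transforms cover and handles saturation", {
  fit <- fit_leaf_area(rep(1 - exp(-1), 8))
  expect_equal(fit$L_s_mean, 1, tolerance = 1e-12)
  expect_equal(fit$L_s_sd, 0)
  expect_warning(fit2 <- fit_leaf_area(c(rep(0.6, 10), 1)), "saturated")
  expect_equal(fit2$n, 10)
  set.seed(4)
  L <- rnorm(500, 0.9, 0.2)
  fit3 <- fit_leaf_area(1 - exp(-pmax(L, 0.05)))
  expect_equal(fit3$L_s_mean, 0.9, tolerance = 0.05)
})

test_that("zero-browse event cap reads one percent of attainable mass", {
  expect_equal(zero_browse_event_cap(1, 3.3e-5), 303)
  expect_equal(zero_browse_event_cap(1, 0.01), 1)
  expect_equal(zero_browse_event_cap(1, 0.02), 0)
  B <- seq(0.5, 20, length.out = 40)
  expect_true(all(diff(zero_browse_event_cap(B, 3.3e-5)) >= 0))
  f <- seq(1e-5, 1e-3, length.out = 40)
  expect_true(all(diff(zero_browse_event_cap(2, f)) <= 0))
})

test_that("site likelihood equals hand-computed Bernoulli terms", {
  sp <- kamahi()
  fo <- default_forest()
  pa <- site_browse_params(200, 1, 0.4)
  B <- c(2, 6)
  mu <- feeding_rate(B, pa, fo, sp$f)
  K <- zero_browse_event_cap(B, sp$f)
  p0 <- vapply(1:2, function(j) 1 - nb_tail_oracle(mu[j], 0.4, K[j]),
               numeric(1))
  nll <- site_nll(pa, B, browsed = c(FALSE, TRUE), fo, sp$f)
  expect_equal(nll, -log(p0[1]) - log(1 - p0[2]), tolerance = 1e-8)
  # zero intake explains all-zero data perfectly and nonzero not at all
  expect_equal(site_nll(site_browse_params(0, 1, 0.4), B,
                        c(FALSE, FALSE), fo, sp$f), 0)
  expect_equal(site_nll(site_browse_params(0, 1, 0.4), B,
                        c(FALSE, TRUE), fo, sp$f), 1e10)
})

test_that("all-zero browse drives the intake estimate to its boundary", {
  sp <- kamahi()
  fo <- default_forest()
  B <- attainable_foliage(seq(12, 40, length.out = 30))
  expect_warning(
    fit <- fit_site_params(B, rep(FALSE, 30), fo, sp$f,
                           ci_method = "none"),
    "boundary")
  expect_true(fit$boundary)
  expect_lt(fit$estimate[["I_s"]], 0.01)
})

test_that("site fit recovers parameters and honours fixed values", {
  sp <- kamahi()
  fo <- default_forest()
  truth <- site_browse_params(300, 2, 0.3)
  tr <- ground_truth(sp, truth, fo, n_tagged = 250, seed = 1003)
  st <- generate_stand(tr)
  B <- attainable_foliage(st$trees$dbh_cm)
  browsed <- st$trees$fbi_category > 0
  fit <- fit_site_params(B, browsed, fo, sp$f)
  # profile intervals must bracket the estimate and cover this truth
  expect_true(all(fit$lower <= fit$estimate & fit$estimate <= fit$upper))
  expect_true(fit$lower[["I_s"]] <= 300 && 300 <= fit$upper[["I_s"]])
  expect_true(fit$lower[["h_s"]] <= 0.3 && 0.3 <= fit$upper[["h_s"]])
  # intake intervals are wide: order(s) of magnitude, as expected from
  # binary scores
  expect_gt(fit$upper[["I_s"]] / fit$lower[["I_s"]], 10)
  ffix <- fit_site_params(B, browsed, fo, sp$f, ci_method = "none",
                          fix = c(y_s = 2))
  expect_equal(ffix$estimate[["y_s"]], 2)
  expect_equal(ffix$lower[["y_s"]], 2)
})
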