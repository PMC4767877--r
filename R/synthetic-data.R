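#' Ground truth for a synthetic monitoring study
#'
#' Bundles the known species, browse and forest parameters together with
#' the study design (numbers of tagged trees and survey plots, visit
#' schedule, seed) used by the generators. Defaults emulate the
#' monitoring design the model is calibrated from: upwards of 200 tagged
#' stems with DBH > 10 cm per species and site, around 120 five-metre
#' radius plots, and two visits roughly five years apart.
#'
#' @param sp A [species_params()] object.
#' @param browse A [site_browse_params()] object (the true intake,
#'   size-preference and dispersion).
#' @param forest A [site_forest_state()] object.
#' @param n_tagged Number of tagged trees (default 250).
#' @param n_plots Number of survey plots (default 120).
#' @param plot_radius_m Plot radius, metres (default 5).
#' @param visit_years Numeric vector of visit times in years (default
#'   `c(0, 5)`).
#' @param seed Integer RNG seed recorded with every generated table.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(sp, browse, forest, n_tagged = 250,
                         n_plots = 120, plot_radius_m = 5,
                         visit_years = c(0, 5), seed = 1) {
  sp <- as_species_params(sp)
  stopifnot(inherits(browse, "site_browse_params"),
            inherits(forest, "site_forest_state"),
            n_tagged >= 1, n_plots >= 1, length(visit_years) >= 1)
  structure(list(sp = sp, browse = browse, forest = forest,
                 n_tagged = n_tagged, n_plots = n_plots,
                 plot_radius_m = plot_radius_m,
                 visit_years = visit_years, seed = as.integer(seed)),
            class = "ground_truth")
}

# lognormal DBH truncated at the survey cut-off
rdbh_truncated <- function(n, forest, min_dbh = 10) {
  draw_dbh(forest, n, min_dbh = min_dbh)
}

# per-tree unbrowsed leaf-area index, normal truncated to positive
rleaf_area <- function(n, forest) {
  L <- stats::rnorm(n, forest$L_s_mean, forest$L_s_sd)
  bad <- L <= 0.01
  while (any(bad)) {
    L[bad] <- stats::rnorm(sum(bad), forest$L_s_mean, forest$L_s_sd)
    bad <- L <= 0.01
  }
  L
}

#' Simulate one year of browse on a set of trees
#'
#' Draws the annual feeding-event count per tree from the negative
#' binomial distribution with mean from [feeding_rate()] and dispersion
#' `h_s`, applies it as a single annual pulse, and scores the outcome the
#' way a field visit would: the browsed mass is `count * f`, capped at
#' the standing foliage `tau * B` (the continuous model cannot overshoot
#' but a discrete annual pulse can); the tree dies if the uncapped intake
#' exceeds the mortality threshold; the FBI category comes from the
#' browsed mass as a fraction of `B` (category 0 exactly when the count
#' is within [zero_browse_event_cap()], keeping the simulator and the
#' site likelihood consistent); and the FCI category is the 10% class of
#' the cover left after the pulse.
#'
#' @param B Attainable foliar masses, kg (one per tree).
#' @param tau Canopy fractions at the start of the year.
#' @param L Unbrowsed leaf-area indices (one per tree).
#' @param sp A [species_params()] object.
#' @param browse A [site_browse_params()] object.
#' @param forest A [site_forest_state()] object.
#' @return Data frame with columns `events`, `browsed_mass`,
#'   `fci_category`, `fbi_category`, `died`.
#' @export
simulate_annual_browse <- function(B, tau, L, sp, browse, forest) {
  sp <- as_species_params(sp)
  n <- length(B)
  stopifnot(length(tau) == n, length(L) == n)
  mu <- feeding_rate(B, browse, forest, sp$f)
  events <- if (browse$I_s == 0) rep(0L, n) else
    stats::rnbinom(n, size = browse$h_s, mu = mu)
  intake <- events * sp$f
  died <- intake > mortality_threshold(tau, sp, B)
  browsed <- pmin(intake, tau * B)
  frac <- browsed / B
  K <- zero_browse_event_cap(B, sp$f)
  fbi <- ifelse(events <= K, 0L,
                ifelse(frac <= 0.25, 1L,
                       ifelse(frac <= 0.50, 2L,
                              ifelse(frac <= 0.75, 3L, 4L))))
  tau_after <- pmax(tau - frac, 0)
  fci <- fci_from_tau(tau_after, L)
  data.frame(events = events, browsed_mass = browsed,
             fci_category = fci_category(fci), fbi_category = fbi,
             died = died)
}

#' Generate a synthetic tagged-tree table and plot survey
#'
#' Produces the two single-visit tables a site calibration needs, with
#' known truth. Tagged trees get a DBH from the truncated lognormal, an
#' unbrowsed leaf-area index from the site normal, and first-visit FCI
#' and FBI scores from one year of simulated browse on a full canopy.
#' Plot stem counts are Poisson with mean `density * plot area`, and plot
#' stems are scored the same way. Deterministic under the recorded seed.
#'
#' @param truth A [ground_truth()] object.
#' @return List with elements `trees` (columns `site`, `species_code`,
#'   `tree_id`, `visit_time`, `dbh_cm`, `fci_category`, `fbi_category`,
#'   `alive`), `plots` (columns `plot_id`, `radius_m`, `species_code`,
#'   `dbh_cm`, `fci_category`) and `seed`.
#' @export
generate_stand <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(truth$seed)
  fo <- truth$forest

  dbh <- rdbh_truncated(truth$n_tagged, fo)
  L <- rleaf_area(truth$n_tagged, fo)
  B <- attainable_foliage(dbh)
  vis <- simulate_annual_browse(B, rep(1, truth$n_tagged), L,
                                truth$sp, truth$browse, fo)
  trees <- data.frame(site = "SYN", species_code = truth$sp$code,
                      tree_id = sprintf("t%04d", seq_len(truth$n_tagged)),
                      visit_time = truth$visit_years[1],
                      dbh_cm = dbh,
                      fci_category = vis$fci_category,
                      fbi_category = vis$fbi_category,
                      alive = !vis$died)

  area_ha <- pi * truth$plot_radius_m^2 / 1e4
  counts <- stats::rpois(truth$n_plots, fo$density_n * area_ha)
  total <- sum(counts)
  if (total > 0) {
    pdbh <- rdbh_truncated(total, fo)
    pL <- rleaf_area(total, fo)
    pvis <- simulate_annual_browse(attainable_foliage(pdbh),
                                   rep(1, total), pL,
                                   truth$sp, truth$browse, fo)
    plots <- data.frame(plot_id = rep(seq_len(truth$n_plots), counts),
                        radius_m = truth$plot_radius_m,
                        species_code = truth$sp$code,
                        dbh_cm = pdbh,
                        fci_category = pvis$fci_category)
  } else {
    plots <- data.frame(plot_id = integer(0), radius_m = numeric(0),
                        species_code = character(0), dbh_cm = numeric(0),
                        fci_category = integer(0))
  }
  list(trees = trees, plots = plots, seed = truth$seed,
       n_plots = truth$n_plots)
}

#' Generate a tagged-tree growth panel
#'
#' Simulates repeated FCI/FBI observations for species-growth
#' calibration, with two data-generating modes.
#'
#' `"regression"` (default) generates from the discrete observation model
#' the growth calibration assumes: each tree carries a fixed browse
#' category `b` whose asymptotic leaf-area index is `kappa_b` times the
#' unbrowsed site value and whose growth rate is the species production
#' curve evaluated at `kappa_b`; between visits
#' `ln L` advances by `dt * (c0b + c1b ln L + noise)`. Parameter-recovery
#' experiments under this mode test the estimator under its own model.
#' The default `kappa` ladder runs from 1 (no browse) down to 0.07
#' (severe browse, over three-quarters of leaves damaged, little canopy
#' held): growth efficiency is identifiable only from categories whose
#' relative asymptote sits in the bend of the production curve (below
#' roughly `3/e`), so the heavy-browse rungs must reach that low.
#'
#' `"ode"` integrates the foliage dynamics directly, with each tree's
#' intake drawn yearly from the negative-binomial feeding model. This
#' mode exercises the mechanistic dynamics (e.g. drift toward full
#' canopy under zero intake); the growth-regression estimator is only an
#' approximation to it.
#'
#' Observed FCI is discretised to 10% classes at every visit and the FBI
#' category at the first visit labels each pair.
#'
#' @param truth A [ground_truth()] object (its `visit_years` give the
#'   schedule).
#' @param n_trees Number of panel trees (default `truth$n_tagged`).
#' @param dynamics `"regression"` or `"ode"`.
#' @param kappa Relative asymptotic leaf-area index per browse category
#'   0-4 (regression mode).
#' @param category_probs Mixing proportions of browse categories 0-4
#'   (regression mode).
#' @param resid_sd Residual standard deviation of the growth rate,
#'   per year (regression mode, default 0.05).
#' @param L0_sdlog Lognormal spread of initial leaf area around the
#'   category asymptote (regression mode, default 0.35).
#' @return Data frame in the tagged-tree schema (`site`, `species_code`,
#'   `tree_id`, `visit_time`, `dbh_cm`, `fci_category`, `fbi_category`,
#'   `alive`), one row per tree and visit.
#' @export
generate_growth_panel <- function(truth, n_trees = truth$n_tagged,
                                  dynamics = c("regression", "ode"),
                                  kappa = c(1, 0.80, 0.50, 0.22, 0.07),
                                  category_probs = c(0.24, 0.22, 0.18,
                                                     0.18, 0.18),
                                  resid_sd = 0.05, L0_sdlog = 0.6) {
  stopifnot(inherits(truth, "ground_truth"))
  dynamics <- match.arg(dynamics)
  visits <- truth$visit_years
  if (length(visits) < 2) {
    stop("invalid parameter: at least 2 visits are required",
         call. = FALSE)
  }
  set.seed(truth$seed)
  sp <- truth$sp; fo <- truth$forest
  dbh <- rdbh_truncated(n_trees, fo)
  B <- attainable_foliage(dbh)

  if (dynamics == "regression") {
    stopifnot(length(kappa) == 5, length(category_probs) == 5)
    b <- sample(0:4, n_trees, replace = TRUE, prob = category_probs)
    L_tilde <- fo$L_s_mean * kappa[b + 1]
    r_b <- (1 - exp(-sp$e * kappa[b + 1])) / sp$a
    lnL <- log(L_tilde) + stats::rnorm(n_trees, 0, L0_sdlog)
    rows <- vector("list", length(visits))
    for (k in seq_along(visits)) {
      if (k > 1) {
        dt <- visits[k] - visits[k - 1]
        rate <- r_b * (log(L_tilde) - lnL) +
          stats::rnorm(n_trees, 0, resid_sd)
        lnL <- lnL + dt * rate
      }
      fci <- 1 - exp(-exp(lnL))
      rows[[k]] <- data.frame(site = "SYN", species_code = sp$code,
                              tree_id = sprintf("t%04d", seq_len(n_trees)),
                              visit_time = visits[k], dbh_cm = dbh,
                              fci_category = fci_category(fci),
                              fbi_category = b, alive = TRUE)
    }
  } else {
    L <- rleaf_area(n_trees, fo)
    tau <- stats::runif(n_trees, 0.4, 1)
    alive <- rep(TRUE, n_trees)
    fbi_now <- rep(0L, n_trees)
    rows <- vector("list", length(visits))
    record <- function(k) {
      fci <- fci_from_tau(tau, L)
      data.frame(site = "SYN", species_code = sp$code,
                 tree_id = sprintf("t%04d", seq_len(n_trees)),
                 visit_time = visits[k], dbh_cm = dbh,
                 fci_category = fci_category(fci),
                 fbi_category = fbi_now, alive = alive)
    }
    rows[[1]] <- record(1)
    for (k in 2:length(visits)) {
      n_years <- round(visits[k] - visits[k - 1])
      for (yr in seq_len(max(n_years, 1))) {
        sim <- simulate_annual_browse(B, tau, L, sp, truth$browse, fo)
        alive <- alive & !sim$died
        tau <- pmax(tau - sim$browsed_mass / B, 0)
        # regrowth over the remainder of the year, tree by tree
        for (i in which(alive & tau > 0)) {
          tr <- integrate_foliage(tau[i], 0, sp, B[i], times = c(0, 1))
          tau[i] <- min(max(tr$tau[nrow(tr)], 0), 1)
        }
        fbi_now <- sim$fbi_category
      }
      tau[!alive] <- 0
      rows[[k]] <- record(k)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- truth$seed
  out
}
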