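# Parameter sets used to propagate the 95% CI of a site fit into
# mortality bands. The lower band pairs the intake lower endpoint with
# the dispersion upper endpoint (uniform browse spares the tail in the
# usual below-threshold regime), the upper band the reverse; the
# size-preference exponent is scanned over both endpoints and the point
# value and the worst case taken. The point-estimate set is included in
# both bands because the dispersion effect reverses once mean feeding
# exceeds the death threshold, which would otherwise let a band cross
# the point prediction.
ci_parameter_sets <- function(fit, I_override = NULL) {
  pick <- function(which) {
    v <- fit[[which]]
    if (any(!is.finite(v))) fit$estimate else v
  }
  if (inherits(fit, "site_browse_params")) {
    est <- fit
    if (!is.null(I_override)) est <- site_browse_params(I_override,
                                                        fit$y_s, fit$h_s)
    return(list(point = est, lower = list(est), upper = list(est)))
  }
  stopifnot(inherits(fit, "site_fit"))
  est <- pick("estimate"); lo <- pick("lower"); hi <- pick("upper")
  I_pt <- if (is.null(I_override)) est[["I_s"]] else I_override
  I_lo <- if (is.null(I_override)) lo[["I_s"]] else I_override
  I_hi <- if (is.null(I_override)) hi[["I_s"]] else I_override
  point <- site_browse_params(I_pt, est[["y_s"]], est[["h_s"]])
  ys <- unique(c(lo[["y_s"]], est[["y_s"]], hi[["y_s"]]))
  list(
    point = point,
    lower = c(lapply(ys, function(y)
      site_browse_params(I_lo, y, hi[["h_s"]])), list(point)),
    upper = c(lapply(ys, function(y)
      site_browse_params(I_hi, y, lo[["h_s"]])), list(point))
  )
}

# DBH draws from the fitted lognormal, truncated at the survey cut-off
draw_dbh <- function(forest, n, min_dbh = 10) {
  if (forest$dbh_sdlog == 0) return(rep(exp(forest$dbh_meanlog), n))
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rlnorm(n, forest$dbh_meanlog, forest$dbh_sdlog)
    out <- c(out, d[d > min_dbh])
  }
  out[seq_len(n)]
}

#' Annual mortality probability by foliage-cover class
#'
#' For each FCI class, the class midpoint is converted to a canopy
#' fraction with the site-mean unbrowsed leaf-area index, the mortality
#' probability is evaluated by [tree_mortality()] and averaged over
#' Monte-Carlo draws of DBH from the fitted site distribution. When `fit`
#' is a `site_fit`, 95% bands are obtained by re-evaluating at the CI
#' endpoint parameter sets (low intake/high dispersion for the lower
#' band, the reverse for the upper, worst case over the size-preference
#' endpoints).
#'
#' @param sp A [species_params()] object.
#' @param fit A `site_fit` from [fit_site_params()], or a
#'   [site_browse_params()] object (no CI bands).
#' @param forest A [site_forest_state()] object.
#' @param categories Integer FCI classes to evaluate (default `1:10`).
#' @param n_dbh_draws Monte-Carlo DBH draws (default 10000).
#' @param seed Optional integer seed for the DBH draws.
#' @return Data frame with columns `category`, `fci_mid`, `tau`, `mean`,
#'   `lower`, `upper`.
#' @export
mortality_by_fci_category <- function(sp, fit, forest, categories = 1:10,
                                      n_dbh_draws = 10000, seed = NULL) {
  sp <- as_species_params(sp)
  stopifnot(inherits(forest, "site_forest_state"))
  if (any(!categories %in% 1:10)) {
    stop("invalid category: FCI classes must be integers 1-10",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  B <- attainable_foliage(draw_dbh(forest, n_dbh_draws))
  sets <- ci_parameter_sets(fit)
  fci_mid <- fci_category_midpoint(categories)
  tau <- tau_from_fci(fci_mid, forest$L_s_mean)
  one <- function(params, tau_c) mean(tree_mortality(tau_c, B, sp,
                                                     params, forest))
  res <- t(vapply(tau, function(tau_c) {
    c(mean  = one(sets$point, tau_c),
      lower = min(vapply(sets$lower, one, 0, tau_c = tau_c)),
      upper = max(vapply(sets$upper, one, 0, tau_c = tau_c)))
  }, numeric(3)))
  data.frame(category = categories, fci_mid = fci_mid, tau = tau,
             mean = res[, "mean"], lower = res[, "lower"],
             upper = res[, "upper"])
}

#' Site-wide annual mortality probability
#'
#' Weights the per-FCI-class mortality triple by the proportion of trees
#' observed in each class (at the first visit), giving the site-wide
#' annual probability of mortality with its band.
#'
#' @param per_category Data frame from [mortality_by_fci_category()].
#' @param weights Numeric vector of class proportions, one per row of
#'   `per_category`; must sum to 1 (small tolerance) and be
#'   non-negative.
#' @return Named numeric vector `c(mean, lower, upper)`.
#' @export
sitewide_mortality <- function(per_category, weights) {
  stopifnot(all(c("mean", "lower", "upper") %in% names(per_category)))
  if (length(weights) != nrow(per_category) || any(weights < 0)) {
    stop("weight normalization error: need one non-negative weight per ",
         "class", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("weight normalization error: weights must sum to 1",
         call. = FALSE)
  }
  c(mean  = sum(weights * per_category$mean),
    lower = sum(weights * per_category$lower),
    upper = sum(weights * per_category$upper))
}

#' Expected deaths over a study period
#'
#' Converts an annual mortality probability into the expected number of
#' deaths among `n_trees` over `T_years`. The default compounds
#' annually, `n (1 - (1 - m)^T)`; the linear approximation `n m T`
#' (which overestimates at high mortality) is available for comparison.
#'
#' @param m_annual Annual mortality probability in `[0, 1]` (vectorised).
#' @param n_trees Number of trees at risk.
#' @param T_years Study period in whole years, `>= 1`.
#' @param method `"compound"` (default) or `"linear"`.
#' @return Expected death count(s) in `[0, n_trees]` (linear method may
#'   exceed `n_trees` at extreme inputs).
#' @export
#' @examples
#' expected_deaths(0.01, n_trees = 250, T_years = 5)  # 12.25
expected_deaths <- function(m_annual, n_trees, T_years,
                            method = c("compound", "linear")) {
  method <- match.arg(method)
  if (any(!is.finite(m_annual)) || any(m_annual < 0) || any(m_annual > 1)) {
    stop("invalid parameter: `m_annual` must lie in [0, 1]", call. = FALSE)
  }
  check_scalar(n_trees, "n_trees", lower = 0)
  check_scalar(T_years, "T_years", lower = 1)
  if (method == "compound") {
    n_trees * (1 - (1 - m_annual)^T_years)
  } else {
    n_trees * m_annual * T_years
  }
}

#' Trap-catch index and possum density conversions
#'
#' The trap-catch index (TCI, captures per 100 trap-nights) relates
#' linearly to possum density `N` (possums/ha) as `TCI = 3.88 + 3.96 N`,
#' an approximation valid up to TCI of about 50. `tci_to_density()`
#' inverts the relation, flooring negative raw densities at zero;
#' `density_to_tci()` applies it forward. `density_to_intake()` converts
#' density to the site-wide intake rate of one tree species,
#' `I_s = 58.4 N p_diet` (58.4 kg dry weight per possum per year), and
#' `intake_to_density()` inverts that assuming the observed species make
#' up the whole diet.
#'
#' @param tci Trap-catch index value(s), `>= 0` (%).
#' @param N Possum density(ies), possums/ha, `>= 0`.
#' @param p_diet Proportion of total diet from the focal species.
#' @param I_s Site-wide intake, kg/ha/year.
#' @return Numeric vector (density, TCI or intake as appropriate).
#' @export
#' @examples
#' tci_to_density(47.4)                 # 11.0 possums/ha
#' density_to_intake(1, p_diet = 1)     # 58.4 kg/ha/yr
tci_to_density <- function(tci) {
  if (any(!is.finite(tci)) || any(tci < 0)) {
    stop("invalid parameter: `tci` must be non-negative", call. = FALSE)
  }
  pmax(0, (tci - 3.88) / 3.96)
}

#' @rdname tci_to_density
#' @export
density_to_tci <- function(N) {
  if (any(!is.finite(N)) || any(N < 0)) {
    stop("invalid parameter: `N` must be non-negative", call. = FALSE)
  }
  3.88 + 3.96 * N
}

#' @rdname tci_to_density
#' @export
density_to_intake <- function(N, p_diet) {
  if (any(!is.finite(N)) || any(N < 0)) {
    stop("invalid parameter: `N` must be non-negative", call. = FALSE)
  }
  if (any(p_diet < 0) || any(p_diet > 1)) {
    stop("invalid parameter: `p_diet` must lie in [0, 1]", call. = FALSE)
  }
  58.4 * N * p_diet
}

#' @rdname tci_to_density
#' @export
intake_to_density <- function(I_s, p_diet = 1) {
  if (any(!is.finite(I_s)) || any(I_s < 0)) {
    stop("invalid parameter: `I_s` must be non-negative", call. = FALSE)
  }
  I_s / (58.4 * p_diet)
}

#' Site-wide mortality as a function of possum density
#'
#' Management curve: over a grid of trap-catch index values, the fitted
#' site intake is replaced by the intake implied by possum density
#' (`I_s = 58.4 N p_diet` with `N` from the TCI relation), while the
#' fitted size-preference and dispersion (and their CI endpoints) are
#' retained; the site-wide mortality triple is computed at each grid
#' point. The TCI goal is the highest grid value whose upper 95% bound
#' stays below the mortality threshold — the density a manager must push
#' possums below to be confident of meeting the target.
#'
#' @param sp A [species_params()] object (supplies `p_diet`).
#' @param fit A `site_fit` or [site_browse_params()] object.
#' @param forest A [site_forest_state()] object.
#' @param weights FCI-class proportions for the site-wide weighting (one
#'   per element of `categories`).
#' @param categories FCI classes in use (default `1:10`).
#' @param tci_grid Grid of TCI values (default `0:50`).
#' @param threshold Acceptable annual mortality (default 0.005, i.e.
#'   0.5%/year).
#' @param n_dbh_draws Monte-Carlo DBH draws shared across the grid.
#' @param seed Optional integer seed.
#' @return An object of class `management_curve`: list with `curve`
#'   (data frame `tci`, `N`, `I_s`, `mean`, `lower`, `upper`),
#'   `tci_goal` (`NA` and `attainable = FALSE` if no grid point
#'   qualifies), `threshold`.
#' @export
mortality_vs_tci_curve <- function(sp, fit, forest, weights,
                                   categories = 1:10, tci_grid = 0:50,
                                   threshold = 0.005,
                                   n_dbh_draws = 10000, seed = NULL) {
  sp <- as_species_params(sp)
  stopifnot(inherits(forest, "site_forest_state"))
  if (is.unsorted(tci_grid)) {
    stop("invalid parameter: `tci_grid` must be sorted increasing",
         call. = FALSE)
  }
  check_scalar(threshold, "threshold", lower = 0, upper = 1)
  if (threshold <= 0) {
    stop("invalid parameter: `threshold` must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  B <- attainable_foliage(draw_dbh(forest, n_dbh_draws))
  fci_mid <- fci_category_midpoint(categories)
  tau <- tau_from_fci(fci_mid, forest$L_s_mean)
  N <- tci_to_density(tci_grid)
  I_grid <- density_to_intake(N, sp$p_diet)

  one <- function(params, tau_c) mean(tree_mortality(tau_c, B, sp,
                                                     params, forest))
  rows <- lapply(seq_along(tci_grid), function(i) {
    sets <- ci_parameter_sets(fit, I_override = I_grid[i])
    per <- t(vapply(tau, function(tau_c) {
      c(mean  = one(sets$point, tau_c),
        lower = min(vapply(sets$lower, one, 0, tau_c = tau_c)),
        upper = max(vapply(sets$upper, one, 0, tau_c = tau_c)))
    }, numeric(3)))
    sw <- sitewide_mortality(as.data.frame(per), weights)
    data.frame(tci = tci_grid[i], N = N[i], I_s = I_grid[i],
               mean = sw[["mean"]], lower = sw[["lower"]],
               upper = sw[["upper"]])
  })
  curve <- do.call(rbind, rows)
  ok <- curve$upper < threshold
  goal <- if (any(ok)) max(curve$tci[ok]) else NA_real_
  structure(list(curve = curve, tci_goal = goal,
                 attainable = any(ok), threshold = threshold),
            class = "management_curve")
}

#' @export
print.management_curve <- function(x, ...) {
  cat("Management curve over TCI ", min(x$curve$tci), "-",
      max(x$curve$tci), " (threshold ", x$threshold, "/yr)\n", sep = "")
  if (x$attainable) {
    cat("  TCI goal:", x$tci_goal, "\n")
  } else {
    cat("  TCI goal unattainable on this grid\n")
  }
  i <- unique(round(seq(1, nrow(x$curve), length.out = 6)))
  print(signif(x$curve[i, c("tci", "N", "mean", "lower", "upper")], 3),
        row.names = FALSE)
  invisible(x)
}
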