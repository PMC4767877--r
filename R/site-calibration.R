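#' Stem density from circular plot surveys
#'
#' Density (trees/ha) of a species from fixed-radius plots: the mean count
#' per plot divided by the plot area, scaled to hectares. Only stems with
#' DBH above `min_dbh` are counted. Plots with no stems of the species
#' still count as plots, so `n_plots` must be the number of plots
#' surveyed, not the number with records.
#'
#' @param survey Data frame with columns `plot_id`, `species_code`,
#'   `dbh_cm` (one row per stem).
#' @param species_code Species to count.
#' @param n_plots Total number of plots surveyed. Defaults to the number
#'   of distinct `plot_id` values in `survey` (correct only if every plot
#'   contains at least one stem of any species).
#' @param radius_m Plot radius in metres (default 5).
#' @param min_dbh Lower DBH cut-off in cm (default 10).
#' @return Density in trees/ha.
#' @export
#' @examples
#' sv <- data.frame(plot_id = rep(1:4, c(3, 2, 3, 2)),
#'                  species_code = "WEIRAC",
#'                  dbh_cm = c(12, 15, 30, 11, 22, 14, 40, 25, 18, 33))
#' estimate_density(sv, "WEIRAC", n_plots = 4)
estimate_density <- function(survey, species_code,
                             n_plots = length(unique(survey$plot_id)),
                             radius_m = 5, min_dbh = 10) {
  stopifnot(all(c("plot_id", "species_code", "dbh_cm") %in% names(survey)))
  if (n_plots < 1) stop("empty survey: no plots", call. = FALSE)
  check_scalar(radius_m, "radius_m", lower = 0, strict = TRUE)
  d <- survey[survey$species_code == species_code &
                survey$dbh_cm > min_dbh, , drop = FALSE]
  if (nrow(d) == 0) {
    warning("no stems of ", species_code, " above ", min_dbh,
            " cm; density is 0", call. = FALSE)
    return(0)
  }
  mean_count <- nrow(d) / n_plots
  mean_count / (pi * radius_m^2) * 1e4
}

#' Lognormal fit to a DBH sample
#'
#' Maximum-likelihood lognormal fit (via [MASS::fitdistr()]) to stem
#' diameters. The sample is taken as-is; no correction is applied for the
#' 10-cm survey cut-off, which biases the fitted mean upward slightly for
#' distributions with substantial mass below the cut-off.
#'
#' @param dbh Vector of diameters, cm; all `> 0`, at least 5 values.
#' @return List with `meanlog`, `sdlog`, their standard errors
#'   (`meanlog_se`, `sdlog_se`), `mean_dbh` (the implied lognormal mean)
#'   and `n`.
#' @export
fit_dbh_distribution <- function(dbh) {
  if (length(dbh) < 5) {
    stop("insufficient data: at least 5 DBH values are required",
         call. = FALSE)
  }
  if (any(!is.finite(dbh)) || any(dbh <= 0)) {
    stop("invalid parameter: DBH values must be positive", call. = FALSE)
  }
  if (stats::sd(dbh) == 0) {
    est <- c(meanlog = log(dbh[1]), sdlog = 0)
    se <- c(meanlog = 0, sdlog = 0)
  } else {
    fd <- MASS::fitdistr(dbh, "lognormal")
    est <- fd$estimate
    se <- fd$sd
  }
  list(meanlog = unname(est["meanlog"]), sdlog = unname(est["sdlog"]),
       meanlog_se = unname(se["meanlog"]), sdlog_se = unname(se["sdlog"]),
       mean_dbh = exp(est[["meanlog"]] + est[["sdlog"]]^2 / 2),
       n = length(dbh))
}

#' Site mean leaf-area index from unbrowsed trees
#'
#' Transforms FCI observations of unbrowsed trees (FBI category 0) to
#' leaf-area indices with `L = -log(1 - FCI)` (the cover relation at
#' `tau = 1`) and fits a normal distribution. Saturated records
#' (`FCI >= 1`) are excluded with a warning; callers must pass only
#' unbrowsed trees.
#'
#' @param fci Vector of FCI proportions for unbrowsed trees (class
#'   midpoints if recorded categorically); at least 5 usable values.
#' @return List with `L_s_mean`, `L_s_sd`, their standard errors and `n`.
#' @export
#' @examples
#' fit_leaf_area(rep(c(0.55, 0.65, 0.75), c(10, 14, 6)))
fit_leaf_area <- function(fci) {
  if (any(!is.finite(fci)) || any(fci < 0)) {
    stop("invalid parameter: FCI values must be in [0, 1]", call. = FALSE)
  }
  if (any(fci >= 1)) {
    warning("saturated FCI records (>= 1) excluded from leaf-area fit",
            call. = FALSE)
    fci <- fci[fci < 1]
  }
  fci <- fci[fci > 0]
  if (length(fci) < 5) {
    stop("insufficient data: at least 5 unbrowsed trees with 0 < FCI < 1 ",
         "are required", call. = FALSE)
  }
  L <- -log(1 - fci)
  if (stats::sd(L) == 0) {
    est <- c(mean = L[1], sd = 0); se <- c(mean = 0, sd = 0)
  } else {
    fd <- MASS::fitdistr(L, "normal")
    est <- fd$estimate; se <- fd$sd
  }
  list(L_s_mean = unname(est["mean"]), L_s_sd = unname(est["sd"]),
       L_s_mean_se = unname(se["mean"]), L_s_sd_se = unname(se["sd"]),
       n = length(L))
}

#' Maximum feeding events consistent with a zero browse score
#'
#' A tree is scored FBI 0 when under 1% of its foliage shows browse
#' (allowing for observer error). Reading the 1% as a mass fraction of the
#' attainable foliar mass `B`, the largest annual event count still scored
#' zero is `K = floor(0.01 B / f)`.
#'
#' @param B Attainable foliar mass(es), kg.
#' @param f Feeding-event size, kg.
#' @return Integer event cap(s), `>= 0`.
#' @export
#' @examples
#' zero_browse_event_cap(B = 1, f = 3.3e-5)  # 303
zero_browse_event_cap <- function(B, f) {
  if (any(!is.finite(B)) || any(B <= 0)) {
    stop("invalid parameter: `B` must be positive", call. = FALSE)
  }
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("invalid parameter: `f` must be positive", call. = FALSE)
  }
  floor(0.01 * B / f)
}

#' Negative log-likelihood of zero/nonzero browse scores
#'
#' Bernoulli likelihood of the observed zero (FBI = 0) vs nonzero
#' (FBI > 0) browse indicator per tree, with the zero probability given by
#' the negative-binomial CDF at the tree's zero-score event cap:
#' `P(zero_j) = P(count_j <= K_j)` with mean from [feeding_rate()] and
#' dispersion `h_s`. Invalid parameter regions return a large penalty so
#' optimisers are steered away rather than stopped.
#'
#' @param params A [site_browse_params()] object (or numeric vector
#'   `c(I_s, y_s, h_s)`).
#' @param B Attainable foliar masses of the scored trees, kg.
#' @param browsed Logical vector, `TRUE` where FBI > 0.
#' @param forest A [site_forest_state()] object.
#' @param f Feeding-event size, kg.
#' @return The negative log-likelihood (scalar).
#' @export
site_nll <- function(params, B, browsed, forest, f) {
  if (is.numeric(params) && length(params) == 3) {
    if (!is.finite(params[1]) || params[1] < 0 ||
        !is.finite(params[2]) ||
        !is.finite(params[3]) || params[3] <= 0) {
      return(1e10)
    }
    params <- site_browse_params(params[1], params[2], params[3])
  }
  stopifnot(inherits(params, "site_browse_params"),
            length(B) == length(browsed), length(B) >= 1)
  mu <- feeding_rate(B, params, forest, f)
  K <- zero_browse_event_cap(B, f)
  p_zero <- stats::pnbinom(K, size = params$h_s, mu = mu)
  p_obs <- ifelse(browsed, 1 - p_zero, p_zero)
  if (any(p_obs <= 0)) return(1e10)
  -sum(log(p_obs))
}

# One-dimensional profile-likelihood interval on the transformed scale.
# Steps outward from the optimum, re-optimising the free parameters at
# each step (warm-started), until the deviance exceeds the chi-squared
# cut-off, then locates the crossing by bisection. Returns the bound
# itself when the profile never crosses before reaching it.
profile_ci_1d <- function(obj, par, i, nll_min, lb, ub, free_set = 1:3,
                          level = 0.95, step0 = 0.3) {
  target <- nll_min + stats::qchisq(level, df = 1) / 2
  free <- setdiff(free_set, i)
  warm <- par[free]
  prof <- function(t) {
    fixed_obj <- function(q) {
      p <- par; p[i] <- t; p[free] <- q
      obj(p)
    }
    if (length(free) == 0) return(fixed_obj(numeric(0)))
    opt <- tryCatch(
      stats::optim(warm, fixed_obj, method = "L-BFGS-B",
                   lower = lb[free], upper = ub[free],
                   control = list(maxit = 200)),
      error = function(err) NULL)
    if (is.null(opt)) return(Inf)
    warm <<- opt$par
    opt$value
  }
  one_side <- function(dir) {
    warm <<- par[free]
    bound <- if (dir > 0) ub[i] else lb[i]
    step <- step0
    t_in <- par[i]
    repeat {
      t_out <- t_in + dir * step
      hit_bound <- (dir > 0 && t_out >= bound) ||
        (dir < 0 && t_out <= bound)
      if (hit_bound) t_out <- bound
      v <- prof(t_out)
      if (v >= target) {
        # bisect between the inside point (< target) and t_out
        a <- t_in; b <- t_out
        for (k in 1:30) {
          if (abs(b - a) < 1e-3) break
          mid <- (a + b) / 2
          if (prof(mid) >= target) b <- mid else a <- mid
        }
        return((a + b) / 2)
      }
      if (hit_bound) return(bound)
      t_in <- t_out
      step <- step * 2
    }
  }
  c(one_side(-1), one_side(1))
}

#' Maximum-likelihood site browse parameters
#'
#' Fits `(I_s, y_s, h_s)` to single-visit zero/nonzero browse scores by
#' maximising the likelihood of [site_nll()]. Optimisation runs on the
#' transformed scale `(log I_s, y_s, log h_s)` (positivity enforced by
#' construction) with `L-BFGS-B` from a lattice of starting points.
#' Binary scores carry limited information about the three parameters
#' jointly — intake and dispersion trade off along a near-flat likelihood
#' ridge — so 95% confidence intervals are computed by profile likelihood
#' by default (each parameter is stepped away from the optimum with the
#' other two re-optimised until the deviance rises by the 0.95
#' chi-squared quantile); intervals spanning an order of magnitude or
#' more on `I_s` are normal for study-sized samples. `ci_method =
#' "hessian"` gives the cheaper Wald intervals from the inverse numerical
#' Hessian (anti-conservative on the ridge), and `"none"` skips CIs.
#'
#' @param B Attainable foliar masses of the scored trees, kg.
#' @param browsed Logical vector, `TRUE` where FBI > 0.
#' @param forest A [site_forest_state()] object.
#' @param f Feeding-event size, kg.
#' @param starts Optional matrix of starting values (columns `I_s`, `y_s`,
#'   `h_s`); defaults to a 3x3x3 lattice spanning plausible ranges.
#' @param y_bounds Bounds for the size-preference exponent (default
#'   `c(-5, 10)`).
#' @param I_bounds Bounds for the site intake, kg/ha/year. The default
#'   upper bound of 2000 corresponds to a herbivore population far
#'   denser than any plausibly observed (about 34 possums/ha eating
#'   nothing but the focal species); without it the likelihood ridge can
#'   carry the estimate to physically meaningless intakes.
#' @param ci_method One of `"profile"` (default), `"hessian"`, `"none"`.
#' @param fix Optional named numeric vector holding any of `I_s`, `y_s`,
#'   `h_s` at a known value (e.g. `c(y_s = 1)`). Useful because the
#'   binary scores identify intake much more sharply once the
#'   size-preference exponent is known; fixed parameters get degenerate
#'   intervals.
#' @return An object of class `site_fit`: list with `estimate` (named
#'   `I_s`, `y_s`, `h_s`), `lower`, `upper` (95% CI), `logLik`,
#'   `convergence` (0 = clean), `boundary` flag and `n_trees`.
#' @export
fit_site_params <- function(B, browsed, forest, f, starts = NULL,
                            y_bounds = c(-5, 10), I_bounds = c(1e-3, 2e3),
                            ci_method = c("profile", "hessian", "none"),
                            fix = NULL) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(B) == length(browsed), length(B) >= 1)
  par_names <- c("I_s", "y_s", "h_s")
  if (!is.null(fix)) {
    if (is.null(names(fix)) || !all(names(fix) %in% par_names)) {
      stop("`fix` must be a named vector with names among I_s, y_s, h_s",
           call. = FALSE)
    }
  }
  fixed_idx <- match(names(fix), par_names)
  free_idx <- setdiff(1:3, fixed_idx)
  if (length(free_idx) == 0) {
    stop("`fix` leaves no free parameters", call. = FALSE)
  }
  to_trans <- function(v) c(log(v[1]), v[2], log(v[3]))
  fixed_t <- if (length(fixed_idx))
    to_trans(replace(rep(1, 3), fixed_idx, fix))[fixed_idx] else numeric(0)
  if (!any(browsed) || all(browsed)) {
    warning("browse scores are all ", if (all(browsed)) "nonzero" else
      "zero", "; the fit will sit on a parameter boundary", call. = FALSE)
  }
  if (is.null(starts)) {
    starts <- as.matrix(expand.grid(I_s = c(10, 100, 600),
                                    y_s = c(0, 1, 2.5),
                                    h_s = c(0.05, 0.3, 1.5)))
  }
  lb <- c(log(I_bounds[1]), y_bounds[1], log(1e-3))
  ub <- c(log(I_bounds[2]), y_bounds[2], log(1e3))
  obj <- function(par) {
    site_nll(c(exp(par[1]), par[2], exp(par[3])), B, browsed, forest, f)
  }
  obj_free <- function(q) {
    p <- numeric(3); p[fixed_idx] <- fixed_t; p[free_idx] <- q
    obj(p)
  }
  best <- NULL
  seen <- character(0)
  for (i in seq_len(nrow(starts))) {
    p0 <- c(log(starts[i, 1]), starts[i, 2],
            log(starts[i, 3]))[free_idx]
    key <- paste(signif(p0, 6), collapse = "/")
    if (key %in% seen) next
    seen <- c(seen, key)
    opt <- tryCatch(
      stats::optim(p0, obj_free, method = "L-BFGS-B",
                   lower = lb[free_idx], upper = ub[free_idx],
                   control = list(maxit = 500)),
      error = function(err) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop("non-convergence: site likelihood optimisation failed from all ",
         "starts", call. = FALSE)
  }
  par <- numeric(3)
  par[fixed_idx] <- fixed_t
  par[free_idx] <- unname(best$par)
  boundary <- any(abs(par[free_idx] - lb[free_idx]) < 1e-6) ||
    any(abs(par[free_idx] - ub[free_idx]) < 1e-6)
  lo_t <- rep(NA_real_, 3)
  hi_t <- rep(NA_real_, 3)
  lo_t[fixed_idx] <- fixed_t
  hi_t[fixed_idx] <- fixed_t
  if (ci_method == "hessian") {
    H <- tryCatch(stats::optimHess(par[free_idx], obj_free),
                  error = function(err) NULL)
    se <- rep(NA_real_, length(free_idx))
    if (!is.null(H) && all(is.finite(H))) {
      # The ridge can leave the Hessian numerically singular; invert on
      # its eigenbasis with flat directions floored so they contribute
      # very wide, not broken, intervals.
      ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
      lam <- pmax(ev$values, 1e-6 * max(abs(ev$values), 1e-12))
      V <- ev$vectors %*% (t(ev$vectors) / lam)
      se <- sqrt(pmax(diag(V), 0))
    }
    lo_t[free_idx] <- par[free_idx] - 1.96 * se
    hi_t[free_idx] <- par[free_idx] + 1.96 * se
  } else if (ci_method == "profile") {
    for (i in free_idx) {
      pr <- profile_ci_1d(obj, par, i, best$value, lb, ub,
                          free_set = free_idx)
      lo_t[i] <- pr[1]
      hi_t[i] <- pr[2]
    }
  }
  est <- c(I_s = exp(par[1]), y_s = par[2], h_s = exp(par[3]))
  lower <- c(I_s = exp(lo_t[1]), y_s = lo_t[2], h_s = exp(lo_t[3]))
  upper <- c(I_s = exp(hi_t[1]), y_s = hi_t[2], h_s = exp(hi_t[3]))
  structure(list(estimate = est, lower = lower, upper = upper,
                 logLik = -best$value, convergence = best$convergence,
                 boundary = boundary, n_trees = length(B)),
            class = "site_fit")
}

#' @export
print.site_fit <- function(x, ...) {
  cat("Site browse fit (", x$n_trees, " trees)\n", sep = "")
  m <- rbind(estimate = x$estimate, lower95 = x$lower, upper95 = x$upper)
  print(signif(m, 4))
  cat(sprintf("  logLik %.3f, convergence %d%s\n", x$logLik,
              x$convergence,
              if (x$boundary) " (boundary estimate)" else ""))
  invisible(x)
}

#' Convert a site fit to browse parameters
#'
#' @param fit A `site_fit` object (or an existing
#'   [site_browse_params()], returned unchanged).
#' @param which One of `"estimate"`, `"lower"`, `"upper"`.
#' @return A [site_browse_params()] object.
#' @export
as_site_browse_params <- function(fit, which = "estimate") {
  if (inherits(fit, "site_browse_params")) return(fit)
  stopifnot(inherits(fit, "site_fit"))
  v <- fit[[match.arg(which, c("estimate", "lower", "upper"))]]
  site_browse_params(v[["I_s"]], v[["y_s"]], v[["h_s"]])
}
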