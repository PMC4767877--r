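#' Leaf-area growth rate from a pair of observations
#'
#' Relative (log-scale) rate of change of leaf-area index between two
#' visits: `(ln(Lt) - ln(L0)) / dt` per year. Records with zero cover at
#' either visit have no defined rate and must be excluded upstream.
#'
#' @param L0,Lt Leaf-area indices at the first and second visit; `> 0`.
#' @param dt Years between visits; `> 0`.
#' @return Growth rate(s), per year.
#' @export
#' @examples
#' leaf_area_rate(L0 = 2.0, Lt = 1.5, dt = 2.1)
leaf_area_rate <- function(L0, Lt, dt) {
  if (any(!is.finite(L0)) || any(L0 <= 0) ||
      any(!is.finite(Lt)) || any(Lt <= 0)) {
    stop("excluded record: leaf-area rate is undefined for zero cover",
         call. = FALSE)
  }
  if (any(!is.finite(dt)) || any(dt <= 0)) {
    stop("invalid parameter: `dt` must be positive", call. = FALSE)
  }
  (log(Lt) - log(L0)) / dt
}

#' Extract consecutive observation pairs from a tagged-tree panel
#'
#' Builds the paired-growth table used by [fit_growth_regression()]:
#' for each tree, consecutive visits are paired; FCI categories are
#' converted to leaf-area indices through the class midpoint
#' (`L = -log(1 - FCI)`), and the pair is labelled with the FBI category
#' at the first visit. Pairs with a bare crown (FCI category 0) at either
#' visit are excluded, as are pairs spanning a death.
#'
#' @param observations Data frame with columns `tree_id`, `visit_time`
#'   (years, numeric), `fci_category` (0-10), `fbi_category` (0-4) and
#'   optionally `alive` (logical).
#' @return Data frame with columns `tree_id`, `L0`, `Lt`, `dt`, `b`
#'   (initial FBI category) and `dLdt`.
#' @export
extract_growth_pairs <- function(observations) {
  req <- c("tree_id", "visit_time", "fci_category", "fbi_category")
  miss <- setdiff(req, names(observations))
  if (length(miss)) {
    stop("missing columns in observations: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  obs <- observations[order(observations$tree_id, observations$visit_time), ]
  if (!"alive" %in% names(obs)) obs$alive <- TRUE
  same <- obs$tree_id[-1] == obs$tree_id[-nrow(obs)]
  i0 <- which(same)            # first of each consecutive pair
  i1 <- i0 + 1L
  keep <- obs$fci_category[i0] > 0 & obs$fci_category[i1] > 0 &
    obs$alive[i0] & obs$alive[i1]
  i0 <- i0[keep]; i1 <- i1[keep]
  L0 <- -log(1 - fci_category_midpoint(obs$fci_category[i0]))
  Lt <- -log(1 - fci_category_midpoint(obs$fci_category[i1]))
  dt <- obs$visit_time[i1] - obs$visit_time[i0]
  if (any(dt <= 0)) {
    stop("invalid panel: non-increasing visit times within a tree",
         call. = FALSE)
  }
  data.frame(tree_id = obs$tree_id[i0], L0 = L0, Lt = Lt, dt = dt,
             b = obs$fbi_category[i0],
             dLdt = leaf_area_rate(L0, Lt, dt))
}

#' Per-browse-category growth regressions
#'
#' Fits, within each FBI category `b`, the ordinary least-squares model
#' `dL/dt = c0b + c1b * ln(L0)`. A negative slope `c1b` implies saturating
#' growth with rate `r_b = -c1b` toward the asymptotic leaf-area index
#' `L~_b = exp(-c0b/c1b)`.
#'
#' @param pairs Data frame from [extract_growth_pairs()] (columns `L0`,
#'   `dLdt`, `b`).
#' @param min_n Minimum observations per category to fit (default 3).
#' @return An object of class `growth_regression_fit`: a data frame with
#'   one row per fitted category and columns `b`, `n`, `c0`, `c0_se`,
#'   `c1`, `c1_se`, `r_b`, `L_tilde`.
#' @export
fit_growth_regression <- function(pairs, min_n = 3) {
  stopifnot(all(c("L0", "dLdt", "b") %in% names(pairs)))
  cats <- sort(unique(pairs$b))
  rows <- lapply(cats, function(b) {
    d <- pairs[pairs$b == b, ]
    if (nrow(d) < min_n || stats::var(log(d$L0)) == 0) {
      warning("insufficient data to fit browse category ", b,
              call. = FALSE)
      return(NULL)
    }
    fit <- stats::lm(dLdt ~ log(L0), data = d)
    cf <- summary(fit)$coefficients
    c0 <- cf[1, 1]; c1 <- cf[2, 1]
    data.frame(b = b, n = nrow(d),
               c0 = c0, c0_se = cf[1, 2],
               c1 = c1, c1_se = cf[2, 2],
               r_b = -c1,
               L_tilde = if (c1 < 0) exp(-c0 / c1) else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    stop("insufficient data: no browse category could be fitted",
         call. = FALSE)
  }
  class(out) <- c("growth_regression_fit", "data.frame")
  out
}

#' Simulated draws of per-category growth parameters
#'
#' Propagates regression uncertainty: for each draw index `j` and each
#' browse category `b`, coefficients `c0` and `c1` are sampled
#' independently from normal distributions with the fitted means and
#' standard errors, then transformed to `r = -c1` and
#' `L~ = exp(-c0/c1)`. Draws are paired across categories by index, so a
#' per-draw maximum across categories is well defined. Draws with
#' `c1 >= 0` leave `L~` undefined (non-saturating growth) and are
#' resampled; sampling aborts if fewer than `n_draws` valid draws are
#' found within `100 * n_draws` attempts per category.
#'
#' @param fit A [fit_growth_regression()] result.
#' @param n_draws Number of paired draws (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with columns `draw`, `b`, `r`, `L_tilde`.
#' @export
simulate_coefficient_draws <- function(fit, n_draws = 1000, seed = NULL) {
  stopifnot(inherits(fit, "growth_regression_fit"))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(fit)), function(i) {
    got <- 0L
    c0v <- numeric(0); c1v <- numeric(0)
    attempts <- 0L
    while (got < n_draws) {
      need <- n_draws - got
      attempts <- attempts + need
      if (attempts > 100 * n_draws) {
        stop("non-convergence: too many draws with non-negative slope in ",
             "browse category ", fit$b[i], call. = FALSE)
      }
      c0 <- stats::rnorm(need, fit$c0[i], fit$c0_se[i])
      c1 <- stats::rnorm(need, fit$c1[i], fit$c1_se[i])
      ok <- c1 < 0
      c0v <- c(c0v, c0[ok]); c1v <- c(c1v, c1[ok])
      got <- length(c1v)
    }
    data.frame(draw = seq_len(n_draws), b = fit$b[i],
               r = -c1v[seq_len(n_draws)],
               L_tilde = exp(-c0v[seq_len(n_draws)] / c1v[seq_len(n_draws)]))
  })
  do.call(rbind, rows)
}

#' Fit species growth parameters from simulated draws
#'
#' For each draw `j`, the reference leaf-area index `L~_j` is the maximum
#' of `L~_bj` across browse categories 0-2 (light browse at most), and the
#' relative asymptote is `tau~_bj = L~_bj / L~_j` for every category.
#' Leaf lifespan `a` and growth efficiency `e` are then estimated by
#' nonlinear least squares of
#' \deqn{r = (1/a)\,(1 - e^{-e\tilde\tau})}
#' over all `(b, j)` points (categories 3-4 contribute points but not the
#' per-draw maximum). The fit is bounded below at `(0.1, 0.1)` and
#' multi-started over initial `e` in `{2, 10, 50}` with `a` started at
#' `1/max(r)`.
#'
#' @param draws Data frame from [simulate_coefficient_draws()].
#' @return A list of class `species_growth_fit` with elements `a`, `e`,
#'   `fit` (the best `nls` object), `rss` and `n_points`.
#' @export
fit_species_growth <- function(draws) {
  stopifnot(all(c("draw", "b", "r", "L_tilde") %in% names(draws)))
  if (!any(draws$b %in% 0:2)) {
    stop("degenerate input: browse categories 0-2 are required to set the ",
         "reference leaf-area index", call. = FALSE)
  }
  ref <- draws[draws$b %in% 0:2, ]
  Lmax <- tapply(ref$L_tilde, ref$draw, max)
  tau <- draws$L_tilde / as.numeric(Lmax[as.character(draws$draw)])
  keep <- is.finite(tau) & tau > 0 & is.finite(draws$r)
  d <- data.frame(r = draws$r[keep], tau = pmin(tau[keep], 1))
  if (length(unique(round(d$tau, 10))) < 2) {
    stop("degenerate tau: all relative asymptotes equal; `e` is not ",
         "identifiable", call. = FALSE)
  }
  a0 <- 1 / max(d$r)
  best <- NULL
  for (e0 in c(2, 10, 50)) {
    fit <- tryCatch(
      stats::nls(r ~ (1 - exp(-e * tau)) / a, data = d,
                 start = list(a = max(a0, 0.2), e = e0),
                 algorithm = "port", lower = c(a = 0.1, e = 0.1),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = TRUE)),
      error = function(err) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("non-convergence: species growth fit failed from all starts",
         call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  structure(list(a = unname(cf["a"]), e = unname(cf["e"]),
                 fit = best$fit, rss = best$rss, n_points = nrow(d)),
            class = "species_growth_fit")
}

#' @export
print.species_growth_fit <- function(x, ...) {
  cat("Species growth fit\n")
  cat(sprintf("  leaf lifespan a     : %.3f yr\n", x$a))
  cat(sprintf("  growth efficiency e : %.3f\n", x$e))
  cat(sprintf("  points / RSS        : %d / %.4g\n", x$n_points, x$rss))
  invisible(x)
}

#' Calibrate species growth parameters from a tagged-tree panel
#'
#' Convenience chain: [extract_growth_pairs()] then
#' [fit_growth_regression()], [simulate_coefficient_draws()] and
#' [fit_species_growth()].
#'
#' @param observations Tagged-tree panel (see [extract_growth_pairs()]).
#' @param n_draws Number of coefficient draws (default 1000).
#' @param seed Optional integer seed.
#' @return A `species_growth_fit` list; the regression fit and draws are
#'   attached as elements `regression` and `draws`.
#' @export
calibrate_species <- function(observations, n_draws = 1000, seed = NULL) {
  pairs <- extract_growth_pairs(observations)
  reg <- fit_growth_regression(pairs)
  draws <- simulate_coefficient_draws(reg, n_draws = n_draws, seed = seed)
  out <- fit_species_growth(draws)
  out$regression <- reg
  out$draws <- draws
  out
}
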