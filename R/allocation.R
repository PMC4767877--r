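#' Distribute site-wide intake among a list of trees
#'
#' Splits a total intake `I_s_total` over trees in proportion to
#' `B^y_s`, the attainable foliar mass raised to the size-preference
#' exponent. Weights are computed in log space (rescaled by the largest
#' `B`) so that large exponents do not overflow, and are normalised to sum
#' to one exactly.
#'
#' @param B Vector of attainable foliar masses, kg; all `> 0`.
#' @param y_s Size-preference exponent (finite).
#' @param I_s_total Total intake to distribute over these trees, kg/year.
#' @return Vector of per-tree intakes, kg/year, summing to `I_s_total`.
#' @export
#' @examples
#' per_tree_intake(B = c(1, 2), y_s = 2, I_s_total = 5)  # 1 and 4
per_tree_intake <- function(B, y_s, I_s_total) {
  if (length(B) == 0L) {
    stop("empty tree list: at least one tree is required", call. = FALSE)
  }
  if (any(!is.finite(B)) || any(B <= 0)) {
    stop("invalid parameter: all `B` must be positive", call. = FALSE)
  }
  check_scalar(y_s, "y_s")
  check_scalar(I_s_total, "I_s_total", lower = 0)
  lw <- y_s * log(B)
  w <- exp(lw - max(lw))
  I_s_total * w / sum(w)
}

#' Moment of attainable foliar mass under the site DBH distribution
#'
#' Closed form for `E(B^y)` when DBH is lognormal and `B = 0.0406 *
#' DBH^1.53`: `B^y` is again lognormal, so
#' `E(B^y) = 0.0406^y * exp(1.53 y m + (1.53 y s)^2 / 2)` with `(m, s)`
#' the DBH meanlog/sdlog. Truncation of the fitted distribution at 10 cm
#' is ignored here, matching how the site fit treats the DBH sample.
#'
#' @param forest A [site_forest_state()] object.
#' @param y_s Size-preference exponent.
#' @return `E(B^y)` in kg^`y_s`.
#' @export
#' @examples
#' fo <- site_forest_state(300, 3, 0.4, 1)
#' expected_B_moment(fo, y_s = 1)
expected_B_moment <- function(forest, y_s) {
  stopifnot(inherits(forest, "site_forest_state"))
  check_scalar(y_s, "y_s")
  exp(y_s * log(0.0406) + 1.53 * y_s * forest$dbh_meanlog +
        (1.53 * y_s * forest$dbh_sdlog)^2 / 2)
}

#' Mean feeding-event rate on a tree
#'
#' Converts the size-biased share of site-wide intake falling on a tree of
#' attainable mass `B_tree` into feeding events per year:
#' \deqn{\mu = \frac{B^{y_s}}{n\,E(B^{y_s})} \cdot \frac{I_s}{f},}
#' with `n` the stem density (trees/ha) and `f` the feeding-event size
#' (kg). This is the mean of the negative-binomial annual event count.
#'
#' @param B_tree Attainable foliar mass(es) of the focal tree(s), kg.
#' @param params A [site_browse_params()] object.
#' @param forest A [site_forest_state()] object.
#' @param f Feeding-event size, kg; `> 0`.
#' @return Mean feeding events per year, one per tree.
#' @export
#' @examples
#' pa <- site_browse_params(I_s = 58.4, y_s = 0, h_s = 0.3)
#' fo <- site_forest_state(100, 3, 0.4, 1)
#' feeding_rate(1, pa, fo, f = 0.0584)  # 10 events/yr
feeding_rate <- function(B_tree, params, forest, f) {
  stopifnot(inherits(params, "site_browse_params"),
            inherits(forest, "site_forest_state"))
  if (any(!is.finite(B_tree)) || any(B_tree <= 0)) {
    stop("invalid parameter: `B_tree` must be positive", call. = FALSE)
  }
  check_scalar(f, "f", lower = 0, strict = TRUE)
  if (forest$density_n <= 0) {
    stop("invalid parameter: zero tree density", call. = FALSE)
  }
  if (params$I_s == 0) return(rep(0, length(B_tree)))
  exp(params$y_s * log(B_tree) - log(forest$density_n) -
        log(expected_B_moment(forest, params$y_s)) +
        log(params$I_s) - log(f))
}

#' Annual probability that feeding exceeds a threshold
#'
#' Tail probability of a negative-binomial annual feeding-event count with
#' mean `mu` and dispersion `h_s` exceeding `threshold_events`. Evaluated
#' through the regularized incomplete beta function with a continuous
#' threshold argument,
#' \deqn{P = I_x(t + 1, h_s), \quad x = \mu/(h_s + \mu),}
#' which at integer `t = K` equals the exact tail `P(count > K)` of the
#' negative-binomial distribution with `p = h_s/(h_s + mu)` (the pmf-sum
#' oracle fixes this orientation of the incomplete beta). Between integer
#' thresholds the expression interpolates smoothly.
#'
#' @param mu Mean feeding events per year; `>= 0`. Vectorised.
#' @param h_s Dispersion; `> 0`.
#' @param threshold_events Event-count threshold(s); `>= 0`, not
#'   necessarily integer.
#' @return Probability(ies) in `[0, 1]`, non-decreasing in `mu` and
#'   non-increasing in `threshold_events`.
#' @export
#' @examples
#' annual_mortality_prob(mu = 5, h_s = 0.3, threshold_events = 10)
annual_mortality_prob <- function(mu, h_s, threshold_events) {
  if (any(!is.finite(mu)) || any(mu < 0)) {
    stop("invalid parameter: `mu` must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(h_s)) || any(h_s <= 0)) {
    stop("invalid parameter: `h_s` must be positive", call. = FALSE)
  }
  if (any(!is.finite(threshold_events)) || any(threshold_events < 0)) {
    stop("invalid parameter: `threshold_events` must be non-negative",
         call. = FALSE)
  }
  stats::pbeta(mu / (h_s + mu), threshold_events + 1, h_s)
}

#' Annual mortality probability of a tree
#'
#' Composes the mortality threshold with the feeding model: a tree with
#' canopy fraction `tau` at the start of the year dies if its annual
#' feeding-event count exceeds \eqn{\Im(\tau)/f}. The event count is
#' negative binomial with mean from [feeding_rate()] and dispersion
#' `h_s`, so the death probability is [annual_mortality_prob()] at that
#' threshold.
#'
#' @param tau Canopy fraction(s) in `[0, 1]`.
#' @param B Attainable foliar mass(es), kg (recycled against `tau`).
#' @param sp A [species_params()] object.
#' @param params A [site_browse_params()] object.
#' @param forest A [site_forest_state()] object.
#' @return Annual probability(ies) of death in `[0, 1]`.
#' @export
#' @examples
#' sp <- species_params("WEIRAC", 4.53, 16.6, 3.3e-5, 0.08)
#' pa <- site_browse_params(I_s = 293, y_s = 2.62, h_s = 0.03)
#' fo <- site_forest_state(308, 3.3, 0.35, 1.24)
#' tree_mortality(tau = 0.5, B = attainable_foliage(30), sp, pa, fo)
tree_mortality <- function(tau, B, sp, params, forest) {
  sp <- as_species_params(sp)
  mu <- feeding_rate(B, params, forest, sp$f)
  thr <- mortality_threshold(tau, sp, B) / sp$f
  annual_mortality_prob(mu, params$h_s, thr)
}
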