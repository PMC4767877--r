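#' Rate of change of the canopy fraction
#'
#' Annual rate of change of `tau`, the proportion of attainable foliar mass
#' currently held in the canopy. Production saturates at `1/a` as `tau`
#' approaches 1, with saturation speed set by the growth efficiency `e`;
#' non-herbivore losses (abscission) remove foliage at rate `tau/a`; and
#' herbivores remove intake `I` (kg/year) from a tree with attainable mass
#' `B` (kg):
#'
#' \deqn{d\tau/dt = (1/a)\,(1 - e^{-e\tau}) - \tau/a - I/B.}
#'
#' @param tau Canopy fraction(s) in `[0, 1]`.
#' @param I Herbivore intake rate(s) from the tree, kg dry weight/year,
#'   `>= 0`.
#' @param sp A [species_params()] object (or list with `a`, `e`).
#' @param B Attainable foliar mass, kg; `> 0`.
#' @return Rate(s) of change of `tau` per year.
#' @seealso [intake_threshold()], [mortality_threshold()],
#'   [equilibrium_tau()], [integrate_foliage()]
#' @export
#' @examples
#' sp <- species_params("WEIRAC", 4.53, 16.6, 3.3e-5, 0.08)
#' foliar_rate(tau = 0.5, I = 0, sp = sp, B = 1)
foliar_rate <- function(tau, I, sp, B) {
  sp <- as_species_params(sp)
  if (any(!is.finite(tau)) || any(tau < 0) || any(tau > 1)) {
    stop("invalid parameter: `tau` must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(B)) || any(B <= 0)) {
    stop("invalid parameter: `B` must be positive", call. = FALSE)
  }
  if (any(!is.finite(I)) || any(I < 0)) {
    stop("invalid parameter: `I` must be non-negative", call. = FALSE)
  }
  (1 - exp(-sp$e * tau)) / sp$a - tau / sp$a - I / B
}

#' Maximum sustainable herbivore intake
#'
#' The intake threshold \eqn{I' = (B/(a e)) (e + \log(1/e) - 1)}: the
#' largest constant herbivore intake under which the tree can hold an
#' equilibrium canopy. Above `I'` the canopy collapses and the tree
#' ultimately dies. As a proportion of attainable mass, `I'/B` depends only
#' on `a` and `e` and measures a species' resilience to browse.
#'
#' @inheritParams foliar_rate
#' @param B Attainable foliar mass, kg (default 1, so that the value is the
#'   proportion `I'/B`).
#' @return Threshold intake, kg/year (or proportion per year when `B = 1`).
#' @export
#' @examples
#' sp <- species_params("WEIRAC", 4.53, 16.6, 3.3e-5, 0.08)
#' intake_threshold(sp)       # 0.170: 17% of the canopy per year
intake_threshold <- function(sp, B = 1) {
  sp <- as_species_params(sp)
  if (any(!is.finite(B)) || any(B <= 0)) {
    stop("invalid parameter: `B` must be positive", call. = FALSE)
  }
  B / (sp$a * sp$e) * (sp$e + log(1 / sp$e) - 1)
}

#' Intake rate that kills a tree within one year
#'
#' The mortality threshold
#' \eqn{\Im(\tau) = B (1/a - e^{-e\tau}/a - \tau/a + \tau)}: a tree whose
#' canopy fraction is `tau` at the start of the year dies within that year
#' if its intake rate exceeds this value. \eqn{\Im(0) = 0} (a fully
#' defoliated tree dies under any browse) and \eqn{\Im} increases
#' monotonically with `tau` for `e > 1`.
#'
#' @inheritParams foliar_rate
#' @return Threshold intake(s), kg/year.
#' @export
#' @examples
#' sp <- species_params("WEIRAC", 4.53, 16.6, 3.3e-5, 0.08)
#' mortality_threshold(c(0, 0.5, 1), sp, B = 1)
mortality_threshold <- function(tau, sp, B = 1) {
  sp <- as_species_params(sp)
  if (any(!is.finite(tau)) || any(tau < 0) || any(tau > 1)) {
    stop("invalid parameter: `tau` must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(B)) || any(B <= 0)) {
    stop("invalid parameter: `B` must be positive", call. = FALSE)
  }
  B * (1 / sp$a - exp(-sp$e * tau) / sp$a - tau / sp$a + tau)
}

#' Equilibrium canopy fraction under constant intake
#'
#' Finds the stable (largest) root `tau*` in `(0, 1]` of [foliar_rate()]
#' for a constant intake `I`. The rate function attains its maximum over
#' `tau` at `log(e)/e`, where its value is `(I' - I)/B`; for `I` below the
#' intake threshold the stable equilibrium lies between that point and 1
#' and is located by [stats::uniroot()].
#'
#' @inheritParams foliar_rate
#' @param I Constant intake, kg/year.
#' @param tol Root-finding tolerance on `tau`.
#' @return The equilibrium canopy fraction, or `NA_real_` when
#'   `I > intake_threshold(sp, B)` (no equilibrium: the canopy collapses).
#' @export
#' @examples
#' sp <- species_params("WEIRAC", 4.53, 16.6, 3.3e-5, 0.08)
#' equilibrium_tau(sp, B = 1, I = 0.5 * intake_threshold(sp))
#' equilibrium_tau(sp, B = 1, I = 1.1 * intake_threshold(sp))  # NA
equilibrium_tau <- function(sp, B = 1, I = 0, tol = 1e-12) {
  sp <- as_species_params(sp)
  check_scalar(I, "I", lower = 0)
  check_scalar(B, "B", lower = 0, strict = TRUE)
  Iprime <- intake_threshold(sp, B)
  if (I > Iprime) {
    return(NA_real_)
  }
  tau_c <- log(sp$e) / sp$e   # argmax of the rate function
  g <- function(tau) foliar_rate(tau, I, sp, B)
  if (I == Iprime) {
    return(tau_c)
  }
  upper <- 1
  if (g(upper) >= 0) return(1)  # only at I = 0 to within exp(-e)
  stats::uniroot(g, lower = tau_c, upper = upper, tol = tol)$root
}

#' Integrate the foliage dynamics
#'
#' Forward integration of the canopy fraction under a constant intake rate,
#' with adaptive step control (deSolve, `lsoda`, relative tolerance 1e-8).
#' `tau` is clamped to `[0, 1]` inside the right-hand side; once the canopy
#' is exhausted the state may continue below zero (interpreted as death).
#'
#' @inheritParams foliar_rate
#' @param tau0 Initial canopy fraction.
#' @param times Numeric vector of output times (years), starting at the
#'   initial time.
#' @return A data frame with columns `time` and `tau`.
#' @export
#' @examples
#' sp <- species_params("WEIRAC", 4.53, 16.6, 3.3e-5, 0.08)
#' integrate_foliage(0.8, I = 0.05, sp = sp, B = 1, times = 0:5)
integrate_foliage <- function(tau0, I, sp, B, times = c(0, 1)) {
  sp <- as_species_params(sp)
  check_scalar(tau0, "tau0", lower = 0, upper = 1)
  rhs <- function(t, y, parms) {
    tau <- min(max(y[1], 0), 1)
    list(foliar_rate(tau, I, sp, B))
  }
  out <- deSolve::ode(y = c(tau = tau0), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  data.frame(time = out[, "time"], tau = unname(out[, "tau"]))
}

#' Convert canopy fraction to Foliage Cover Index
#'
#' The Foliage Cover Index (FCI) is the proportion of light occluded by
#' leaves looking up through the crown. With `L_s` the leaf-area index of
#' the unbrowsed tree, overlap of leaves gives the saturating relation
#' `FCI = 1 - exp(-tau * L_s)`.
#'
#' @param tau Canopy fraction(s) in `[0, 1]`.
#' @param L_s Unbrowsed leaf-area index, `> 0`.
#' @return FCI value(s) in `[0, 1)`.
#' @export
#' @examples
#' fci_from_tau(1, 2.303)  # 0.900
fci_from_tau <- function(tau, L_s) {
  if (any(!is.finite(tau)) || any(tau < 0) || any(tau > 1)) {
    stop("invalid parameter: `tau` must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(L_s)) || any(L_s <= 0)) {
    stop("invalid parameter: `L_s` must be positive", call. = FALSE)
  }
  1 - exp(-tau * L_s)
}

#' Convert Foliage Cover Index to canopy fraction
#'
#' Inverts [fci_from_tau()]: `tau = -log(1 - FCI)/L_s`, capped at 1.
#' Observed FCI can exceed the cover implied by the site-mean unbrowsed
#' leaf-area index, which would put `tau` above 1; since `tau` is defined
#' as a proportion of attainable mass, values are capped at 1 to keep the
#' foliage model in its stated domain.
#'
#' @param fci FCI value(s) in `[0, 1)`.
#' @param L_s Unbrowsed leaf-area index, `> 0`.
#' @return Canopy fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' tau_from_fci(0.5, 1.0)          # 0.693
#' tau_from_fci(0.95, 1.0)         # capped at 1
tau_from_fci <- function(fci, L_s) {
  if (any(!is.finite(fci)) || any(fci < 0) || any(fci >= 1)) {
    stop("invalid parameter: `fci` must lie in [0, 1)", call. = FALSE)
  }
  if (any(!is.finite(L_s)) || any(L_s <= 0)) {
    stop("invalid parameter: `L_s` must be positive", call. = FALSE)
  }
  pmin(1, -log(1 - fci) / L_s)
}

#' Attainable foliar mass from stem diameter
#'
#' Allometric relation for native New Zealand trees:
#' `B = 0.0406 * DBH^1.53` with DBH in cm and `B` in kg dry weight.
#'
#' @param dbh Diameter(s) at breast height, cm; `> 0`.
#' @return Attainable foliar mass(es), kg dry weight.
#' @export
#' @examples
#' attainable_foliage(c(10, 20, 40))
attainable_foliage <- function(dbh) {
  if (any(!is.finite(dbh)) || any(dbh <= 0)) {
    stop("invalid parameter: `dbh` must be positive", call. = FALSE)
  }
  0.0406 * dbh^1.53
}

# FBI category -> browsed-leaf proportion intervals. Category 0 allows
# <1% actual browse (observer error); the remaining bins follow the field
# protocol: 1 light (<=25%), 2 moderate (26-50%), 3 heavy (51-75%),
# 4 severe (>75%).
fbi_bins <- data.frame(
  category = 0:4,
  lower    = c(0, 0.01, 0.25, 0.50, 0.75),
  upper    = c(0.01, 0.25, 0.50, 0.75, 1),
  midpoint = c(0.005, 0.13, 0.375, 0.625, 0.875)
)

#' Foliar Browse Index category to browsed-leaf proportion
#'
#' Maps an FBI category (0-4) to the interval of the proportion of foliage
#' browsed, and its midpoint. The intact fraction is `omega = 1 - fraction`
#' (FBI measures `1 - omega`). Category 0 covers browse below 1% (an
#' allowance for observer error when actual browse is very low).
#'
#' @param fbi_category Integer vector with values in `0:4`.
#' @return A data frame with columns `category`, `lower`, `upper`,
#'   `midpoint` and `omega_midpoint`.
#' @export
#' @examples
#' fbi_to_browse_fraction(0:4)
fbi_to_browse_fraction <- function(fbi_category) {
  if (any(!fbi_category %in% 0:4)) {
    stop("invalid category: FBI categories must be integers 0-4",
         call. = FALSE)
  }
  out <- fbi_bins[match(fbi_category, fbi_bins$category), , drop = FALSE]
  rownames(out) <- NULL
  out$omega_midpoint <- 1 - out$midpoint
  out
}

#' Foliage Cover Index categories
#'
#' FCI is recorded in 10% classes. The package codes them as integers
#' 0-10: category 0 means a bare crown (FCI = 0, excluded from growth-rate
#' calculations), and category `k >= 1` means FCI in `((k-1)/10, k/10]`,
#' with midpoint `(k - 0.5)/10`. `fci_category()` bins a continuous FCI;
#' `fci_category_midpoint()` returns the class midpoint used when a
#' category must become a number (unbiased under within-class uniformity).
#'
#' @param fci Continuous FCI value(s) in `[0, 1]`.
#' @param category Integer category code(s) in `0:10`.
#' @return Integer categories, or numeric midpoints.
#' @export
#' @examples
#' fci_category(c(0, 0.07, 0.55, 1))
#' fci_category_midpoint(1:10)
fci_category <- function(fci) {
  if (any(!is.finite(fci)) || any(fci < 0) || any(fci > 1)) {
    stop("invalid parameter: `fci` must lie in [0, 1]", call. = FALSE)
  }
  as.integer(ceiling(fci * 10))
}

#' @rdname fci_category
#' @export
fci_category_midpoint <- function(category) {
  if (any(!category %in% 0:10)) {
    stop("invalid category: FCI categories must be integers 0-10",
         call. = FALSE)
  }
  ifelse(category == 0, 0, (category - 0.5) / 10)
}
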