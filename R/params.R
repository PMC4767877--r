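#' Species growth and feeding parameters
#'
#' Container for the per-species constants of the foliage model: average leaf
#' lifespan `a` (years), growth efficiency `e` (dimensionless, must exceed 1
#' so that the intake threshold is positive), feeding-event size `f` (kg dry
#' weight of foliage removed from one leaf in one herbivore visit) and the
#' proportion `p_diet` of the total herbivore diet made up by this species.
#'
#' @param code Short character species code (e.g. `"WEIRAC"`).
#' @param a Average leaf lifespan in years; `a > 0`.
#' @param e Growth efficiency; must satisfy `e > 1` (otherwise foliage
#'   production can never balance losses and the intake threshold would be
#'   non-positive).
#' @param f Feeding-event size, kg dry weight; `f > 0`.
#' @param p_diet Proportion of total herbivore diet, in `[0, 1]`.
#'
#' @return An object of class `species_params`.
#' @seealso [intake_threshold()], [mortality_threshold()],
#'   [read_species_params()]
#' @export
#' @examples
#' kamahi <- species_params("WEIRAC", a = 4.53, e = 16.6,
#'                          f = 3.3e-5, p_diet = 0.08)
#' intake_threshold(kamahi)
species_params <- function(code, a, e, f, p_diet) {
  stopifnot(is.character(code), length(code) == 1L)
  check_scalar(a, "a", lower = 0, strict = TRUE)
  check_scalar(e, "e")
  if (e <= 1) {
    stop("invalid parameter: growth efficiency `e` must exceed 1 (got ",
         format(e), "); the intake threshold e + log(1/e) - 1 would be ",
         "non-positive", call. = FALSE)
  }
  check_scalar(f, "f", lower = 0, strict = TRUE)
  check_scalar(p_diet, "p_diet", lower = 0, upper = 1)
  structure(list(code = code, a = a, e = e, f = f, p_diet = p_diet),
            class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat("Species parameters [", x$code, "]\n", sep = "")
  cat(sprintf("  leaf lifespan a      : %.3g yr\n", x$a))
  cat(sprintf("  growth efficiency e  : %.4g\n", x$e))
  cat(sprintf("  intake threshold I'/B: %.3f\n", intake_threshold(x)))
  cat(sprintf("  feeding event f      : %.3g kg\n", x$f))
  cat(sprintf("  diet proportion      : %.2f\n", x$p_diet))
  invisible(x)
}

#' Site-level browse parameters
#'
#' The three parameters governing how site-wide herbivore offtake is spread
#' over the trees of one species at one site: total intake `I_s` (kg dry
#' weight/ha/year), size-preference exponent `y_s` (0 = size-independent,
#' 1 = proportional to attainable foliar mass, >1 = supra-proportional
#' preference for large trees), and negative-binomial dispersion `h_s`
#' (small values mean browse is concentrated on a few trees).
#'
#' @param I_s Site-wide intake, kg/ha/year; `I_s >= 0`.
#' @param y_s Size-preference exponent (finite).
#' @param h_s Negative-binomial dispersion; `h_s > 0`.
#' @return An object of class `site_browse_params`.
#' @export
#' @examples
#' site_browse_params(I_s = 293, y_s = 2.62, h_s = 0.03)
site_browse_params <- function(I_s, y_s, h_s) {
  check_scalar(I_s, "I_s", lower = 0)
  check_scalar(y_s, "y_s")
  check_scalar(h_s, "h_s", lower = 0, strict = TRUE)
  structure(list(I_s = I_s, y_s = y_s, h_s = h_s),
            class = "site_browse_params")
}

#' @export
print.site_browse_params <- function(x, ...) {
  cat("Site browse parameters\n")
  cat(sprintf("  intake I_s     : %.4g kg/ha/yr\n", x$I_s))
  cat(sprintf("  size pref. y_s : %.3g\n", x$y_s))
  cat(sprintf("  dispersion h_s : %.3g\n", x$h_s))
  invisible(x)
}

#' Site forest state for one species
#'
#' Distributional description of the focal species at a site: stem density
#' (trees/ha with DBH > 10 cm), a lognormal DBH distribution (cm scale) and
#' a normal distribution of the unbrowsed leaf-area index.
#'
#' @param density_n Trees per hectare (DBH > 10 cm); `> 0`.
#' @param dbh_meanlog,dbh_sdlog Lognormal parameters of DBH in cm;
#'   `dbh_sdlog >= 0`.
#' @param L_s_mean,L_s_sd Normal parameters of the unbrowsed leaf-area index
#'   (m^2 foliage per m^2 crown); `L_s_mean > 0`, `L_s_sd >= 0`.
#' @return An object of class `site_forest_state`.
#' @export
#' @examples
#' site_forest_state(density_n = 308, dbh_meanlog = 3.3, dbh_sdlog = 0.35,
#'                   L_s_mean = 1.24, L_s_sd = 0.3)
site_forest_state <- function(density_n, dbh_meanlog, dbh_sdlog,
                              L_s_mean, L_s_sd = 0) {
  check_scalar(density_n, "density_n", lower = 0, strict = TRUE)
  check_scalar(dbh_meanlog, "dbh_meanlog")
  check_scalar(dbh_sdlog, "dbh_sdlog", lower = 0)
  check_scalar(L_s_mean, "L_s_mean", lower = 0, strict = TRUE)
  check_scalar(L_s_sd, "L_s_sd", lower = 0)
  structure(list(density_n = density_n, dbh_meanlog = dbh_meanlog,
                 dbh_sdlog = dbh_sdlog, L_s_mean = L_s_mean,
                 L_s_sd = L_s_sd),
            class = "site_forest_state")
}

#' @export
print.site_forest_state <- function(x, ...) {
  cat("Site forest state\n")
  cat(sprintf("  density        : %.4g trees/ha (DBH > 10 cm)\n", x$density_n))
  cat(sprintf("  DBH lognormal  : meanlog %.3f, sdlog %.3f (mean %.1f cm)\n",
              x$dbh_meanlog, x$dbh_sdlog,
              exp(x$dbh_meanlog + x$dbh_sdlog^2 / 2)))
  cat(sprintf("  leaf area L_s  : mean %.3f, sd %.3f\n",
              x$L_s_mean, x$L_s_sd))
  invisible(x)
}

# internal scalar validator
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("invalid parameter: `", name, "` must be a finite numeric scalar",
         call. = FALSE)
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) {
    stop("invalid parameter: `", name, "` = ", format(x),
         " is outside its allowed range", call. = FALSE)
  }
  invisible(x)
}

as_species_params <- function(x) {
  if (inherits(x, "species_params")) return(x)
  if (is.list(x) && all(c("a", "e", "f") %in% names(x))) {
    return(species_params(code = if (is.null(x$code)) "SP" else x$code,
                          a = x$a, e = x$e, f = x$f,
                          p_diet = if (is.null(x$p_diet)) 1 else x$p_diet))
  }
  stop("cannot interpret `sp` as species parameters", call. = FALSE)
}
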