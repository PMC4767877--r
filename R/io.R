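#' Read the species parameter table
#'
#' Reads a CSV with header `code,a,e,f,p_diet` and validates every row
#' against the parameter invariants (`a > 0`, `e > 1`, `f > 0`,
#' `p_diet` in `[0, 1]`). The package ships a table of fitted values for
#' five possum-preferred New Zealand tree species as
#' `system.file("extdata", "species_params.csv", package = "treebrowse")`,
#' which is the default.
#'
#' @param path Path to the CSV (default: the packaged table).
#' @return Data frame of class `species_params_table`; use
#'   [get_species_params()] to extract one species.
#' @export
#' @examples
#' tab <- read_species_params()
#' get_species_params(tab, "SCHDIG")
read_species_params <- function(path = system.file("extdata",
                                                   "species_params.csv",
                                                   package = "treebrowse")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("code", "a", "e", "f", "p_diet")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop("schema mismatch in ", path, ": missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(d))) {
    species_params(d$code[i], d$a[i], d$e[i], d$f[i], d$p_diet[i])
  }
  class(d) <- c("species_params_table", "data.frame")
  d
}

#' @rdname read_species_params
#' @param table A `species_params_table`.
#' @param code Species code to extract.
#' @export
get_species_params <- function(table, code) {
  i <- match(code, table$code)
  if (is.na(i)) {
    stop("unknown species code: ", code, call. = FALSE)
  }
  species_params(table$code[i], table$a[i], table$e[i], table$f[i],
                 table$p_diet[i])
}

validate_rows <- function(d, path, checks) {
  bad <- character(0)
  for (nm in names(checks)) {
    ok <- checks[[nm]](d)
    if (any(!ok)) {
      lines <- which(!ok) + 1L  # header is line 1
      bad <- c(bad, paste0(nm, " (line",
                           if (length(lines) > 1) "s" else "", " ",
                           paste(utils::head(lines, 10), collapse = ", "),
                           if (length(lines) > 10) ", ..." else "", ")"))
    }
  }
  if (length(bad)) {
    stop("validation failure in ", path, ":\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  }
}

#' Read a tagged-tree observation table
#'
#' Reads and validates the panel CSV with columns `site`, `species_code`,
#' `tree_id`, `visit_time` (years), `dbh_cm`, `fci_category` (0-10),
#' `fbi_category` (0-4) and `alive` (logical/0-1). Out-of-range
#' categories and non-positive DBH are reported with their line numbers.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame.
#' @export
read_observations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("site", "species_code", "tree_id", "visit_time", "dbh_cm",
           "fci_category", "fbi_category", "alive")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop("schema mismatch in ", path, ": missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  validate_rows(d, path, list(
    "non-positive DBH" = function(x) is.finite(x$dbh_cm) & x$dbh_cm > 0,
    "FCI category out of range 0-10" =
      function(x) x$fci_category %in% 0:10,
    "FBI category out of range 0-4" =
      function(x) x$fbi_category %in% 0:4,
    "non-finite visit time" = function(x) is.finite(x$visit_time)
  ))
  d$alive <- as.logical(d$alive)
  d
}

#' Read a plot-survey table
#'
#' Reads and validates the plot CSV with columns `plot_id`, `radius_m`,
#' `species_code`, `dbh_cm`, `fci_category` (one row per stem).
#'
#' @param path Path to the CSV file.
#' @return Validated data frame.
#' @export
read_plot_survey <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("plot_id", "radius_m", "species_code", "dbh_cm",
           "fci_category")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop("schema mismatch in ", path, ": missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  validate_rows(d, path, list(
    "non-positive DBH" = function(x) is.finite(x$dbh_cm) & x$dbh_cm > 0,
    "non-positive radius" =
      function(x) is.finite(x$radius_m) & x$radius_m > 0,
    "FCI category out of range 0-10" =
      function(x) x$fci_category %in% 0:10
  ))
  d
}

#' Write a site fit report
#'
#' Serialises a `site_fit` (plus provenance: seed, package version) as
#' JSON.
#'
#' @param fit A `site_fit` object.
#' @param path Output path (`.json`).
#' @param seed Seed used upstream, recorded for reproducibility.
#' @return `path`, invisibly.
#' @export
write_site_fit <- function(fit, path, seed = NA) {
  stopifnot(inherits(fit, "site_fit"))
  obj <- list(estimate = as.list(fit$estimate),
              lower95 = as.list(fit$lower),
              upper95 = as.list(fit$upper),
              logLik = fit$logLik, convergence = fit$convergence,
              boundary = fit$boundary, n_trees = fit$n_trees,
              provenance = list(package = "treebrowse",
                                version = as.character(
                                  utils::packageVersion("treebrowse")),
                                seed = seed))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full browse-model pipeline
#'
#' Orchestrates the analysis stages over files on disk: read inputs,
#' calibrate the site (and optionally the species growth parameters from
#' the same panel), predict mortality by FCI class and site-wide, and
#' compute the management curve. Results are written under `out_dir` as
#' `site_fit.json`, `mortality_by_fci.csv`, `management_curve.csv` and
#' `summary.json` (which carries provenance: input MD5 hashes, seed,
#' package version). Identical config and seed give byte-identical
#' outputs.
#'
#' @param config A named list, or the path to a YAML file, with fields:
#'   `species_table` (optional path; default packaged table),
#'   `observations` (path to tagged-tree CSV), `plots` (path to
#'   plot-survey CSV), `species` (code), `site` (site label in the
#'   observations), `calibrate_species` (logical, default `FALSE`),
#'   `n_plots` (total plots surveyed; default distinct plot ids),
#'   `threshold` (annual mortality target, default 0.005), `tci_grid`
#'   (default `0:50`), `n_dbh_draws` (default 10000), `T_years`
#'   (study period for expected deaths, default 5), `seed` (default 1),
#'   `out_dir` (output directory, created if needed).
#' @return Invisibly, a list with elements `site_fit`, `per_category`,
#'   `sitewide`, `curve`, `expected_deaths` and (optionally)
#'   `species_fit`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  need <- c("observations", "plots", "species", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop("pipeline config is missing fields: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(list(threshold = 0.005, tci_grid = 0:50,
                                n_dbh_draws = 10000, seed = 1,
                                T_years = 5,
                                calibrate_species = FALSE), config)
  check_scalar(cfg$threshold, "threshold", lower = 0, upper = 1)
  for (f in c("observations", "plots")) {
    if (!file.exists(cfg[[f]])) {
      stop("pipeline stage `read`: input file not found: ", cfg[[f]],
           call. = FALSE)
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(err) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(err),
           call. = FALSE)
    })
  }

  tab <- if (is.null(cfg$species_table)) read_species_params() else
    read_species_params(cfg$species_table)
  sp <- get_species_params(tab, cfg$species)
  obs <- stage("read", read_observations(cfg$observations))
  plots <- stage("read", read_plot_survey(cfg$plots))
  if (!is.null(cfg$site)) obs <- obs[obs$site == cfg$site, ]
  obs <- obs[obs$species_code == cfg$species, ]
  if (nrow(obs) == 0) {
    stop("pipeline stage `read` failed: no observations for species ",
         cfg$species, call. = FALSE)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  if (isTRUE(cfg$calibrate_species)) {
    results$species_fit <- stage("calibrate-species",
      calibrate_species(obs, seed = cfg$seed))
  }

  results$site_fit <- stage("calibrate-site", {
    n_plots <- if (is.null(cfg$n_plots))
      length(unique(plots$plot_id)) else cfg$n_plots
    dens <- estimate_density(plots, cfg$species, n_plots = n_plots,
                             radius_m = plots$radius_m[1])
    t1 <- obs[obs$visit_time == min(obs$visit_time), ]
    dfit <- fit_dbh_distribution(t1$dbh_cm[t1$dbh_cm > 10])
    unbrowsed <- t1$fci_category[t1$fbi_category == 0 &
                                   t1$fci_category > 0]
    lfit <- fit_leaf_area(fci_category_midpoint(unbrowsed))
    forest <- site_forest_state(dens, dfit$meanlog, dfit$sdlog,
                                lfit$L_s_mean, lfit$L_s_sd)
    B <- attainable_foliage(t1$dbh_cm)
    fit <- fit_site_params(B, t1$fbi_category > 0, forest, sp$f)
    list(fit = fit, forest = forest, t1 = t1)
  })
  fit <- results$site_fit$fit
  forest <- results$site_fit$forest
  t1 <- results$site_fit$t1
  write_site_fit(fit, file.path(cfg$out_dir, "site_fit.json"),
                 seed = cfg$seed)

  results$per_category <- stage("predict",
    mortality_by_fci_category(sp, fit, forest,
                              n_dbh_draws = cfg$n_dbh_draws,
                              seed = cfg$seed))
  w <- tabulate(pmax(t1$fci_category, 1), nbins = 10)
  w <- w / sum(w)
  results$sitewide <- sitewide_mortality(results$per_category, w)
  results$expected_deaths <- expected_deaths(results$sitewide[["mean"]],
                                             nrow(t1), cfg$T_years)
  utils::write.csv(results$per_category,
                   file.path(cfg$out_dir, "mortality_by_fci.csv"),
                   row.names = FALSE)

  results$curve <- stage("manage",
    mortality_vs_tci_curve(sp, fit, forest, weights = w,
                           tci_grid = cfg$tci_grid,
                           threshold = cfg$threshold,
                           n_dbh_draws = cfg$n_dbh_draws,
                           seed = cfg$seed))
  utils::write.csv(results$curve$curve,
                   file.path(cfg$out_dir, "management_curve.csv"),
                   row.names = FALSE)

  summary <- list(
    species = cfg$species, site = cfg$site,
    sitewide_mortality = as.list(results$sitewide),
    expected_deaths = results$expected_deaths,
    n_trees = nrow(t1), T_years = cfg$T_years,
    tci_goal = results$curve$tci_goal,
    tci_goal_attainable = results$curve$attainable,
    threshold = cfg$threshold,
    site_fit = as.list(fit$estimate),
    provenance = list(
      package = "treebrowse",
      version = as.character(utils::packageVersion("treebrowse")),
      seed = cfg$seed,
      inputs = list(
        observations = unname(tools::md5sum(cfg$observations)),
        plots = unname(tools::md5sum(cfg$plots)))))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
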