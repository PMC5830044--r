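# Configuration files, density records, synthetic fixtures, and the
# run-a-city driver.

#' Geometric mean density from density records
#'
#' Published cat-density records are strongly right-skewed; their logs are
#' approximately normal, so the equilibrium density is taken as the
#' exponentiated mean of the natural-log densities (the geometric mean).
#'
#' @param density Vector of densities (cats/ha), or a data frame with a
#'   `density_cats_per_ha` column.
#' @return Geometric mean density in cats/ha.
#' @examples
#' mean_density(c(0.1, 10)) # 1
#' @export
mean_density <- function(density) {
  if (is.data.frame(density)) {
    stopifnot("density_cats_per_ha" %in% names(density))
    density <- density$density_cats_per_ha
  }
  if (length(density) < 1) stop("at least one density record is required")
  if (any(!is.finite(density)) || any(density <= 0))
    stop("densities must be positive and finite")
  exp(mean(log(density)))
}

#' Generate synthetic cat-density records
#'
#' Draws reproducible lognormal density records emulating a compilation of
#' published density studies. With `log_sd = 0` every record equals
#' `exp(log_mean)`.
#'
#' @param n Number of records.
#' @param log_mean Mean of log density.
#' @param log_sd Standard deviation of log density.
#' @param class Population class label (`"freeroaming"` or `"feral"`).
#' @param seed Integer seed; the same seed reproduces the same records.
#' @return Data frame with columns `density_cats_per_ha`, `class`, `source`.
#' @export
generate_density_fixtures <- function(n, log_mean, log_sd,
                                      class = c("freeroaming", "feral"),
                                      seed = 1L) {
  class <- match.arg(class)
  stopifnot(n >= 1, log_sd >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  data.frame(
    density_cats_per_ha = stats::rlnorm(n, meanlog = log_mean, sdlog = log_sd),
    class = class,
    source = sprintf("synthetic-%s-%03d", class, seq_len(n)),
    stringsAsFactors = FALSE
  )
}

#' Read density records from CSV
#'
#' @param path CSV with columns `density_cats_per_ha`, `class`, `source`.
#' @return Data frame of density records.
#' @export
read_density_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("density_cats_per_ha", "class")
  missing <- setdiff(needed, names(rec))
  if (length(missing))
    stop("density CSV lacks column(s): ", paste(missing, collapse = ", "))
  if (any(rec$density_cats_per_ha <= 0))
    stop("densities must be positive")
  rec
}

# Keys allowed at the top level of a city config file.
config_keys <- c("name", "latitude", "dwellings", "area_ha",
                 "freeroaming_density", "feral_density",
                 "shelter_capacity", "mean_length_of_stay",
                 "prop_dwellings_with_cats", "cats_per_dwelling",
                 "density_dependence", "solver", "sensitivity", "overrides")

#' Read a city configuration file
#'
#' City configurations are YAML with keys `latitude`, `dwellings`,
#' `area_ha`, optional density/shelter settings, an optional
#' `density_dependence` block (`variant`, `juvenile_rule`,
#' `sterilization_preset`, `density_interpretation`), optional `solver`
#' (`max_iter`, `tol`) and `sensitivity` (`method`, `delta`) blocks, and an
#' optional `overrides` map of lower-level parameters (names as in
#' [parameter_names()]). Unknown keys are an error, which guards against
#' silently ignored typos.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `city` (a [city_inputs()] object), `name`,
#'   `dd` (density-dependence choices), `solver`, `sensitivity`, and
#'   `overrides`.
#' @export
read_city_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown))
    stop("unknown config key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  needed <- c("latitude", "dwellings", "area_ha")
  missing <- setdiff(needed, names(cfg))
  if (length(missing))
    stop("config lacks required key(s): ", paste(missing, collapse = ", "))
  city_args <- cfg[intersect(names(cfg),
                             setdiff(names(formals(city_inputs)), ""))]
  city <- do.call(city_inputs, city_args)
  dd <- cfg$density_dependence
  if (!is.null(dd)) {
    dd_known <- c("variant", "juvenile_rule", "sterilization_preset",
                  "density_interpretation")
    bad <- setdiff(names(dd), dd_known)
    if (length(bad))
      stop("unknown density_dependence key(s): ", paste(bad, collapse = ", "))
  }
  ov <- cfg$overrides
  if (!is.null(ov)) {
    bad <- setdiff(names(ov), parameter_names())
    if (length(bad))
      stop("unknown override parameter(s): ", paste(bad, collapse = ", "))
  }
  list(city = city,
       name = if (is.null(cfg$name)) basename(path) else cfg$name,
       dd = dd,
       solver = cfg$solver,
       sensitivity = cfg$sensitivity,
       overrides = if (is.null(ov)) list() else ov)
}

config_to_params <- function(config) {
  dd <- config$dd
  build_parameter_set(
    config$city,
    dd_variant = if (!is.null(dd$variant)) dd$variant else "calibrated",
    juvenile_rule = if (!is.null(dd$juvenile_rule)) dd$juvenile_rule
                    else "sqrt_adult",
    sterilization_preset = if (!is.null(dd$sterilization_preset))
      dd$sterilization_preset else "table",
    density_interpretation = if (!is.null(dd$density_interpretation))
      dd$density_interpretation else "female",
    overrides = config$overrides
  )
}

#' Run the population model for a configured city
#'
#' Parameterizes the model from a configuration (path to a YAML file or the
#' list returned by [read_city_config()]), solves for the equilibrium, and
#' optionally computes the elasticity table. When `output_dir` is given,
#' writes `abundance.csv` (per stage and state, female and doubled both-sex
#' counts), `summary.json` (inputs, derived constants, convergence
#' diagnostics, totals), optionally `elasticity.csv`, and
#' `trajectory.csv` when `keep_trajectory = TRUE`.
#'
#' @param config Path to a config file or a parsed config list.
#' @param elasticity If `TRUE`, compute the elasticity table.
#' @param output_dir Directory for output files (created if needed);
#'   `NULL` writes nothing.
#' @param keep_trajectory Store/write the per-year trajectory.
#' @return A list with `params`, `equilibrium`, and `elasticity` (`NULL`
#'   unless requested), invisibly when writing outputs.
#' @export
run_city <- function(config, elasticity = FALSE, output_dir = NULL,
                     keep_trajectory = FALSE) {
  if (is.character(config)) config <- read_city_config(config)
  params <- config_to_params(config)
  solver <- config$solver
  max_iter <- if (!is.null(solver$max_iter)) solver$max_iter else 1200
  tol <- if (!is.null(solver$tol)) solver$tol else 1e-9
  eq <- solve_equilibrium(params, max_iter = max_iter, tol = tol,
                          keep_trajectory = keep_trajectory)
  elas <- NULL
  if (elasticity) {
    if (!eq$converged)
      stop("cannot compute elasticities: equilibrium not reached (",
           eq$diagnostic, ")")
    sens <- config$sensitivity
    method <- if (!is.null(sens$method)) sens$method else "finite-difference"
    delta <- if (!is.null(sens$delta)) sens$delta else 1e-3
    elas <- if (method == "implicit")
      elasticity_implicit(params, baseline = NULL)
    else elasticity_fd(params, delta = delta)
  }
  result <- list(name = config$name, params = params, equilibrium = eq,
                 elasticity = elas)
  if (!is.null(output_dir)) {
    write_run_outputs(result, output_dir)
    return(invisible(result))
  }
  result
}

write_run_outputs <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  eq <- result$equilibrium
  n <- as_population_vector(eq$n)
  abundance <- data.frame(
    stage = rep(CAT_STAGES, each = 4L),
    state = rep(CAT_STATES, 4L),
    females = n,
    both_sexes = 2 * n,
    stringsAsFactors = FALSE
  )
  utils::write.csv(abundance, file.path(output_dir, "abundance.csv"),
                   row.names = FALSE)
  p <- result$params
  summary <- list(
    name = result$name,
    inputs = list(latitude = p$city$latitude, dwellings = p$city$dwellings,
                  area_ha = p$city$area_ha,
                  freeroaming_density = p$city$freeroaming_density,
                  feral_density = p$city$feral_density),
    derived = list(season_days = p$season_days, litters = p$litters,
                   K_females = unclass(p$K)),
    density_dependence = p$dd[c("variant", "juvenile_rule",
                                "density_interpretation")],
    parameters = stats::setNames(
      lapply(parameter_names(), function(nm) p[[nm]]), parameter_names()),
    converged = eq$converged,
    iterations = eq$iterations,
    diagnostic = eq$diagnostic,
    female_totals = as.list(eq$female_totals),
    both_sex_totals = as.list(eq$totals)
  )
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(result$elasticity))
    utils::write.csv(result$elasticity,
                     file.path(output_dir, "elasticity.csv"),
                     row.names = FALSE)
  if (!is.null(eq$trajectory)) {
    traj <- as.data.frame(eq$trajectory)
    names(traj) <- paste(rep(CAT_STAGES, each = 4L), rep(CAT_STATES, 4L),
                         sep = ".")
    traj <- cbind(year = seq_len(nrow(traj)) - 1L, traj)
    utils::write.csv(traj, file.path(output_dir, "trajectory.csv"),
                     row.names = FALSE)
  }
  invisible(output_dir)
}

#' Sweep the published rate variants for a city
#'
#' Solves the model under each combination of density-dependence variant
#' (`calibrated`, `composite`, `per_hectare`) and unowned sterilization preset
#' (`table`, `text`), returning the equilibrium abundances of each run.
#' Useful for reproduction exercises where the published parameterizations
#' conflict.
#'
#' @param city A [city_inputs()] object.
#' @param overrides Passed to [build_parameter_set()].
#' @param max_iter,tol Solver settings.
#' @return Data frame with one row per variant combination: the both-sex
#'   equilibrium abundances (owned, shelter, free-roaming, feral, total) and
#'   the convergence flag.
#' @export
sweep_variants <- function(city, overrides = list(), max_iter = 1200,
                           tol = 1e-9) {
  grid <- expand.grid(variant = c("calibrated", "composite", "per_hectare"),
                      sterilization = c("table", "text"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- build_parameter_set(city, dd_variant = grid$variant[i],
                             sterilization_preset = grid$sterilization[i],
                             overrides = overrides)
    eq <- solve_equilibrium(p, max_iter = max_iter, tol = tol)
    data.frame(variant = grid$variant[i],
               sterilization = grid$sterilization[i],
               converged = eq$converged,
               owned = eq$totals[["owned"]],
               shelter = eq$totals[["shelter"]],
               freeroaming = eq$totals[["freeroaming"]],
               feral = eq$totals[["feral"]],
               total = eq$totals[["total"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
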