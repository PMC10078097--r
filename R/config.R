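#' Load a run configuration
#'
#' Reads a YAML configuration (grouped as in [default_params()]: `herd`,
#' `energetics`, `winter`, `pasture`, `econ`, `scenario`, `solver`), fills
#' unspecified entries with the package defaults, rejects unknown keys, and
#' validates all values with field-level messages.  An empty (or missing
#' content) file yields the full default configuration: baseline 10/80/10
#' winter probabilities, EUR 0.4/kg feed, 30 m2/day normal cratering area.
#'
#' @param path YAML file.
#' @return A `reindeer_params` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || length(raw) == 0) return(default_params())
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  # winter sub-vectors arrive as named lists from YAML; restore vectors
  raw <- lapply(raw, function(grp) {
    if (!is.list(grp)) return(grp)
    lapply(grp, function(v) if (is.list(v)) unlist(v) else v)
  })
  do.call(default_params, raw)
}

#' Save a run configuration
#'
#' Writes the full parameter set as YAML, such that
#' `load_config(save_config(p, f))` reproduces `p` (up to YAML numeric
#' precision).
#'
#' @param params a `reindeer_params`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  validate_params(params)
  out <- unclass(params)
  # named vectors must be written as YAML maps to keep their names
  out$winter$cratering_area <- as.list(out$winter$cratering_area)
  out$winter$energy_multiplier <- as.list(out$winter$energy_multiplier)
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' Write experiment results
#'
#' Serializes a named list of experiment outputs into a directory: per-year
#' trajectory CSVs for `herd_trajectory` objects, summary CSVs mirroring the
#' report-table schemas for single-winter experiments (steady-state EUR/yr;
#' first-year, subsequent, total undiscounted and total discounted deltas)
#' and for ensembles (one row per interest rate: constant-winter PV,
#' stochastic PV, loss in EUR and percent), plus a JSON run manifest with
#' the configuration hash and seeds.
#'
#' @param results named list whose elements are `herd_trajectory`,
#'   `single_winter_experiment`, `winter_ensemble` or data frame objects.
#' @param dir output directory (created if needed).
#' @param params the `reindeer_params` used for the run.
#' @param seeds named or unnamed vector of seeds used.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(results, dir, params = default_params(),
                          seeds = integer(0)) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir))
      stop("cannot create output directory: ", dir, call. = FALSE)
  }
  if (is.null(names(results)) || any(names(results) == ""))
    stop("'results' must be a fully named list", call. = FALSE)
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    path <- file.path(dir, paste0(nm, ".csv"))
    tab <- result_table(x)
    utils::write.csv(tab, path, row.names = FALSE)
    files <- c(files, path)
  }
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = rlang::hash(params),
    seeds = as.list(seeds),
    files = basename(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

result_table <- function(x) {
  if (inherits(x, "herd_trajectory")) return(x$years)
  if (inherits(x, "single_winter_experiment"))
    return(data.frame(
      label = x$label, interest_rate = x$r,
      steady_net_revenue = x$steady_net_revenue,
      first_year = x$first_year, first_year_pct = x$first_year_pct,
      subsequent = x$subsequent, subsequent_pct = x$subsequent_pct,
      total_undiscounted = x$total_undiscounted,
      total_undiscounted_pct = x$total_undiscounted_pct,
      total_discounted = x$total_discounted,
      total_discounted_pct = x$total_discounted_pct,
      herd_change_pct = x$herd_change_pct,
      lichen_change_pct = x$lichen_change_pct))
  if (inherits(x, "winter_ensemble"))
    return(data.frame(
      interest_rate = x$r, p_easy = x$probs$p_easy,
      p_normal = x$probs$p_normal, p_difficult = x$probs$p_difficult,
      reps = x$reps, horizon = x$horizon,
      pv_constant = x$pv_constant, pv_stochastic = x$pv_mean,
      loss = x$loss, loss_pct = x$loss_pct))
  if (inherits(x, "steady_state"))
    return(data.frame(
      interest_rate = x$r, net_revenue = x$net_revenue,
      lichen_biomass = x$lichen_biomass, herd_size = x$herd_size,
      calf_pct = x$calf_pct, male_calf_share = x$male_calf_share,
      female_calf_share = x$female_calf_share, pv100 = x$pv100))
  if (is.data.frame(x)) return(x)
  stop("cannot serialize result of class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

#' Read back a trajectory CSV
#'
#' @param path CSV written by [write_results()] for a trajectory.
#' @return Data frame of per-year results.
#' @export
read_trajectory <- function(path) utils::read.csv(path,
                                                  stringsAsFactors = FALSE)
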