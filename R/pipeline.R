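#' Analysis configuration
#'
#' Exactly one of `simulate` (a [panel_config()] or a list of its arguments)
#' or `paths` (a list with `panel`, `district_info`, optionally `case_points`
#' CSV paths) must be supplied.
#'
#' @param simulate Optional simulation configuration.
#' @param paths Optional list of input CSV paths.
#' @param scan Scan parameters: `max_pop_fraction`, `max_time_fraction`,
#'   `n_replicates`, `alpha`.
#' @param horizon Grey forecast horizon in years (default 3).
#' @param sr_breakpoints,ir_breaks Rank breakpoints (see [rate_table()]).
#' @param out_dir Output directory for [write_report()].
#' @param seed Master seed.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(simulate = NULL, paths = NULL,
                            scan = list(), horizon = 3L,
                            sr_breakpoints = c(0.580, 0.890, 1.270, 1.840, 2.500),
                            ir_breaks = c(-0.29, 0.61, 1.5),
                            out_dir = NULL, seed = 1L) {
  if (is.null(simulate) == is.null(paths))
    stop_domain("supply exactly one of `simulate` or `paths`")
  if (horizon < 1) stop_domain("horizon must be at least 1")
  scan_defaults <- list(max_pop_fraction = 0.5, max_time_fraction = 0.5,
                        n_replicates = 999L, alpha = 0.05)
  scan <- utils::modifyList(scan_defaults, scan)
  structure(list(simulate = simulate, paths = paths, scan = scan,
                 horizon = as.integer(horizon),
                 sr_breakpoints = sr_breakpoints, ir_breaks = ir_breaks,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML or JSON file
#'
#' The file mirrors the [analysis_config()] arguments; `simulate` holds
#' [panel_config()] fields.
#'
#' @param path Config file (`.yaml`, `.yml` or `.json`).
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_domain("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(cfg$simulate$cluster_spec))
    cfg$simulate$cluster_spec <- lapply(cfg$simulate$cluster_spec, unlist)
  do.call(analysis_config, cfg)
}

#' Load and validate the pipeline inputs
#'
#' Builds (by simulation) or reads (from CSV) the panel, district info and
#' case points, then checks referential integrity: positive populations,
#' non-negative integer admissions, no duplicated district-year cell, a
#' rectangular district-by-year frame, and every case point referring to an
#' existing district. All violations are collected and reported together.
#'
#' @param config An [analysis_config()].
#' @return List with `panel`, `district_info`, `case_points`, `violations`
#'   (character vector, empty when valid).
#' @export
load_and_validate <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (!inherits(sim, "panel_config")) {
      if (is.null(sim$seed)) sim$seed <- config$seed
      sim <- do.call(panel_config, sim)
    }
    sp <- generate_panel(sim)
    panel <- sp$records; dinfo <- sp$district_info; pts <- sp$case_points
  } else {
    panel <- read_panel_csv(config$paths$panel)
    dinfo <- read_district_info_csv(config$paths$district_info)
    pts <- if (!is.null(config$paths$case_points))
      read_case_points_csv(config$paths$case_points) else NULL
  }

  v <- character(0)
  bad_pop <- panel$population <= 0 | !is.finite(panel$population)
  if (any(bad_pop))
    v <- c(v, sprintf("non-positive population at (%s, %d)",
                      panel$district[bad_pop], panel$year[bad_pop]))
  bad_adm <- panel$admissions < 0 | panel$admissions != round(panel$admissions)
  if (any(bad_adm))
    v <- c(v, sprintf("invalid admissions at (%s, %d)",
                      panel$district[bad_adm], panel$year[bad_adm]))
  dup <- duplicated(panel[c("district", "year")])
  if (any(dup))
    v <- c(v, sprintf("duplicated district-year (%s, %d)",
                      panel$district[dup], panel$year[dup]))
  full <- expand.grid(district = unique(panel$district),
                      year = unique(panel$year), stringsAsFactors = FALSE)
  miss <- !paste(full$district, full$year) %in%
    paste(panel$district, panel$year)
  if (any(miss))
    v <- c(v, sprintf("missing cell (%s, %d)",
                      full$district[miss], full$year[miss]))
  unknown <- setdiff(unique(panel$district), dinfo$district)
  if (length(unknown))
    v <- c(v, paste0("district without info row: ", unknown))
  if (!is.null(pts)) {
    orphan <- !pts$district %in% dinfo$district
    if (any(orphan))
      v <- c(v, sprintf("case point %d references unknown district %s",
                        which(orphan), pts$district[orphan]))
  }
  list(panel = panel, district_info = dinfo, case_points = pts, violations = v)
}

#' Run the full surveillance analysis
#'
#' Orchestrates, in order: rate standardization and ranking, SR change
#' patterns, mean-center/ellipse trajectories of the case cloud and of the
#' population, space-time cluster detection, grey forecasting of rates and
#' admissions with validation grades, and per-hospital burden projection.
#' Deterministic given the config seed.
#'
#' @param config An [analysis_config()].
#' @return Object of class `analysis_report`: a named list of result tables
#'   plus run metadata.
#' @export
run_full_analysis <- function(config) {
  inputs <- load_and_validate(config)
  if (length(inputs$violations))
    stop_domain("input validation failed:\n  ",
                paste(inputs$violations, collapse = "\n  "))
  panel <- inputs$panel
  dinfo <- inputs$district_info
  pts <- inputs$case_points

  rates <- rate_table(panel, sr_breakpoints = config$sr_breakpoints,
                      ir_breaks = config$ir_breaks)
  changes <- sr_change_table(rates)

  spatial <- NULL
  if (!is.null(pts) && nrow(pts) > 0) {
    years <- sort(unique(pts$year))
    by_year <- split(pts, pts$year)
    case_mc <- center_trajectory(by_year)
    pop_by_year <- lapply(years, function(yr) {
      p <- merge(dinfo, panel[panel$year == yr, c("district", "population")],
                 by = "district")
      data.frame(x = p$x, y = p$y, weight = p$population)
    })
    names(pop_by_year) <- years
    pop_mc <- center_trajectory(pop_by_year)
    spatial <- list(case_centers = case_mc, population_centers = pop_mc,
                    ellipses = annual_ellipses(pts))
  }

  clusters <- detect_clusters(
    panel, dinfo,
    max_pop_fraction = config$scan$max_pop_fraction,
    max_time_fraction = config$scan$max_time_fraction,
    n_replicates = config$scan$n_replicates,
    alpha = config$scan$alpha, seed = sub_seed(config$seed, "pipeline_scan"))

  fc_ir <- grey_forecast_panel(panel, "ir", config$horizon)
  fc_adm <- grey_forecast_panel(panel, "admissions", config$horizon)
  hospitals <- stats::setNames(dinfo$hospitals, dinfo$district)
  fc <- fc_adm$forecasts
  burden_df <- data.frame(
    district = fc$district, year = fc$year,
    admissions_per_hospital = burden(
      stats::setNames(fc$value, fc$district),
      hospitals[fc$district]),
    stringsAsFactors = FALSE)
  rownames(burden_df) <- NULL

  structure(list(
    rates = rates, changes = changes, spatial = spatial, clusters = clusters,
    forecast_ir = fc_ir, forecast_admissions = fc_adm, burden = burden_df,
    metadata = list(seed = config$seed, horizon = config$horizon,
                    scan = config$scan,
                    n_districts = length(unique(panel$district)),
                    years = range(panel$year),
                    package_version = as.character(utils::packageVersion("citysurv")))
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d districts, %d-%d\n",
              x$metadata$n_districts, x$metadata$years[1], x$metadata$years[2]))
  cat(sprintf("  clusters detected: %d\n", nrow(x$clusters)))
  cat(sprintf("  grey degrees (admissions): %s\n",
              paste(sprintf("%s=%d", names(table(x$forecast_admissions$validation$degree)),
                            table(x$forecast_admissions$validation$degree)),
                    collapse = ", ")))
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits one CSV/GeoJSON file per report section plus a JSON manifest listing
#' every file with its MD5 checksum. Re-running the same configuration and
#' seed reproduces identical checksums.
#'
#' @param report An [run_full_analysis()] result.
#' @param out_dir Output directory (created if absent).
#' @return The manifest, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) round(v, 8))
    df
  }
  emit <- function(df, name) {
    write_csv_plain(fmt(df), file.path(out_dir, name))
    name
  }
  files <- c(
    emit(report$rates, "rates.csv"),
    emit(report$changes, "sr_changes.csv"),
    emit(as.data.frame(report$clusters), "clusters.csv"),
    emit(report$forecast_ir$forecasts, "forecast_ir.csv"),
    emit(report$forecast_ir$validation, "validation_ir.csv"),
    emit(report$forecast_admissions$forecasts, "forecast_admissions.csv"),
    emit(report$forecast_admissions$validation, "validation_admissions.csv"),
    emit(report$burden, "burden.csv")
  )
  if (!is.null(report$spatial)) {
    files <- c(files,
               emit(report$spatial$case_centers, "case_centers.csv"),
               emit(report$spatial$population_centers, "population_centers.csv"),
               emit(report$spatial$ellipses, "ellipses.csv"))
    write_ellipses_geojson(report$spatial$ellipses,
                           file.path(out_dir, "ellipses.geojson"))
    files <- c(files, "ellipses.geojson")
  }
  jsonlite::write_json(report$metadata, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, "metadata.json")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE)
  invisible(manifest)
}
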