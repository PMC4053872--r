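#' Configuration for a synthetic district panel
#'
#' Bundles and validates the parameters of the synthetic-data generator. The
#' defaults emulate a ten-district, ten-year urban study frame: district
#' populations spanning roughly 1e5 to 1e6 persons with steady growth, annual
#' admission counts that are Poisson around population times a rising baseline
#' rate (order 0.3 to 3 per 1,000 person-years), district centroids drifting
#' slowly northward, and an optional embedded space-time cluster.
#'
#' @param n_districts Number of districts (at least 2).
#' @param years Inclusive vector of consecutive study years (length at least 4,
#'   since the grey model needs four or more points).
#' @param base_populations Positive first-year population per district; recycled
#'   defaults span 1e5 to 1e6 on a log scale.
#' @param pop_growth_rate Annual multiplicative population growth rate
#'   (e.g. 0.04 for 4 percent per year).
#' @param centroid_drift Length-2 planar drift vector in map units per year
#'   applied to every district centroid.
#' @param baseline_rate First-year admission rate per person-year, one value
#'   per district (recycled).
#' @param rate_trend Multiplicative factor applied to the rate each year.
#' @param cluster_spec Optional list with elements `districts` (district ids),
#'   `years` (contiguous years within the study) and `multiplier` (rate
#'   multiplier, non-negative) defining an embedded space-time cluster.
#' @param dispersion Isotropic standard deviation (map units) of the case point
#'   cloud around each district's drifting centroid.
#' @param seed Master integer seed; every stochastic sub-operation derives its
#'   own stream from it.
#'
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(n_districts = 10L,
                         years = 2003:2012,
                         base_populations = NULL,
                         pop_growth_rate = 0.04,
                         centroid_drift = c(0, 150),
                         baseline_rate = NULL,
                         rate_trend = 1.08,
                         cluster_spec = NULL,
                         dispersion = 1500,
                         seed = 1L) {
  err <- function(field, msg) stop_domain(sprintf("invalid `%s`: %s", field, msg))

  if (!is.numeric(n_districts) || length(n_districts) != 1L || n_districts < 2)
    err("n_districts", "need at least 2 districts")
  n_districts <- as.integer(n_districts)
  years <- as.integer(years)
  if (length(years) < 4L || any(diff(years) != 1L))
    err("years", "need at least 4 consecutive years")
  if (is.null(base_populations))
    base_populations <- round(10^seq(5, 6, length.out = n_districts))
  base_populations <- rep_len(as.numeric(base_populations), n_districts)
  if (any(!is.finite(base_populations)) || any(base_populations <= 0))
    err("base_populations", "must be positive and finite")
  assert_scalar_number(pop_growth_rate, "pop_growth_rate", lower = -0.5, upper = 1)
  if (!is.numeric(centroid_drift) || length(centroid_drift) != 2L ||
      any(!is.finite(centroid_drift)))
    err("centroid_drift", "must be a finite length-2 vector")
  if (is.null(baseline_rate))
    baseline_rate <- seq(3e-4, 1.5e-3, length.out = n_districts)
  baseline_rate <- rep_len(as.numeric(baseline_rate), n_districts)
  if (any(!is.finite(baseline_rate)) || any(baseline_rate < 0))
    err("baseline_rate", "must be non-negative and finite")
  assert_scalar_number(rate_trend, "rate_trend", lower = 0)
  assert_scalar_number(dispersion, "dispersion", lower = 1e-9)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    err("seed", "must be a single integer")
  seed <- as.integer(seed)

  district_ids <- sprintf("D%02d", seq_len(n_districts))
  if (!is.null(cluster_spec)) {
    if (!is.list(cluster_spec) ||
        !all(c("districts", "years", "multiplier") %in% names(cluster_spec)))
      err("cluster_spec", "must be a list with districts, years, multiplier")
    if (!all(cluster_spec$districts %in% district_ids))
      err("cluster_spec", paste0("unknown district(s): ",
          paste(setdiff(cluster_spec$districts, district_ids), collapse = ", ")))
    if (!all(cluster_spec$years %in% years))
      err("cluster_spec", "cluster years outside the study period")
    if (!is.numeric(cluster_spec$multiplier) || cluster_spec$multiplier < 0)
      err("cluster_spec", "multiplier must be >= 0")
  }

  structure(
    list(n_districts = n_districts, district_ids = district_ids, years = years,
         base_populations = base_populations, pop_growth_rate = pop_growth_rate,
         centroid_drift = centroid_drift, baseline_rate = baseline_rate,
         rate_trend = rate_trend, cluster_spec = cluster_spec,
         dispersion = dispersion, seed = seed),
    class = "panel_config"
  )
}

## Deterministic, seeded district geometry: a jittered 2-row grid spanning an
## elongated east-west city (~45 x 20 km), in meters.
district_centroids <- function(config) {
  n <- config$n_districts
  cols <- ceiling(n / 2)
  gx <- rep(seq(0, 45000, length.out = cols), each = 2)[seq_len(n)]
  gy <- rep(c(5000, 15000), length.out = n)
  jit <- withr::with_seed(sub_seed(config$seed, "centroids"), {
    matrix(stats::runif(2 * n, -2000, 2000), ncol = 2)
  })
  data.frame(district = config$district_ids,
             x = gx + jit[, 1], y = gy + jit[, 2],
             stringsAsFactors = FALSE)
}

## Expected admissions per cell under the configured log-linear model.
cell_means <- function(config) {
  t_idx <- config$years - config$years[1]
  grid <- expand.grid(district = seq_len(config$n_districts),
                      year_idx = seq_along(config$years))
  pop <- config$base_populations[grid$district] *
    (1 + config$pop_growth_rate)^t_idx[grid$year_idx]
  rate <- config$baseline_rate[grid$district] *
    config$rate_trend^t_idx[grid$year_idx]
  mult <- rep(1, nrow(grid))
  cs <- config$cluster_spec
  if (!is.null(cs)) {
    in_win <- config$district_ids[grid$district] %in% cs$districts &
      config$years[grid$year_idx] %in% cs$years
    mult[in_win] <- cs$multiplier
  }
  data.frame(district = config$district_ids[grid$district],
             year = config$years[grid$year_idx],
             population = round(pop), mean_admissions = pop * rate * mult,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic district-year panel
#'
#' Draws annual admission counts for every district-year cell from a Poisson
#' distribution with mean `population x baseline_rate x rate_trend^(t - t0)`,
#' scaled by the cluster multiplier inside an embedded cluster window, if one
#' is configured. Populations grow geometrically. District centroids, hospital
#' counts and (optionally) per-case point locations are generated alongside.
#' Identical configurations (including the seed) give byte-identical panels.
#'
#' @param config A [panel_config()].
#' @param case_points Logical; also simulate case point locations (default TRUE).
#' @return An object of class `synthetic_panel`: a list with `records`
#'   (data.frame `district, year, population, admissions`), `district_info`
#'   (data.frame `district, x, y, hospitals`), `case_points` (data.frame
#'   `district, year, x, y` or NULL) and the generating `config`.
#' @export
generate_panel <- function(config, case_points = TRUE) {
  if (!inherits(config, "panel_config")) config <- do.call(panel_config, config)
  means <- cell_means(config)
  admissions <- withr::with_seed(sub_seed(config$seed, "admissions"), {
    stats::rpois(nrow(means), means$mean_admissions)
  })
  records <- data.frame(district = means$district, year = means$year,
                        population = means$population, admissions = admissions,
                        stringsAsFactors = FALSE)
  centroids <- district_centroids(config)
  hospitals <- pmax(1L, as.integer(round(config$base_populations / 7e4)))
  district_info <- data.frame(district = centroids$district,
                              x = centroids$x, y = centroids$y,
                              hospitals = hospitals, stringsAsFactors = FALSE)
  panel <- structure(
    list(records = records, district_info = district_info,
         case_points = NULL, config = config),
    class = "synthetic_panel"
  )
  if (case_points) {
    panel$case_points <- generate_case_points(panel, config$dispersion,
                                              sub_seed(config$seed, "points"))
  }
  panel
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("<synthetic_panel> %d districts x %d years, %d admissions%s\n",
              length(unique(x$records$district)),
              length(unique(x$records$year)),
              sum(x$records$admissions),
              if (is.null(x$config$cluster_spec)) "" else ", embedded cluster"))
  invisible(x)
}

## Centroid of a district in a given year, after linear drift.
drifted_centroid <- function(panel, district, year) {
  info <- panel$district_info[panel$district_info$district == district, ]
  dt <- year - panel$config$years[1]
  c(info$x + panel$config$centroid_drift[1] * dt,
    info$y + panel$config$centroid_drift[2] * dt)
}

#' Simulate case point locations for a panel
#'
#' For each district-year cell, draws exactly `admissions` points from an
#' isotropic bivariate normal (standard deviation `dispersion` on each axis)
#' centered on the district's year-specific (drifting) centroid.
#'
#' @param panel A `synthetic_panel`.
#' @param dispersion Positive isotropic standard deviation in map units.
#' @param seed Integer seed.
#' @return A data.frame `district, year, x, y` with one row per admission.
#' @export
generate_case_points <- function(panel, dispersion = panel$config$dispersion,
                                 seed = panel$config$seed) {
  assert_scalar_number(dispersion, "dispersion", lower = 1e-12)
  rec <- panel$records
  total <- sum(rec$admissions)
  withr::with_seed(sub_seed(seed, "case_points"), {
    out <- vector("list", nrow(rec))
    for (i in seq_len(nrow(rec))) {
      m <- rec$admissions[i]
      if (m == 0) next
      ctr <- drifted_centroid(panel, rec$district[i], rec$year[i])
      out[[i]] <- data.frame(district = rec$district[i], year = rec$year[i],
                             x = ctr[1] + stats::rnorm(m, sd = dispersion),
                             y = ctr[2] + stats::rnorm(m, sd = dispersion),
                             stringsAsFactors = FALSE)
    }
    pts <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(pts)) {
      pts <- data.frame(district = character(), year = integer(),
                        x = numeric(), y = numeric(), stringsAsFactors = FALSE)
    }
    rownames(pts) <- NULL
    stopifnot(nrow(pts) == total)
    pts
  })
}

#' Inject a space-time cluster into an existing panel
#'
#' Redraws the admission counts inside the given district-by-year window from a
#' Poisson distribution whose mean is the configured cell mean scaled by
#' `multiplier`; all other cells are untouched. Case points for the affected
#' cells are regenerated so that point counts stay equal to admissions.
#'
#' @param panel A `synthetic_panel`.
#' @param districts District ids forming the cluster base.
#' @param year_interval Contiguous years forming the cluster height.
#' @param multiplier Non-negative rate multiplier.
#' @param seed Integer seed for the redraw.
#' @return The modified `synthetic_panel`.
#' @export
inject_cluster <- function(panel, districts, year_interval, multiplier, seed) {
  stopifnot(inherits(panel, "synthetic_panel"))
  unknown_d <- setdiff(districts, panel$district_info$district)
  if (length(unknown_d))
    stop_domain("unknown district(s): ", paste(unknown_d, collapse = ", "))
  unknown_y <- setdiff(year_interval, panel$config$years)
  if (length(unknown_y))
    stop_domain("unknown year(s): ", paste(unknown_y, collapse = ", "))
  if (!is.numeric(multiplier) || multiplier < 0)
    stop_domain("multiplier must be >= 0")

  base_cfg <- panel$config
  base_cfg$cluster_spec <- NULL          # means without any configured cluster
  means <- cell_means(base_cfg)
  idx <- which(panel$records$district %in% districts &
               panel$records$year %in% year_interval)
  new_counts <- withr::with_seed(sub_seed(seed, "inject"), {
    stats::rpois(length(idx), means$mean_admissions[idx] * multiplier)
  })
  panel$records$admissions[idx] <- new_counts
  panel$config$cluster_spec <- list(districts = districts,
                                    years = year_interval,
                                    multiplier = multiplier)
  if (!is.null(panel$case_points)) {
    keep <- !(panel$case_points$district %in% districts &
              panel$case_points$year %in% year_interval)
    kept <- panel$case_points[keep, , drop = FALSE]
    sub <- panel
    sub$records <- panel$records[idx, , drop = FALSE]
    sub$case_points <- NULL
    new_pts <- generate_case_points(sub, panel$config$dispersion,
                                    sub_seed(seed, "inject_points"))
    panel$case_points <- rbind(kept, new_pts)
    rownames(panel$case_points) <- NULL
  }
  panel
}
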